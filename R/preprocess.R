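#' Average ambient background frames
#'
#' Pointwise arithmetic mean of a set of background frames sharing one
#' axis, as measured before each sample (5 exposures, then averaged).
#'
#' @param frames A [raman_spectra] tibble of background frames.
#' @return A [raman_spectra] tibble holding one averaged background
#'   spectrum (`frame_kind = "background"`).
#' @export
average_background <- function(frames) {
  if (nrow(frames) == 0) rlang::abort("no background frames to average")
  meta <- spectra_meta(frames)
  avg <- frames |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$wavenumber) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop") |>
    dplyr::mutate(
      spectrum_id = paste0(meta$sample_id[1], "_bgavg"),
      patient_id = meta$patient_id[1], sample_id = meta$sample_id[1],
      replicate = 1L, tissue_class = meta$tissue_class[1],
      frame_kind = "background"
    )
  raman_spectra(avg, provenance = c(provenance(frames),
                                    sprintf("average_background: %d frames", nrow(meta))))
}

#' Subtract a background spectrum pointwise
#'
#' Removes ambient illumination: the averaged background is subtracted
#' from each measurement on the identical axis. Negative residuals
#' (noise) are preserved.
#'
#' @param x A [raman_spectra] tibble of measurement spectra.
#' @param bg A [raman_spectra] tibble with exactly one spectrum.
#' @return `x` with `intensity` replaced by the difference.
#' @export
subtract_background <- function(x, bg) {
  if (dplyr::n_distinct(bg$spectrum_id) != 1) {
    rlang::abort("bg must contain exactly one spectrum")
  }
  ax <- spectra_axis(x)
  if (!identical(spectra_axis(bg), ax)) rlang::abort("axis mismatch between x and bg")
  bgv <- dplyr::arrange(tibble::as_tibble(bg), .data$wavenumber)$intensity
  out <- tibble::as_tibble(x) |>
    dplyr::group_by(.data$spectrum_id) |>
    dplyr::arrange(.data$wavenumber, .by_group = TRUE) |>
    dplyr::mutate(intensity = .data$intensity - bgv) |>
    dplyr::ungroup()
  restore_spectra(out, x, "subtract_background")
}

#' Exclude overexposed spectra
#'
#' Drops any measurement whose maximum raw intensity exceeds
#' `threshold` x `dynamic_range_max` (default 90% of the detector
#' dynamic range), to avoid errors from oversaturation.
#'
#' @param x A [raman_spectra] tibble (raw intensities).
#' @param dynamic_range_max Detector ceiling (counts).
#' @param threshold Fraction of the ceiling above which a spectrum is
#'   discarded.
#' @return `x` without the saturated spectra; the excluded ids are
#'   recorded in the provenance log and in the `excluded` attribute.
#' @export
exclude_saturated <- function(x, dynamic_range_max, threshold = 0.90) {
  stopifnot(dynamic_range_max > 0, threshold > 0, threshold <= 1)
  peak <- tibble::as_tibble(x) |>
    dplyr::group_by(.data$spectrum_id) |>
    dplyr::summarise(mx = max(.data$intensity), .groups = "drop")
  drop_ids <- peak$spectrum_id[peak$mx > threshold * dynamic_range_max]
  out <- dplyr::filter(tibble::as_tibble(x), !.data$spectrum_id %in% drop_ids)
  if (nrow(out) == 0) rlang::warn("all spectra excluded as saturated")
  out <- restore_spectra(out, x,
                         sprintf("exclude_saturated(>%g%% of %g): removed %d [%s]",
                                 100 * threshold, dynamic_range_max,
                                 length(drop_ids), paste(drop_ids, collapse = ", ")))
  attr(out, "excluded") <- drop_ids
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (default 15-point window,
#' 3rd-order polynomial) applied to every spectrum. Edges are handled
#' by polynomial fits on the truncated window, so any polynomial of
#' degree <= `order` is reproduced exactly over the whole axis.
#'
#' @param x A [raman_spectra] tibble.
#' @param window Odd window length in points.
#' @param order Polynomial order, < `window`.
#' @return Smoothed [raman_spectra] tibble.
#' @export
savitzky_golay <- function(x, window = 15, order = 3) {
  stopifnot(window %% 2 == 1, window > order)
  ax <- spectra_axis(x)
  if (window >= length(ax)) rlang::abort("window must be shorter than the axis")
  m <- spectra_matrix(x)
  sm <- t(apply(m, 1, signal::sgolayfilt, p = order, n = window))
  matrix_to_spectra(sm, ax, spectra_meta(x),
                    provenance = c(provenance(x),
                                   sprintf("savitzky_golay(window=%d, order=%d)",
                                           window, order)))
}

#' Crop spectra to a wavenumber interval
#'
#' Keeps points with `lo <= wavenumber <= hi` (closed interval); the
#' default 900-1800 cm^-1 is where the primary Raman peaks for brain
#' tumor identification lie.
#'
#' @param x A [raman_spectra] tibble.
#' @param lo,hi Interval bounds (cm^-1).
#' @return Cropped [raman_spectra] tibble.
#' @export
crop_range <- function(x, lo = 900, hi = 1800) {
  stopifnot(lo < hi)
  out <- dplyr::filter(tibble::as_tibble(x),
                       .data$wavenumber >= lo, .data$wavenumber <= hi)
  if (nrow(out) == 0) rlang::abort("crop interval contains no axis points")
  restore_spectra(out, x, sprintf("crop_range(%g, %g)", lo, hi))
}

#' Normalize spectra by integral intensity
#'
#' Divides each spectrum by its trapezoidal integral over the current
#' axis, so composition rather than overall brightness drives
#' comparisons. After normalization every spectrum integrates to 1;
#' the operation is idempotent and scale-invariant.
#'
#' @param x A [raman_spectra] tibble.
#' @return Normalized [raman_spectra] tibble.
#' @export
normalize_integral <- function(x) {
  out <- tibble::as_tibble(x) |>
    dplyr::group_by(.data$spectrum_id) |>
    dplyr::arrange(.data$wavenumber, .by_group = TRUE) |>
    dplyr::mutate(.integral = trapz_integral(.data$wavenumber, .data$intensity)) |>
    dplyr::ungroup()
  bad <- unique(out$spectrum_id[out$.integral <= 0])
  if (length(bad) > 0) {
    rlang::abort(paste0("non-positive integral intensity (failed baseline removal?) for: ",
                        paste(bad, collapse = ", ")))
  }
  out <- dplyr::mutate(out, intensity = .data$intensity / .data$.integral,
                       .integral = NULL)
  restore_spectra(out, x, "normalize_integral")
}

#' Preprocessing configuration
#'
#' @param saturation_threshold Fraction of the dynamic range above
#'   which a raw spectrum is excluded.
#' @param sg_window,sg_order Savitzky-Golay window (points, odd) and
#'   polynomial order.
#' @param crop_lo,crop_hi Analysis interval (cm^-1).
#' @param baseline A [morlet_fit_config] for fluorescence removal.
#' @param clip_negative Clip negative intensities to zero after
#'   baseline removal (off by default; negatives are plain noise).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(saturation_threshold = 0.90, sg_window = 15,
                              sg_order = 3, crop_lo = 900, crop_hi = 1800,
                              baseline = morlet_fit_config(),
                              clip_negative = FALSE) {
  stopifnot(sg_window %% 2 == 1, sg_window > sg_order, crop_lo < crop_hi,
            saturation_threshold > 0, saturation_threshold <= 1)
  structure(list(saturation_threshold = saturation_threshold,
                 sg_window = sg_window, sg_order = sg_order,
                 crop_lo = crop_lo, crop_hi = crop_hi, baseline = baseline,
                 clip_negative = clip_negative),
            class = "preprocess_config")
}

#' Full preprocessing chain
#'
#' Applies, in order: saturation exclusion, per-sample background
#' averaging and subtraction, Savitzky-Golay smoothing, Morlet-sum
#' fluorescence baseline fitting and removal, cropping to the analysis
#' interval, and integral-intensity normalization. The chain is a pure
#' function of its inputs and configuration; every step is appended to
#' the provenance log with its parameters.
#'
#' @param measurements A [raman_spectra] tibble of raw measurement
#'   frames.
#' @param backgrounds A [raman_spectra] tibble of ambient background
#'   frames, matched to measurements by `sample_id`.
#' @param config A [preprocess_config].
#' @param dynamic_range_max Detector ceiling used for saturation
#'   exclusion.
#' @return A preprocessed [raman_spectra] tibble of measurement
#'   spectra on the cropped axis, each with unit integral. Fitted
#'   baseline models are attached as the `baselines` attribute (one
#'   [morlet_baseline] per spectrum).
#' @export
preprocess_pipeline <- function(measurements, backgrounds,
                                config = preprocess_config(),
                                dynamic_range_max = 65535) {
  x <- exclude_saturated(measurements, dynamic_range_max,
                         config$saturation_threshold)
  excluded <- attr(x, "excluded")

  # per-sample background average, subtracted from that sample's frames
  bg_split <- split(tibble::as_tibble(backgrounds), backgrounds$sample_id)
  parts <- tibble::as_tibble(x) |> dplyr::group_split(.data$sample_id)
  sub <- purrr::map_dfr(parts, function(part) {
    sid <- part$sample_id[1]
    if (!sid %in% names(bg_split)) {
      rlang::abort(paste0("no background frames for sample ", sid))
    }
    bgavg <- average_background(raman_spectra(bg_split[[sid]]))
    tibble::as_tibble(subtract_background(raman_spectra(part), bgavg))
  })
  x <- restore_spectra(sub, x, "subtract_background(per-sample average)")

  x <- savitzky_golay(x, config$sg_window, config$sg_order)

  m <- spectra_matrix(x)
  ax <- spectra_axis(x)
  models <- lapply(seq_len(nrow(m)), function(i) {
    fit_morlet_baseline(m[i, ], ax, config$baseline)
  })
  names(models) <- rownames(m)
  for (i in seq_len(nrow(m))) {
    m[i, ] <- m[i, ] - predict_morlet(models[[i]], ax)
  }
  if (config$clip_negative) m <- pmax(m, 0)
  x <- matrix_to_spectra(m, ax, spectra_meta(x),
                         provenance = c(provenance(x),
                                        sprintf("remove_baseline(morlet, K=%d)",
                                                config$baseline$n_wavelets)))

  x <- crop_range(x, config$crop_lo, config$crop_hi)
  x <- normalize_integral(x)
  attr(x, "excluded") <- excluded
  attr(x, "baselines") <- models
  x
}
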