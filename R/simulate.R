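#' Default component profiles for the synthetic generator
#'
#' One row per Raman peak: component name, peak center (cm^-1), full
#' width at half maximum, class mean amplitudes (detector counts) for
#' normal white matter, tumor edge and tumor center, and the
#' between-sample / within-sample (replicate) coefficients of
#' variation. Replicates are acquired at different probe angles on
#' heterogeneous tissue, so within-sample (replicate) variability is
#' set at or above between-sample variability. Class contrasts follow
#' the biochemistry of glioma
#' tissue: cholesterol and carotenoids decrease toward the tumor
#' center, hemoglobin (blood filling) and water increase, and
#' cholesterol is elevated at the infiltration edge near 960 and
#' 1228 cm^-1. Peaks with identical amplitudes across classes
#' (phenylalanine, CH2 lipid deformation, amide bands) carry no class
#' signal but large between-sample variability, emulating the dense
#' nuisance structure of real tissue spectra.
#'
#' @return Tibble with columns `component`, `peak_center`, `fwhm`,
#'   `amp_normal`, `amp_edge`, `amp_center`, `between_sample_cv`,
#'   `within_sample_cv`.
#' @export
default_component_profiles <- function() {
  tibble::tribble(
    ~component,      ~peak_center, ~fwhm, ~amp_normal, ~amp_edge, ~amp_center, ~between_sample_cv, ~within_sample_cv,
    "cholesterol",    926,  18, 1500, 1400,  900, 0.10, 0.20,
    "cholesterol",    960,  18, 1200, 1500,  800, 0.10, 0.20,
    "cholesterol",   1228,  18, 1000, 1300,  700, 0.10, 0.20,
    "phospholipid",  1066,  18,  900,  900,  900, 0.10, 0.20,
    "protein",       1097,  18,  800,  900, 1100, 0.10, 0.20,
    "protein",       1178,  18, 1000, 1000, 1000, 0.10, 0.20,
    "carotenoid",    1157,  18, 1400, 1100,  600, 0.10, 0.20,
    "carotenoid",    1521,  18, 1300, 1000,  500, 0.10, 0.20,
    "hemoglobin",    1552,  18,  700, 1100, 1600, 0.10, 0.20,
    "water",         1640,  24,  800, 1000, 1400, 0.10, 0.20,
    "amide_i",       1655,  24, 1500, 1500, 1500, 0.15, 0.30,
    "amide_iii",     1255,  20, 1100, 1100, 1100, 0.15, 0.30,
    "phenylalanine", 1003,  14, 1800, 1800, 1800, 0.15, 0.30,
    "lipid_ch2",     1445,  20, 2500, 2500, 2500, 0.15, 0.30,
    "ch_stretch",    2930,  40, 3000, 3000, 3000, 0.15, 0.30
  )
}

#' Configuration for the synthetic Raman dataset generator
#'
#' Defaults emulate the study design the package targets: a 2050-point
#' axis on 127-2830 cm^-1, 3/3/4 samples for normal / tumor edge /
#' tumor center, 5 measurement replicates and 5 ambient background
#' frames per sample, an intense smooth fluorescence continuum, slow
#' ambient drift, i.i.d. detector noise on a 16-bit dynamic range, and
#' occasional overexposed (saturated) replicates.
#'
#' @param n_points,axis_lo,axis_hi Evenly spaced wavenumber axis.
#' @param n_samples Named integer vector of samples per class.
#' @param replicates Measurement replicates per sample.
#' @param n_background Background frames per sample.
#' @param components Component profile table, see
#'   [default_component_profiles].
#' @param fluor_n_lobes,fluor_amplitude,fluor_smoothness Fluorescence
#'   continuum: number of broad Gaussian lobes, amplitude scale
#'   (counts) and lobe width scale (cm^-1; must stay well above peak
#'   widths so the continuum cannot be confused with Raman lines).
#' @param fluor_replicate_cv Lognormal CV of the per-replicate
#'   fluorescence amplitude (tissue repositioning between exposures).
#' @param ambient_level,ambient_drift Ambient background level
#'   (counts) and relative slope of its slow drift across the axis.
#' @param gain_drift_cv Standard deviation of the per-replicate
#'   smooth spectral gain modulation (relative units). Samples are
#'   measured repeatedly at varying probe angles, which tilts the
#'   collected spectrum by a few percent across the axis; modeled as
#'   a random low-order Legendre gain applied to the tissue signal
#'   (fluorescence + peaks).
#' @param noise_sd Detector noise standard deviation (counts).
#' @param dynamic_range_max Saturation ceiling (counts).
#' @param saturation_fraction Probability that a measurement replicate
#'   is overexposed (driven to the ceiling).
#' @param exact_saturated Optional named integer vector (per class) of
#'   exactly how many replicates to overexpose; overrides
#'   `saturation_fraction` when given. `c(normal = 1, edge = 0,
#'   center = 1)` reproduces a 14/15/19 post-exclusion design from the
#'   default 15/15/20.
#' @param seed Integer seed; one dataset per seed, bit-reproducible.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_points = 2050, axis_lo = 127, axis_hi = 2830,
                             n_samples = c(normal = 3, edge = 3, center = 4),
                             replicates = 5, n_background = 5,
                             components = default_component_profiles(),
                             fluor_n_lobes = 3, fluor_amplitude = 14000,
                             fluor_smoothness = 500, fluor_replicate_cv = 0.15,
                             gain_drift_cv = 0.05,
                             ambient_level = 500, ambient_drift = 0.10,
                             noise_sd = 120, dynamic_range_max = 65535,
                             saturation_fraction = 0.05,
                             exact_saturated = NULL, seed = 1) {
  stopifnot(n_points >= 2, axis_lo < axis_hi, replicates >= 1,
            fluor_amplitude >= 0, fluor_smoothness > 0, ambient_level >= 0,
            gain_drift_cv >= 0, noise_sd >= 0, dynamic_range_max > 0,
            saturation_fraction >= 0, saturation_fraction <= 1)
  if (!all(tissue_classes() %in% names(n_samples))) {
    rlang::abort("n_samples must be named with normal, edge, center")
  }
  components <- tibble::as_tibble(components)
  if (any(components$between_sample_cv < 0) || any(components$within_sample_cv < 0)) {
    rlang::abort("component CVs must be >= 0")
  }
  if (fluor_amplitude > 0 && fluor_smoothness < 3 * max(components$fwhm)) {
    rlang::abort("fluor_smoothness must be >= 3x the widest component peak")
  }
  structure(list(
    n_points = n_points, axis_lo = axis_lo, axis_hi = axis_hi,
    n_samples = n_samples[tissue_classes()], replicates = replicates,
    n_background = n_background, components = components,
    fluor_n_lobes = fluor_n_lobes, fluor_amplitude = fluor_amplitude,
    fluor_smoothness = fluor_smoothness, fluor_replicate_cv = fluor_replicate_cv,
    gain_drift_cv = gain_drift_cv,
    ambient_level = ambient_level, ambient_drift = ambient_drift,
    noise_sd = noise_sd, dynamic_range_max = dynamic_range_max,
    saturation_fraction = saturation_fraction,
    exact_saturated = exact_saturated, seed = seed
  ), class = "generator_config")
}

#' Paper-like study design
#'
#' The default generator configuration with exactly one overexposed
#' replicate in the normal class and one in the tumor center, so that
#' saturation exclusion leaves 14/15/19 measurement spectra.
#'
#' @param ... Overrides passed to [generator_config].
#' @return A `generator_config`.
#' @export
study_design_config <- function(...) {
  generator_config(exact_saturated = c(normal = 1, edge = 0, center = 1), ...)
}

#' Rescale the class contrasts of a component profile table
#'
#' Moves each peak's class amplitudes toward (factor < 1) or away from
#' (factor > 1) their across-class mean; `factor = 0` removes all
#' class signal (chance-level data), `factor = 1` is the identity.
#'
#' @param components Profile tibble (see [default_component_profiles]).
#' @param factor Non-negative contrast multiplier.
#' @return Profile tibble with rescaled amplitudes.
#' @export
scale_class_contrast <- function(components, factor) {
  stopifnot(factor >= 0)
  amp <- as.matrix(components[, c("amp_normal", "amp_edge", "amp_center")])
  mid <- rowMeans(amp)
  amp <- mid + factor * (amp - mid)
  components$amp_normal <- pmax(amp[, 1], 0)
  components$amp_edge <- pmax(amp[, 2], 0)
  components$amp_center <- pmax(amp[, 3], 0)
  components
}

#' Draw a smooth fluorescence continuum
#'
#' Sum of `n_lobes` broad Gaussian lobes with widths at or above the
#' smoothness scale, giving a non-negative curve far smoother than any
#' Raman line. Consumes the current RNG state.
#'
#' @param axis Wavenumber axis (cm^-1).
#' @param n_lobes Number of lobes.
#' @param amplitude Amplitude scale (counts); 0 gives the zero curve.
#' @param smoothness Lower bound on lobe standard deviation (cm^-1).
#' @param max_peak_width Widest Raman peak FWHM the curve must stay
#'   distinguishable from; `smoothness` below 3x this is an error.
#' @return Numeric vector over `axis`.
#' @export
generate_fluorescence <- function(axis, n_lobes = 3, amplitude = 20000,
                                  smoothness = 500, max_peak_width = 40) {
  if (amplitude == 0) return(numeric(length(axis)))
  if (smoothness < 3 * max_peak_width) {
    rlang::abort("fluorescence smoothness must be >= 3x the widest peak")
  }
  span <- diff(range(axis))
  centers <- stats::runif(n_lobes, min(axis) + 0.1 * span, max(axis) - 0.1 * span)
  widths <- stats::runif(n_lobes, smoothness, 1.8 * smoothness)
  amps <- amplitude * stats::runif(n_lobes, 0.4, 1)
  curve <- numeric(length(axis))
  for (k in seq_len(n_lobes)) {
    curve <- curve + amps[k] * exp(-((axis - centers[k]) / widths[k])^2 / 2)
  }
  curve
}

# lognormal multiplier with unit mean and given coefficient(s) of variation
lognorm_factor <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  out <- exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  out[rep_len(cv == 0, n)] <- 1
  out
}

#' Generate a labeled synthetic Raman dataset with ground truth
#'
#' Builds measurement spectra as ambient background + fluorescence
#' continuum + Gaussian component peaks + i.i.d. detector noise,
#' clipped to `[0, dynamic_range_max]`, plus ambient-only background
#' frames per sample. Amplitudes vary lognormally between samples and
#' between replicates; overexposed replicates are rescaled to the
#' ceiling. Independent RNG sub-streams (design, amplitudes,
#' fluorescence, ambient, noise, saturation) are derived from the seed
#' so that, e.g., changing the noise level does not reshuffle the
#' sampling design.
#'
#' @param config A [generator_config].
#' @return List with `spectra` (a [raman_spectra] tibble of
#'   measurement and background frames) and `truth`, a list holding
#'   per-spectrum metadata with saturation flags, true per-replicate
#'   component amplitudes, the true fluorescence and ambient curves
#'   (matrices, rows = measurement spectra), and
#'   `discriminative_bands` — the peak intervals whose class mean
#'   amplitudes differ.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  axis <- seq(config$axis_lo, config$axis_hi, length.out = config$n_points)
  comp <- config$components
  classes <- tissue_classes()

  # design: sample/patient layout (deterministic), per-replicate saturation flags
  design <- purrr::map_dfr(classes, function(cl) {
    tibble::tibble(
      tissue_class = cl,
      sample_idx = seq_len(config$n_samples[[cl]])
    )
  })
  design$sample_id <- sprintf("%s_s%d", design$tissue_class, design$sample_idx)
  design$patient_id <- default_patient_map()[design$sample_id]

  reps <- design[rep(seq_len(nrow(design)), each = config$replicates), ]
  reps$replicate <- rep(seq_len(config$replicates), times = nrow(design))
  reps$spectrum_id <- sprintf("%s_r%d", reps$sample_id, reps$replicate)

  reps <- withr::with_seed(sub_seed(config$seed, "saturation"), {
    if (!is.null(config$exact_saturated)) {
      reps$saturated <- FALSE
      for (cl in classes) {
        k <- config$exact_saturated[[cl]] %||% 0L
        if (k > 0) {
          idx <- which(reps$tissue_class == cl)
          reps$saturated[sample(idx, k)] <- TRUE
        }
      }
    } else {
      reps$saturated <- stats::runif(nrow(reps)) < config$saturation_fraction
    }
    reps
  })
  if (mean(reps$saturated) > 0.5) {
    rlang::warn("more than half of the replicates are saturated")
  }

  # per-sample, per-replicate component amplitudes
  amp_cols <- c(normal = "amp_normal", edge = "amp_edge", center = "amp_center")
  n_peak <- nrow(comp)
  amp_tbl <- withr::with_seed(sub_seed(config$seed, "amplitude"), {
    purrr::map_dfr(seq_len(nrow(design)), function(i) {
      cl <- design$tissue_class[i]
      base <- comp[[amp_cols[[cl]]]] *
        lognorm_factor(n_peak, comp$between_sample_cv)
      purrr::map_dfr(seq_len(config$replicates), function(r) {
        tibble::tibble(
          spectrum_id = sprintf("%s_r%d", design$sample_id[i], r),
          component = comp$component, peak_center = comp$peak_center,
          fwhm = comp$fwhm,
          amplitude = base * lognorm_factor(n_peak, comp$within_sample_cv)
        )
      })
    })
  })

  # per-sample fluorescence lobes, per-replicate amplitude jitter
  fluor_sample <- withr::with_seed(sub_seed(config$seed, "fluorescence"), {
    lapply(seq_len(nrow(design)), function(i) {
      generate_fluorescence(axis, config$fluor_n_lobes, config$fluor_amplitude,
                            config$fluor_smoothness,
                            max_peak_width = max(comp$fwhm))
    })
  })
  fluor_jitter <- withr::with_seed(sub_seed(config$seed, "fluorescence") + 1L, {
    lognorm_factor(nrow(reps), config$fluor_replicate_cv)
  })

  # per-sample ambient background (level + slow linear drift)
  ambient_sample <- withr::with_seed(sub_seed(config$seed, "ambient"), {
    lapply(seq_len(nrow(design)), function(i) {
      slope <- stats::runif(1, -config$ambient_drift, config$ambient_drift)
      config$ambient_level *
        (1 + slope * (axis - mean(axis)) / diff(range(axis)))
    })
  })

  # per-replicate smooth gain tilt (probe angle / focus changes)
  tgrid <- (axis - mean(axis)) / (diff(range(axis)) / 2)
  gain_coef <- withr::with_seed(sub_seed(config$seed, "gain"), {
    matrix(stats::rnorm(2 * n_meas_planned(design, config), 0, config$gain_drift_cv),
           ncol = 2)
  })

  sigma <- comp$fwhm / (2 * sqrt(2 * log(2)))
  peak_basis <- exp(-outer(axis, comp$peak_center, "-")^2 /
                      matrix(2 * sigma^2, length(axis), n_peak, byrow = TRUE))

  n_meas <- nrow(reps)
  meas <- matrix(0, n_meas, length(axis), dimnames = list(reps$spectrum_id, NULL))
  fluor_true <- meas
  ambient_true <- meas
  sample_of_rep <- match(reps$sample_id, design$sample_id)
  amp_wide <- matrix(amp_tbl$amplitude, nrow = n_meas, ncol = n_peak, byrow = TRUE)
  rownames(amp_wide) <- unique(amp_tbl$spectrum_id)
  amp_wide <- amp_wide[reps$spectrum_id, , drop = FALSE]

  noise <- withr::with_seed(sub_seed(config$seed, "noise"), {
    matrix(stats::rnorm(n_meas * length(axis), 0, config$noise_sd),
           n_meas, length(axis))
  })
  bg_noise <- withr::with_seed(sub_seed(config$seed, "noise") + 1L, {
    matrix(stats::rnorm(nrow(design) * config$n_background * length(axis),
                        0, config$noise_sd),
           nrow(design) * config$n_background, length(axis))
  })

  for (i in seq_len(n_meas)) {
    s <- sample_of_rep[i]
    gain <- 1 + gain_coef[i, 1] * tgrid +
      gain_coef[i, 2] * (1.5 * tgrid^2 - 0.5)
    fl <- fluor_sample[[s]] * fluor_jitter[i] * gain
    am <- ambient_sample[[s]]
    peaks <- drop(peak_basis %*% amp_wide[i, ]) * gain
    meas[i, ] <- am + fl + peaks + noise[i, ]
    fluor_true[i, ] <- fl
    ambient_true[i, ] <- am
  }

  # overexposure: rescale flagged replicates to just above the ceiling, then clip
  for (i in which(reps$saturated)) {
    meas[i, ] <- meas[i, ] * (1.05 * config$dynamic_range_max / max(meas[i, ]))
  }
  meas <- pmin(pmax(meas, 0), config$dynamic_range_max)

  meta_meas <- tibble::tibble(
    spectrum_id = reps$spectrum_id, patient_id = reps$patient_id,
    sample_id = reps$sample_id, replicate = reps$replicate,
    tissue_class = reps$tissue_class, frame_kind = "measurement"
  )

  bg_ids <- as.vector(t(outer(design$sample_id, seq_len(config$n_background),
                              function(s, k) sprintf("%s_bg%d", s, k))))
  bg <- matrix(0, length(bg_ids), length(axis), dimnames = list(bg_ids, NULL))
  for (i in seq_along(bg_ids)) {
    s <- ceiling(i / config$n_background)
    bg[i, ] <- ambient_sample[[s]] + bg_noise[i, ]
  }
  bg <- pmin(pmax(bg, 0), config$dynamic_range_max)
  meta_bg <- tibble::tibble(
    spectrum_id = bg_ids,
    patient_id = rep(design$patient_id, each = config$n_background),
    sample_id = rep(design$sample_id, each = config$n_background),
    replicate = rep(seq_len(config$n_background), times = nrow(design)),
    tissue_class = rep(design$tissue_class, each = config$n_background),
    frame_kind = "background"
  )

  spectra <- matrix_to_spectra(rbind(meas, bg), axis,
                               dplyr::bind_rows(meta_meas, meta_bg),
                               provenance = sprintf(
                                 "generate_dataset(seed=%d): %d measurement + %d background frames",
                                 config$seed, n_meas, length(bg_ids)))

  amp_class <- as.matrix(comp[, unname(amp_cols)])
  disc <- apply(amp_class, 1, function(a) diff(range(a)) > 0)
  discriminative_bands <- tibble::tibble(
    component = comp$component[disc],
    lo = comp$peak_center[disc] - comp$fwhm[disc],
    hi = comp$peak_center[disc] + comp$fwhm[disc]
  )

  truth <- list(
    meta = dplyr::mutate(meta_meas, saturated = reps$saturated),
    amplitudes = amp_tbl,
    fluorescence = fluor_true,
    ambient = ambient_true,
    axis = axis,
    discriminative_bands = discriminative_bands
  )
  list(spectra = spectra, truth = truth)
}

# deterministic sample -> patient assignment (8 patients over 10 samples;
# edge and center samples can come from the same patient)
default_patient_map <- function() {
  c(normal_s1 = "p1", normal_s2 = "p2", normal_s3 = "p3",
    edge_s1 = "p4", edge_s2 = "p5", edge_s3 = "p6",
    center_s1 = "p4", center_s2 = "p5", center_s3 = "p7", center_s4 = "p8")
}


n_meas_planned <- function(design, config) nrow(design) * config$replicates
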