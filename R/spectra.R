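#' Long-format Raman spectrum container
#'
#' A `raman_spectra` object is a long tibble with one row per
#' (spectrum, wavenumber) pair and the columns
#' `spectrum_id`, `patient_id`, `sample_id`, `replicate`,
#' `tissue_class`, `frame_kind`, `wavenumber`, `intensity`.
#' All spectra in one object share an identical wavenumber axis
#' (strictly increasing, finite, length >= 2). A `provenance`
#' attribute records every operation applied, append-only.
#'
#' @param x A data frame with at least `spectrum_id`, `wavenumber`,
#'   `intensity`; missing metadata columns are filled with defaults
#'   (`replicate = 1L`, `frame_kind = "measurement"`, `tissue_class = NA`).
#' @param provenance Character vector of log lines carried over.
#'
#' @return A `raman_spectra` tibble, rows sorted by spectrum then
#'   wavenumber.
#' @export
raman_spectra <- function(x, provenance = character()) {
  x <- tibble::as_tibble(x)
  req <- c("spectrum_id", "wavenumber", "intensity")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    rlang::abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"patient_id" %in% names(x)) x$patient_id <- x$spectrum_id
  if (!"sample_id" %in% names(x)) x$sample_id <- x$spectrum_id
  if (!"replicate" %in% names(x)) x$replicate <- 1L
  if (!"tissue_class" %in% names(x)) x$tissue_class <- NA_character_
  if (is.logical(x$tissue_class)) x$tissue_class <- as.character(x$tissue_class)
  x$replicate <- as.integer(x$replicate)
  if (!"frame_kind" %in% names(x)) x$frame_kind <- "measurement"
  if (!is.numeric(x$wavenumber) || !is.numeric(x$intensity)) {
    rlang::abort("wavenumber and intensity must be numeric")
  }
  if (anyNA(x$wavenumber) || any(!is.finite(x$wavenumber))) {
    rlang::abort("wavenumber contains non-finite values")
  }
  if (any(!is.finite(x$intensity))) {
    rlang::abort("intensity contains non-finite values")
  }
  bad <- setdiff(unique(x$tissue_class[!is.na(x$tissue_class)]), tissue_classes())
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown tissue_class value(s): ", paste(bad, collapse = ", ")))
  }
  if (!all(x$frame_kind %in% c("measurement", "background"))) {
    rlang::abort("frame_kind must be 'measurement' or 'background'")
  }
  x <- dplyr::arrange(x, .data$spectrum_id, .data$wavenumber)
  cols <- c("spectrum_id", "patient_id", "sample_id", "replicate",
            "tissue_class", "frame_kind", "wavenumber", "intensity")
  x <- dplyr::select(x, dplyr::all_of(cols), dplyr::everything())
  validate_shared_axis(x)
  structure(x, provenance = provenance,
            class = c("raman_spectra", class(tibble::tibble())))
}

tissue_classes <- function() c("normal", "edge", "center")

validate_shared_axis <- function(x) {
  axes <- split(x$wavenumber, x$spectrum_id)
  ref <- axes[[1]]
  if (length(ref) < 2) rlang::abort("spectral axis must have length >= 2")
  if (any(diff(ref) <= 0)) rlang::abort("spectral axis must be strictly increasing")
  same <- vapply(axes, function(a) length(a) == length(ref) && all(a == ref), logical(1))
  if (!all(same)) {
    rlang::abort(paste0("spectra do not share one axis; offending spectrum_id(s): ",
                        paste(names(axes)[!same], collapse = ", ")))
  }
  invisible(ref)
}

#' Shared wavenumber axis of a spectrum set
#' @param x A `raman_spectra` tibble.
#' @return Numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @export
spectra_axis <- function(x) {
  sort(unique(x$wavenumber))
}

#' Per-spectrum metadata
#' @param x A `raman_spectra` tibble.
#' @return Tibble with one row per spectrum: id, patient, sample,
#'   replicate, tissue class, frame kind.
#' @export
spectra_meta <- function(x) {
  out <- dplyr::distinct(tibble::as_tibble(x), .data$spectrum_id, .data$patient_id,
                         .data$sample_id, .data$replicate, .data$tissue_class,
                         .data$frame_kind)
  attr(out, "provenance") <- NULL
  out
}

#' Intensity matrix view (spectra x wavenumbers)
#' @param x A `raman_spectra` tibble.
#' @return Numeric matrix, rownames = spectrum ids, colnames = wavenumbers.
#' @export
spectra_matrix <- function(x) {
  axis <- spectra_axis(x)
  x <- dplyr::arrange(tibble::as_tibble(x), .data$spectrum_id, .data$wavenumber)
  ids <- unique(x$spectrum_id)
  m <- matrix(x$intensity, nrow = length(ids), ncol = length(axis),
              byrow = TRUE, dimnames = list(ids, format(axis, trim = TRUE)))
  m
}

# inverse of spectra_matrix: rebuild a raman_spectra from a matrix plus meta
matrix_to_spectra <- function(m, axis, meta, provenance = character()) {
  long <- tibble::tibble(
    spectrum_id = rep(rownames(m), each = ncol(m)),
    wavenumber = rep(axis, times = nrow(m)),
    intensity = as.vector(t(m))
  )
  long <- dplyr::left_join(long, meta, by = "spectrum_id")
  raman_spectra(long, provenance = provenance)
}

#' Provenance log of a spectrum set
#' @param x A `raman_spectra` tibble.
#' @return Character vector of applied operations, oldest first.
#' @export
provenance <- function(x) attr(x, "provenance") %||% character()

add_provenance <- function(x, line) {
  attr(x, "provenance") <- c(provenance(x), line)
  x
}

# rebuild class/provenance after dplyr verbs strip attributes
restore_spectra <- function(x, template, extra_provenance = NULL) {
  raman_spectra(x, provenance = c(provenance(template), extra_provenance))
}

#' @export
print.raman_spectra <- function(x, ...) {
  meta <- spectra_meta(x)
  axis <- spectra_axis(x)
  cat(sprintf("<raman_spectra> %d spectra x %d points (%.1f-%.1f cm^-1)\n",
              nrow(meta), length(axis), min(axis), max(axis)))
  tc <- table(meta$tissue_class, useNA = "ifany")
  cat("  frames:", paste(sprintf("%s=%d", names(table(meta$frame_kind)),
                                 table(meta$frame_kind)), collapse = " "),
      "| classes:", paste(sprintf("%s=%d", names(tc), tc), collapse = " "), "\n")
  if (length(provenance(x)) > 0) {
    cat("  provenance:", length(provenance(x)), "step(s); last:",
        utils::tail(provenance(x), 1), "\n")
  }
  NextMethod()
}
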