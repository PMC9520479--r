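#' Read spectra from a delimited table
#'
#' Two plain-text dialects are supported. `long`: columns
#' `spectrum_id`, `wavenumber`, `intensity` (one row per point), with
#' per-spectrum metadata in an optional JSON sidecar. `wide`: first
#' column `wavenumber`, one intensity column per spectrum (column name
#' = spectrum id), metadata again in the sidecar. The sidecar is a
#' JSON array of objects keyed by `spectrum_id` with any of
#' `patient_id`, `sample_id`, `replicate`, `tissue_class`,
#' `frame_kind`; a missing `tissue_class` is allowed (prediction-only
#' use). Unsorted wavenumbers are sorted ascending with intensities
#' co-permuted.
#'
#' @param path Path to a CSV/TSV file (delimiter inferred from extension).
#' @param dialect `"long"` or `"wide"`.
#' @param meta_path Optional path to the JSON metadata sidecar;
#'   defaults to `<path>.meta.json` when that file exists.
#' @return A [raman_spectra] tibble.
#' @export
read_spectra <- function(path, dialect = c("wide", "long"), meta_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  # base strtod parsing is correctly rounded, so text -> double -> text
  # round trips are bit-exact
  raw <- tibble::as_tibble(utils::read.delim(path, sep = delim,
                                             check.names = FALSE,
                                             stringsAsFactors = FALSE))
  long <- switch(dialect,
    long = parse_long_dialect(raw, path),
    wide = parse_wide_dialect(raw, path)
  )
  if (is.null(meta_path)) {
    cand <- paste0(path, ".meta.json")
    if (file.exists(cand)) meta_path <- cand
  }
  if (!is.null(meta_path)) {
    meta <- tibble::as_tibble(jsonlite::fromJSON(meta_path))
    if (!"spectrum_id" %in% names(meta)) {
      rlang::abort("metadata sidecar must contain spectrum_id")
    }
    long <- dplyr::left_join(long, meta, by = "spectrum_id")
  }
  raman_spectra(long, provenance = paste0("read_spectra(", dialect, "): ", path))
}

parse_long_dialect <- function(raw, path) {
  req <- c("spectrum_id", "wavenumber", "intensity")
  if (!all(req %in% names(raw))) {
    rlang::abort(paste0("long dialect requires columns ",
                        paste(req, collapse = ", "), " in ", path))
  }
  assert_numeric_column(raw$wavenumber, "wavenumber", path)
  assert_numeric_column(raw$intensity, "intensity", path)
  raw[req]
}

parse_wide_dialect <- function(raw, path) {
  if (names(raw)[1] != "wavenumber") {
    rlang::abort(paste0("wide dialect requires first column 'wavenumber' in ", path))
  }
  assert_numeric_column(raw$wavenumber, "wavenumber", path)
  for (nm in names(raw)[-1]) assert_numeric_column(raw[[nm]], nm, path)
  tidyr::pivot_longer(raw, -"wavenumber", names_to = "spectrum_id",
                      values_to = "intensity")
}

assert_numeric_column <- function(col, name, path) {
  if (is.numeric(col) && !anyNA(col)) return(invisible(TRUE))
  num <- suppressWarnings(as.numeric(col))
  bad <- which(is.na(num))
  rlang::abort(sprintf("non-numeric cell(s) in column '%s' of %s (first at row %d)",
                       name, path, if (length(bad)) bad[1] else NA_integer_))
}

#' Write spectra to a delimited table
#'
#' Inverse of [read_spectra]; intensities round-trip bit-exactly
#' (written with full precision). Metadata goes to a JSON sidecar at
#' `<path>.meta.json`.
#'
#' @param x A [raman_spectra] tibble.
#' @param path Output CSV/TSV path.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  if (dialect == "long") {
    out <- dplyr::select(tibble::as_tibble(x), "spectrum_id", "wavenumber",
                         "intensity")
  } else {
    out <- tidyr::pivot_wider(
      dplyr::select(tibble::as_tibble(x), "spectrum_id", "wavenumber", "intensity"),
      names_from = "spectrum_id", values_from = "intensity")
    out <- dplyr::arrange(out, .data$wavenumber)
  }
  # %.17g guarantees doubles survive the text round trip bit-exactly
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                          ~ sprintf("%.17g", .x)))
  readr::write_delim(out, path, delim = delim)
  jsonlite::write_json(spectra_meta(x), paste0(path, ".meta.json"),
                       auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' Read a biochemical band library
#'
#' A band library is a CSV with header `component,lo,hi`, one row per
#' Raman-shift interval attributed to a molecular constituent.
#' Overlapping bands are permitted (e.g. cholesterol and protein
#' share peaks near 926 and 1178 cm^-1).
#'
#' @param path CSV path.
#' @return Tibble with columns `component` (character), `lo`, `hi`
#'   (cm^-1, 127 <= lo < hi <= 2830).
#' @export
read_band_library <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  bands <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(bands) == 0) {
    rlang::warn("empty band library")
    return(tibble::tibble(component = character(), lo = double(), hi = double()))
  }
  validate_bands(bands)
}

validate_bands <- function(bands) {
  bands <- tibble::as_tibble(bands)
  req <- c("component", "lo", "hi")
  if (!all(req %in% names(bands))) {
    rlang::abort("band library requires columns component, lo, hi")
  }
  if (any(bands$lo >= bands$hi)) {
    rlang::abort("band library: lo must be < hi in every row")
  }
  if (any(bands$lo < 127) || any(bands$hi > 2830)) {
    rlang::abort("band library: bands must lie within 127-2830 cm^-1")
  }
  bands[req]
}

#' Default biochemical band library
#'
#' Raman-shift intervals for the constituents that discriminate
#' glioma tissue classes: cholesterol (926, 960, 1228 cm^-1),
#' phospholipids, protein (C-N 1097, 1178 cm^-1), carotenoids (1157,
#' 1521 cm^-1), hemoglobin (1546-1558 cm^-1), water and the amide
#' bands. Boundaries are +/- a half-width around the literature peak
#' positions; override with your own library via [read_band_library].
#'
#' @return Tibble with columns `component`, `lo`, `hi`.
#' @export
default_band_library <- function() {
  tibble::tribble(
    ~component,     ~lo,   ~hi,
    "cholesterol",  918,   934,   # 926
    "cholesterol",  952,   968,   # 960
    "cholesterol",  1220,  1236,  # 1228
    "phospholipid", 1058,  1074,
    "protein",      1089,  1105,  # C-N 1097
    "protein",      1170,  1186,  # 1178, overlaps cholesterol region
    "carotenoid",   1149,  1165,  # 1157
    "carotenoid",   1513,  1529,  # 1521
    "hemoglobin",   1546,  1558,
    "water",        1630,  1650,
    "amide_i",      1647,  1672,  # ~1655
    "amide_iii",    1243,  1270
  )
}

#' Write a classification report to JSON
#'
#' Serializes the confusion matrix (with an explicit `class_order`
#' key), the binary malignant-vs-normal metrics both as raw fractions
#' and as 1-decimal percent strings, the split seed(s) and a hash of
#' the configuration, so that a report is self-describing and
#' round-trips through [read_report].
#'
#' @param report A `classification_report` (see [evaluate]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "classification_report"))
  payload <- list(
    variant = report$variant,
    class_order = report$class_order,
    confusion = unname(apply(report$confusion, 1, as.list)),
    metrics = list(
      accuracy = report$accuracy,
      sensitivity = report$sensitivity,
      specificity = report$specificity
    ),
    metrics_percent = list(
      accuracy = sprintf("%.1f%%", 100 * report$accuracy),
      sensitivity = sprintf("%.1f%%", 100 * report$sensitivity),
      specificity = sprintf("%.1f%%", 100 * report$specificity)
    ),
    n_test = report$n_test,
    seed = report$seed,
    config_hash = report$config_hash %||% NA
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a classification report written by [write_report]
#' @param path JSON path.
#' @return A `classification_report` object.
#' @export
read_report <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  conf <- do.call(rbind, lapply(p$confusion, unlist))
  dimnames(conf) <- list(true = p$class_order, predicted = p$class_order)
  new_classification_report(
    confusion = conf, accuracy = p$metrics$accuracy,
    sensitivity = p$metrics$sensitivity, specificity = p$metrics$specificity,
    variant = p$variant, seed = p$seed, config_hash = p$config_hash
  )
}
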