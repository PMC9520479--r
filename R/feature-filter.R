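#' Grouped intensity matrix for class comparisons
#'
#' Pivots preprocessed measurement spectra into an n-spectra by
#' p-wavenumbers matrix with a tissue-class label per row — the layout
#' in which the per-wavenumber Fisher criterion and the classifiers
#' operate.
#'
#' @param x A preprocessed [raman_spectra] tibble with known
#'   `tissue_class` for every measurement.
#' @return A `grouped_matrix`: list with `values` (matrix), `labels`
#'   (factor with levels normal/edge/center), `wavenumbers`, `meta`.
#' @export
grouped_matrix <- function(x) {
  meta <- spectra_meta(dplyr::filter(tibble::as_tibble(x),
                                     .data$frame_kind == "measurement"))
  if (anyNA(meta$tissue_class)) rlang::abort("all measurement spectra need a tissue_class")
  m <- spectra_matrix(raman_spectra(dplyr::filter(tibble::as_tibble(x),
                                                  .data$frame_kind == "measurement")))
  labels <- factor(meta$tissue_class[match(rownames(m), meta$spectrum_id)],
                   levels = tissue_classes())
  new_grouped_matrix(m, labels, spectra_axis(x), meta)
}

new_grouped_matrix <- function(values, labels, wavenumbers, meta = NULL) {
  labels <- factor(labels, levels = tissue_classes())
  if (any(table(labels) > 0 & table(labels) < 2)) {
    rlang::abort("every represented class needs >= 2 spectra (variance undefined otherwise)")
  }
  stopifnot(nrow(values) == length(labels), ncol(values) == length(wavenumbers))
  structure(list(values = values, labels = labels, wavenumbers = wavenumbers,
                 meta = meta),
            class = "grouped_matrix")
}

#' Per-wavenumber Fisher criterion (one-way ANOVA F)
#'
#' For each column, the ratio of between-class to within-class mean
#' squares over the k = 3 tissue classes, with df1 = k - 1 and
#' df2 = n - k, and the upper-tail p-value. Columns with zero
#' within-class variance get F = Inf (p = 0) when class means differ
#' and F = 0 (p = 1) when they are all equal. Vectorized over columns.
#'
#' @param values Numeric matrix (rows = spectra) or vector.
#' @param labels Class factor, one level per row.
#' @return Tibble with columns `statistic`, `p.value`, `df1`, `df2`,
#'   one row per column of `values`.
#' @export
fisher_statistic <- function(values, labels) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  labels <- droplevels(factor(labels))
  k <- nlevels(labels)
  n <- nrow(values)
  if (k < 2) rlang::abort("need at least two classes")
  if (any(table(labels) < 2)) rlang::abort("every class needs >= 2 observations")

  grand <- colMeans(values)
  ss_between <- numeric(ncol(values))
  ss_within <- numeric(ncol(values))
  for (g in levels(labels)) {
    rows <- labels == g
    ng <- sum(rows)
    mg <- colMeans(values[rows, , drop = FALSE])
    ss_between <- ss_between + ng * (mg - grand)^2
    ss_within <- ss_within +
      colSums((values[rows, , drop = FALSE] -
                 matrix(mg, ng, ncol(values), byrow = TRUE))^2)
  }
  df1 <- k - 1
  df2 <- n - k
  msb <- ss_between / df1
  msw <- ss_within / df2
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  p <- ifelse(is.infinite(f), 0, stats::pf(f, df1, df2, lower.tail = FALSE))
  tibble::tibble(statistic = f, p.value = p, df1 = df1, df2 = df2)
}

# Fisher discriminant ratio per column: scatter of class means around
# the grand mean over the pooled within-class variance
discriminant_ratio <- function(values, labels) {
  labels <- droplevels(factor(labels))
  grand <- colMeans(values)
  num <- 0
  den <- 0
  for (g in levels(labels)) {
    rows <- labels == g
    mg <- colMeans(values[rows, , drop = FALSE])
    num <- num + (mg - grand)^2
    den <- den + colSums((values[rows, , drop = FALSE] -
                            matrix(mg, sum(rows), ncol(values), byrow = TRUE))^2) /
      (sum(rows) - 1)
  }
  ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
}

#' Critical value of the F distribution
#'
#' Upper-alpha quantile with df1 = k - 1 and df2 = n - k; a
#' wavenumber is retained when its F statistic exceeds this value.
#'
#' @param alpha Significance level in (0, 1).
#' @param df1,df2 Degrees of freedom (>= 1).
#' @return Scalar F quantile.
#' @export
critical_value <- function(alpha, df1, df2) {
  stopifnot(alpha > 0, alpha < 1)
  if (df1 < 1 || df2 < 1) rlang::abort("degrees of freedom must be >= 1")
  stats::qf(alpha, df1, df2, lower.tail = FALSE)
}

#' Build a per-wavenumber keep/drop mask
#'
#' Computes the Fisher criterion for every wavenumber and keeps those
#' exceeding the critical value at level `alpha`. No multiple-testing
#' correction is applied by default (each wavenumber is tested on its
#' own); Benjamini-Hochberg is available as an option. A
#' Fisher-discriminant-ratio criterion (between-class scatter of the
#' class means over pooled within-class variance, with no null
#' distribution) is available for sensitivity analysis; it keeps the
#' top `alpha` fraction of wavenumbers by ratio.
#'
#' @param m A `grouped_matrix` (see [grouped_matrix]).
#' @param alpha Significance level (for `"anova_f"`), or the kept
#'   fraction (for `"discriminant_ratio"`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param criterion `"anova_f"` (default) or `"discriminant_ratio"`.
#' @return A `feature_mask`: tibble with `wavenumber`, `statistic`,
#'   `p.value`, `keep`, plus attributes `alpha` and `f_critical`.
#' @export
build_mask <- function(m, alpha = 0.05, adjust = c("none", "BH"),
                       criterion = c("anova_f", "discriminant_ratio")) {
  adjust <- match.arg(adjust)
  criterion <- match.arg(criterion)
  stopifnot(inherits(m, "grouped_matrix"))
  if (criterion == "discriminant_ratio") {
    dr <- discriminant_ratio(m$values, m$labels)
    out <- tibble::tibble(wavenumber = m$wavenumbers, statistic = dr,
                          p.value = NA_real_,
                          keep = dr >= stats::quantile(dr, 1 - alpha))
    return(structure(out, alpha = alpha,
                     f_critical = unname(stats::quantile(dr, 1 - alpha)),
                     df1 = NA_real_, df2 = NA_real_, adjust = "none",
                     class = c("feature_mask", class(out))))
  }
  ft <- fisher_statistic(m$values, m$labels)
  fc <- critical_value(alpha, ft$df1[1], ft$df2[1])
  keep <- if (adjust == "none") {
    ft$statistic > fc
  } else {
    stats::p.adjust(ft$p.value, "BH") < alpha
  }
  out <- tibble::tibble(wavenumber = m$wavenumbers,
                        statistic = ft$statistic, p.value = ft$p.value,
                        keep = keep)
  structure(out, alpha = alpha, f_critical = fc, df1 = ft$df1[1],
            df2 = ft$df2[1], adjust = adjust,
            class = c("feature_mask", class(out)))
}

#' Drop masked-out wavenumbers from a grouped matrix
#'
#' @param m A `grouped_matrix`.
#' @param mask A `feature_mask` of matching length.
#' @return A `grouped_matrix` restricted to the kept wavenumbers.
#' @export
filter_matrix <- function(m, mask) {
  stopifnot(inherits(m, "grouped_matrix"), inherits(mask, "feature_mask"))
  if (nrow(mask) != ncol(m$values)) rlang::abort("mask length does not match columns")
  if (!any(mask$keep)) {
    rlang::abort("no wavenumbers retained; consider a larger alpha")
  }
  new_grouped_matrix(m$values[, mask$keep, drop = FALSE], m$labels,
                     m$wavenumbers[mask$keep], m$meta)
}

#' Sum retained intensities within biochemical bands
#'
#' For each spectrum and band, sums the intensities at mask-retained
#' wavenumbers inside `[lo, hi]` (zero when none are retained), then
#' summarizes each band per class (mean, standard error) and
#' annotates its significance tier from a fresh one-way ANOVA on the
#' band sums: `**` for p < 0.001, `*` for p < 0.05, `ns` otherwise.
#'
#' @param m A `grouped_matrix`.
#' @param mask A `feature_mask`; use `mask = NULL` to sum over full
#'   bands regardless of the filter.
#' @param bands Band library tibble (`component`, `lo`, `hi`), e.g.
#'   [default_band_library()].
#' @return A `band_summary` list: `sums` (tibble spectrum x band) and
#'   `bands` (per-band class means, standard errors, F, p, tier).
#' @export
aggregate_bands <- function(m, mask = NULL, bands = default_band_library()) {
  stopifnot(inherits(m, "grouped_matrix"))
  bands <- validate_bands(bands)
  if (nrow(bands) == 0) rlang::abort("band library is empty")
  kept <- if (is.null(mask)) rep(TRUE, length(m$wavenumbers)) else mask$keep
  band_id <- sprintf("%s_%g_%g", bands$component, bands$lo, bands$hi)

  sums <- purrr::map_dfr(seq_len(nrow(bands)), function(b) {
    cols <- kept & m$wavenumbers >= bands$lo[b] & m$wavenumbers <= bands$hi[b]
    tibble::tibble(
      spectrum_id = rownames(m$values),
      tissue_class = as.character(m$labels),
      band = band_id[b], component = bands$component[b],
      lo = bands$lo[b], hi = bands$hi[b],
      n_wavenumbers = sum(cols),
      band_sum = if (any(cols)) unname(rowSums(m$values[, cols, drop = FALSE])) else 0
    )
  })

  per_band <- sums |>
    dplyr::group_by(.data$band, .data$component, .data$lo, .data$hi,
                    .data$n_wavenumbers, .data$tissue_class) |>
    dplyr::summarise(mean = mean(.data$band_sum),
                     se = stats::sd(.data$band_sum) / sqrt(dplyr::n()),
                     .groups = "drop")
  tiers <- sums |>
    dplyr::group_by(.data$band) |>
    dplyr::group_modify(function(d, key) {
      if (all(d$band_sum == 0) || stats::sd(d$band_sum) == 0) {
        return(tibble::tibble(statistic = 0, p.value = 1))
      }
      fisher_statistic(d$band_sum, d$tissue_class)[, c("statistic", "p.value")]
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(tier = dplyr::case_when(.data$p.value < 0.001 ~ "**",
                                          .data$p.value < 0.05 ~ "*",
                                          TRUE ~ "ns"))
  structure(list(sums = sums, bands = dplyr::left_join(per_band, tiers, by = "band")),
            class = "band_summary")
}

#' @rdname build_mask
#' @param x A `feature_mask`.
#' @param ... Unused.
#' @method tidy feature_mask
#' @export
tidy.feature_mask <- function(x, ...) tibble::as_tibble(x)

#' @rdname build_mask
#' @method glance feature_mask
#' @export
glance.feature_mask <- function(x, ...) {
  tibble::tibble(n_features = nrow(x), n_kept = sum(x$keep),
                 alpha = attr(x, "alpha"), f_critical = attr(x, "f_critical"),
                 df1 = attr(x, "df1"), df2 = attr(x, "df2"),
                 adjust = attr(x, "adjust"))
}

#' @rdname aggregate_bands
#' @param x A `band_summary`.
#' @param ... Unused.
#' @method tidy band_summary
#' @export
tidy.band_summary <- function(x, ...) x$bands

#' @export
print.band_summary <- function(x, ...) {
  cat("<band_summary>\n")
  print(x$bands)
  invisible(x)
}
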