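#' Run one dimensionality-reduction / classification variant
#'
#' The three compared configurations:
#' \describe{
#'   \item{`pca_only`}{PCA (2 components) on all retained wavenumbers,
#'     then RBF-SVM.}
#'   \item{`filtered_svm`}{Fisher-criterion mask, SVM directly on the
#'     retained wavenumbers.}
#'   \item{`combined`}{Fisher-criterion mask, then PCA (2 components)
#'     on the retained wavenumbers, then SVM.}
#' }
#' The split is passed in so all variants of one run see identical
#' train/test partitions (paired comparison). PCA is fitted on
#' training rows only unless `pca_fit_all = TRUE` (which mimics
#' fitting the score plane on the full dataset, at the cost of
#' information leakage into the test projection).
#'
#' @param m A `grouped_matrix` of preprocessed spectra.
#' @param variant `"pca_only"`, `"filtered_svm"` or `"combined"`.
#' @param split List with `train`/`test` spectrum ids
#'   (see [split_train_test]).
#' @param mask A `feature_mask` (required by the filtered variants);
#'   compute it once per dataset with [build_mask] and share it.
#' @param n_components PCA components for the projecting variants.
#' @param svm An [svm_config].
#' @param pca_fit_all Fit PCA on all rows instead of training rows.
#' @param seed Split seed, recorded in the report.
#' @return A `classification_report`.
#' @export
run_variant <- function(m, variant = c("pca_only", "filtered_svm", "combined"),
                        split, mask = NULL, n_components = 2,
                        svm = svm_config(), pca_fit_all = FALSE,
                        seed = NA_integer_) {
  variant <- match.arg(variant)
  stopifnot(inherits(m, "grouped_matrix"))
  ids <- rownames(m$values)
  tr <- match(split$train, ids)
  te <- match(split$test, ids)
  if (anyNA(tr) || anyNA(te)) rlang::abort("split ids not found in the matrix")

  if (variant %in% c("filtered_svm", "combined")) {
    if (is.null(mask)) rlang::abort("filtered variants need a feature_mask")
    m <- filter_matrix(m, mask)
  }
  x <- m$values
  if (variant %in% c("pca_only", "combined")) {
    pca <- fit_pca(x[if (pca_fit_all) seq_len(nrow(x)) else tr, , drop = FALSE],
                   n_components = n_components)
    x <- project(pca, x)
  }
  model <- train_svm(x[tr, , drop = FALSE], m$labels[tr], svm)
  evaluate(model, x[te, , drop = FALSE], as.character(m$labels[te]),
           variant = variant, seed = seed)
}

#' Repeated paired evaluation of the classification variants
#'
#' Re-splits, trains and evaluates `n_repeats` times with seeds
#' `base_seed + 1 .. base_seed + n_repeats`; within each repeat all
#' variants share the same split, so differences between variants are
#' paired. A single random 30% split of ~48 spectra is high-variance,
#' which is why the default protocol reports means over repeats.
#'
#' @param m A `grouped_matrix`.
#' @param variants Character vector of variants to run.
#' @param n_repeats Number of repeated splits.
#' @param base_seed Integer; repeat r uses seed `base_seed + r`.
#' @param plan A [split_plan].
#' @param alpha Significance level for the Fisher mask.
#' @param mask Optional precomputed `feature_mask`; built from the
#'   full matrix at `alpha` when omitted.
#' @param n_components,svm,pca_fit_all Passed to [run_variant].
#' @return A `variant_comparison`: list with `results` (one row per
#'   repeat x variant), `summary` (mean and sd per variant and
#'   metric), `mask_glance`.
#' @export
repeated_evaluation <- function(m, variants = c("pca_only", "filtered_svm", "combined"),
                                n_repeats = 50, base_seed = 1,
                                plan = split_plan(), alpha = 0.05,
                                mask = NULL, n_components = 2,
                                svm = svm_config(), pca_fit_all = FALSE) {
  stopifnot(n_repeats >= 1)
  needs_mask <- any(variants %in% c("filtered_svm", "combined"))
  if (needs_mask && is.null(mask)) mask <- build_mask(m, alpha)
  meta <- m$meta %||% tibble::tibble(spectrum_id = rownames(m$values),
                                     tissue_class = as.character(m$labels),
                                     patient_id = rownames(m$values))
  results <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    seed_r <- as.integer(base_seed) + r
    split <- split_train_test(meta, plan, seed = seed_r)
    purrr::map_dfr(variants, function(v) {
      rep <- run_variant(m, v, split, mask = mask,
                         n_components = n_components, svm = svm,
                         pca_fit_all = pca_fit_all, seed = seed_r)
      dplyr::mutate(glance(rep), repeat_id = r, .before = 1)
    })
  })
  summary <- results |>
    tidyr::pivot_longer(c("accuracy", "sensitivity", "specificity"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$variant, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(list(results = results, summary = summary,
                 mask_glance = if (needs_mask) glance(mask) else NULL,
                 n_repeats = n_repeats, base_seed = base_seed),
            class = "variant_comparison")
}

#' @rdname repeated_evaluation
#' @param x A `variant_comparison`.
#' @param ... Unused.
#' @method tidy variant_comparison
#' @export
tidy.variant_comparison <- function(x, ...) x$summary

#' @rdname repeated_evaluation
#' @method glance variant_comparison
#' @export
glance.variant_comparison <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::mutate(wide, n_repeats = x$n_repeats)
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat(sprintf("<variant_comparison> %d repeats, base_seed=%d\n",
              x$n_repeats, x$base_seed))
  print(glance(x))
  invisible(x)
}

#' End-to-end pipeline: simulate (optionally), preprocess, filter,
#' classify, compare
#'
#' Orchestrates the whole analysis and returns one comparison report:
#' synthetic data generation (when `spectra` is not supplied),
#' preprocessing, Fisher-criterion masking, band aggregation, and
#' repeated paired evaluation of the requested variants.
#'
#' @param generator A [generator_config], used when `spectra` is NULL.
#' @param spectra Optional [raman_spectra] of raw measurement +
#'   background frames to analyze instead of simulating.
#' @param preprocess A [preprocess_config].
#' @param alpha Fisher-mask significance level.
#' @param bands Band library tibble.
#' @param plan A [split_plan].
#' @param svm An [svm_config].
#' @param variants Variants to compare.
#' @param n_repeats Repeated splits per variant.
#' @param seed Base seed for the splits.
#' @param out Optional path: writes the comparison as JSON.
#' @return A `pipeline_result` list: `comparison`
#'   (`variant_comparison`), `mask`, `band_summary`, `preprocessed`
#'   spectra, `excluded` ids and the configuration echo.
#' @export
run_full <- function(generator = study_design_config(), spectra = NULL,
                     preprocess = preprocess_config(), alpha = 0.05,
                     bands = default_band_library(), plan = split_plan(),
                     svm = svm_config(),
                     variants = c("pca_only", "filtered_svm", "combined"),
                     n_repeats = 50, seed = 1, out = NULL) {
  if (length(variants) == 0) rlang::abort("at least one variant is required")
  truth <- NULL
  if (is.null(spectra)) {
    sim <- generate_dataset(generator)
    spectra <- sim$spectra
    truth <- sim$truth
  }
  tbl <- tibble::as_tibble(spectra)
  meas <- raman_spectra(dplyr::filter(tbl, .data$frame_kind == "measurement"),
                        provenance = provenance(spectra))
  bgs <- raman_spectra(dplyr::filter(tbl, .data$frame_kind == "background"))
  pre <- preprocess_pipeline(meas, bgs, preprocess,
                             dynamic_range_max = generator$dynamic_range_max %||% 65535)
  m <- grouped_matrix(pre)
  mask <- build_mask(m, alpha)
  bands_out <- aggregate_bands(m, mask, bands)
  comparison <- repeated_evaluation(m, variants, n_repeats = n_repeats,
                                    base_seed = seed, plan = plan,
                                    alpha = alpha, mask = mask, svm = svm)
  result <- structure(list(
    comparison = comparison, mask = mask, band_summary = bands_out,
    preprocessed = pre, excluded = attr(pre, "excluded"), truth = truth,
    config = list(alpha = alpha, n_repeats = n_repeats, seed = seed,
                  variants = variants, plan = unclass(plan))
  ), class = "pipeline_result")
  if (!is.null(out)) {
    payload <- list(
      summary = comparison$summary,
      per_repeat = comparison$results,
      mask = glance(mask),
      excluded = attr(pre, "excluded"),
      config = result$config
    )
    jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  excluded spectra: %s\n",
              if (length(x$excluded)) paste(x$excluded, collapse = ", ") else "none"))
  cat(sprintf("  retained wavenumbers: %d of %d (alpha=%g)\n",
              sum(x$mask$keep), nrow(x$mask), attr(x$mask, "alpha")))
  print(x$comparison)
  invisible(x)
}
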