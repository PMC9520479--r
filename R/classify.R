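#' Principal component analysis of a spectral matrix
#'
#' Column-mean-centered covariance eigendecomposition (via
#' [stats::prcomp]), components ordered by decreasing eigenvalue.
#' Sign convention: each loading's largest-magnitude entry is made
#' positive, so results are reproducible across platforms.
#'
#' @param values Numeric matrix, rows = spectra.
#' @param n_components Components retained for projection (default 2,
#'   which suffices to map the 646-900 retained wavenumbers of a
#'   cropped tissue spectrum onto an interpretable score plane).
#' @return A `raman_pca` object: `mean`, `loadings` (orthonormal
#'   columns), `eigenvalues`, `n_components`.
#' @export
fit_pca <- function(values, n_components = 2) {
  stopifnot(nrow(values) >= 2, ncol(values) >= 1)
  pc <- stats::prcomp(values, center = TRUE, scale. = FALSE)
  load <- pc$rotation
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  ev <- pc$sdev^2
  if (all(ev < 1e-12)) rlang::warn("constant matrix: all eigenvalues are zero")
  structure(list(mean = pc$center, loadings = load, eigenvalues = ev,
                 n_components = min(n_components, ncol(load))),
            class = "raman_pca")
}

#' Project data onto fitted principal components
#'
#' @param model A `raman_pca`.
#' @param values Matrix with the same columns the model was fitted on.
#' @param n_components Override of the model's component count (e.g.
#'   `ncol(values)` for a full-rank, distance-preserving projection).
#' @return Score matrix (rows = spectra, columns = components).
#' @export
project <- function(model, values, n_components = model$n_components) {
  stopifnot(inherits(model, "raman_pca"))
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (ncol(values) != nrow(model$loadings)) {
    rlang::abort("column count does not match the PCA model")
  }
  k <- min(n_components, ncol(model$loadings))
  sweep(values, 2, model$mean) %*% model$loadings[, seq_len(k), drop = FALSE]
}

#' @rdname fit_pca
#' @param x A `raman_pca`.
#' @param ... Unused.
#' @method tidy raman_pca
#' @export
tidy.raman_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 variance_fraction = x$eigenvalues / sum(x$eigenvalues))
}

#' Train/test split plan
#'
#' Per class, `max(round(train_fraction * class size), min_per_class)`
#' spectra go to training; the rest are the test set. With the study's
#' class sizes 14/15/19 the defaults give training counts 5/5/6.
#' `group_by_patient` keeps all spectra of a patient on one side of
#' the split (off by default to mirror the original protocol; turn it
#' on to avoid patient leakage).
#'
#' @param train_fraction Training fraction (default 0.30).
#' @param min_per_class Minimum training spectra per class (default 5).
#' @param group_by_patient Logical.
#' @return A `split_plan` list.
#' @export
split_plan <- function(train_fraction = 0.30, min_per_class = 5,
                       group_by_patient = FALSE) {
  stopifnot(train_fraction > 0, train_fraction < 1, min_per_class >= 1)
  structure(list(train_fraction = train_fraction,
                 min_per_class = min_per_class,
                 group_by_patient = group_by_patient),
            class = "split_plan")
}

#' Split spectra into training and test sets
#'
#' @param meta Tibble with `spectrum_id`, `tissue_class` and (for
#'   grouped splits) `patient_id`, one row per spectrum.
#' @param plan A [split_plan].
#' @param seed Integer seed; the split is deterministic given
#'   (`meta`, `plan`, `seed`).
#' @return List with disjoint character vectors `train` and `test` of
#'   spectrum ids.
#' @export
split_train_test <- function(meta, plan = split_plan(), seed = 1) {
  stopifnot(inherits(plan, "split_plan"))
  meta <- tibble::as_tibble(meta)
  targets <- vapply(tissue_classes(), function(cl) {
    n_cl <- sum(meta$tissue_class == cl)
    want <- max(round(plan$train_fraction * n_cl), plan$min_per_class)
    if (want >= n_cl) {
      rlang::abort(sprintf("class '%s' (%d spectra) cannot supply %d training plus a test set",
                           cl, n_cl, want))
    }
    want
  }, double(1))
  withr::with_seed(as.integer(seed), {
    if (plan$group_by_patient) {
      # whole patients go to one side; patients are drawn until every
      # class reaches its training target (targets become minimums)
      for (cl in tissue_classes()) {
        if (dplyr::n_distinct(meta$patient_id[meta$tissue_class == cl]) < 2) {
          rlang::abort(sprintf("class '%s' has a single patient; grouped split infeasible", cl))
        }
      }
      pats <- sample(unique(meta$patient_id))
      got <- stats::setNames(rep(0, 3), tissue_classes())
      in_train <- character()
      for (p in pats) {
        if (all(got >= targets)) break
        rows <- meta[meta$patient_id == p, ]
        helps <- any(got[rows$tissue_class] < targets[rows$tissue_class])
        if (helps) {
          in_train <- c(in_train, p)
          got <- got + vapply(tissue_classes(),
                              function(cl) sum(rows$tissue_class == cl), double(1))
        }
      }
      train <- meta$spectrum_id[meta$patient_id %in% in_train]
      test <- setdiff(meta$spectrum_id, train)
      test_cls <- meta$tissue_class[match(test, meta$spectrum_id)]
      short <- tissue_classes()[!tissue_classes() %in% test_cls]
      if (any(got < targets) || length(short) > 0) {
        rlang::abort(paste0("grouped split infeasible for class: ",
                            paste(c(names(got)[got < targets], short), collapse = ", ")))
      }
      list(train = train, test = test)
    } else {
      train <- unlist(lapply(tissue_classes(), function(cl) {
        sample(meta$spectrum_id[meta$tissue_class == cl], targets[[cl]])
      }))
      list(train = train, test = setdiff(meta$spectrum_id, train))
    }
  })
}

#' RBF-SVM configuration
#'
#' @param cost Soft-margin regularization weight C.
#' @param gamma Kernel width of `exp(-gamma * ||x - x'||^2)`;
#'   `NULL` (default) uses `1 / (n_features * var(training values))`.
#' @param standardize Z-score each feature with training-set
#'   statistics before fitting (RBF kernels are scale-sensitive).
#' @return An `svm_config` list.
#' @export
svm_config <- function(cost = 1, gamma = NULL, standardize = TRUE) {
  stopifnot(cost > 0, is.null(gamma) || gamma > 0)
  structure(list(cost = cost, gamma = gamma, standardize = standardize),
            class = "svm_config")
}

#' Train an RBF-kernel support vector machine
#'
#' Maximum-margin classifier with a radial-basis-function kernel and
#' one-vs-one multiclass voting (libsvm via e1071), deterministic
#' given inputs and configuration.
#'
#' @param values Training feature matrix (rows = spectra).
#' @param labels Class factor per row; >= 2 classes required.
#' @param config An [svm_config].
#' @return An `svm_model` wrapping the fit plus the standardization
#'   statistics used.
#' @export
train_svm <- function(values, labels, config = svm_config()) {
  labels <- droplevels(factor(labels, levels = tissue_classes()))
  if (nlevels(labels) < 2) rlang::abort("training set holds a single class")
  center <- rep(0, ncol(values)); scale <- rep(1, ncol(values))
  if (config$standardize) {
    center <- colMeans(values)
    scale <- apply(values, 2, stats::sd)
    scale[scale == 0] <- 1
    values <- sweep(sweep(values, 2, center), 2, scale, "/")
  }
  gamma <- config$gamma %||% {
    v <- stats::var(as.vector(values))
    if (v <= 0) v <- 1
    1 / (ncol(values) * v)
  }
  fit <- e1071::svm(values, labels, type = "C-classification",
                    kernel = "radial", cost = config$cost, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale,
                 gamma = gamma, config = config, levels = levels(labels)),
            class = "svm_model")
}

#' @rdname train_svm
#' @param model An `svm_model`.
#' @export
predict_svm <- function(model, values) {
  stopifnot(inherits(model, "svm_model"))
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  values <- sweep(sweep(values, 2, model$center), 2, model$scale, "/")
  as.character(stats::predict(model$fit, values))
}

new_classification_report <- function(confusion, accuracy, sensitivity,
                                      specificity, variant = NA_character_,
                                      seed = NA_integer_, config_hash = NULL) {
  structure(list(confusion = confusion, accuracy = accuracy,
                 sensitivity = sensitivity, specificity = specificity,
                 class_order = tissue_classes(),
                 n_test = sum(confusion), variant = variant, seed = seed,
                 config_hash = config_hash),
            class = "classification_report")
}

#' Evaluate a classifier on labeled test spectra
#'
#' Builds the 3x3 confusion matrix (rows = true class, columns =
#' predicted, order normal/edge/center), then collapses to the binary
#' malignant-vs-normal problem with positive = tumor edge or center:
#' any malignant-subtype prediction counts as positive regardless of
#' edge/center confusion. Reports accuracy = (TP+TN)/N, sensitivity =
#' TP/(TP+FN) and specificity = TN/(TN+FP).
#'
#' @param model An `svm_model`.
#' @param values Test feature matrix.
#' @param labels True class per test row.
#' @param variant Optional variant tag stored in the report.
#' @param seed Optional split seed stored in the report.
#' @return A `classification_report`.
#' @export
evaluate <- function(model, values, labels, variant = NA_character_,
                     seed = NA_integer_) {
  if (length(labels) == 0) rlang::abort("empty test set")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), tissue_classes())
  if (length(bad) > 0) rlang::abort(paste0("unseen label(s): ", paste(bad, collapse = ", ")))
  pred <- predict_svm(model, values)
  report_from_predictions(labels, pred, variant = variant, seed = seed)
}

#' Build a classification report from labels and predictions
#' @param truth,pred Character vectors over normal/edge/center.
#' @inheritParams evaluate
#' @return A `classification_report`.
#' @method tidy classification_report
#' @export
report_from_predictions <- function(truth, pred, variant = NA_character_,
                                    seed = NA_integer_) {
  cls <- tissue_classes()
  bad <- setdiff(unique(c(truth, pred)), cls)
  if (length(bad) > 0) {
    rlang::abort(paste0("unseen label(s): ", paste(bad, collapse = ", ")))
  }
  conf <- table(factor(truth, cls), factor(pred, cls))
  conf <- matrix(conf, 3, 3, dimnames = list(true = cls, predicted = cls))
  malignant <- c("edge", "center")
  tp <- sum(conf[malignant, malignant])
  fn <- sum(conf[malignant, "normal"])
  tn <- conf["normal", "normal"]
  fp <- sum(conf["normal", malignant])
  new_classification_report(
    confusion = conf,
    accuracy = (tp + tn) / sum(conf),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    variant = variant, seed = seed
  )
}

#' @rdname evaluate
#' @param x A `classification_report`.
#' @param ... Unused.
#' @export
tidy.classification_report <- function(x, ...) {
  tibble::tibble(metric = c("accuracy", "sensitivity", "specificity"),
                 value = c(x$accuracy, x$sensitivity, x$specificity))
}

#' @rdname evaluate
#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(variant = x$variant, accuracy = x$accuracy,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 n_test = x$n_test, seed = x$seed)
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> variant=%s n_test=%d\n",
              x$variant, x$n_test))
  print(x$confusion)
  cat(sprintf("accuracy %.1f%% | sensitivity %.1f%% | specificity %.1f%% (malignant = edge+center)\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
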