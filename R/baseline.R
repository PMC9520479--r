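#' Configuration for the Morlet-sum fluorescence baseline fit
#'
#' The fluorescence continuum under tissue Raman spectra is modeled as
#' a sum of K real-valued Morlet wavelets
#' \deqn{B(\nu) = \sum_k a_k \exp(-((\nu-c_k)/s_k)^2/2)\cos(\omega_0 (\nu-c_k)/s_k)}
#' fitted by bounded nonlinear least squares with an asymmetric loss:
#' residuals where the baseline exceeds the signal are penalized
#' `asymmetry`-fold more than residuals below it, which keeps the
#' estimated continuum under the Raman peaks (standard
#' baseline-estimation practice). The fit is deterministic: multiple
#' starts are placed at fixed quantiles of the axis and the best final
#' objective wins.
#'
#' @param n_wavelets Number of Morlet terms K.
#' @param omega0 Carrier frequency of the mother wavelet
#'   (dimensionless).
#' @param scale_bounds Allowed wavelet scales (cm^-1). The lower bound
#'   must stay far above the smoothing window so the baseline cannot
#'   chase individual Raman lines. The upper bound must comfortably
#'   exceed the width of the fluorescence continuum: with carrier
#'   omega0 the positive central lobe of a Morlet spans only about
#'   +/- (pi/2) s / omega0, so representing a lobe of standard
#'   deviation sigma needs scales near 3-4 sigma. The default upper
#'   bound of 8000 cm^-1 admits continua wider than the whole
#'   127-2830 cm^-1 axis.
#' @param center_bounds Allowed centers (cm^-1); default is the axis
#'   range of the fitted spectrum.
#' @param asymmetry Penalty ratio for baseline-above-signal residuals
#'   (>= 1). The default of 100 pins the continuum to the lower
#'   envelope of the signal so that narrow Raman peaks are left
#'   intact; mild ratios let the baseline absorb 10-20% of the peak
#'   area.
#' @param max_iter,tol Optimizer budget and relative convergence
#'   tolerance.
#' @param n_starts Number of deterministic multi-starts.
#' @return A `morlet_fit_config` list.
#' @export
morlet_fit_config <- function(n_wavelets = 4, omega0 = 5,
                              scale_bounds = c(150, 8000),
                              center_bounds = NULL, asymmetry = 100,
                              max_iter = 300, tol = 1e-9, n_starts = 6) {
  stopifnot(n_wavelets >= 1, omega0 > 0, length(scale_bounds) == 2,
            scale_bounds[1] > 0, scale_bounds[1] < scale_bounds[2],
            asymmetry >= 1, max_iter >= 1, n_starts >= 1)
  structure(list(n_wavelets = n_wavelets, omega0 = omega0,
                 scale_bounds = scale_bounds, center_bounds = center_bounds,
                 asymmetry = asymmetry, max_iter = max_iter, tol = tol,
                 n_starts = n_starts),
            class = "morlet_fit_config")
}

# evaluate a sum of real Morlet wavelets; theta = (a_1..a_K, c_1..c_K, s_1..s_K)
morlet_sum <- function(theta, axis, omega0) {
  K <- length(theta) / 3
  a <- theta[seq_len(K)]
  c0 <- theta[K + seq_len(K)]
  s <- theta[2 * K + seq_len(K)]
  out <- numeric(length(axis))
  for (k in seq_len(K)) {
    u <- (axis - c0[k]) / s[k]
    out <- out + a[k] * exp(-u^2 / 2) * cos(omega0 * u)
  }
  out
}

#' Fit a Morlet-sum baseline to one spectrum
#'
#' @param x A single-spectrum [raman_spectra] tibble, or a numeric
#'   intensity vector (then `axis` is required).
#' @param axis Wavenumber axis matching `x` when `x` is numeric.
#' @param config A [morlet_fit_config].
#' @return A `morlet_baseline` object: tibble of per-wavelet
#'   parameters (`amplitude`, `center`, `scale`), `omega0`,
#'   `fit_loss` (final mean asymmetric squared residual), `converged`
#'   flag and the config used. Use [predict_morlet] to evaluate it.
#' @export
fit_morlet_baseline <- function(x, axis = NULL, config = morlet_fit_config()) {
  if (inherits(x, "raman_spectra")) {
    if (dplyr::n_distinct(x$spectrum_id) != 1) {
      rlang::abort("fit_morlet_baseline expects a single spectrum; see preprocess_pipeline for sets")
    }
    axis <- spectra_axis(x)
    y <- dplyr::arrange(tibble::as_tibble(x), .data$wavenumber)$intensity
  } else {
    y <- as.numeric(x)
    if (is.null(axis) || length(axis) != length(y)) {
      rlang::abort("numeric input requires a matching axis")
    }
  }
  stopifnot(inherits(config, "morlet_fit_config"))
  K <- config$n_wavelets
  omega0 <- config$omega0
  cb <- config$center_bounds %||% range(axis)
  sb <- config$scale_bounds
  asym <- config$asymmetry

  ymax <- max(y, 0)
  lower <- c(rep(0, K), rep(cb[1], K), rep(sb[1], K))
  upper <- c(rep(max(2 * ymax, 1e-8), K), rep(cb[2], K), rep(sb[2], K))

  objective <- function(theta) {
    r <- morlet_sum(theta, axis, omega0) - y
    w <- ifelse(r > 0, asym, 1)
    mean(w * r^2)
  }
  gradient <- function(theta) {
    B <- morlet_sum(theta, axis, omega0)
    r <- B - y
    w <- ifelse(r > 0, asym, 1)
    wr <- 2 * w * r / length(y)
    g <- numeric(3 * K)
    a <- theta[seq_len(K)]; c0 <- theta[K + seq_len(K)]; s <- theta[2 * K + seq_len(K)]
    for (k in seq_len(K)) {
      u <- (axis - c0[k]) / s[k]
      E <- exp(-u^2 / 2); C <- cos(omega0 * u); S <- sin(omega0 * u)
      core <- E * (u * C + omega0 * S)
      g[k] <- sum(wr * E * C)
      g[K + k] <- sum(wr * a[k] * core / s[k])
      g[2 * K + k] <- sum(wr * a[k] * core * u / s[k])
    }
    g
  }

  starts <- morlet_starts(y, axis, K, cb, sb, config$n_starts)
  best <- NULL
  for (st in starts) {
    fit <- stats::nlminb(st, objective, gradient = gradient,
                         lower = lower, upper = upper,
                         control = list(iter.max = config$max_iter,
                                        eval.max = 4 * config$max_iter,
                                        rel.tol = config$tol))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  # polish: a finite-difference pass is less prone to stalling at the
  # kinks of the asymmetric loss than the analytic-gradient pass
  pre_obj <- best$objective
  polish <- stats::nlminb(best$par, objective, lower = lower, upper = upper,
                          control = list(iter.max = config$max_iter,
                                         eval.max = 4 * config$max_iter,
                                         rel.tol = config$tol))
  if (polish$objective < best$objective) best <- polish
  # stability: if the polish pass barely moves the objective, the
  # optimum is settled even when the optimizer stopped at its budget
  stable <- pre_obj - best$objective < 1e-4 * max(pre_obj, .Machine$double.eps)
  # nlminb reports several benign stopping messages ("relative
  # convergence", "false convergence") besides code 0; only hitting
  # the iteration/evaluation budget counts as non-convergence here
  converged <- stable || best$convergence == 0 ||
    (grepl("convergence", best$message %||% "") &&
       !grepl("limit", best$message %||% ""))
  if (!converged) rlang::warn("Morlet baseline fit did not converge")
  theta <- best$par
  params <- tibble::tibble(amplitude = theta[seq_len(K)],
                           center = theta[K + seq_len(K)],
                           scale = theta[2 * K + seq_len(K)])
  structure(list(params = params, omega0 = omega0,
                 fit_loss = best$objective, converged = converged,
                 config = config),
            class = "morlet_baseline")
}

# deterministic multi-start layouts: centers at fixed axis quantiles,
# scales proportional to the axis span (the continuum varies on that
# scale), amplitudes from the signal level at each center
morlet_starts <- function(y, axis, K, cb, sb, n_starts) {
  ypos <- pmax(y, 0)
  span <- diff(range(axis))
  clamp <- function(s) max(min(s, sb[2]), sb[1])
  layouts <- list(
    list(probs = seq_len(K) / (K + 1), scale = clamp(0.8 * span), frac = 0.8),
    list(probs = (seq_len(K) - 0.5) / K, scale = clamp(2 * sb[1]), frac = 0.7),
    list(probs = (seq_len(K) - 0.5) / K, scale = clamp(1.5 * span), frac = 0.9),
    list(probs = seq_len(K) / (K + 1), scale = clamp(sqrt(sb[1] * sb[2])), frac = 0.6),
    list(probs = seq_len(K) / (K + 1), scale = clamp(0.6 * span), frac = 0.8),
    list(probs = (seq_len(K) - 0.5) / K, scale = clamp(0.25 * span), frac = 0.7)
  )
  layouts <- layouts[seq_len(min(n_starts, length(layouts)))]
  lapply(layouts, function(l) {
    centers <- cb[1] + l$probs * diff(cb)
    amps <- l$frac * stats::approx(axis, ypos, xout = pmin(pmax(centers, min(axis)),
                                                           max(axis)))$y
    c(pmax(amps, 0), centers, rep(l$scale, K))
  })
}

#' Evaluate a fitted Morlet baseline on an axis
#' @param model A `morlet_baseline`.
#' @param axis Wavenumber axis (cm^-1).
#' @return Numeric baseline curve.
#' @export
predict_morlet <- function(model, axis) {
  stopifnot(inherits(model, "morlet_baseline"))
  morlet_sum(c(model$params$amplitude, model$params$center,
               model$params$scale), axis, model$omega0)
}

#' Remove a fitted baseline from spectra
#'
#' Subtracts the evaluated Morlet-sum baseline pointwise; values are
#' not clipped at zero (set `clip_negative = TRUE` to clip).
#'
#' @param x A [raman_spectra] tibble.
#' @param models A single `morlet_baseline` (applied to every
#'   spectrum) or a named list, one model per `spectrum_id`.
#' @param clip_negative Clip negative residuals to zero.
#' @return `x` with the baseline removed.
#' @export
remove_baseline <- function(x, models, clip_negative = FALSE) {
  ax <- spectra_axis(x)
  m <- spectra_matrix(x)
  if (inherits(models, "morlet_baseline")) {
    models <- stats::setNames(rep(list(models), nrow(m)), rownames(m))
  }
  for (id in rownames(m)) {
    if (is.null(models[[id]])) rlang::abort(paste0("no baseline model for ", id))
    m[id, ] <- m[id, ] - predict_morlet(models[[id]], ax)
  }
  if (clip_negative) m <- pmax(m, 0)
  matrix_to_spectra(m, ax, spectra_meta(x),
                    provenance = c(provenance(x), "remove_baseline(morlet)"))
}

#' @export
print.morlet_baseline <- function(x, ...) {
  cat(sprintf("<morlet_baseline> K=%d, omega0=%g, loss=%.4g, converged=%s\n",
              nrow(x$params), x$omega0, x$fit_loss, x$converged))
  print(x$params)
  invisible(x)
}

#' @rdname fit_morlet_baseline
#' @param x A `morlet_baseline` object.
#' @param ... Unused.
#' @method tidy morlet_baseline
#' @export
tidy.morlet_baseline <- function(x, ...) {
  dplyr::mutate(x$params, wavelet = dplyr::row_number(), .before = 1)
}

#' @rdname fit_morlet_baseline
#' @method glance morlet_baseline
#' @export
glance.morlet_baseline <- function(x, ...) {
  tibble::tibble(n_wavelets = nrow(x$params), omega0 = x$omega0,
                 fit_loss = x$fit_loss, converged = x$converged)
}
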