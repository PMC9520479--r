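# shared fixtures built in code; the expensive preprocessed dataset is
# computed once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

# small, fast generator setup: short axis, same structure
small_config <- function(...) {
  defaults <- list(n_points = 400, axis_lo = 127, axis_hi = 2830,
                   saturation_fraction = 0)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# deterministic noiseless setup used for exact constructions
clean_config <- function(...) {
  small_config(noise_sd = 0, fluor_amplitude = 0, ambient_drift = 0,
               gain_drift_cv = 0, fluor_replicate_cv = 0, ...)
}

# a single-peak profile with no amplitude variability
single_peak_profile <- function(amp = 1, center = 1400, fwhm = 30) {
  tibble::tibble(component = "test", peak_center = center, fwhm = fwhm,
                 amp_normal = amp, amp_edge = amp, amp_center = amp,
                 between_sample_cv = 0, within_sample_cv = 0)
}

split_frames <- function(spectra) {
  tbl <- tibble::as_tibble(spectra)
  list(
    meas = raman_spectra(dplyr::filter(tbl, frame_kind == "measurement")),
    bg = raman_spectra(dplyr::filter(tbl, frame_kind == "background"))
  )
}

# full-size paper-like dataset preprocessed once and reused across tests
shared_preprocessed <- function() {
  if (is.null(.fixture_env$pre)) {
    sim <- generate_dataset(study_design_config(seed = 11))
    fr <- split_frames(sim$spectra)
    pre <- suppressWarnings(preprocess_pipeline(fr$meas, fr$bg))
    .fixture_env$pre <- pre
    .fixture_env$sim <- sim
  }
  list(pre = .fixture_env$pre, sim = .fixture_env$sim)
}

# scalar, loop-based one-way ANOVA used as an independent oracle
anova_bruteforce <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}
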