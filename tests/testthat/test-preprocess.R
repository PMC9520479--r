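make_flat_frames <- function(levels, axis = seq(900, 1000, by = 10)) {
  long <- purrr::imap_dfr(levels, function(v, i) {
    tibble::tibble(spectrum_id = paste0("f", i), sample_id = "s1",
                   frame_kind = "background",
                   wavenumber = axis, intensity = v)
  })
  raman_spectra(long)
}

test_that("background averaging is the pointwise mean", {
  same <- make_flat_frames(rep(3.5, 5))
  avg <- average_background(same)
  expect_equal(unique(avg$intensity), 3.5)
  two <- make_flat_frames(c(0, 2))
  expect_equal(unique(average_background(two)$intensity), 1)
  expect_error(average_background(raman_spectra(tibble::tibble(
    spectrum_id = character(), wavenumber = double(), intensity = double()))))
  # seeded noisy frames: mean within 3 sd/sqrt(n) of the true level
  noise_sd <- 4
  noisy <- withr::with_seed(2, make_flat_frames(rep(100, 5)) |>
                              dplyr::mutate(intensity = intensity + rnorm(dplyr::n(), 0, noise_sd)) |>
                              raman_spectra())
  avg <- average_background(noisy)
  expect_true(all(abs(avg$intensity - 100) < 3 * noise_sd / sqrt(5) + 1e-12))
})

test_that("background subtraction is exact, preserves negatives, checks axes", {
  x <- make_flat_frames(c(5, 7))
  bg <- average_background(make_flat_frames(6))
  out <- subtract_background(x, bg)
  expect_equal(sort(unique(out$intensity)), c(-1, 1))
  expect_equal(unique(subtract_background(x, average_background(make_flat_frames(0)))$intensity),
               c(5, 7))
  self <- raman_spectra(dplyr::filter(tibble::as_tibble(x), spectrum_id == "f1"))
  expect_equal(unique(subtract_background(self, self)$intensity), 0)
  bg_other <- make_flat_frames(1, axis = seq(900, 1000, by = 5))
  expect_error(subtract_background(x, average_background(bg_other)), "axis")
})

test_that("saturation exclusion removes exactly the overexposed spectra", {
  x <- make_flat_frames(c(100, 180, 195))   # ceiling 200, threshold 0.9 -> 180
  x$frame_kind <- "measurement"
  x <- raman_spectra(x)
  none <- exclude_saturated(x, 400, 0.9)
  expect_equal(dplyr::n_distinct(none$spectrum_id), 3)
  some <- exclude_saturated(x, 200, 0.9)
  expect_setequal(attr(some, "excluded"), "f3")
  expect_equal(dplyr::n_distinct(some$spectrum_id), 2)
  # cross-check against generator ground truth on a seeded run
  d <- generate_dataset(small_config(seed = 7, saturation_fraction = 0.05))
  kept <- exclude_saturated(split_frames(d$spectra)$meas, 65535, 0.90)
  expect_setequal(attr(kept, "excluded"),
                  d$truth$meta$spectrum_id[d$truth$meta$saturated])
})

test_that("Savitzky-Golay reproduces low-order polynomials and damps noise", {
  ax <- seq(900, 1800, length.out = 300)
  long <- tibble::tibble(spectrum_id = "a", wavenumber = ax,
                         intensity = 2 + 0.01 * ax - 1e-5 * ax^2 + 1e-8 * ax^3)
  x <- raman_spectra(long)
  sm <- savitzky_golay(x, 15, 3)
  expect_lt(max(abs(sm$intensity - x$intensity) / abs(x$intensity)), 1e-9)

  const <- raman_spectra(dplyr::mutate(long, intensity = 4.2))
  expect_equal(savitzky_golay(const, 15, 3)$intensity, rep(4.2, 300))
  expect_error(savitzky_golay(raman_spectra(long[1:10, ]), 15, 3), "window")

  # white-noise variance shrinks by the sum of squared central weights
  w <- signal::sgolay(p = 3, n = 15)[8, ]
  shrink <- sum(w^2)
  vars <- purrr::map_dbl(1:100, function(s) {
    y <- withr::with_seed(s, rnorm(300))
    stats::var(signal::sgolayfilt(y, p = 3, n = 15)[30:270])
  })
  expect_lt(abs(mean(vars) / shrink - 1), 0.10)
})

test_that("cropping keeps the closed interval and the synthetic grid count", {
  ax4 <- c(899, 900, 1800, 1801)
  x4 <- raman_spectra(tibble::tibble(spectrum_id = "a", wavenumber = ax4,
                                     intensity = 1:4))
  expect_equal(crop_range(x4, 900, 1800)$wavenumber, c(900, 1800))
  full <- crop_range(x4, 899, 1801)
  expect_equal(nrow(full), 4)
  ax2050 <- seq(127, 2830, length.out = 2050)
  x <- raman_spectra(tibble::tibble(spectrum_id = "a", wavenumber = ax2050,
                                    intensity = 0))
  expect_equal(nrow(crop_range(x, 900, 1800)), 683)
  expect_error(crop_range(x4, 1000, 1100), "no axis points")
})

test_that("integral normalization has unit area, idempotence and scale invariance", {
  ax <- seq(900, 1800, length.out = 200)
  x <- raman_spectra(tibble::tibble(spectrum_id = "a", wavenumber = ax,
                                    intensity = 2))
  n1 <- normalize_integral(x)
  expect_equal(unique(n1$intensity), 1 / 900, tolerance = 1e-12)
  scaled <- raman_spectra(dplyr::mutate(tibble::as_tibble(x), intensity = intensity * 7))
  expect_equal(normalize_integral(scaled)$intensity, n1$intensity)
  expect_equal(normalize_integral(n1)$intensity, n1$intensity)
  neg <- raman_spectra(dplyr::mutate(tibble::as_tibble(x), intensity = -1))
  expect_error(normalize_integral(neg), "integral")
})

test_that("the full chain is deterministic and reproduces class band ordering", {
  sh <- shared_preprocessed()
  pre <- sh$pre
  ints <- tibble::as_tibble(pre) |>
    dplyr::group_by(spectrum_id) |>
    dplyr::summarise(I = pracma::trapz(wavenumber, intensity))
  expect_true(all(abs(ints$I - 1) < 1e-9))
  expect_equal(length(spectra_axis(pre)), 683)
  expect_equal(sort(as.integer(table(spectra_meta(pre)$tissue_class))), c(14L, 15L, 19L))

  # configured carotenoid ordering survives preprocessing: normal > edge > center
  car <- tibble::as_tibble(pre) |>
    dplyr::filter(wavenumber >= 1149, wavenumber <= 1165) |>
    dplyr::group_by(tissue_class) |>
    dplyr::summarise(m = mean(intensity))
  expect_gt(car$m[car$tissue_class == "normal"], car$m[car$tissue_class == "edge"])
  expect_gt(car$m[car$tissue_class == "edge"], car$m[car$tissue_class == "center"])
  # hemoglobin ordering is reversed: center > normal
  hb <- tibble::as_tibble(pre) |>
    dplyr::filter(wavenumber >= 1546, wavenumber <= 1558) |>
    dplyr::group_by(tissue_class) |>
    dplyr::summarise(m = mean(intensity))
  expect_gt(hb$m[hb$tissue_class == "center"], hb$m[hb$tissue_class == "normal"])

  # determinism of the chain on a small instance
  d <- generate_dataset(small_config(seed = 3))
  fr <- split_frames(d$spectra)
  cfgp <- preprocess_config(baseline = morlet_fit_config(n_starts = 2, max_iter = 150))
  p1 <- suppressWarnings(preprocess_pipeline(fr$meas, fr$bg, cfgp))
  p2 <- suppressWarnings(preprocess_pipeline(fr$meas, fr$bg, cfgp))
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))
})

test_that("a clean single peak passes through the chain as a unit-integral peak", {
  grid <- seq(127, 2830, length.out = 400)
  center <- grid[189]
  cfg <- clean_config(components = single_peak_profile(amp = 50, center = center,
                                                       fwhm = 40),
                      ambient_level = 20)
  d <- generate_dataset(cfg)
  fr <- split_frames(d$spectra)
  pre <- suppressWarnings(preprocess_pipeline(fr$meas, fr$bg,
                                              dynamic_range_max = cfg$dynamic_range_max))
  one <- dplyr::filter(tibble::as_tibble(pre),
                       spectrum_id == spectra_meta(pre)$spectrum_id[1])
  expect_equal(pracma::trapz(one$wavenumber, one$intensity), 1, tolerance = 1e-9)
  # shape: maximum at the configured center, near-zero far from it
  expect_equal(one$wavenumber[which.max(one$intensity)], center)
  far <- dplyr::filter(one, abs(wavenumber - center) > 200)
  expect_lt(max(abs(far$intensity)), 0.05 * max(one$intensity))
})
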