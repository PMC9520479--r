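test_that("the Fisher criterion matches independent ANOVA oracles", {
  # worked example: F and p agree with anova(lm(...)) exactly
  g <- list(c(6, 8, 4, 5, 3, 4), c(8, 12, 9, 11, 6, 8), c(13, 9, 11, 8, 7, 12))
  labels <- factor(rep(c("normal", "edge", "center"), each = 6))
  ft <- fisher_statistic(unlist(g), labels)
  d <- data.frame(y = unlist(g), cls = labels)
  oracle <- stats::anova(stats::lm(y ~ cls, d))
  expect_equal(ft$statistic, oracle$`F value`[1], tolerance = 1e-12)
  expect_equal(ft$p.value, oracle$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(c(ft$df1, ft$df2), c(2, 15))

  # vectorized path equals anova(lm) on random matrices
  withr::with_seed(1, {
    for (rep in 1:25) {
      n_g <- sample(2:8, 3, replace = TRUE)
      labs <- factor(rep(tissue_classes(), times = n_g))
      m <- matrix(rnorm(sum(n_g) * 4), ncol = 4)
      ft <- fisher_statistic(m, labs)
      for (j in 1:4) {
        a <- stats::anova(stats::lm(m[, j] ~ labs))
        expect_equal(ft$statistic[j], a$`F value`[1], tolerance = 1e-10)
        expect_equal(ft$p.value[j], a$`Pr(>F)`[1], tolerance = 1e-10)
      }
    }
  })
})

test_that("degenerate group structures are handled by convention", {
  labels <- factor(rep(tissue_classes(), each = 3))
  # identical groups: F = 0, p = 1
  ft0 <- fisher_statistic(rep(c(1, 2, 3), times = 3), factor(rep(tissue_classes(), each = 3)))
  expect_equal(ft0$statistic, 0)
  expect_equal(ft0$p.value, 1)
  # zero variance, equal means
  ftc <- fisher_statistic(rep(5, 9), labels)
  expect_equal(ftc$statistic, 0)
  # zero within variance, unequal means
  fti <- fisher_statistic(rep(c(0, 0, 5), each = 3), labels)
  expect_equal(fti$statistic, Inf)
  expect_equal(fti$p.value, 0)
  # near-perfect separation blows up
  y <- c(rep(0, 6), rep(5, 3)) + withr::with_seed(2, rnorm(9, 0, 1e-6))
  expect_gt(fisher_statistic(y, labels)$statistic, 1e6)
  expect_error(fisher_statistic(1:3, factor(c("normal", "edge", "center"))), ">= 2")
})

test_that("F critical values agree with an independent numerical integrator", {
  expect_equal(critical_value(0.05, 2, 45), 3.204, tolerance = 1e-3)
  # independent route: integrate the F density until the upper tail is alpha
  fc <- critical_value(0.05, 2, 45)
  tail <- pracma::integral(function(x) stats::df(x, 2, 45), fc, 200)
  expect_equal(tail, 0.05, tolerance = 1e-6)
  expect_gt(critical_value(0.001, 2, 45), critical_value(0.05, 2, 45))
  expect_lt(critical_value(0.999, 2, 45), 1e-2)
  expect_error(critical_value(0.05, 0, 45), "degrees")
})

test_that("masks keep the discriminative column and compose with filtering", {
  withr::with_seed(4, {
    labs <- rep(tissue_classes(), times = c(14, 15, 19))
    m <- matrix(rnorm(48 * 30), 48, 30,
                dimnames = list(sprintf("s%02d", 1:48), NULL))
    m[, 7] <- m[, 7] + c(rep(0, 14), rep(3, 15), rep(6, 19))
    gm <- ramanbiopsy:::new_grouped_matrix(m, labs, seq(900, 1800, length.out = 30))
    mask <- build_mask(gm, 0.05)
    expect_true(mask$keep[7])
    expect_equal(attr(mask, "f_critical"), stats::qf(0.95, 2, 45))
    expect_true(all((mask$statistic > attr(mask, "f_critical")) == mask$keep))

    flt <- filter_matrix(gm, mask)
    expect_equal(ncol(flt$values), sum(mask$keep))
    expect_equal(flt$wavenumbers, gm$wavenumbers[mask$keep])

    # all-true mask is the identity
    mask_all <- mask
    mask_all$keep <- rep(TRUE, nrow(mask_all))
    expect_identical(filter_matrix(gm, mask_all)$values, gm$values)

    # permutation equivariance: shuffling columns and flags together
    perm <- sample(30)
    gm_p <- ramanbiopsy:::new_grouped_matrix(m[, perm], labs,
                                             seq(900, 1800, length.out = 30)[perm])
    mask_p <- mask[perm, ]
    class(mask_p) <- class(mask)
    expect_setequal(as.vector(filter_matrix(gm_p, mask_p)$values),
                    as.vector(flt$values))

    mask_none <- mask
    mask_none$keep <- rep(FALSE, nrow(mask_none))
    expect_error(filter_matrix(gm, mask_none), "alpha")
  })
})

test_that("band sums aggregate only retained wavenumbers and annotate tiers", {
  withr::with_seed(5, {
    labs <- rep(tissue_classes(), times = c(6, 6, 6))
    wn <- seq(1000, 1590, by = 10)
    m <- matrix(rnorm(18 * 60), 18, 60,
                dimnames = list(sprintf("s%02d", 1:18), NULL))
    m[, 56] <- m[, 56] + c(rep(0, 6), rep(2, 6), rep(6, 6))  # 1550: hemoglobin-like
    gm <- ramanbiopsy:::new_grouped_matrix(m, labs, wn)
    mask <- build_mask(gm, 0.05)
    bands <- tibble::tribble(~component, ~lo, ~hi,
                             "hemoglobin", 1546, 1558,
                             "empty_zone", 1200, 1203)
    bs <- aggregate_bands(gm, mask, bands)
    expect_s3_class(bs, "band_summary")
    hb <- dplyr::filter(bs$bands, component == "hemoglobin")
    expect_true(all(hb$tier != "ns"))
    expect_gt(hb$mean[hb$tissue_class == "center"], hb$mean[hb$tissue_class == "normal"])
    empty <- dplyr::filter(bs$sums, component == "empty_zone")
    # the 1200-1203 interval holds the (unretained) 1200 column at most
    if (all(empty$n_wavenumbers == 0)) expect_true(all(empty$band_sum == 0))
    expect_true(all(dplyr::filter(bs$bands, component == "empty_zone")$tier == "ns" |
                      any(empty$n_wavenumbers > 0)))

    # a band covering exactly one retained column equals that column
    one <- tibble::tibble(component = "single", lo = 1549, hi = 1551)
    bs1 <- aggregate_bands(gm, mask, one)
    expect_equal(bs1$sums$band_sum, unname(m[, 56]))

    # with an all-true mask aggregation equals plain band integration
    mask_all <- mask
    mask_all$keep <- rep(TRUE, nrow(mask_all))
    bs_all <- aggregate_bands(gm, mask_all, bands)
    plain <- rowSums(m[, wn >= 1546 & wn <= 1558, drop = FALSE])
    expect_equal(dplyr::filter(bs_all$sums, component == "hemoglobin")$band_sum,
                 unname(plain))
  })
})

test_that("permuted labels retain close to alpha of pure-noise columns", {
  withr::with_seed(6, {
    labs <- rep(tissue_classes(), times = c(14, 15, 19))
    fracs <- purrr::map_dbl(1:10, function(r) {
      m <- matrix(rnorm(48 * 200), 48, 200)
      gm <- ramanbiopsy:::new_grouped_matrix(m, sample(labs), 1:200)
      mean(build_mask(gm, 0.05)$keep)
    })
    ci <- 2.576 * sqrt(0.05 * 0.95 / (10 * 200))
    expect_lt(abs(mean(fracs) - 0.05), ci)
  })
})

test_that("the hemoglobin contrast in the study-like dataset reaches significance", {
  sh <- shared_preprocessed()
  m <- grouped_matrix(sh$pre)
  mask <- build_mask(m, 0.05)
  bs <- aggregate_bands(m, mask, default_band_library())
  hb <- dplyr::filter(bs$bands, component == "hemoglobin")
  expect_gt(hb$mean[hb$tissue_class == "center"], hb$mean[hb$tissue_class == "normal"])
  expect_true(all(hb$tier %in% c("*", "**")))
  # every configured discriminative band overlaps at least one kept wavenumber
  db <- sh$sim$truth$discriminative_bands
  kept_wn <- mask$wavenumber[mask$keep]
  overlaps <- vapply(seq_len(nrow(db)), function(b) {
    any(kept_wn >= db$lo[b] & kept_wn <= db$hi[b])
  }, logical(1))
  expect_true(all(overlaps))
})

test_that("the discriminant-ratio criterion keeps the top fraction by ratio", {
  withr::with_seed(9, {
    labs <- rep(tissue_classes(), times = c(8, 8, 8))
    m <- matrix(rnorm(24 * 40), 24, 40, dimnames = list(sprintf("s%02d", 1:24), NULL))
    m[, 5] <- m[, 5] + c(rep(0, 8), rep(3, 8), rep(6, 8))
    gm <- ramanbiopsy:::new_grouped_matrix(m, labs, 1:40)
    mask <- build_mask(gm, alpha = 0.10, criterion = "discriminant_ratio")
    expect_true(mask$keep[5])
    expect_equal(sum(mask$keep), 4)   # top 10% of 40 columns
    expect_equal(which.max(mask$statistic), 5L)
  })
})
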