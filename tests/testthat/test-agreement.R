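test_that("MAAPE matches hand values and its brute-force oracle", {
  expect_equal(maape(c(5, 7), c(5, 7))$maape, 0)
  expect_equal(maape(2, 1)$maape, 100 * atan(1))   # 25*pi ~ 78.54
  expect_equal(maape(2, 1)$maape, 25 * pi)

  set.seed(61)
  d <- runif(40, 10, 100)
  c_ <- runif(40, 10, 100)
  brute <- mean(vapply(seq_along(d),
                       function(i) atan(abs(d[i] - c_[i]) / abs(c_[i])),
                       numeric(1))) * 100
  expect_equal(maape(d, c_)$maape, brute, tolerance = 1e-12)

  # asymptotic bound and scale invariance
  expect_lt(maape(1e9 * d, c_)$maape, 100 * pi / 2)
  expect_equal(maape(3 * d, 3 * c_)$maape, maape(d, c_)$maape,
               tolerance = 1e-12)

  expect_error(maape(c(1, 2), c(1, 0)), "criterion value of 0")
})

test_that("regression matches exact lines and the normal-equations oracle", {
  x <- c(1, 2, 3, 4, 5)
  r1 <- regress_pairs(x, x)
  expect_equal(r1$slope, 1)
  expect_equal(r1$intercept, 0)
  expect_equal(r1$r, 1)

  r2 <- regress_pairs(2 * x + 1, x)
  expect_equal(r2$slope, 2)
  expect_equal(r2$intercept, 1)
  expect_equal(r2$r, 1)

  set.seed(62)
  cx <- rnorm(100, 70, 10)
  dy <- 1.2 * cx - 3 + rnorm(100, 0, 4)
  fit <- regress_pairs(dy, cx)
  # closed-form least squares
  b <- sum((cx - mean(cx)) * (dy - mean(dy))) / sum((cx - mean(cx))^2)
  a <- mean(dy) - b * mean(cx)
  expect_equal(fit$slope, b, tolerance = 1e-10)
  expect_equal(fit$intercept, a, tolerance = 1e-10)
  expect_equal(fit$r, cor(dy, cx), tolerance = 1e-12)

  expect_error(regress_pairs(c(1, 2), c(1, 2)), "at least 3")
  expect_error(regress_pairs(c(1, 2, 3), c(5, 5, 5)), "zero variance")
})

test_that("correlation bands follow the conventional cut points", {
  expect_equal(band_label(0.95), "very high")
  expect_equal(band_label(0.90), "very high")  # boundary goes up
  expect_equal(band_label(0.70), "high")
  expect_equal(band_label(0.50), "moderate")
  expect_equal(band_label(0.30), "low")
  expect_equal(band_label(0.29), "negligible")
  expect_equal(band_label(-0.8), "high")       # computed on |r|
})

test_that("Bland-Altman recovers bias and limits of agreement", {
  x <- c(60, 70, 80)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  ba2 <- bland_altman(x + 2, x)
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$sd_diff, 0)
  expect_equal(c(ba2$loa_low, ba2$loa_high), c(2, 2))

  # sign convention: offsetting device by -k negates the bias exactly
  set.seed(63)
  c_ <- rnorm(50, 70, 8)
  ba_pos <- bland_altman(c_ + 3, c_)
  ba_neg <- bland_altman(c_ - 3, c_)
  expect_equal(ba_pos$bias, -ba_neg$bias)

  # parameter recovery: diffs ~ N(1, 2), n = 200, within 3 Monte-Carlo SEs
  set.seed(64)
  n <- 200
  crit <- rnorm(n, 70, 10)
  dev <- crit + rnorm(n, mean = 1, sd = 2)
  ba <- bland_altman(dev, crit)
  se_bias <- 2 / sqrt(n)
  se_loa <- 2 * sqrt(3 / n)
  expect_lt(abs(ba$bias - 1), 3 * se_bias)
  expect_lt(abs(ba$loa_low - (1 - 1.96 * 2)), 3 * se_loa)
  expect_lt(abs(ba$loa_high - (1 + 1.96 * 2)), 3 * se_loa)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("log transform round-trips positives and names bad entries", {
  expect_equal(ln_transform(1), 0)
  expect_equal(ln_transform(exp(1)), 1)
  set.seed(65)
  v <- runif(30, 0.1, 100)
  expect_equal(exp(ln_transform(v)), v, tolerance = 1e-12)
  expect_error(ln_transform(c(5, -1, 3), label = "RMSSD"), "position 2")
})

test_that("Bonferroni adjustment multiplies and clamps", {
  expect_equal(adjust_p(0.001, m = 32), 0.032)
  expect_equal(adjust_p(0.5, m = 32), 1)
  expect_equal(adjust_p(0.04, m = 1), 0.04)
})

test_that("pairing is pairwise complete and n tracks dropped pairs", {
  feats <- tibble::tibble(
    participant_id = rep(c("p1", "p2", "p3"), each = 2),
    device_id = rep(c("criterion", "dev"), 3),
    condition = "sitting",
    hr_bpm = c(60, 62, 70, 71, 80, NA),
    rmssd_ms = c(40, 38, 50, 49, 45, 44),
    hf_ms2 = NA_real_
  )
  paired <- pair_features(feats, criterion_id = "criterion")
  hr <- paired[paired$feature == "hr_bpm", ]
  expect_equal(nrow(hr), 3)  # pairing keeps rows; stats drop incomplete ones
  ag <- agreement_stats(paired)
  expect_equal(ag$n_pairs[ag$feature == "hr_bpm"], 2)   # p3 dropped
  expect_equal(ag$n_pairs[ag$feature == "rmssd_ms"], 3)
})

test_that("the agreement panel is coherent on a constructed cell", {
  set.seed(66)
  crit <- rnorm(20, 70, 8)
  paired <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:20),
    device_id = "dev", condition = "sitting", feature = "hr_bpm",
    device_value = crit + 2, criterion_value = crit
  )
  ag <- agreement_stats(paired)
  expect_s3_class(ag, "hrv_agreement")
  expect_equal(ag$bias, 2, tolerance = 1e-12)
  expect_equal(ag$r, 1, tolerance = 1e-12)
  expect_equal(ag$r_band, "very high")
  expect_true(ag$loa_low <= ag$bias && ag$bias <= ag$loa_high)
  expect_equal(glance(ag)$n_cells, 1)
  expect_equal(nrow(tidy(ag)), 1)
})
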