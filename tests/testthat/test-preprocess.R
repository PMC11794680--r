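test_that("range filter flags strictly out-of-range intervals only", {
  expect_equal(range_filter_flags(c(250, 800, 800)), c(TRUE, FALSE, FALSE))
  expect_false(any(range_filter_flags(c(300, 1000, 2000))))  # bounds kept
  expect_equal(range_filter_flags(c(299, 2001)), c(TRUE, TRUE))
})

test_that("Karlsson rule flags interior deviations beyond c times neighbor mean", {
  # |1100 - 800| = 300 > 0.25 * 800 = 200
  expect_equal(karlsson_flags(c(800, 1100, 800), 0.25), c(FALSE, TRUE, FALSE))
  # |990 - 800| = 190 <= 200
  expect_false(any(karlsson_flags(c(800, 990, 800), 0.25)))
  expect_false(any(karlsson_flags(rep(777, 50), 0.01)))
  expect_false(any(karlsson_flags(c(800, 1100), 0.25)))   # length < 3
  # first and last are never flagged
  f <- karlsson_flags(c(3000, 800, 800, 800, 3000), 0.25)
  expect_false(f[1])
  expect_false(f[5])
})

test_that("Karlsson flag count is monotone non-increasing in the threshold", {
  set.seed(31)
  ibis <- round(rnorm(400, 850, 120))
  grid <- seq(0.05, 1.5, by = 0.05)
  counts <- vapply(grid, function(c) sum(karlsson_flags(ibis, c)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(sum(karlsson_flags(ibis, 1e9)), 0)  # c -> Inf: all clear
})

test_that("flagged intervals are linearly interpolated over beat index", {
  s <- ibi_series(c(800, 1900, 2700), c(800, 1100, 800))
  res <- correct_flagged(s, c(FALSE, TRUE, FALSE))
  expect_equal(res$series$ibi_ms, c(800, 800, 800))
  expect_equal(res$n_artifacts, 1)
  expect_equal(res$series$interpolated, c(FALSE, TRUE, FALSE))
  expect_identical(res$series$onset_ms, s$onset_ms)

  # run of two flags interpolates evenly across the run
  s2 <- ibi_series(cumsum(c(600, 600, 600, 900)), c(600, 650, 650, 900))
  res2 <- correct_flagged(s2, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(res2$series$ibi_ms, c(600, 700, 800, 900))

  # flags at the extremes take the nearest unflagged value
  s3 <- ibi_series(cumsum(c(100, 800, 800, 100)), c(100, 800, 800, 100))
  res3 <- correct_flagged(s3, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(res3$series$ibi_ms, c(800, 800, 800, 800))

  # identity on no flags
  res4 <- correct_flagged(s, rep(FALSE, 3))
  expect_identical(res4$series, s)
  expect_equal(res4$n_artifacts, 0)

  expect_error(correct_flagged(s, rep(TRUE, 3)), "anchor")
})

test_that("clean_segment applies range filter then Karlsson and counts the union", {
  s <- tone_series(duration_s = 60, amp_ms = 0)
  res <- clean_segment(s, threshold = 0.25)
  expect_equal(res$n_artifacts, 0)
  expect_identical(res$series$ibi_ms, s$ibi_ms)

  # one range violation plus one neighbor-mean violation
  ibis <- c(800, 250, 800, 800, 1100, 800, 800)
  s2 <- ibi_series(cumsum(ibis) + 1000, ibis)
  res2 <- clean_segment(s2, threshold = 0.25)
  expect_equal(res2$n_artifacts, 2)
  expect_equal(sum(res2$series$interpolated), 2)
  expect_equal(nrow(res2$series), nrow(s2))  # replacement, not deletion

  expect_equal(glance(res2)$n_artifacts, 2)
  expect_identical(tidy(res2), res2$series)
})

test_that("cleaning is idempotent at a fixed threshold", {
  set.seed(32)
  s <- random_series(300, sd_ms = 60)
  # plant corruption
  s$ibi_ms[c(50, 120)] <- c(250, 2600)
  s$ibi_ms[200] <- s$ibi_ms[200] + 500
  first <- clean_segment(s, threshold = 0.3)
  second <- clean_segment(first$series, threshold = 0.3)
  expect_equal(second$n_artifacts, 0)
  expect_equal(second$series$ibi_ms, first$series$ibi_ms)
})

test_that("threshold tuning escalates from 0.25 in steps of 0.05", {
  clean <- tone_series(duration_s = 120, amp_ms = 10)
  w <- tibble::tibble(condition = "all", start_ms = 0, end_ms = 121000)
  expect_equal(tune_threshold(segment_ibis(clean, w)), 0.25)

  # largest neighbor-deviation ratio exactly 0.32 -> first clearing step 0.35
  ibis <- c(rep(800, 10), 800 * 1.32, rep(800, 10))
  fixture <- ibi_series(cumsum(ibis) + 1000, ibis)
  ratios <- vapply(2:(length(ibis) - 1), function(i) {
    m <- (ibis[i - 1] + ibis[i + 1]) / 2
    abs(ibis[i] - m) / m
  }, numeric(1))
  expect_equal(max(ratios), 0.32, tolerance = 1e-12)  # brute-force check
  w2 <- tibble::tibble(condition = "all", start_ms = 0,
                       end_ms = max(fixture$onset_ms) + 1)
  expect_equal(tune_threshold(segment_ibis(fixture, w2)), 0.35)

  # an in-range spike too large for any threshold <= cap errors out
  bad <- c(rep(320, 5), 2000, rep(320, 5))
  s_bad <- ibi_series(cumsum(bad) + 1000, bad)
  w3 <- tibble::tibble(condition = "all", start_ms = 0,
                       end_ms = max(s_bad$onset_ms) + 1)
  expect_error(tune_threshold(segment_ibis(s_bad, w3)), "manual review")
})

test_that("length is conserved by every preprocessing operation", {
  set.seed(33)
  s <- random_series(150)
  s$ibi_ms[c(10, 75)] <- c(200, 2500)
  expect_equal(length(range_filter_flags(s$ibi_ms)), nrow(s))
  expect_equal(length(karlsson_flags(s$ibi_ms)), nrow(s))
  expect_equal(nrow(clean_segment(s)$series), nrow(s))
})
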