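test_that("mean HR converts the mean heart period to bpm", {
  expect_equal(mean_hr(rep(1000, 7)), 60)
  expect_equal(mean_hr(rep(500, 3)), 120)
  expect_equal(mean_hr(c(800, 1000)), 60000 / 900)
  expect_true(is.na(mean_hr(numeric(0))))
})

test_that("RMSSD matches brute-force evaluation of its formula", {
  expect_equal(rmssd(rep(850, 20)), 0)
  expect_equal(rmssd(c(1000, 1100)), 100)
  expect_true(is.na(rmssd(1000)))

  set.seed(41)
  ibis <- rnorm(50, 900, 80)
  brute <- sqrt(sum((ibis[2:50] - ibis[1:49])^2) / 49)
  expect_equal(rmssd(ibis), brute, tolerance = 1e-12)
})

test_that("RMSSD is shift-invariant; mean HR is not", {
  set.seed(42)
  ibis <- rnorm(100, 900, 50)
  expect_equal(rmssd(ibis + 123), rmssd(ibis), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(mean_hr(ibis + 123), mean_hr(ibis))))
})

test_that("Welch PSD integrates to the signal variance", {
  set.seed(43)
  x <- rnorm(2048)
  spec <- welch_psd(x, fs = 4, nperseg = 256)
  total <- band_power(spec, 0, 2)
  # Welch with per-segment demeaning loses a little low-frequency power
  expect_equal(total, stats::var(x), tolerance = 0.1)
})

test_that("HF power recovers the analytic power of an in-band tone", {
  # constant series: essentially zero HF
  const <- uniform_series(400, ibi_ms = 900)
  expect_lt(hf_power(const), 1e-6)

  # 0.25 Hz, 50 ms amplitude over 5 min: HF ~ 50^2/2 = 1250 ms^2
  inband <- tone_series(duration_s = 300, amp_ms = 50, freq_hz = 0.25)
  hf_in <- hf_power(inband)
  expect_equal(hf_in, 1250, tolerance = 0.10)

  # 0.05 Hz tone lies below the band: < 5% of the in-band target
  outband <- tone_series(duration_s = 300, amp_ms = 50, freq_hz = 0.05)
  expect_lt(hf_power(outband), 0.05 * 1250)
})

test_that("HF of in-band plus out-of-band tones is close to the in-band tone alone", {
  dur <- 300
  t <- 0
  onsets <- c(); ibis <- c()
  while (t <= dur * 1000) {
    ibi <- round(900 + 40 * sin(2 * pi * 0.25 * t / 1000) +
                   60 * sin(2 * pi * 0.03 * t / 1000))
    t <- t + ibi
    if (t > dur * 1000) break
    onsets <- c(onsets, t); ibis <- c(ibis, ibi)
  }
  both <- ibi_series(onsets, ibis)
  alone <- tone_series(duration_s = dur, amp_ms = 40, freq_hz = 0.25)
  expect_equal(hf_power(both), hf_power(alone), tolerance = 0.15)
})

test_that("segments spanning under a minute return NA HF with a reason", {
  short <- uniform_series(20, ibi_ms = 800)
  expect_message(v <- hf_power(short), "not computed")
  expect_true(is.na(v))
})

test_that("respiration limits convert to the spectral band", {
  expect_equal(breaths_to_hz(c(7.2, 24)), c(0.12, 0.40))
})

test_that("features on the synthetic criterion recover generator ground truth", {
  cfg <- synth_config(seed = 44, duration_s = 300, mean_ibi_ms = 800,
                      rsa_amp_ms = 40, noise_sd_ms = 15)
  sim <- simulate_criterion(cfg)
  expect_gte(sim$truth$n_ibis, 300)
  f <- extract_features(
    segment_ibis(sim$series,
                 tibble::tibble(condition = "all", start_ms = 0,
                                end_ms = max(sim$series$onset_ms) + 1)))
  expect_equal(f$hr_bpm, sim$truth$hr_bpm, tolerance = 1e-12)      # exact
  expect_equal(f$rmssd_ms, sim$truth$rmssd_ms, tolerance = 0.02)   # within 2%
})

test_that("extract_features emits one row per condition with counts", {
  s <- tone_series(duration_s = 240, amp_ms = 20)
  w <- tibble::tibble(condition = c("a", "b"),
                      start_ms = c(0, 120000), end_ms = c(120000, 240001))
  f <- extract_features(segment_ibis(s, w), conditions = c("a", "b"))
  expect_equal(nrow(f), 2)
  expect_equal(sum(f$n_ibis), nrow(s))
  expect_true(all(f$hr_bpm > 0))
  expect_true(all(f$rmssd_ms >= 0))
})
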