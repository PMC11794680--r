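test_that("config invariants are enforced", {
  expect_error(synth_config(miss_rate = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(rsa_amp_ms = -1), "non-negative")
  expect_error(synth_config(mean_ibi_ms = 400, rsa_amp_ms = 80), "300 ms")
})

test_that("the degenerate generator produces a perfectly regular heartbeat", {
  cfg <- synth_config(seed = 71, duration_s = 120, mean_ibi_ms = 900,
                      rsa_amp_ms = 0, noise_sd_ms = 0)
  sim <- simulate_criterion(cfg)
  expect_true(all(sim$series$ibi_ms == 900))
  expect_equal(sim$truth$rmssd_ms, 0)
  expect_equal(sim$truth$hr_bpm, 60000 / 900)
  # beat count within +/- 2 of duration / mean
  expect_lte(abs(sim$truth$n_ibis - 120000 / 900), 2)
})

test_that("the generator is deterministic under its seed", {
  cfg <- synth_config(seed = 72, duration_s = 60, noise_sd_ms = 25)
  expect_identical(simulate_criterion(cfg)$series,
                   simulate_criterion(cfg)$series)
  dev1 <- corrupt_series(simulate_criterion(cfg)$series,
                         synth_config(seed = 72, miss_rate = 0.2,
                                      jitter_sd_ms = 5))
  dev2 <- corrupt_series(simulate_criterion(cfg)$series,
                         synth_config(seed = 72, miss_rate = 0.2,
                                      jitter_sd_ms = 5))
  expect_identical(dev1, dev2)
})

test_that("ground-truth RMSSD matches the features module to 1e-9", {
  cfg <- synth_config(seed = 73, duration_s = 240, noise_sd_ms = 30)
  sim <- simulate_criterion(cfg)
  expect_equal(sim$truth$rmssd_ms, rmssd(sim$series$ibi_ms),
               tolerance = 1e-9)
  expect_equal(sim$truth$hr_bpm, mean_hr(sim$series$ibi_ms),
               tolerance = 1e-9)
})

test_that("corruption with all rates zero and no offset is the identity", {
  cfg <- synth_config(seed = 74, duration_s = 90)
  crit <- simulate_criterion(cfg)$series
  dev <- corrupt_series(crit, synth_config(seed = 74), device_id = "criterion")
  expect_equal(dev$onset_ms, crit$onset_ms)
  expect_equal(dev$ibi_ms, crit$ibi_ms)

  # pure clock offset shifts onsets only
  off <- corrupt_series(crit, synth_config(seed = 74, clock_offset_ms = 5000))
  expect_equal(off$onset_ms, crit$onset_ms + 5000)
  expect_equal(off$ibi_ms, crit$ibi_ms)
})

test_that("missed beats halve the detection rate at miss_rate 0.5", {
  cfg <- synth_config(seed = 75, duration_s = 600, mean_ibi_ms = 800,
                      rsa_amp_ms = 0, noise_sd_ms = 0)
  crit <- simulate_criterion(cfg)$series
  dev <- corrupt_series(crit, synth_config(seed = 75, miss_rate = 0.5))
  rate <- detection_rate(nrow(dev), nrow(crit))
  # binomial tolerance: sd of survivor fraction ~ 0.5/sqrt(n)
  n <- nrow(crit)
  expect_lt(abs(rate - 50), 100 * 4 * 0.5 / sqrt(n))
})

test_that("increasing miss_rate monotonically lowers mean detection rate", {
  cfg <- synth_config(seed = 76, duration_s = 300, rsa_amp_ms = 0,
                      noise_sd_ms = 0)
  crit <- simulate_criterion(cfg)$series
  rates <- vapply(c(0, 0.2, 0.4, 0.6), function(mr) {
    mean(vapply(1:5, function(s) {
      dev <- corrupt_series(crit, synth_config(seed = 760 + s, miss_rate = mr))
      detection_rate(nrow(dev), nrow(crit))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("spurious beats split intervals and raise the count", {
  cfg <- synth_config(seed = 77, duration_s = 300, rsa_amp_ms = 0,
                      noise_sd_ms = 0)
  crit <- simulate_criterion(cfg)$series
  dev <- corrupt_series(crit, synth_config(seed = 77, extra_rate = 0.3))
  expect_gt(nrow(dev), nrow(crit))
  # total span is preserved by splitting
  expect_equal(sum(dev$ibi_ms), sum(crit$ibi_ms), tolerance = 0.01)
})

test_that("a dropout window empties the overlapping condition", {
  cfg <- synth_config(seed = 78, duration_s = 360)
  crit <- simulate_criterion(cfg)$series
  dev <- corrupt_series(crit, synth_config(
    seed = 78, dropout_windows = list(c(120000, 240000))))
  w <- tibble::tibble(condition = c("a", "drop", "c"),
                      start_ms = c(0, 121000, 241000),
                      end_ms = c(120000, 239000, 360000))
  seg <- segment_ibis(dev, w)
  expect_equal(sum(!is.na(seg$condition) & seg$condition == "drop"), 0)
  expect_gt(sum(!is.na(seg$condition) & seg$condition == "a"), 0)
})

test_that("simulate_cohort builds a consistent paired study", {
  cohort <- simulate_cohort(n_participants = 2,
                            devices = list(good = NULL),
                            conditions = c("sitting", "walking"),
                            durations_s = c(sitting = 120, walking = 120),
                            seed = 79)
  expect_setequal(unique(cohort$ibi$device_id), c("criterion", "good"))
  expect_equal(nrow(cohort$conditions), 4)
  # perfect device: identical streams per participant
  for (p in unique(cohort$ibi$participant_id)) {
    a <- cohort$ibi[cohort$ibi$participant_id == p &
                      cohort$ibi$device_id == "criterion", ]
    b <- cohort$ibi[cohort$ibi$participant_id == p &
                      cohort$ibi$device_id == "good", ]
    expect_equal(a$ibi_ms, b$ibi_ms)
  }
})
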