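#' Configuration for the paired-stream simulator
#'
#' Defines a criterion interbeat-interval stream with respiratory-band
#' sinusoidal modulation (respiratory sinus arrhythmia, RSA) and beat-to-beat
#' Gaussian noise, plus the corruption applied to derive a device stream:
#' missed beats (adjacent intervals merge), spurious beats (an interval
#' splits), peak-time jitter, contiguous dropouts, and a constant clock
#' offset. Defaults emulate a seated adult over one 3-minute experimental
#' condition: 800 ms mean heart period (75 bpm), 40 ms RSA amplitude at
#' 0.25 Hz (15 breaths/min, inside the 0.12-0.40 Hz band) and 20 ms
#' beat-to-beat noise.
#'
#' @param seed Integer seed; every stochastic step is deterministic under it.
#' @param duration_s Recording span in seconds.
#' @param mean_ibi_ms Mean heart period in ms.
#' @param rsa_amp_ms RSA modulation amplitude in ms.
#' @param rsa_freq_hz RSA frequency in Hz.
#' @param noise_sd_ms SD of beat-to-beat Gaussian noise in ms.
#' @param miss_rate Per-beat probability that the device misses a beat.
#' @param extra_rate Per-interval probability of a spurious detected beat.
#' @param jitter_sd_ms SD of Gaussian timing jitter on device peak times.
#' @param dropout_windows List of `c(start_ms, end_ms)` windows (device
#'   clock) in which all beats are lost.
#' @param clock_offset_ms Constant offset of the device clock ahead of the
#'   criterion clock.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, duration_s = 180, mean_ibi_ms = 800,
                         rsa_amp_ms = 40, rsa_freq_hz = 0.25,
                         noise_sd_ms = 20, miss_rate = 0, extra_rate = 0,
                         jitter_sd_ms = 0, dropout_windows = list(),
                         clock_offset_ms = 0) {
  cfg <- list(seed = as.integer(seed), duration_s = duration_s,
              mean_ibi_ms = mean_ibi_ms, rsa_amp_ms = rsa_amp_ms,
              rsa_freq_hz = rsa_freq_hz, noise_sd_ms = noise_sd_ms,
              miss_rate = miss_rate, extra_rate = extra_rate,
              jitter_sd_ms = jitter_sd_ms, dropout_windows = dropout_windows,
              clock_offset_ms = clock_offset_ms)
  if (cfg$miss_rate < 0 || cfg$miss_rate > 1 ||
      cfg$extra_rate < 0 || cfg$extra_rate > 1) {
    stop("miss_rate and extra_rate must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$rsa_amp_ms < 0 || cfg$noise_sd_ms < 0 || cfg$jitter_sd_ms < 0) {
    stop("Amplitudes and noise SDs must be non-negative", call. = FALSE)
  }
  if (cfg$mean_ibi_ms - cfg$rsa_amp_ms - 4 * cfg$noise_sd_ms <= 300) {
    stop("mean_ibi_ms - rsa_amp_ms - 4*noise_sd_ms must exceed 300 ms ",
         "(keeps true intervals inside the plausibility range)", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# evaluate code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  # burn-in: initial draws from nearby Mersenne-Twister seeds are correlated,
  # and derived per-participant/per-device seeds are nearby by construction
  stats::runif(32)
  force(code)
}

#' Simulate a criterion IBI stream with known ground truth
#'
#' Beats are generated iteratively: the next interval is
#' `mean_ibi_ms + rsa_amp_ms * sin(2 * pi * rsa_freq_hz * t) + N(0, noise_sd_ms)`
#' with t the current beat time in seconds, rounded to integer milliseconds.
#' Ground-truth features are computed directly from the realized intervals
#' through formulas written out here, independently of the features module;
#' the HF truth is the analytic tone power `rsa_amp_ms^2 / 2` (exact for the
#' pure sinusoid; beat noise adds broadband power on top).
#'
#' @param cfg A [synth_config()].
#' @param start_ms Epoch time of the first (opening) beat.
#' @param participant_id,device_id Labels for the emitted series.
#' @return A list: `series` (IBI series tibble) and `truth` (one-row tibble
#'   `hr_bpm`, `rmssd_ms`, `hf_ms2`, `n_ibis`).
#' @export
simulate_criterion <- function(cfg, start_ms = 0,
                               participant_id = "p1",
                               device_id = "criterion") {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(cfg$seed, {
    end_ms <- start_ms + cfg$duration_s * 1000
    # generous upper bound on beat count, then truncate
    n_max <- ceiling(cfg$duration_s * 1000 /
                       (cfg$mean_ibi_ms - cfg$rsa_amp_ms - 4 * cfg$noise_sd_ms)) + 8
    t <- start_ms
    onsets <- numeric(0)
    ibis <- numeric(0)
    for (i in seq_len(n_max)) {
      ibi <- cfg$mean_ibi_ms +
        cfg$rsa_amp_ms * sin(2 * pi * cfg$rsa_freq_hz * t / 1000) +
        stats::rnorm(1, 0, cfg$noise_sd_ms)
      ibi <- round(ibi)
      t <- t + ibi
      if (t > end_ms) break
      onsets <- c(onsets, t)
      ibis <- c(ibis, ibi)
    }
    series <- ibi_series(onsets, ibis, participant_id, device_id)
    n <- length(ibis)
    truth <- tibble::tibble(
      hr_bpm = 60000 / (sum(ibis) / n),
      rmssd_ms = if (n >= 2)
        sqrt(sum((ibis[-1] - ibis[-n])^2) / (n - 1)) else NA_real_,
      hf_ms2 = cfg$rsa_amp_ms^2 / 2,
      n_ibis = n
    )
    list(series = series, truth = truth)
  })
}

#' Corrupt a criterion stream into a device stream
#'
#' Corruption acts on reconstructed peak times (miss/extra events physically
#' act on beats), then intervals are re-derived, keeping merge/split
#' semantics exact. Order of operations: clock offset; per-beat deletion with
#' probability `miss_rate` (adjacent intervals merge); per-interval insertion
#' with probability `extra_rate` at a uniform point (the interval splits);
#' Gaussian jitter on every peak time; removal of all beats inside
#' `dropout_windows`. Deterministic under `cfg$seed`.
#'
#' @param criterion An IBI series tibble from [simulate_criterion()].
#' @param cfg A [synth_config()].
#' @param device_id Label for the emitted device series.
#' @return The corrupted IBI series tibble.
#' @export
corrupt_series <- function(criterion, cfg, device_id = "device") {
  stopifnot(inherits(cfg, "synth_config"), nrow(criterion) > 0)
  with_local_seed(cfg$seed + 104729L, {
    peaks <- ibis_to_peaks(criterion) + cfg$clock_offset_ms
    n <- length(peaks)
    if (cfg$miss_rate > 0 && n > 2) {
      drop <- c(FALSE, stats::runif(n - 2) < cfg$miss_rate, FALSE)
      peaks <- peaks[!drop]
    }
    if (cfg$extra_rate > 0 && length(peaks) > 1) {
      gaps <- which(stats::runif(length(peaks) - 1) < cfg$extra_rate)
      if (length(gaps) > 0) {
        ins <- peaks[gaps] +
          stats::runif(length(gaps)) * (peaks[gaps + 1] - peaks[gaps])
        peaks <- sort(c(peaks, ins))
      }
    }
    if (cfg$jitter_sd_ms > 0) {
      peaks <- sort(peaks + stats::rnorm(length(peaks), 0, cfg$jitter_sd_ms))
    }
    for (w in cfg$dropout_windows) {
      peaks <- peaks[peaks < w[1] | peaks >= w[2]]
    }
    peaks <- unique(round(peaks))
    peaks_to_ibis(peaks,
                  participant_id = criterion$participant_id[1],
                  device_id = device_id)
  })
}

#' Simulate a raw tri-axial accelerometer trace
#'
#' Per condition window, band-limited Gaussian noise whose total (3-axis)
#' RMS equals the requested movement level is superimposed on a constant 1 g
#' gravity vector along z, then quantized to ADC counts under the given
#' calibration. Band-limiting is a low-pass at a quarter of the sample rate
#' (capped at 5 Hz), which keeps essentially all power above the 0.1 Hz
#' gravity-removal high-pass.
#'
#' @param windows A tibble with `condition`, `start_ms`, `end_ms`.
#' @param movement_levels Named numeric vector: target RMS magnitude in g per
#'   condition (e.g. `c(sitting = 0.01, walking = 0.16)`).
#' @param sample_rate_hz Accelerometer rate in Hz.
#' @param cfg A [synth_config()] (for the seed).
#' @param digital_range,physical_range ADC calibration.
#' @return An AccelRaw tibble: `time_ms,x,y,z,digital_range,physical_range`.
#' @export
simulate_accel <- function(windows, movement_levels, sample_rate_hz = 32,
                           cfg = synth_config(),
                           digital_range = 65536, physical_range = 4) {
  with_local_seed(cfg$seed + 7919L, {
    step_ms <- 1000 / sample_rate_hz
    cutoff <- min(5, sample_rate_hz / 4)
    bf <- signal::butter(4, cutoff / (sample_rate_hz / 2), type = "low")
    out <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
      t_ms <- seq(windows$start_ms[i], windows$end_ms[i] - step_ms,
                  by = step_ms)
      nsamp <- length(t_ms)
      level <- movement_levels[[windows$condition[i]]]
      axis <- function() {
        v <- as.numeric(signal::filtfilt(bf, stats::rnorm(nsamp)))
        if (level > 0 && stats::sd(v) > 0) {
          v * (level / sqrt(3)) / stats::sd(v)
        } else {
          rep(0, nsamp)
        }
      }
      tibble::tibble(time_ms = t_ms, gx = axis(), gy = axis(),
                     gz = 1 + axis())
    })
    sens <- physical_range / digital_range
    tibble::tibble(
      time_ms = out$time_ms,
      x = round(out$gx / sens),
      y = round(out$gy / sens),
      z = round(out$gz / sens),
      digital_range = digital_range,
      physical_range = physical_range
    )
  })
}

#' Simulate a full paired-device cohort
#'
#' Builds the canonical study layout: per participant, a criterion stream
#' covering the whole condition sequence, one corrupted device stream per
#' configured device, and the condition-window table. Condition durations
#' default to the standard protocol: 5 min seated rest, ~10 min
#' neuropsychological task, 3 min otherwise.
#'
#' @param n_participants Number of simulated participants.
#' @param devices Named list: per device, either a [synth_config()] carrying
#'   the corruption parameters, or `NULL` for a perfect (uncorrupted) device.
#'   Missing recordings are simulated by the `missing_prob` element if a
#'   device entry is a list with `cfg` and `missing_prob`.
#' @param conditions Character vector of condition names in protocol order.
#' @param durations_s Named numeric vector of condition durations in seconds;
#'   unnamed conditions default to 180 s.
#' @param seed Cohort seed; participant p and device d derive their own seed
#'   from it.
#' @param ... Passed to [synth_config()] for the criterion generator (e.g.
#'   `mean_ibi_ms`, `noise_sd_ms`).
#' @return A list: `ibi` (all series row-bound), `conditions` (window table),
#'   `truth` (per participant x condition criterion ground truth).
#' @export
simulate_cohort <- function(n_participants = 5,
                            devices = list(device = NULL),
                            conditions = c("sitting", "arithmetic", "recovery",
                                           "standing", "breathing", "neurotask",
                                           "walking", "biking"),
                            durations_s = c(sitting = 300, neurotask = 600),
                            seed = 1L, ...) {
  dur <- stats::setNames(rep(180, length(conditions)), conditions)
  dur[names(durations_s)] <- durations_s
  gap_ms <- 10000  # short inter-condition transition
  starts <- cumsum(c(0, (dur[-length(dur)] * 1000 + gap_ms)))
  windows_one <- tibble::tibble(
    condition = conditions,
    start_ms = unname(starts),
    end_ms = unname(starts + dur * 1000)
  )
  total_s <- (max(windows_one$end_ms) + gap_ms) / 1000

  all_ibi <- list()
  all_windows <- list()
  all_truth <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("p%02d", p)
    pseed <- seed * 1000L + p
    base_cfg <- synth_config(seed = pseed, duration_s = total_s, ...)
    crit <- simulate_criterion(base_cfg, start_ms = 0,
                               participant_id = pid,
                               device_id = "criterion")
    all_ibi[[length(all_ibi) + 1]] <- crit$series

    seg_truth <- segment_ibis(crit$series, windows_one)
    all_truth[[length(all_truth) + 1]] <-
      extract_features(seg_truth, conditions = conditions) |>
      dplyr::mutate(device_id = "criterion_truth")

    for (d in seq_along(devices)) {
      dname <- names(devices)[d]
      spec <- devices[[d]]
      miss_prob <- 0
      dcfg <- spec
      if (is.list(spec) && !inherits(spec, "synth_config") &&
          any(c("cfg", "missing_prob") %in% names(spec))) {
        miss_prob <- spec$missing_prob %||% 0
        dcfg <- spec$cfg
      }
      record <- with_local_seed(pseed * 10L + d,
                                stats::runif(1) >= miss_prob)
      if (!record) next  # device-level recording failure -> no rows at all
      if (is.null(dcfg)) {
        dev <- crit$series
        dev$device_id <- dname
      } else {
        dcfg$seed <- pseed * 10L + d
        dev <- corrupt_series(crit$series, dcfg, device_id = dname)
      }
      all_ibi[[length(all_ibi) + 1]] <- dev
    }
    w <- windows_one
    w$participant_id <- pid
    all_windows[[length(all_windows) + 1]] <- w
  }
  list(
    ibi = dplyr::bind_rows(all_ibi),
    conditions = dplyr::bind_rows(all_windows)[
      , c("participant_id", "condition", "start_ms", "end_ms")],
    truth = dplyr::bind_rows(all_truth)
  )
}
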