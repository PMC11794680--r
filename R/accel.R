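#' Convert raw accelerometer counts to g units
#'
#' Sensitivity is the ratio of the physical range to the digital range;
#' counts are assumed two's-complement centered at zero (no offset term).
#'
#' @param raw A tibble from [read_accel_csv()] (`time_ms,x,y,z` plus
#'   `digital_range`, `physical_range`), or one with those calibration values
#'   passed explicitly.
#' @param digital_range,physical_range Optional calibration overrides.
#' @return A tibble `time_ms, gx, gy, gz` in g.
#' @export
#' @examples
#' raw <- tibble::tibble(time_ms = 0, x = 16384, y = 0, z = 0,
#'                       digital_range = 65536, physical_range = 4)
#' adc_to_g(raw) # gx = 1
adc_to_g <- function(raw, digital_range = NULL, physical_range = NULL) {
  dr <- digital_range %||% raw$digital_range[1]
  pr <- physical_range %||% raw$physical_range[1]
  if (is.null(dr) || is.null(pr) || is.na(dr) || is.na(pr) ||
      dr <= 0 || pr <= 0) {
    stop("Positive digital_range and physical_range calibration is required",
         call. = FALSE)
  }
  sens <- pr / dr
  tibble::tibble(
    time_ms = raw$time_ms,
    gx = raw$x * sens,
    gy = raw$y * sens,
    gz = raw$z * sens
  )
}

#' Zero-phase high-pass filter for an accelerometer axis
#'
#' First-order Butterworth high-pass (default cutoff 0.1 Hz) applied
#' forward-backward with [signal::filtfilt()], removing the static
#' gravitational component without phase lag against the condition windows.
#'
#' @param x Numeric signal, uniformly sampled.
#' @param sample_rate_hz Sampling rate in Hz; must exceed twice the cutoff.
#' @param cutoff_hz High-pass cutoff in Hz.
#' @param order Filter order.
#' @return The filtered signal.
#' @export
accel_highpass <- function(x, sample_rate_hz, cutoff_hz = 0.1, order = 1) {
  if (sample_rate_hz <= 2 * cutoff_hz) {
    stop("Sample rate must exceed twice the cutoff frequency", call. = FALSE)
  }
  if (length(x) < 3 * (order + 1)) {
    stop("Signal too short for stable filtering", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2), type = "high")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (the filter settles over ~1/cutoff seconds)
  n <- length(x)
  npad <- min(n - 1, ceiling(3 * sample_rate_hz / cutoff_hz))
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(npad + 1):(npad + n)]
}

#' Per-sample acceleration magnitude and per-condition means
#'
#' Magnitude is the Euclidean norm `sqrt(gx^2 + gy^2 + gz^2)` per sample;
#' the mean magnitude within each condition window summarizes movement
#' intensity. Empty windows yield `NA`.
#'
#' @param accel A tibble `time_ms, gx, gy, gz` (already high-pass filtered,
#'   see [accel_highpass()]).
#' @param windows A tibble with `condition`, `start_ms`, `end_ms` (half-open
#'   windows).
#' @return A tibble per condition: `condition`, `mean_magnitude_g`,
#'   `n_samples`.
#' @export
accel_condition_means <- function(accel, windows) {
  mag <- sqrt(accel$gx^2 + accel$gy^2 + accel$gz^2)
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    hit <- accel$time_ms >= windows$start_ms[i] &
      accel$time_ms < windows$end_ms[i]
    tibble::tibble(
      condition = windows$condition[i],
      mean_magnitude_g = if (any(hit)) mean(mag[hit]) else NA_real_,
      n_samples = sum(hit)
    )
  })
}

#' Full accelerometer movement summary from raw counts
#'
#' Convenience wrapper: ADC-to-g conversion, per-axis zero-phase high-pass,
#' Euclidean magnitude, per-condition means.
#'
#' @inheritParams adc_to_g
#' @inheritParams accel_highpass
#' @inheritParams accel_condition_means
#' @return As [accel_condition_means()].
#' @export
movement_summary <- function(raw, windows, sample_rate_hz,
                             cutoff_hz = 0.1, order = 1) {
  g <- adc_to_g(raw)
  g$gx <- accel_highpass(g$gx, sample_rate_hz, cutoff_hz, order)
  g$gy <- accel_highpass(g$gy, sample_rate_hz, cutoff_hz, order)
  g$gz <- accel_highpass(g$gz, sample_rate_hz, cutoff_hz, order)
  accel_condition_means(g, windows)
}
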