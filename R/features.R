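#' Mean heart rate from IBIs
#'
#' `HR = 60000 / mean(IBI)` in beats per minute: the mean heart period in ms
#' converted to a rate.
#'
#' @param ibis Numeric vector of IBIs in ms.
#' @return Heart rate in bpm, or `NA` for an empty segment.
#' @export
#' @examples
#' mean_hr(c(1000, 1000)) # 60 bpm
mean_hr <- function(ibis) {
  if (length(ibis) < 1) return(NA_real_)
  60000 / mean(ibis)
}

#' Root mean square of successive differences (RMSSD)
#'
#' `sqrt(mean(diff(IBI)^2))` with the conventional `N - 1` divisor over the
#' `N - 1` successive differences, in ms. A time-domain vagal-tone proxy.
#'
#' @param ibis Numeric vector of IBIs in ms (index order).
#' @return RMSSD in ms, or `NA` when fewer than 2 intervals are available.
#' @export
rmssd <- function(ibis) {
  if (length(ibis) < 2) return(NA_real_)
  sqrt(mean(diff(ibis)^2))
}

#' Welch power spectral density estimate
#'
#' Hann-windowed, overlapping-segment averaged one-sided periodogram with
#' density scaling (power per Hz): integrating the returned density over all
#' frequencies recovers the signal variance. Segments shorter than `nperseg`
#' use the whole signal as a single segment.
#'
#' @param x Numeric signal (uniformly sampled, mean already removed if DC is
#'   not wanted).
#' @param fs Sampling rate in Hz.
#' @param nperseg Samples per Welch segment (default 256).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A tibble with `freq_hz` and `psd` (units of `x` squared per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 256, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  if (nperseg < 8) stop("Signal too short for spectral estimation", call. = FALSE)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / nperseg)  # periodic Hann
  scale <- fs * sum(w^2)
  nfreq <- nperseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[1:nfreq])^2 / scale
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nfreq] <- 1
  tibble::tibble(
    freq_hz = seq(0, nfreq - 1) * fs / nperseg,
    psd = psd * dbl
  )
}

#' High-frequency spectral power of an IBI series
#'
#' The IBI values are interpolated by a cubic spline onto a uniform grid
#' (default 4 Hz) over the segment span, the mean is removed, a Welch
#' periodogram is computed (Hann window, 256-sample segments or the whole
#' grid if shorter, 50\% overlap) and the density is integrated over the
#' high-frequency band (default 0.12-0.40 Hz, i.e. 7.2-24 breaths per
#' minute) by the trapezoidal rule. Units are ms squared. Cubic-spline
#' resampling is used because piecewise-linear resampling from beat-rate
#' samples attenuates in-band power by roughly `sinc(f*T)^4` (about 29\% of
#' the power of a 0.25 Hz tone at a 900 ms heart period), biasing HF
#' downward; the spline tracks respiratory-band oscillations with under 2\%
#' power error at typical heart rates.
#'
#' @param series An IBI series tibble spanning at least `min_span_s` seconds
#'   with at least 2 beats.
#' @param hf_low_hz,hf_high_hz Band edges in Hz.
#' @param resample_hz Uniform grid rate in Hz.
#' @param nperseg,overlap Welch parameters, see [welch_psd()].
#' @param min_span_s Minimum segment span in seconds; shorter segments return
#'   `NA` (too little data for a stable spectral estimate).
#' @return HF power in ms^2, or `NA` with a message when the span is too
#'   short.
#' @export
hf_power <- function(series, hf_low_hz = 0.12, hf_high_hz = 0.40,
                     resample_hz = 4, nperseg = 256, overlap = 0.5,
                     min_span_s = 60) {
  if (nrow(series) < 2) return(NA_real_)
  span_ms <- series$onset_ms[nrow(series)] - series$onset_ms[1]
  if (span_ms < min_span_s * 1000) {
    message("Segment span ", round(span_ms / 1000, 1),
            " s < ", min_span_s, " s: HF power not computed")
    return(NA_real_)
  }
  step_ms <- 1000 / resample_hz
  t_grid <- seq(series$onset_ms[1], series$onset_ms[nrow(series)], by = step_ms)
  x <- stats::spline(series$onset_ms, series$ibi_ms, xout = t_grid,
                     method = "fmm")$y
  x <- x - mean(x)
  spec <- welch_psd(x, fs = resample_hz, nperseg = nperseg, overlap = overlap)
  band_power(spec, hf_low_hz, hf_high_hz)
}

#' Integrate a PSD over a frequency band by the trapezoidal rule
#'
#' Band edges falling between PSD bins are included by linear interpolation
#' of the density at the exact edges.
#'
#' @param spec A tibble from [welch_psd()].
#' @param low_hz,high_hz Band edges in Hz.
#' @return Integrated power in the band.
#' @export
band_power <- function(spec, low_hz, high_hz) {
  f <- spec$freq_hz
  p <- spec$psd
  inside <- f > low_hz & f < high_hz
  fk <- c(low_hz, f[inside], high_hz)
  pk <- c(stats::approx(f, p, xout = low_hz, rule = 2)$y,
          p[inside],
          stats::approx(f, p, xout = high_hz, rule = 2)$y)
  sum(diff(fk) * (pk[-1] + pk[-length(pk)]) / 2)
}

#' Convert a respiration rate to a spectral frequency
#'
#' Breaths per minute divided by 60 gives Hz; the conventional respiratory
#' band of 7.2-24 breaths per minute maps onto 0.12-0.40 Hz.
#'
#' @param breaths_per_min Respiration rate(s) in breaths per minute.
#' @return Frequency in Hz.
#' @export
#' @examples
#' breaths_to_hz(c(7.2, 24)) # 0.12 0.40
breaths_to_hz <- function(breaths_per_min) {
  breaths_per_min / 60
}

#' Extract the outcome features for every segment
#'
#' One row per participant x device x condition: mean HR (bpm), RMSSD (ms),
#' HF power (ms^2) and the number of intervals used. Empty segments yield a
#' row of `NA` features with `n_ibis = 0` so missingness stays visible.
#'
#' @param segmented An IBI series tibble with a `condition` column (beats with
#'   `NA` condition are ignored). Usually cleaned first, see [clean_segment()].
#' @param conditions Optional character vector of the full condition set, so
#'   conditions with no beats still appear.
#' @param ... Passed to [hf_power()].
#' @return A tibble of feature rows.
#' @export
extract_features <- function(segmented, conditions = NULL, ...) {
  df <- segmented[!is.na(segmented$condition), , drop = FALSE]
  conds <- conditions %||% unique(df$condition)
  pid <- if (nrow(segmented) > 0) segmented$participant_id[1] else NA_character_
  did <- if (nrow(segmented) > 0) segmented$device_id[1] else NA_character_
  purrr::map_dfr(conds, function(cn) {
    seg <- df[df$condition == cn, , drop = FALSE]
    tibble::tibble(
      participant_id = pid,
      device_id = did,
      condition = cn,
      hr_bpm = mean_hr(seg$ibi_ms),
      rmssd_ms = rmssd(seg$ibi_ms),
      hf_ms2 = hf_power(seg, ...),
      n_ibis = nrow(seg)
    )
  })
}
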