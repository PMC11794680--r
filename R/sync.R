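#' Sample an IBI series as a step function on a uniform grid
#'
#' The instantaneous heart period is held piecewise-constant between beats:
#' at time t the value is the IBI of the interval containing t (intervals are
#' anchored at their closing beat). Grid points are aligned to multiples of
#' the grid step in absolute epoch time so that two series sampled
#' independently share grid phase.
#'
#' @param series An IBI series tibble.
#' @param grid_hz Sampling rate of the grid in Hz.
#' @return A list with `t_ms` (grid times) and `value` (IBI in ms at each
#'   grid time), covering the series span.
#' @keywords internal
ibi_step_grid <- function(series, grid_hz = 4) {
  step_ms <- 1000 / grid_hz
  start <- series$onset_ms[1] - series$ibi_ms[1]
  end <- series$onset_ms[nrow(series)]
  t0 <- ceiling(start / step_ms) * step_ms
  t_ms <- seq(t0, end, by = step_ms)
  # value at t is the IBI whose closing onset is the next onset >= t
  knots_x <- c(start, series$onset_ms)
  knots_y <- c(series$ibi_ms[1], series$ibi_ms)
  v <- stats::approx(knots_x, knots_y, xout = t_ms,
                     method = "constant", f = 1, rule = 2)$y
  list(t_ms = t_ms, value = v)
}

#' Estimate the clock lag between a device and the criterion stream
#'
#' Both series are rendered as piecewise-constant instantaneous heart-period
#' step functions on a shared uniform grid (default 4 Hz, matching the
#' spectral resampling rate) and the integer-grid lag maximizing the Pearson
#' correlation of the overlapping samples is returned. A positive lag means
#' the device clock runs ahead of the criterion clock; [apply_lag()] subtracts
#' it. Ties are broken toward the smallest absolute lag.
#'
#' @param device,criterion IBI series tibbles; they must overlap by at least
#'   60 s after the lag search window is applied.
#' @param max_lag_s Half-width of the lag search window in seconds.
#' @param grid_hz Grid rate in Hz; the lag estimate is quantized to
#'   `1000 / grid_hz` ms.
#' @return A one-row tibble: `lag_ms`, `correlation`, `n_overlap` (grid
#'   samples in the best overlap) and `low_correlation` (`TRUE` when the best
#'   correlation is below 0.3, advising manual review).
#' @export
estimate_lag <- function(device, criterion, max_lag_s = 60, grid_hz = 4) {
  if (nrow(device) < 2 || nrow(criterion) < 2) {
    stop("Both series must be non-empty to synchronize", call. = FALSE)
  }
  step_ms <- 1000 / grid_hz
  gd <- ibi_step_grid(device, grid_hz)
  gc <- ibi_step_grid(criterion, grid_hz)
  max_shift <- round(max_lag_s * grid_hz)
  min_overlap <- 60 * grid_hz

  # index offset between the two grids (both phase-aligned to the epoch)
  base_off <- round((gd$t_ms[1] - gc$t_ms[1]) / step_ms)
  nd <- length(gd$value)
  nc <- length(gc$value)

  best <- tibble::tibble(lag = integer(0), r = numeric(0), n = integer(0))
  lags <- seq(-max_shift, max_shift)
  r_all <- rep(NA_real_, length(lags))
  n_all <- integer(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    # compare device sample at criterion time t + lag: device index j maps to
    # criterion grid index j + base_off - k
    off <- base_off - k
    j_lo <- max(1L, 1L - off)
    j_hi <- min(nd, nc - off)
    n_ov <- j_hi - j_lo + 1L
    n_all[i] <- max(0L, n_ov)
    if (n_ov < min_overlap) next
    dv <- gd$value[j_lo:j_hi]
    cv <- gc$value[(j_lo + off):(j_hi + off)]
    if (stats::sd(dv) == 0 || stats::sd(cv) == 0) {
      r_all[i] <- if (all(dv == dv[1]) && all(cv == cv[1])) NA else NA
    } else {
      r_all[i] <- stats::cor(dv, cv)
    }
  }
  if (all(is.na(r_all))) {
    if (max(n_all) < min_overlap) {
      stop("Insufficient overlap (< 60 s) between device and criterion ",
           "within the lag search window", call. = FALSE)
    }
    # degenerate (constant) signals: fall back to zero lag
    r_best <- NA_real_
    k_best <- 0L
    n_best <- n_all[lags == 0]
  } else {
    r_max <- max(r_all, na.rm = TRUE)
    cand <- which(!is.na(r_all) & r_all >= r_max - 1e-12)
    k_best <- lags[cand[which.min(abs(lags[cand]))]]
    r_best <- r_max
    n_best <- n_all[lags == k_best]
  }
  low <- is.na(r_best) || r_best < 0.3
  if (low) {
    warning("Best synchronization correlation ",
            if (is.na(r_best)) "undefined" else sprintf("%.2f", r_best),
            " < 0.3; manual review advised", call. = FALSE)
  }
  tibble::tibble(
    lag_ms = k_best * step_ms,
    correlation = r_best,
    n_overlap = as.integer(n_best),
    low_correlation = low
  )
}

#' Shift a device series onto the criterion clock
#'
#' Subtracts the estimated lag from every onset so device and criterion share
#' a time base. Thin wrapper over [normalize_timestamps()] with `-lag_ms`.
#'
#' @param device An IBI series tibble.
#' @param lag_ms Lag as returned by [estimate_lag()] (positive = device ahead).
#' @return The aligned series.
#' @export
apply_lag <- function(device, lag_ms) {
  normalize_timestamps(device, -lag_ms)
}

#' Slice an IBI series into condition windows
#'
#' Membership is by interval onset (the closing beat) under half-open
#' `[start, end)` windows. Beats in no window get `NA` condition; windows with
#' no beats are retained downstream because empty segments feed the "missing"
#' quality classification.
#'
#' @param series An IBI series tibble.
#' @param windows A tibble with columns `condition`, `start_ms`, `end_ms`
#'   (optionally `participant_id`, matched against the series if present).
#'   Windows must not overlap.
#' @return The series with an added `condition` column.
#' @export
segment_ibis <- function(series, windows) {
  if ("participant_id" %in% names(windows) && nrow(series) > 0) {
    windows <- windows[windows$participant_id %in% series$participant_id[1], ]
  }
  if (nrow(windows) > 1) {
    w <- windows[order(windows$start_ms), ]
    if (any(w$end_ms[-nrow(w)] > w$start_ms[-1])) {
      stop("Condition windows overlap", call. = FALSE)
    }
  }
  if (anyDuplicated(windows$condition)) {
    stop("Condition names must be unique within a participant", call. = FALSE)
  }
  cond <- rep(NA_character_, nrow(series))
  for (i in seq_len(nrow(windows))) {
    hit <- series$onset_ms >= windows$start_ms[i] &
      series$onset_ms < windows$end_ms[i]
    cond[hit] <- windows$condition[i]
  }
  series$condition <- cond
  series
}
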