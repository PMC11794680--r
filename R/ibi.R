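#' Construct a tidy interbeat-interval series
#'
#' The interbeat-interval (IBI) series is the universal currency of the
#' validation pipeline: one row per beat-to-beat interval, timestamped in
#' integer milliseconds since the Unix epoch. An interval is anchored at the
#' time of the beat that *closes* it, and that convention is used everywhere
#' (segmentation, synchronization, resampling).
#'
#' @param onset_ms Numeric vector, milliseconds since the Unix epoch of the
#'   beat closing each interval. Must be strictly increasing.
#' @param ibi_ms Numeric vector of interval durations in milliseconds, all
#'   positive, same length as `onset_ms`.
#' @param participant_id,device_id Scalar character labels.
#' @param interpolated Logical vector marking values replaced during artifact
#'   correction; all `FALSE` on freshly ingested data.
#'
#' @return A tibble with columns `participant_id`, `device_id`, `onset_ms`,
#'   `ibi_ms`, `interpolated`.
#' @export
#' @examples
#' ibi_series(c(1000, 1800), c(800, 800))
ibi_series <- function(onset_ms, ibi_ms,
                       participant_id = "p1", device_id = "device",
                       interpolated = rep(FALSE, length(onset_ms))) {
  out <- tibble::tibble(
    participant_id = as.character(participant_id),
    device_id = as.character(device_id),
    onset_ms = as.numeric(onset_ms),
    ibi_ms = as.numeric(ibi_ms),
    interpolated = as.logical(interpolated)
  )
  validate_ibi_series(out)
}

#' Check the IBI-series invariants
#'
#' Onsets strictly increasing, equal column lengths (guaranteed by the tibble
#' container), and all intervals positive.
#'
#' @param series A tibble as returned by [ibi_series()].
#' @return The series, invisibly unchanged, or an error.
#' @export
validate_ibi_series <- function(series) {
  needed <- c("participant_id", "device_id", "onset_ms", "ibi_ms", "interpolated")
  missing <- setdiff(needed, names(series))
  if (length(missing) > 0) {
    stop("IBI series is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(series) > 0) {
    if (any(diff(series$onset_ms) <= 0)) {
      stop("IBI onsets must be strictly increasing", call. = FALSE)
    }
    if (any(series$ibi_ms <= 0)) {
      stop("All IBIs must be positive", call. = FALSE)
    }
  }
  series
}

#' Convert a train of systolic peak times to an IBI series
#'
#' Successive differences of detected systolic peaks become intervals; the
#' interval between peaks i and i+1 is anchored at peak i+1 (the closing
#' beat). Fewer than two peaks give an empty series.
#'
#' @param peaks A tibble with a `peak_time_ms` column (strictly increasing),
#'   or a bare numeric vector of peak times in ms.
#' @inheritParams ibi_series
#' @return An IBI series tibble of length `n_peaks - 1`.
#' @export
#' @examples
#' peaks_to_ibis(c(0, 800, 1600))
peaks_to_ibis <- function(peaks, participant_id = "p1", device_id = "device") {
  times <- if (is.data.frame(peaks)) peaks$peak_time_ms else as.numeric(peaks)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("Peak times must be strictly increasing", call. = FALSE)
  }
  if (length(times) < 2) {
    return(ibi_series(numeric(0), numeric(0), participant_id, device_id))
  }
  ibi_series(
    onset_ms = times[-1],
    ibi_ms = diff(times),
    participant_id = participant_id,
    device_id = device_id
  )
}

#' Reconstruct peak times from an IBI series
#'
#' Inverse of [peaks_to_ibis()] under the closing-beat convention: the first
#' peak is the first onset minus the first interval, then every onset. Exact
#' on integer-millisecond data.
#'
#' @param series An IBI series tibble.
#' @return Numeric vector of peak times in ms (length `nrow(series) + 1`, or
#'   0 for an empty series).
#' @export
ibis_to_peaks <- function(series) {
  if (nrow(series) == 0) return(numeric(0))
  c(series$onset_ms[1] - series$ibi_ms[1], series$onset_ms)
}

#' Shift all timestamps of an IBI series by a constant clock offset
#'
#' Used to bring device clocks onto the criterion time base. Interval values
#' are untouched.
#'
#' @param series An IBI series tibble.
#' @param clock_offset_ms Signed offset in milliseconds added to every onset.
#' @return The shifted series.
#' @export
normalize_timestamps <- function(series, clock_offset_ms) {
  series$onset_ms <- series$onset_ms + clock_offset_ms
  series
}
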