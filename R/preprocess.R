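#' Flag physiologically implausible intervals
#'
#' Intervals strictly shorter than `low_ms` or strictly longer than `high_ms`
#' are flagged; values exactly on a bound are kept. Defaults are the standard
#' 300-2000 ms plausibility window for adult heart periods.
#'
#' @param ibis Numeric vector of IBIs in ms.
#' @param low_ms,high_ms Plausibility bounds in ms.
#' @return Logical flag vector, `TRUE` where implausible.
#' @export
range_filter_flags <- function(ibis, low_ms = 300, high_ms = 2000) {
  ibis < low_ms | ibis > high_ms
}

#' Flag outliers by the Karlsson neighbor-mean rule
#'
#' For each interior interval i the mean m of its two neighbors is computed
#' on the *original* values; the interval is flagged when
#' `|ibi[i] - m| > c * m`. The first and last intervals are never flagged.
#' All flags are evaluated simultaneously (no sequential re-evaluation), so
#' the result does not depend on processing order.
#'
#' @param ibis Numeric vector of IBIs in ms.
#' @param c Fractional threshold coefficient (> 0); the conventional starting
#'   value is 0.25.
#' @return Logical flag vector; all `FALSE` for series shorter than 3.
#' @export
karlsson_flags <- function(ibis, c = 0.25) {
  stopifnot(c > 0)
  n <- length(ibis)
  flags <- rep(FALSE, n)
  if (n < 3) return(flags)
  i <- 2:(n - 1)
  m <- (ibis[i - 1] + ibis[i + 1]) / 2
  flags[i] <- abs(ibis[i] - m) > c * m
  flags
}

#' Replace flagged intervals by linear interpolation
#'
#' Each flagged value is replaced by linear interpolation *over beat index*
#' between the nearest unflagged neighbors; runs of consecutive flags are
#' interpolated across the run, and flagged values at either extreme take the
#' nearest unflagged value (constant extension). Onsets are unchanged and the
#' series keeps its length; replacements are recorded in the
#' `interpolated` mask.
#'
#' @param series An IBI series tibble.
#' @param flags Logical vector, same length as the series.
#' @return A list of class `ibi_clean`: `series` (corrected tibble),
#'   `n_artifacts` (number of replaced intervals), `threshold_used`
#'   (`NA` here; set by [clean_segment()]).
#' @export
correct_flagged <- function(series, flags) {
  stopifnot(length(flags) == nrow(series))
  if (nrow(series) > 0 && all(flags)) {
    stop("All intervals flagged: nothing to anchor interpolation",
         call. = FALSE)
  }
  ibis <- series$ibi_ms
  if (any(flags)) {
    idx <- seq_along(ibis)
    ibis[flags] <- stats::approx(idx[!flags], ibis[!flags], xout = idx[flags],
                                 method = "linear", rule = 2)$y
  }
  series$ibi_ms <- ibis
  series$interpolated <- series$interpolated | flags
  structure(
    list(series = series, n_artifacts = sum(flags), threshold_used = NA_real_),
    class = "ibi_clean"
  )
}

#' Clean one segment: range filter, then Karlsson rule, with interpolation
#'
#' Order of operations: (1) flag out-of-range intervals and interpolate them
#' in place; (2) flag Karlsson outliers on the range-corrected values at the
#' given threshold, in a single pass, and interpolate those. Both kinds of
#' replacement count as artifacts and the union is recorded in the
#' `interpolated` mask, so `n_artifacts` equals the number of distinct
#' intervals ever replaced.
#'
#' @param series An IBI series tibble (one segment).
#' @param threshold Karlsson coefficient, typically from [tune_threshold()].
#' @param range_low_ms,range_high_ms Plausibility bounds for the range filter.
#' @return An `ibi_clean` list: corrected `series`, `n_artifacts`,
#'   `threshold_used`.
#' @export
clean_segment <- function(series, threshold = 0.25,
                          range_low_ms = 300, range_high_ms = 2000) {
  if (nrow(series) == 0) {
    return(structure(
      list(series = series, n_artifacts = 0L, threshold_used = threshold),
      class = "ibi_clean"
    ))
  }
  mask0 <- series$interpolated
  step1 <- correct_flagged(series,
                           range_filter_flags(series$ibi_ms,
                                              range_low_ms, range_high_ms))
  step2 <- correct_flagged(step1$series,
                           karlsson_flags(step1$series$ibi_ms, threshold))
  out <- step2$series
  structure(
    list(
      series = out,
      n_artifacts = sum(out$interpolated & !mask0),
      threshold_used = threshold
    ),
    class = "ibi_clean"
  )
}

#' @export
print.ibi_clean <- function(x, ...) {
  cat("<ibi_clean> ", nrow(x$series), " intervals, ",
      x$n_artifacts, " artifact(s) corrected",
      if (!is.na(x$threshold_used))
        paste0(", Karlsson threshold ", x$threshold_used), "\n", sep = "")
  invisible(x)
}

#' @method tidy ibi_clean
#' @export
tidy.ibi_clean <- function(x, ...) x$series

#' @method glance ibi_clean
#' @export
glance.ibi_clean <- function(x, ...) {
  tibble::tibble(
    n_ibis = nrow(x$series),
    n_artifacts = x$n_artifacts,
    threshold_used = x$threshold_used
  )
}

#' Tune the per-participant Karlsson threshold on criterion data
#'
#' The criterion ECG series is assumed artifact-free after expert scoring, so
#' a threshold that still flags criterion beats is too aggressive for that
#' participant (individuals with naturally high variability would be
#' over-corrected). Starting at `start`, the coefficient is escalated in
#' `step` increments until the Karlsson rule flags nothing on any criterion
#' segment (after range filtering); that single threshold is then shared by
#' all of the participant's devices and conditions.
#'
#' @param criterion_segments An IBI series tibble with a `condition` column
#'   (from [segment_ibis()]) for the criterion device, or a list of IBI
#'   series tibbles.
#' @param start,step,cap Threshold grid: candidates `start, start+step, ...`
#'   up to `cap`.
#' @param range_low_ms,range_high_ms Bounds passed to the range filter.
#' @return The smallest passing coefficient. Reaching `cap` with flags
#'   remaining is an error advising manual review of the criterion data.
#' @export
tune_threshold <- function(criterion_segments, start = 0.25, step = 0.05,
                           cap = 1.0, range_low_ms = 300, range_high_ms = 2000) {
  segs <- if (is.data.frame(criterion_segments)) {
    if ("condition" %in% names(criterion_segments)) {
      df <- criterion_segments[!is.na(criterion_segments$condition), ]
      split(df, df$condition)
    } else {
      list(criterion_segments)
    }
  } else {
    criterion_segments
  }
  segs <- segs[vapply(segs, nrow, integer(1)) > 0]
  if (length(segs) == 0) {
    stop("Criterion record has no non-empty segments", call. = FALSE)
  }
  # range-correct once; escalation concerns the Karlsson rule only
  corrected <- lapply(segs, function(s) {
    correct_flagged(s, range_filter_flags(s$ibi_ms, range_low_ms,
                                          range_high_ms))$series$ibi_ms
  })
  for (c_try in seq(start, cap + 1e-9, by = step)) {
    n_flags <- sum(vapply(corrected,
                          function(v) sum(karlsson_flags(v, c_try)),
                          numeric(1)))
    if (n_flags == 0) return(c_try)
  }
  stop("Karlsson threshold cap ", cap, " reached with outliers remaining ",
       "on the criterion series; manual review advised", call. = FALSE)
}
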