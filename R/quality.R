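#' IBI detection rate of a device against the criterion
#'
#' Device beat count as a percentage of the criterion beat count in the same
#' segment. Over-detection (> 100\%) is representable.
#'
#' @param n_device,n_criterion Interval counts for the segment.
#' @return Percent, or `NA` when the criterion count is zero (undefined,
#'   propagates as missing).
#' @export
#' @examples
#' detection_rate(60, 100) # 60
detection_rate <- function(n_device, n_criterion) {
  ifelse(n_criterion > 0, 100 * n_device / n_criterion, NA_real_)
}

#' Classify segment signal quality
#'
#' A segment is `missing` when the device recorded no data at all (device
#' failure: connection loss, unreadable export, ...). Otherwise it is `poor`
#' when the detected-interval count deviates by more than 30\% from the
#' criterion count, or when artifacts exceed 30\% of the detected intervals;
#' else `acceptable`. Both comparisons use strict inequality. A segment with
#' data but zero beats inside the window counts as a 100\% deficit (poor),
#' not missing.
#'
#' @param n_device,n_criterion Interval counts.
#' @param n_artifacts Artifacts detected in the device segment.
#' @param has_data `FALSE` when the device produced no recording for this
#'   segment.
#' @param threshold Fractional deviation threshold (default 0.30).
#' @return A one-row tibble: `label`, `detection_rate` (percent, `NA` when
#'   missing), `artifact_fraction` (percent of detected intervals), `reason`.
#' @export
classify_quality <- function(n_device, n_criterion, n_artifacts,
                             has_data = TRUE, threshold = 0.30) {
  if (!has_data) {
    return(tibble::tibble(label = "missing", detection_rate = NA_real_,
                          artifact_fraction = NA_real_,
                          reason = "no recorded data"))
  }
  rate <- detection_rate(n_device, n_criterion)
  art_frac <- if (n_device > 0) 100 * n_artifacts / n_device else NA_real_
  count_dev <- if (n_criterion > 0) abs(n_device - n_criterion) / n_criterion else NA_real_
  count_poor <- !is.na(count_dev) && count_dev > threshold
  art_poor <- n_device > 0 && n_artifacts / n_device > threshold
  if (n_device == 0) {
    label <- "poor"
    reason <- "no beats detected in segment (100% count deficit)"
  } else if (count_poor || art_poor) {
    label <- "poor"
    reason <- paste(c(
      if (count_poor) sprintf("IBI count deviates %.0f%% from criterion",
                              100 * count_dev),
      if (art_poor) sprintf("artifacts are %.0f%% of detected IBIs", art_frac)
    ), collapse = "; ")
  } else {
    label <- "acceptable"
    reason <- ""
  }
  tibble::tibble(label = label, detection_rate = rate,
                 artifact_fraction = art_frac, reason = reason)
}

#' Summarize signal quality per device and condition
#'
#' Mirrors the usual validation-report layout: percentage of poor and missing
#' segments, mean and SD of artifact counts, and mean detection rate over
#' non-missing segments, per device x condition cell.
#'
#' @param labels A tibble with one row per participant x device x condition
#'   carrying `device_id`, `condition`, `label`, `n_artifacts`,
#'   `detection_rate` (as produced by the pipeline or by binding
#'   [classify_quality()] rows).
#' @return A tibble per device x condition with `pct_poor`, `pct_missing`,
#'   `pct_acceptable`, `artifacts_mean`, `artifacts_sd`,
#'   `mean_detection_rate`, `n_segments`.
#' @export
quality_table <- function(labels) {
  labels |>
    dplyr::group_by(.data$device_id, .data$condition) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      pct_poor = 100 * mean(.data$label == "poor"),
      pct_missing = 100 * mean(.data$label == "missing"),
      pct_acceptable = 100 * mean(.data$label == "acceptable"),
      artifacts_mean = mean(.data$n_artifacts[.data$label != "missing"]),
      artifacts_sd = stats::sd(.data$n_artifacts[.data$label != "missing"]),
      mean_detection_rate = mean(.data$detection_rate[.data$label != "missing"],
                                 na.rm = TRUE),
      .groups = "drop"
    )
}
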