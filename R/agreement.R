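#' Mean arctangent absolute percentage error (MAAPE)
#'
#' The absolute percentage error of each device-criterion pair is passed
#' through the arctangent, bounding the per-pair error at pi/2 so
#' over-estimation of near-zero reference values cannot dominate the mean.
#' The mean arctan (radians) is multiplied by 100, giving a percent-like
#' scale with asymptote 100 * pi / 2 ~ 157.08.
#'
#' @param device,criterion Paired numeric vectors; criterion values must be
#'   non-zero.
#' @param conf_level Confidence level for the t-based interval over the
#'   per-pair transformed errors.
#' @return A one-row tibble: `maape`, `ci_low`, `ci_high` (`NA` CIs when
#'   n < 2), `n`.
#' @export
#' @examples
#' maape(2, 1) # 100 * atan(1) = 78.54
maape <- function(device, criterion, conf_level = 0.95) {
  stopifnot(length(device) == length(criterion), length(device) >= 1)
  if (any(criterion == 0)) {
    stop("MAAPE undefined: criterion value of 0 encountered", call. = FALSE)
  }
  e <- 100 * atan(abs(device - criterion) / abs(criterion))
  n <- length(e)
  m <- mean(e)
  if (n >= 2 && stats::sd(e) > 0) {
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
      stats::sd(e) / sqrt(n)
  } else {
    half <- if (n >= 2) 0 else NA_real_
  }
  tibble::tibble(maape = m, ci_low = m - half, ci_high = m + half, n = n)
}

#' Ordinary least-squares regression of device on criterion
#'
#' Slope, intercept, Pearson's r, the two-sided p-value for zero slope, the
#' standard error of the slope, and n.
#'
#' @param device,criterion Paired numeric vectors, n >= 3, with non-zero
#'   criterion variance.
#' @return A one-row tibble: `slope`, `intercept`, `r`, `p_value`, `stderr`,
#'   `n`.
#' @export
regress_pairs <- function(device, criterion) {
  stopifnot(length(device) == length(criterion))
  n <- length(device)
  if (n < 3) stop("Regression requires at least 3 pairs", call. = FALSE)
  if (stats::var(criterion) == 0) {
    stop("Criterion values have zero variance", call. = FALSE)
  }
  fit <- stats::lm(device ~ criterion)
  # a perfect device reproduces the criterion exactly; the resulting
  # zero-residual fit is legitimate here, not a modelling mistake
  s <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble::tibble(
    slope = unname(s["criterion", "Estimate"]),
    intercept = unname(s["(Intercept)", "Estimate"]),
    r = stats::cor(device, criterion),
    p_value = unname(s["criterion", "Pr(>|t|)"]),
    stderr = unname(s["criterion", "Std. Error"]),
    n = n
  )
}

#' Qualitative band for a correlation coefficient
#'
#' Conventional interpretation bands on `|r|`: very high `[0.90, 1]`, high
#' `[0.70, 0.90)`, moderate `[0.50, 0.70)`, low `[0.30, 0.50)`, negligible
#' `[0, 0.30)`. Boundary values are assigned to the upper band.
#'
#' @param r Correlation coefficient(s).
#' @return Character vector of band labels.
#' @export
#' @examples
#' band_label(c(0.95, 0.90, 0.29))
band_label <- function(r) {
  a <- abs(r)
  dplyr::case_when(
    a >= 0.90 ~ "very high",
    a >= 0.70 ~ "high",
    a >= 0.50 ~ "moderate",
    a >= 0.30 ~ "low",
    TRUE ~ "negligible"
  )
}

#' Bland-Altman analysis of device-criterion differences
#'
#' Differences are device minus criterion. Bias is their mean; the limits of
#' agreement are `bias +/- 1.96 * SD` (sample SD, n-1 denominator), expected
#' to contain ~95\% of differences. The bias CI uses the t distribution
#' (`t_{n-1} * sd / sqrt(n)`); each LoA CI uses the standard large-sample
#' variance `3 * sd^2 / n` with a normal quantile.
#'
#' @param device,criterion Paired numeric vectors, n >= 2.
#' @param conf_level Confidence level for the intervals.
#' @return A one-row tibble: `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `ci_bias_low`, `ci_bias_high`, `ci_loa_low_low`, `ci_loa_low_high`,
#'   `ci_loa_high_low`, `ci_loa_high_high`, `n`.
#' @export
bland_altman <- function(device, criterion, conf_level = 0.95) {
  stopifnot(length(device) == length(criterion))
  n <- length(device)
  if (n < 2) stop("Bland-Altman requires at least 2 pairs", call. = FALSE)
  d <- device - criterion
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_d
  loa_high <- bias + 1.96 * sd_d
  t_half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * sd_d / sqrt(n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  loa_half <- z * sd_d * sqrt(3 / n)
  tibble::tibble(
    bias = bias, sd_diff = sd_d,
    loa_low = loa_low, loa_high = loa_high,
    ci_bias_low = bias - t_half, ci_bias_high = bias + t_half,
    ci_loa_low_low = loa_low - loa_half, ci_loa_low_high = loa_low + loa_half,
    ci_loa_high_low = loa_high - loa_half, ci_loa_high_high = loa_high + loa_half,
    n = n
  )
}

#' Natural-log transform for right-skewed HRV features
#'
#' RMSSD and HF power are log-transformed before regression and Bland-Altman
#' analysis to approximate normality (LnRMSSD, LnHF).
#'
#' @param values Positive numeric vector.
#' @param label Context used in the error message for nonpositive values.
#' @return `log(values)`.
#' @export
ln_transform <- function(values, label = "value") {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad) > 0) {
    stop("Cannot log-transform nonpositive ", label, " at position ", bad[1],
         call. = FALSE)
  }
  log(values)
}

#' Bonferroni adjustment for a family of tests
#'
#' `p_adj = min(1, p * m)` with family size m; by default m is the number of
#' device x condition cells tested per feature. Delegates to
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Family size (default: the number of p-values supplied).
#' @return Adjusted p-values.
#' @export
adjust_p <- function(p_values, m = length(p_values)) {
  stats::p.adjust(p_values, method = "bonferroni", n = max(m, length(p_values)))
}

#' Full agreement panel for paired feature observations
#'
#' Computes MAAPE (on the raw scale), OLS regression and Bland-Altman
#' statistics for each feature x device x condition cell of a paired feature
#' table, log-transforming RMSSD and HF for regression and Bland-Altman as is
#' conventional. Pairs are pairwise complete: rows where either value is
#' missing are dropped and the per-cell n reported.
#'
#' @param paired A tibble with columns `feature`, `device_id`, `condition`,
#'   `device_value`, `criterion_value` (one row per participant pair; see
#'   [pair_features()]).
#' @param log_features Features whose regression/Bland-Altman run on the log
#'   scale (MAAPE always uses the raw scale).
#' @param bonferroni_m Family size per feature for the Bonferroni adjustment;
#'   default is the number of device x condition cells present for that
#'   feature.
#' @return An object of class `hrv_agreement`: a tibble with one row per
#'   cell carrying all statistics, plus metadata attributes.
#' @export
agreement_stats <- function(paired,
                            log_features = c("rmssd_ms", "hf_ms2"),
                            bonferroni_m = NULL) {
  cells <- paired |>
    dplyr::filter(!is.na(.data$device_value), !is.na(.data$criterion_value)) |>
    dplyr::group_by(.data$feature, .data$device_id, .data$condition)

  res <- cells |>
    dplyr::group_modify(function(df, key) {
      use_log <- key$feature %in% log_features
      d_raw <- df$device_value
      c_raw <- df$criterion_value
      if (use_log) {
        keep <- d_raw > 0 & c_raw > 0
        d_t <- log(d_raw[keep])
        c_t <- log(c_raw[keep])
      } else {
        d_t <- d_raw
        c_t <- c_raw
      }
      n <- length(d_raw)
      ma <- if (n >= 1 && all(c_raw != 0)) maape(d_raw, c_raw) else
        tibble::tibble(maape = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, n = n)
      rg <- if (length(d_t) >= 3 && stats::var(c_t) > 0) {
        regress_pairs(d_t, c_t)
      } else {
        tibble::tibble(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                       p_value = NA_real_, stderr = NA_real_, n = length(d_t))
      }
      ba <- if (length(d_t) >= 2) bland_altman(d_t, c_t) else
        tibble::tibble(bias = NA_real_, sd_diff = NA_real_, loa_low = NA_real_,
                       loa_high = NA_real_, ci_bias_low = NA_real_,
                       ci_bias_high = NA_real_, ci_loa_low_low = NA_real_,
                       ci_loa_low_high = NA_real_, ci_loa_high_low = NA_real_,
                       ci_loa_high_high = NA_real_, n = length(d_t))
      tibble::tibble(
        n_pairs = n,
        maape = ma$maape, maape_ci_low = ma$ci_low, maape_ci_high = ma$ci_high,
        slope = rg$slope, intercept = rg$intercept, r = rg$r,
        r_band = band_label(rg$r), p_raw = rg$p_value, stderr = rg$stderr,
        n_regression = rg$n,
        bias = ba$bias, sd_diff = ba$sd_diff,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        ci_bias_low = ba$ci_bias_low, ci_bias_high = ba$ci_bias_high,
        ci_loa_low_low = ba$ci_loa_low_low,
        ci_loa_low_high = ba$ci_loa_low_high,
        ci_loa_high_low = ba$ci_loa_high_low,
        ci_loa_high_high = ba$ci_loa_high_high
      )
    }) |>
    dplyr::ungroup()

  res <- res |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(
      p_adjusted = adjust_p(.data$p_raw,
                            m = bonferroni_m %||% dplyr::n())
    ) |>
    dplyr::ungroup()

  structure(res,
            class = c("hrv_agreement", class(res)),
            log_features = log_features,
            maape_ci = "t-based on per-pair arctan errors")
}

#' @method tidy hrv_agreement
#' @export
tidy.hrv_agreement <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance hrv_agreement
#' @export
glance.hrv_agreement <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_features = length(unique(x$feature)),
    n_devices = length(unique(x$device_id)),
    n_conditions = length(unique(x$condition)),
    median_maape = stats::median(x$maape, na.rm = TRUE),
    median_r = stats::median(x$r, na.rm = TRUE)
  )
}

#' Build the paired feature table for agreement analysis
#'
#' Long feature rows (participant x device x condition x feature) are paired
#' with the matching criterion rows so that each row holds one device value
#' and the criterion value for the same participant, condition and feature.
#'
#' @param features A feature tibble as returned by [extract_features()] rows
#'   bound over participants and devices (columns `participant_id`,
#'   `device_id`, `condition`, `hr_bpm`, `rmssd_ms`, `hf_ms2`).
#' @param criterion_id Device id of the criterion recordings.
#' @return A tibble `feature, device_id, condition, participant_id,
#'   device_value, criterion_value`.
#' @export
pair_features <- function(features, criterion_id = "criterion") {
  long <- features |>
    tidyr::pivot_longer(cols = dplyr::any_of(c("hr_bpm", "rmssd_ms", "hf_ms2")),
                        names_to = "feature", values_to = "value")
  crit <- long |>
    dplyr::filter(.data$device_id == criterion_id) |>
    dplyr::select("participant_id", "condition", "feature",
                  criterion_value = "value")
  long |>
    dplyr::filter(.data$device_id != criterion_id) |>
    dplyr::select("participant_id", "device_id", "condition", "feature",
                  device_value = "value") |>
    dplyr::inner_join(crit, by = c("participant_id", "condition", "feature"))
}
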