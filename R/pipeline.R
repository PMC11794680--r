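#' Run the full device-validation pipeline
#'
#' Orchestrates, per participant: clock-lag estimation against the criterion
#' and realignment; segmentation into condition windows; per-participant
#' Karlsson threshold tuning on the criterion; artifact cleaning of every
#' segment; feature extraction (mean HR, RMSSD, HF); signal-quality
#' classification; and, over the cohort, the device-vs-criterion agreement
#' panel (MAAPE, regression, Bland-Altman). Per-participant failures are
#' logged and skipped, not fatal. The pipeline is deterministic given its
#' inputs.
#'
#' @param ibi_data An IBI series tibble holding all participants and devices
#'   (including the criterion rows).
#' @param conditions Condition-window tibble:
#'   `participant_id, condition, start_ms, end_ms`.
#' @param criterion_id Device id of the criterion recordings.
#' @param sync Logical: estimate and remove device clock lags (default TRUE).
#' @param max_lag_s,grid_hz Synchronization parameters, see [estimate_lag()].
#' @param lag_override Optional named numeric vector
#'   (`"participant.device" = ms`) of manually determined lags that replace
#'   the automatic estimate.
#' @param exclude_poor Drop poor-quality segments from the agreement
#'   statistics (default FALSE: they are kept, since in field use no
#'   criterion exists to identify them).
#' @param karlsson_start,karlsson_step,karlsson_cap Threshold-tuning grid,
#'   see [tune_threshold()].
#' @param range_low_ms,range_high_ms Plausibility bounds for the range filter.
#' @param hf_low_hz,hf_high_hz,resample_hz,welch_nperseg,welch_overlap
#'   Spectral parameters, see [hf_power()].
#' @param bonferroni_m Family size for the Bonferroni adjustment (default:
#'   cells present per feature).
#' @return An object of class `hrv_validation`: a list with tibbles
#'   `features`, `quality_labels`, `quality`, `agreement`, `sync`,
#'   `thresholds`, and the parameter list `params`.
#' @export
run_pipeline <- function(ibi_data, conditions, criterion_id = "criterion",
                         sync = TRUE, max_lag_s = 60, grid_hz = 4,
                         lag_override = NULL, exclude_poor = FALSE,
                         karlsson_start = 0.25, karlsson_step = 0.05,
                         karlsson_cap = 1.0,
                         range_low_ms = 300, range_high_ms = 2000,
                         hf_low_hz = 0.12, hf_high_hz = 0.40,
                         resample_hz = 4, welch_nperseg = 256,
                         welch_overlap = 0.5, bonferroni_m = NULL) {
  params <- list(
    criterion_id = criterion_id, sync = sync, max_lag_s = max_lag_s,
    grid_hz = grid_hz, exclude_poor = exclude_poor,
    karlsson_start = karlsson_start, karlsson_step = karlsson_step,
    karlsson_cap = karlsson_cap, range_low_ms = range_low_ms,
    range_high_ms = range_high_ms, hf_low_hz = hf_low_hz,
    hf_high_hz = hf_high_hz, resample_hz = resample_hz,
    welch_nperseg = welch_nperseg, welch_overlap = welch_overlap,
    bonferroni_m = bonferroni_m
  )
  pids <- unique(ibi_data$participant_id)
  device_ids <- setdiff(unique(ibi_data$device_id), criterion_id)
  cond_names <- unique(conditions$condition)

  features <- list()
  qlabels <- list()
  sync_log <- list()
  thresholds <- list()
  skipped <- character(0)

  for (pid in pids) {
    res <- tryCatch(
      run_participant(ibi_data, conditions, pid, device_ids, cond_names,
                      params, lag_override),
      error = function(e) {
        message("Skipping participant ", pid, ": ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(res)) {
      skipped <- c(skipped, pid)
      next
    }
    features[[pid]] <- res$features
    qlabels[[pid]] <- res$quality
    sync_log[[pid]] <- res$sync
    thresholds[[pid]] <- res$threshold
  }

  features <- dplyr::bind_rows(features)
  qlabels <- dplyr::bind_rows(qlabels)
  paired <- pair_features(features, criterion_id = criterion_id)
  if (exclude_poor && nrow(qlabels) > 0) {
    poor <- qlabels[qlabels$label != "acceptable",
                    c("participant_id", "device_id", "condition")]
    paired <- dplyr::anti_join(
      paired, poor, by = c("participant_id", "device_id", "condition"))
  }
  agreement <- if (nrow(paired) > 0) {
    agreement_stats(paired, bonferroni_m = bonferroni_m)
  } else {
    NULL
  }

  structure(
    list(
      features = features,
      quality_labels = qlabels,
      quality = if (nrow(qlabels) > 0) quality_table(qlabels) else NULL,
      agreement = agreement,
      sync = dplyr::bind_rows(sync_log),
      thresholds = dplyr::bind_rows(thresholds),
      skipped = skipped,
      params = params
    ),
    class = "hrv_validation"
  )
}

# one participant: sync, segment, tune, clean, features, quality
run_participant <- function(ibi_data, conditions, pid, device_ids,
                            cond_names, params, lag_override) {
  crit <- ibi_data[ibi_data$participant_id == pid &
                     ibi_data$device_id == params$criterion_id, ]
  if (nrow(crit) == 0) stop("no criterion data")
  wins <- conditions[conditions$participant_id == pid, ]
  if (nrow(wins) == 0) stop("no condition windows")

  crit_seg <- segment_ibis(crit, wins)
  threshold <- tune_threshold(
    crit_seg, start = params$karlsson_start, step = params$karlsson_step,
    cap = params$karlsson_cap, range_low_ms = params$range_low_ms,
    range_high_ms = params$range_high_ms
  )

  feat <- list()
  qual <- list()
  sync_rows <- list()

  clean_features <- function(seg_df, did) {
    by_cond <- purrr::map(cond_names, function(cn) {
      seg <- seg_df[!is.na(seg_df$condition) & seg_df$condition == cn, ]
      clean_segment(seg, threshold = threshold,
                    range_low_ms = params$range_low_ms,
                    range_high_ms = params$range_high_ms)
    })
    names(by_cond) <- cond_names
    f <- purrr::map_dfr(cond_names, function(cn) {
      s <- by_cond[[cn]]$series
      tibble::tibble(
        participant_id = pid, device_id = did, condition = cn,
        hr_bpm = mean_hr(s$ibi_ms),
        rmssd_ms = rmssd(s$ibi_ms),
        hf_ms2 = suppressMessages(hf_power(
          s, hf_low_hz = params$hf_low_hz, hf_high_hz = params$hf_high_hz,
          resample_hz = params$resample_hz, nperseg = params$welch_nperseg,
          overlap = params$welch_overlap)),
        n_ibis = nrow(s),
        n_artifacts = by_cond[[cn]]$n_artifacts
      )
    })
    f
  }

  crit_feat <- clean_features(crit_seg, params$criterion_id)
  feat[[params$criterion_id]] <- crit_feat

  for (did in device_ids) {
    dev <- ibi_data[ibi_data$participant_id == pid &
                      ibi_data$device_id == did, ]
    has_data <- nrow(dev) > 0
    lag_ms <- 0
    if (has_data && params$sync) {
      key <- paste(pid, did, sep = ".")
      if (!is.null(lag_override) && key %in% names(lag_override)) {
        lag_ms <- lag_override[[key]]
        sync_rows[[did]] <- tibble::tibble(
          participant_id = pid, device_id = did, lag_ms = lag_ms,
          correlation = NA_real_, low_correlation = FALSE,
          source = "override")
      } else {
        est <- tryCatch(
          suppressWarnings(estimate_lag(dev, crit,
                                        max_lag_s = params$max_lag_s,
                                        grid_hz = params$grid_hz)),
          error = function(e) NULL
        )
        if (!is.null(est)) {
          lag_ms <- est$lag_ms
          sync_rows[[did]] <- tibble::tibble(
            participant_id = pid, device_id = did, lag_ms = est$lag_ms,
            correlation = est$correlation,
            low_correlation = est$low_correlation, source = "estimated")
        } else {
          sync_rows[[did]] <- tibble::tibble(
            participant_id = pid, device_id = did, lag_ms = 0,
            correlation = NA_real_, low_correlation = TRUE,
            source = "failed")
        }
      }
    }
    dev_seg <- if (has_data) {
      segment_ibis(apply_lag(dev, lag_ms), wins)
    } else {
      dev
    }
    dev_feat <- if (has_data) clean_features(dev_seg, did) else
      tibble::tibble(
        participant_id = pid, device_id = did, condition = cond_names,
        hr_bpm = NA_real_, rmssd_ms = NA_real_, hf_ms2 = NA_real_,
        n_ibis = 0L, n_artifacts = 0L)
    feat[[did]] <- dev_feat

    qual[[did]] <- purrr::map_dfr(cond_names, function(cn) {
      nd <- dev_feat$n_ibis[dev_feat$condition == cn]
      nc <- crit_feat$n_ibis[crit_feat$condition == cn]
      na <- dev_feat$n_artifacts[dev_feat$condition == cn]
      q <- classify_quality(nd, nc, na, has_data = has_data)
      dplyr::bind_cols(
        tibble::tibble(participant_id = pid, device_id = did,
                       condition = cn, n_device = nd, n_criterion = nc,
                       n_artifacts = na),
        q
      )
    })
  }

  list(
    features = dplyr::bind_rows(feat),
    quality = dplyr::bind_rows(qual),
    sync = dplyr::bind_rows(sync_rows),
    threshold = tibble::tibble(participant_id = pid,
                               threshold_used = threshold)
  )
}

#' @export
print.hrv_validation <- function(x, ...) {
  cat("<hrv_validation>\n")
  cat("  participants: ",
      length(unique(x$features$participant_id)), sep = "")
  if (length(x$skipped) > 0) cat(" (", length(x$skipped), " skipped)", sep = "")
  cat("\n  devices: ",
      paste(setdiff(unique(x$features$device_id), x$params$criterion_id),
            collapse = ", "),
      "\n  conditions: ", length(unique(x$features$condition)),
      "\n  agreement cells: ",
      if (is.null(x$agreement)) 0 else nrow(x$agreement), "\n", sep = "")
  invisible(x)
}

#' @method tidy hrv_validation
#' @export
tidy.hrv_validation <- function(x, ...) {
  if (is.null(x$agreement)) return(tibble::tibble())
  tidy(x$agreement)
}

#' @method glance hrv_validation
#' @export
glance.hrv_validation <- function(x, ...) {
  tibble::tibble(
    n_participants = length(unique(x$features$participant_id)),
    n_skipped = length(x$skipped),
    n_devices = length(setdiff(unique(x$features$device_id),
                               x$params$criterion_id)),
    n_conditions = length(unique(x$features$condition)),
    n_agreement_cells = if (is.null(x$agreement)) 0L else nrow(x$agreement)
  )
}

#' Write the validation report bundle to a directory
#'
#' Emits CSV tables (features, quality, agreement, sync log, thresholds), a
#' Markdown quality table, and a machine-readable JSON bundle of every
#' statistic plus the parameters actually used. Tables are a pure rendering
#' of the JSON bundle; rerunning on the same inputs reproduces it
#' byte-identically.
#'
#' @param result An `hrv_validation` object from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$features, file.path(dir, "features.csv"))
  readr::write_csv(result$quality_labels, file.path(dir, "quality_labels.csv"))
  if (!is.null(result$quality)) {
    readr::write_csv(result$quality, file.path(dir, "quality_table.csv"))
    writeLines(md_table(result$quality), file.path(dir, "quality_table.md"))
  }
  if (!is.null(result$agreement)) {
    readr::write_csv(tidy(result$agreement), file.path(dir, "agreement.csv"))
  }
  if (nrow(result$sync) > 0) {
    readr::write_csv(result$sync, file.path(dir, "sync.csv"))
  }
  readr::write_csv(result$thresholds, file.path(dir, "thresholds.csv"))
  bundle <- list(
    params = result$params,
    thresholds = result$thresholds,
    sync = result$sync,
    quality = result$quality,
    agreement = if (!is.null(result$agreement)) tidy(result$agreement),
    features = result$features
  )
  jsonlite::write_json(bundle, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# minimal Markdown renderer for a tibble
md_table <- function(df) {
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 4, format = "g") else
      as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
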