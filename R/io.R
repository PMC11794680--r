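#' Read a timestamped IBI export
#'
#' Supported dialects:
#' \describe{
#'   \item{generic}{CSV with header `timestamp_ms,ibi_ms` (canonical
#'     interchange format, also what [write_ibi_csv()] emits).}
#'   \item{hrv_logger}{CSV exported by the HRV Logger phone app; its first
#'     two columns (UNIX-millisecond timestamp, IBI in ms) are mapped onto
#'     the canonical ones regardless of their native names.}
#'   \item{criterion_txt}{Whitespace/tab-separated `timestamp ibi` lines as
#'     exported from the criterion ECG scoring software; lines starting with
#'     `#` are skipped.}
#' }
#'
#' Rows are sorted by timestamp; duplicate timestamps keep the first
#' occurrence with a warning. An empty file yields an empty series, not an
#' error. A row whose IBI or timestamp does not parse as a number is an
#' ingestion error naming the offending line.
#'
#' @param path Path to the export file.
#' @param dialect One of `"generic"`, `"hrv_logger"`, `"criterion_txt"`.
#' @inheritParams ibi_series
#' @return An IBI series tibble (see [ibi_series()]).
#' @export
read_ibi_csv <- function(path, dialect = c("generic", "hrv_logger", "criterion_txt"),
                         participant_id = "p1", device_id = "device") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)

  if (dialect == "criterion_txt") {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    lines <- lines[keep]
    line_no <- which(keep)
    if (length(lines) == 0) {
      return(ibi_series(numeric(0), numeric(0), participant_id, device_id))
    }
    fields <- strsplit(trimws(lines), "\\s+")
    bad <- which(vapply(fields, length, integer(1)) < 2)
    if (length(bad) > 0) {
      stop("Cannot parse line ", line_no[bad[1]], " of ", path, call. = FALSE)
    }
    ts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1)))
    ibi <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    if (nrow(raw) == 0) {
      return(ibi_series(numeric(0), numeric(0), participant_id, device_id))
    }
    if (dialect == "generic") {
      if (!all(c("timestamp_ms", "ibi_ms") %in% names(raw))) {
        stop("Expected columns timestamp_ms, ibi_ms in ", path, call. = FALSE)
      }
      ts_chr <- raw$timestamp_ms
      ibi_chr <- raw$ibi_ms
    } else {
      # HRV Logger: first column timestamp, second IBI, whatever the header
      ts_chr <- raw[[1]]
      ibi_chr <- raw[[2]]
    }
    ts <- suppressWarnings(as.numeric(ts_chr))
    ibi <- suppressWarnings(as.numeric(ibi_chr))
    line_no <- seq_along(ts) + 1L  # header is line 1
  }

  bad <- which(is.na(ts) | is.na(ibi))
  if (length(bad) > 0) {
    stop("Cannot parse line ", line_no[bad[1]], " of ", path,
         ": non-numeric timestamp or IBI", call. = FALSE)
  }

  ord <- order(ts)
  ts <- ts[ord]
  ibi <- ibi[ord]
  dup <- duplicated(ts)
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) in ", path,
            "; keeping first occurrence", call. = FALSE)
    ts <- ts[!dup]
    ibi <- ibi[!dup]
  }
  ibi_series(ts, ibi, participant_id, device_id)
}

#' Write an IBI series in the canonical CSV dialect
#'
#' Emits `timestamp_ms,ibi_ms`; `read_ibi_csv(..., dialect = "generic")` is
#' its exact inverse on canonical series.
#'
#' @param series An IBI series tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ibi_csv <- function(series, path) {
  utils::write.csv(
    data.frame(timestamp_ms = series$onset_ms, ibi_ms = series$ibi_ms),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a systolic-peak timestamp file
#'
#' Canonical peaks interchange format: CSV with header `peak_time_ms`.
#'
#' @param path Path to the peaks CSV.
#' @return A tibble with a strictly increasing `peak_time_ms` column.
#' @export
read_peaks_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"peak_time_ms" %in% names(raw)) {
    stop("Expected column peak_time_ms in ", path, call. = FALSE)
  }
  t <- sort(as.numeric(raw$peak_time_ms))
  tibble::tibble(peak_time_ms = t[!duplicated(t)])
}

#' Read a condition-window table
#'
#' CSV with header `participant_id,condition,start_ms,end_ms`. Windows are
#' half-open `[start, end)` and must not overlap within a participant.
#'
#' @param path Path to the condition table.
#' @return A tibble with those four columns.
#' @export
read_conditions_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "condition", "start_ms", "end_ms")
  if (!all(needed %in% names(raw))) {
    stop("Expected columns ", paste(needed, collapse = ", "), " in ", path,
         call. = FALSE)
  }
  out <- tibble::as_tibble(raw[needed])
  out$start_ms <- as.numeric(out$start_ms)
  out$end_ms <- as.numeric(out$end_ms)
  if (any(out$start_ms >= out$end_ms)) {
    stop("Condition windows must satisfy start < end", call. = FALSE)
  }
  out
}

#' Read a raw tri-axial accelerometer export
#'
#' CSV with header `time_ms,x,y,z`, values in ADC counts. Calibration ranges
#' are supplied separately (they live in study configuration, not the file).
#'
#' @param path Path to the accelerometer CSV.
#' @param digital_range Full-scale span in ADC counts (> 0).
#' @param physical_range Full-scale span in g units (> 0).
#' @return A tibble `time_ms,x,y,z` with calibration attached as the columns
#'   `digital_range`, `physical_range`.
#' @export
read_accel_csv <- function(path, digital_range, physical_range) {
  if (missing(digital_range) || missing(physical_range) ||
      digital_range <= 0 || physical_range <= 0) {
    stop("Positive digital_range and physical_range calibration is required",
         call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_ms", "x", "y", "z")
  if (!all(needed %in% names(raw))) {
    stop("Expected columns ", paste(needed, collapse = ", "), " in ", path,
         call. = FALSE)
  }
  out <- tibble::as_tibble(raw[needed])
  out$digital_range <- digital_range
  out$physical_range <- physical_range
  out
}
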