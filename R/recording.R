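#' Multi-channel iEEG recording segment
#'
#' Container for one condition's signal block: a samples-by-channels numeric
#' matrix in microvolts, the sampling rate, and per-channel metadata. Signals
#' are assumed already referenced (typical intracranial montages use the
#' average of all intracranial signals as recording reference); see
#' [common_average_reference()] for an optional re-reference.
#'
#' @param signals Numeric matrix, one column per channel, in uV. Column names,
#'   if present, must match `channels$channel_id`.
#' @param fs Sampling rate in Hz. The analysis ceiling is 800 Hz, so
#'   `fs > 1600` is required.
#' @param channels Channel metadata as a data frame with columns
#'   `channel_id`, `subject_id`, `electrode_id`, `contact_index`,
#'   `hippocampus_id`, `label` (one of `"EH"`, `"NEH"`, `"unknown"`).
#' @param condition `"rest"` or `"task"`.
#' @param task_name Free-text task label or `NULL`.
#'
#' @return An object of class `recording_segment` with elements `signals`,
#'   `fs`, `channels`, `condition`, `task_name`, `duration_s`.
#' @examples
#' seg <- recording_segment(matrix(rnorm(4000), ncol = 2), fs = 2000,
#'                          channels = example_channel_metadata(2))
#' seg$duration_s
#' @export
recording_segment <- function(signals, fs, channels,
                              condition = c("rest", "task"),
                              task_name = NULL) {
  condition <- match.arg(condition)
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  channels <- validate_channel_metadata(channels)
  if (ncol(signals) == 0) abort("recording_segment: no channels")
  if (ncol(signals) != nrow(channels)) {
    abort(sprintf(
      "recording_segment: %d signal columns but %d metadata rows",
      ncol(signals), nrow(channels)
    ))
  }
  if (!is.null(colnames(signals)) &&
      !identical(colnames(signals), channels$channel_id)) {
    abort("recording_segment: signal column names disagree with channel_id")
  }
  colnames(signals) <- channels$channel_id
  if (!is.numeric(fs) || fs <= 2 * 800) {
    abort("recording_segment: fs must exceed 1600 Hz (2 x 800 Hz ceiling)")
  }
  structure(
    list(signals = signals, fs = fs, channels = channels,
         condition = condition, task_name = task_name,
         duration_s = nrow(signals) / fs),
    class = "recording_segment"
  )
}

#' @export
print.recording_segment <- function(x, ...) {
  cat(sprintf(
    "<recording_segment> %d channels x %.1f s @ %g Hz, condition=%s%s\n",
    ncol(x$signals), x$duration_s, x$fs, x$condition,
    if (is.null(x$task_name)) "" else paste0(" (", x$task_name, ")")
  ))
  print(x$channels, n = 6)
  invisible(x)
}

channel_metadata_cols <- c("channel_id", "subject_id", "electrode_id",
                           "contact_index", "hippocampus_id", "label")

validate_channel_metadata <- function(channels) {
  channels <- tibble::as_tibble(channels)
  missing <- setdiff(channel_metadata_cols, names(channels))
  if (length(missing) > 0) {
    abort(sprintf("channel metadata: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  channels <- channels[channel_metadata_cols]
  channels$channel_id <- as.character(channels$channel_id)
  channels$contact_index <- as.integer(channels$contact_index)
  if (anyDuplicated(channels$channel_id)) {
    abort("channel metadata: duplicate channel_id")
  }
  key <- paste(channels$subject_id, channels$electrode_id,
               channels$contact_index)
  if (anyDuplicated(key)) {
    abort("channel metadata: (electrode_id, contact_index) not unique within subject")
  }
  bad <- !channels$label %in% c("EH", "NEH", "unknown")
  if (any(bad)) {
    abort(sprintf("channel metadata: invalid label(s) %s",
                  paste(unique(channels$label[bad]), collapse = ", ")))
  }
  channels
}

#' Read channel metadata from a delimited table
#'
#' Expects a CSV with header
#' `channel_id,subject_id,electrode_id,contact_index,hippocampus_id,label`.
#' Labels must be `EH`, `NEH` or `unknown`; duplicate channel ids are an
#' error.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated channel metadata.
#' @export
read_channel_metadata <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_channel_metadata(tab)
}

#' @rdname read_channel_metadata
#' @param channels Validated channel metadata.
#' @export
write_channel_metadata <- function(channels, path) {
  readr::write_csv(validate_channel_metadata(channels), path, progress = FALSE)
  invisible(path)
}

#' Small example channel-metadata table
#'
#' One electrode with `n` hippocampal contacts, used in examples and tests.
#'
#' @param n Number of contacts.
#' @param label Hippocampus label for all contacts.
#' @return A channel metadata tibble.
#' @export
example_channel_metadata <- function(n = 2, label = "unknown") {
  tibble::tibble(
    channel_id = sprintf("A%02d", seq_len(n)),
    subject_id = "s01", electrode_id = "A",
    contact_index = seq_len(n), hippocampus_id = "s01-hA",
    label = label
  )
}

#' Write / read a recording segment in the package fixture format
#'
#' A segment is stored as two sidecar files sharing a stem: `<stem>.csv`
#' (samples by channels, one column per channel, header = channel ids) and
#' `<stem>.json` (sampling rate, condition, task name, channel metadata).
#' The format is plain text and round-trips to double precision via full
#' decimal serialization.
#'
#' @param segment A [recording_segment()].
#' @param stem Path stem (without extension).
#' @return `write_recording()` returns `stem` invisibly; `read_recording()`
#'   returns a `recording_segment`.
#' @export
write_recording <- function(segment, stem) {
  stopifnot(inherits(segment, "recording_segment"))
  df <- tibble::as_tibble(segment$signals)
  readr::write_csv(df, paste0(stem, ".csv"), progress = FALSE)
  meta <- list(
    fs = segment$fs, condition = segment$condition,
    task_name = segment$task_name, channels = segment$channels
  )
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}

#' Read a recording segment
#'
#' Reads either the package's CSV+JSON fixture format (pass the `.csv` path
#' or the bare stem) or a European Data Format file (`.edf`, read-only).
#' For EDF, channel metadata comes from a sidecar CSV given via
#' `metadata_path`; EDF channel labels must match its `channel_id` column.
#'
#' @param path Path to `<stem>.csv`, bare stem, or an `.edf` file.
#' @param format_hint `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param metadata_path Optional channel-metadata CSV (required for EDF).
#' @param condition,task_name Condition attached to an EDF segment (the
#'   fixture format stores these itself).
#' @return A [recording_segment()].
#' @export
read_recording <- function(path, format_hint = c("auto", "csv", "edf"),
                           metadata_path = NULL,
                           condition = "rest", task_name = NULL) {
  format_hint <- match.arg(format_hint)
  fmt <- if (format_hint != "auto") {
    format_hint
  } else if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (fmt == "edf") {
    edf <- read_edf(path)
    if (is.null(metadata_path)) {
      abort("read_recording: EDF input requires metadata_path")
    }
    channels <- read_channel_metadata(metadata_path)
    idx <- match(channels$channel_id, colnames(edf$signals))
    if (anyNA(idx)) {
      abort(sprintf("read_recording: metadata channels absent from EDF: %s",
                    paste(channels$channel_id[is.na(idx)], collapse = ", ")))
    }
    return(recording_segment(edf$signals[, idx, drop = FALSE], edf$fs,
                             channels, condition = condition,
                             task_name = task_name))
  }
  stem <- sub("\\.csv$", "", path)
  csv <- paste0(stem, ".csv"); json <- paste0(stem, ".json")
  if (!file.exists(csv) || !file.exists(json)) {
    abort(sprintf("read_recording: missing %s or %s", csv, json))
  }
  sig <- readr::read_csv(csv, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  recording_segment(
    as.matrix(sig), fs = meta$fs,
    channels = tibble::as_tibble(meta$channels),
    condition = meta$condition,
    task_name = if (is.null(meta$task_name)) NULL else meta$task_name
  )
}

#' Minimal European Data Format reader
#'
#' Parses the fixed-layout EDF header and signal records and converts digital
#' values to physical units. All signals must share one sampling rate (EDF
#' allows per-signal rates; mixed-rate files are rejected). Annotation
#' channels are not supported.
#'
#' @param path Path to an `.edf` file.
#' @return A list with `signals` (samples x channels matrix, physical units,
#'   columns named by EDF labels) and `fs` (Hz).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_char <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr_char(8)
  if (version != "0") abort("read_edf: not an EDF file (version field)")
  hdr_char(80); hdr_char(80); hdr_char(8); hdr_char(8)  # patient/rec/date/time
  n_header <- as.integer(hdr_char(8))
  hdr_char(44)  # reserved
  n_records <- as.integer(hdr_char(8))
  record_dur <- as.numeric(hdr_char(8))
  ns <- as.integer(hdr_char(4))
  if (is.na(ns) || ns < 1) abort("read_edf: file contains no signals")
  field <- function(w) vapply(seq_len(ns), function(i) hdr_char(w), "")
  labels <- field(16)
  field(80); field(8)  # transducer, physical dimension
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  field(80)  # prefiltering
  nsamp <- as.integer(field(8))
  field(32)  # reserved
  if (length(unique(nsamp)) != 1) {
    abort("read_edf: mixed per-signal sampling rates are not supported")
  }
  if (is.na(n_records) || n_records < 1) abort("read_edf: no data records")
  seek(con, n_header)
  per_rec <- nsamp[1]
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  out <- matrix(0, nrow = n_records * per_rec, ncol = ns)
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = per_rec * ns, size = 2,
                     signed = TRUE, endian = "little")
    if (length(block) < per_rec * ns) abort("read_edf: truncated data record")
    block <- matrix(block, nrow = per_rec, ncol = ns)
    rows <- ((r - 1) * per_rec + 1):(r * per_rec)
    out[rows, ] <- block
  }
  for (j in seq_len(ns)) {
    out[, j] <- phys_min[j] + (out[, j] - dig_min[j]) * gain[j]
  }
  colnames(out) <- labels
  list(signals = out, fs = per_rec / record_dur)
}

#' Common-average re-reference
#'
#' Subtracts the across-channel mean from every sample. Off by default in the
#' pipeline: inputs are assumed already referenced at acquisition.
#'
#' @param segment A [recording_segment()].
#' @return The re-referenced segment.
#' @export
common_average_reference <- function(segment) {
  stopifnot(inherits(segment, "recording_segment"))
  segment$signals <- segment$signals - rowMeans(segment$signals)
  segment
}
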