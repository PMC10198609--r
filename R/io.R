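# Readers/writers for the session file set. The acquisition system writes
# three CSVs per session: per-frame detections, frame timestamps, and the
# RFID read log. The dialect is pinned: comma-separated, header required,
# UTF-8, '.' decimal, NA written as an empty field.

read_csv_quiet <- function(path, col_types) {
  # readr warns when a declared column is absent; missing columns are
  # reported by our own schema checks instead
  suppressWarnings(
    readr::read_csv(path, col_types = col_types, na = c("", "NA"),
                    progress = FALSE)
  )
}

#' Read per-frame detections
#'
#' Expects columns `frame, x_min, y_min, x_max, y_max, confidence`. Rows
#' with missing values, invalid geometry (`x_min >= x_max`,
#' `y_min >= y_max`) or confidence outside `[0, 1]` are rejected with an
#' error naming the offending row numbers; rows are never silently dropped.
#'
#' @param path CSV file path.
#' @return Tibble of detections sorted by frame.
#' @export
read_detections <- function(path) {
  need <- c("frame", box_cols, "confidence")
  d <- read_csv_quiet(path, readr::cols(
    frame = readr::col_integer(),
    x_min = readr::col_double(), y_min = readr::col_double(),
    x_max = readr::col_double(), y_max = readr::col_double(),
    confidence = readr::col_double()
  ))
  if (!all(need %in% names(d))) {
    abort(sprintf("detections file %s is missing columns: %s", path,
                  paste(setdiff(need, names(d)), collapse = ", ")))
  }
  bad <- which(is.na(d$frame) | is.na(d$x_min) | is.na(d$y_min) |
                 is.na(d$x_max) | is.na(d$y_max) |
                 d$x_min >= d$x_max | d$y_min >= d$y_max |
                 is.na(d$confidence) | d$confidence < 0 | d$confidence > 1 |
                 d$frame < 0)
  if (length(bad)) {
    abort(sprintf("invalid detection row(s) in %s: %s", path,
                  paste(bad, collapse = ", ")))
  }
  arrange(d, .data$frame)
}

#' Read the frame-timestamp clock
#'
#' Expects columns `frame, time` (seconds). Frame indices must be strictly
#' increasing and timestamps non-decreasing.
#'
#' @param path CSV file path.
#' @return Tibble `frame`, `time`, sorted by frame.
#' @export
read_frame_clock <- function(path) {
  d <- read_csv_quiet(path, readr::cols(frame = readr::col_integer(),
                                        time = readr::col_double()))
  if (!all(c("frame", "time") %in% names(d))) {
    abort(sprintf("clock file %s needs columns frame, time", path))
  }
  d <- arrange(d, .data$frame)
  if (anyDuplicated(d$frame)) abort("duplicate frame indices in clock")
  if (is.unsorted(d$time)) abort("clock timestamps must be non-decreasing")
  d
}

#' Read the RFID read log
#'
#' Expects columns `timestamp, reader_id, tag`. Tags are kept as opaque
#' strings; output is sorted by timestamp. Reads referencing a reader absent
#' from `config$readers` are retained but flagged (`known_reader = FALSE`)
#' with a warning.
#'
#' @param path CSV file path.
#' @param config Optional `mt_config`; enables the known-reader check.
#' @return Tibble `time`, `reader_id`, `tag`, `known_reader`.
#' @export
read_rfid_log <- function(path, config = NULL) {
  d <- read_csv_quiet(path, readr::cols(timestamp = readr::col_double(),
                                        reader_id = readr::col_integer(),
                                        tag = readr::col_character()))
  if (!all(c("timestamp", "reader_id", "tag") %in% names(d))) {
    abort(sprintf("RFID log %s needs columns timestamp, reader_id, tag", path))
  }
  d <- tibble(time = d$timestamp, reader_id = d$reader_id, tag = d$tag)
  d$known_reader <- TRUE
  if (!is.null(config) && !is.null(config$readers)) {
    d$known_reader <- d$reader_id %in% config$readers$reader_id
    if (any(!d$known_reader)) {
      warn(sprintf("%d RFID read(s) reference reader ids absent from config: %s",
                   sum(!d$known_reader),
                   paste(unique(d$reader_id[!d$known_reader]), collapse = ", ")))
    }
  }
  arrange(d, .data$time)
}

#' Write / read tracked output
#'
#' The tracked table is the pipeline's central product: one row per
#' (frame, sort_id) with the box, centroid, RFID tag (empty when
#' unassigned) and the coasted flag marking Kalman-predicted boxes emitted
#' through detection failures. The pair round-trips exactly up to float
#' formatting.
#'
#' @param tracked Tracked tibble (see [track_sort()] / [match_rfid()]).
#' @param path CSV file path.
#' @return `write_tracked()` returns `path` invisibly; `read_tracked()` the
#'   tibble.
#' @export
write_tracked <- function(tracked, path) {
  need <- c("frame", "sort_id", box_cols, "coasted")
  if (!all(need %in% names(tracked))) {
    abort(sprintf("tracked table is missing columns: %s",
                  paste(setdiff(need, names(tracked)), collapse = ", ")))
  }
  if (anyDuplicated(tracked[, c("frame", "sort_id")])) {
    abort("duplicate (frame, sort_id) rows in tracked table")
  }
  out <- tracked
  if (!"tag" %in% names(out)) out$tag <- NA_character_
  if (!"cx" %in% names(out)) out$cx <- (out$x_min + out$x_max) / 2
  if (!"cy" %in% names(out)) out$cy <- (out$y_min + out$y_max) / 2
  if (!"time" %in% names(out)) out$time <- NA_real_
  out <- out[, c("frame", "time", "sort_id", "tag", box_cols, "cx", "cy", "coasted")]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_tracked
#' @export
read_tracked <- function(path) {
  d <- read_csv_quiet(path, readr::cols(
    frame = readr::col_integer(), time = readr::col_double(),
    sort_id = readr::col_integer(), tag = readr::col_character(),
    x_min = readr::col_double(), y_min = readr::col_double(),
    x_max = readr::col_double(), y_max = readr::col_double(),
    cx = readr::col_double(), cy = readr::col_double(),
    coasted = readr::col_logical()
  ))
  arrange(d, .data$frame, .data$sort_id)
}

#' Assemble a session bundle from files
#'
#' Reads the three session CSVs, attaches the configuration, and flags RFID
#' reads falling outside the recorded time span by more than one nominal
#' frame interval.
#'
#' @param detections_path,clock_path,rfid_path CSV file paths.
#' @param config An `mt_config` (or path to one).
#' @return A list of class `mt_session` with elements `detections`, `clock`,
#'   `reads`, `config`.
#' @export
read_session <- function(detections_path, clock_path, rfid_path, config) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  clock <- read_frame_clock(clock_path)
  detections <- read_detections(detections_path)
  if (!all(detections$frame %in% clock$frame)) {
    abort("detections reference frames absent from the clock")
  }
  reads <- read_rfid_log(rfid_path, config)
  dt <- 1 / config$fps
  out_of_span <- reads$time < (min(clock$time) - dt) |
    reads$time > (max(clock$time) + dt)
  if (any(out_of_span)) {
    warn(sprintf("%d RFID read(s) fall outside the recorded time span",
                 sum(out_of_span)))
  }
  reads$in_span <- !out_of_span
  structure(list(detections = detections, clock = clock, reads = reads,
                 config = config),
            class = "mt_session")
}
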