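# Orchestrators wiring the modules into the offline workflow. Each command
# is a plain function (composable in R) and is also exposed through the
# thin command-line wrapper in inst/cli/mousetrackr.R. Commands only write
# inside their output directory and log a run manifest (package version,
# config, input checksums) for provenance.

write_manifest <- function(out_dir, inputs, config) {
  manifest <- list(
    package = "mousetrackr",
    version = as.character(utils::packageVersion("mousetrackr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = lapply(inputs, function(pth) {
      list(path = pth, md5 = unname(tools::md5sum(pth)))
    }),
    config = unclass_config(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

unclass_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$readers)) out$readers <- as.data.frame(out$readers)
  out
}

#' Run tracking and RFID matching on a session's files
#'
#' Reads the session file set, runs [track_sort()] then [match_rfid()],
#' and writes the tagged tracked table, the audit log and a run manifest
#' into `out_dir`.
#'
#' @param detections_path,clock_path,rfid_path Session CSVs.
#' @param config An `mt_config` or path to a YAML/JSON config. The config
#'   must define reader zones.
#' @param out_dir Output directory (created if needed).
#' @return The `mt_match` result, invisibly.
#' @export
cmd_track <- function(detections_path, clock_path, rfid_path, config,
                      out_dir) {
  for (pth in c(detections_path, clock_path, rfid_path)) {
    if (!file.exists(pth)) abort(sprintf("missing input file: %s", pth))
  }
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("missing config file: %s", config))
    config <- read_config(config)
  }
  if (is.null(config$readers)) {
    abort("config defines no reader zones; add a `readers` table before tracking")
  }
  ses <- read_session(detections_path, clock_path, rfid_path, config)
  tracked <- track_sort(ses$detections, ses$clock, ses$config)
  res <- match_rfid(tracked, ses$reads, ses$clock, ses$config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tracked(res$tracked, file.path(out_dir, "tracked.csv"))
  readr::write_csv(res$audit, file.path(out_dir, "audit.csv"), na = "")
  write_manifest(out_dir, list(detections = detections_path,
                               clock = clock_path, rfid = rfid_path),
                 ses$config)
  invisible(res)
}

#' Compute behavior metrics from tracked output
#'
#' Writes the per-animal session metrics and the social-interaction
#' episode table; for two-animal trials additionally the segment
#' pair-score and trial-summary tables. With fewer than two identified
#' animals the social outputs are skipped with a notice.
#'
#' @param tracked_path Tracked-output CSV (from [cmd_track()]).
#' @param config An `mt_config` or config file path.
#' @param out_dir Output directory.
#' @return Named list of the computed tables, invisibly.
#' @export
cmd_analyze <- function(tracked_path, config, out_dir) {
  if (!file.exists(tracked_path)) {
    abort(sprintf("missing input file: %s", tracked_path))
  }
  if (is.character(config)) config <- read_config(config)
  tracked <- read_tracked(tracked_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(tracked) == 0) {
    warn("tracked file is empty; writing empty metrics")
  }
  metrics <- session_metrics(tracked, config)
  readr::write_csv(metrics, file.path(out_dir, "session_metrics.csv"), na = "")
  itc <- itc_episodes(tracked, config$analytics$itc_area_factor, config$fps)
  readr::write_csv(itc$episodes, file.path(out_dir, "itc_episodes.csv"),
                   na = "")
  out <- list(metrics = metrics, itc = itc)
  n_tags <- length(unique(stats::na.omit(tracked$tag)))
  if (n_tags == 2) {
    pairs <- score_segment_pairs(tracked, config)
    readr::write_csv(pairs, file.path(out_dir, "pair_scores.csv"), na = "")
    readr::write_csv(trial_summary(pairs),
                     file.path(out_dir, "trial_summary.csv"), na = "")
    out$pairs <- pairs
  } else {
    inform(sprintf(
      "social pair scoring skipped: needs exactly 2 identified animals, found %d",
      n_tags))
  }
  invisible(out)
}

#' Evaluate tracked output against a ground-truth table
#'
#' @param tracked_path Tracked-output CSV.
#' @param truth_path Ground-truth CSV (`frame, tag, x_min, y_min, x_max,
#'   y_max`), from the simulator or human annotation.
#' @param out_dir Output directory; receives the per-frame counts, episode
#'   list and a one-row summary.
#' @param clock_path Optional clock CSV for per-minute rates.
#' @return The `mt_eval`, invisibly.
#' @export
cmd_evaluate <- function(tracked_path, truth_path, out_dir,
                         clock_path = NULL) {
  for (pth in c(tracked_path, truth_path)) {
    if (!file.exists(pth)) abort(sprintf("missing input file: %s", pth))
  }
  tracked <- read_tracked(tracked_path)
  truth <- readr::read_csv(truth_path, show_col_types = FALSE, na = "")
  clock <- if (!is.null(clock_path)) read_frame_clock(clock_path) else NULL
  ev <- evaluate_tracking(tracked, truth, clock)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(ev), file.path(out_dir, "eval_counts.csv"), na = "")
  readr::write_csv(ev$episodes, file.path(out_dir, "identity_episodes.csv"),
                   na = "")
  readr::write_csv(glance(ev), file.path(out_dir, "eval_summary.csv"), na = "")
  invisible(ev)
}

#' Simulate a session and write its file set
#'
#' @param out_dir Output directory.
#' @param preset Preset name (see [sim_preset()]).
#' @param noise Noise level (see [sim_preset()]).
#' @param seed Integer seed.
#' @param ... Parameter overrides passed to [simulate_session()].
#' @return The `mt_sim`, invisibly.
#' @export
cmd_simulate <- function(out_dir, preset = "homecage", noise = "none",
                         seed = 1, ...) {
  sim <- simulate_session(sim_preset(preset, noise), seed = seed, ...)
  write_session(sim, out_dir)
  invisible(sim)
}
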