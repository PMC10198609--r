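# Run configuration: arena geometry, reader zones, tracker / matcher /
# analytics parameters. Stored as a plain nested list (class "mt_config")
# so it round-trips through YAML or JSON unchanged.

#' Default run configuration
#'
#' Builds the configuration consumed by [track_sort()], [match_rfid()] and
#' the analytics functions. All tracking and matching knobs are exposed
#' here; defaults follow common SORT practice (IOU match threshold 0.3,
#' coast up to one second of frames, re-association window of two seconds).
#'
#' @param fps Nominal frame rate (frames per second).
#' @param arena_w_px,arena_h_px Arena extent in pixels.
#' @param px_per_cm Calibration, pixels per centimetre.
#' @param readers Tibble of reader zones with columns `reader_id`, `x_min`,
#'   `y_min`, `x_max`, `y_max` and optionally `range_radius` (pixels). When
#'   the radius is absent it defaults to the zone half-diagonal plus half a
#'   typical mouse-box diagonal.
#' @param typical_box_px Typical mouse box size `c(width, height)` in pixels,
#'   used only to derive default proximity / range radii.
#' @param entrance_reader_id,entrance_stop_distance_px Home-cage mode: the
#'   reader under the housing-area entrance, and the distance to the
#'   entrance zone within which cage-reader matching is suppressed. Both
#'   `NULL` outside home-cage mode.
#' @return A list of class `mt_config`.
#' @export
default_config <- function(fps = 15,
                           arena_w_px = 512, arena_h_px = 400,
                           px_per_cm = 15,
                           readers = NULL,
                           typical_box_px = c(50, 30),
                           entrance_reader_id = NULL,
                           entrance_stop_distance_px = NULL) {
  stopifnot(fps > 0, px_per_cm > 0)
  mouse_diag <- sqrt(sum(typical_box_px^2))
  if (!is.null(readers)) {
    readers <- as_tibble(readers)
    req <- c("reader_id", box_cols)
    if (!all(req %in% names(readers))) {
      abort("`readers` needs columns reader_id, x_min, y_min, x_max, y_max")
    }
    if (!"range_radius" %in% names(readers)) {
      zd <- sqrt((readers$x_max - readers$x_min)^2 +
                 (readers$y_max - readers$y_min)^2) / 2
      readers$range_radius <- zd + mouse_diag / 2
    }
  }
  structure(list(
    fps = fps,
    arena = list(width_px = arena_w_px, height_px = arena_h_px,
                 px_per_cm = px_per_cm),
    readers = readers,
    entrance = list(reader_id = entrance_reader_id,
                    stop_distance_px = entrance_stop_distance_px),
    tracker = list(
      iou_match_threshold = 0.3,
      max_coast_frames = max(1L, round(fps)),       # one second of coasting
      reassoc_window_frames = max(1L, round(2 * fps)),
      reassoc_iou_threshold = 0.3,
      min_hits = 1L,
      # coasting bridges detector failures for established tracks; a track
      # with fewer hits than this dies immediately when unmatched instead
      # of emitting predictions (suppresses ghosts from spurious boxes)
      coast_min_hits = 3L
    ),
    matcher = list(
      proximity_iou = 0.3,          # reuse of the tracker's IOU threshold
      proximity_dist_px = mouse_diag
    ),
    analytics = list(
      rdp_epsilon = 10,
      sharp_turn_threshold_deg = 90,
      itc_area_factor = 1.25,
      segment_seconds = 5,
      displacement_min_cm = 1,
      length_ratio_max = 0.35,
      sp_split = 300
    ),
    motion = list(
      alpha = 0.05,
      diff_threshold = 25,
      min_contour_area = 50,
      kernel_size = 21,
      kernel_sigma = 3.5,
      warmup_s = 1
    )
  ), class = "mt_config")
}

#' Read / write a run configuration
#'
#' YAML is the native format; files ending in `.json` are read and written
#' as JSON. All defaults are materialised into the written file so a run's
#' full parameterisation is preserved for provenance.
#'
#' @param path File path (`.yaml`, `.yml` or `.json`).
#' @param config An `mt_config` list.
#' @return `read_config()` returns an `mt_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_config()
  cfg <- utils::modifyList(cfg, raw, keep.null = TRUE)
  if (!is.null(cfg$readers)) cfg$readers <- as_tibble(as.data.frame(cfg$readers))
  class(cfg) <- "mt_config"
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  if (!is.null(out$readers)) out$readers <- as.data.frame(out$readers)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

validate_config <- function(config) {
  if (!inherits(config, "mt_config")) abort("not an mt_config object")
  with(config, {
    stopifnot(fps > 0, arena$px_per_cm > 0,
              tracker$iou_match_threshold > 0, tracker$iou_match_threshold < 1,
              tracker$max_coast_frames >= 1, tracker$min_hits >= 1,
              analytics$rdp_epsilon >= 0, analytics$itc_area_factor > 0)
  })
  if (!is.null(config$readers)) {
    r <- config$readers
    bad <- r$x_min < 0 | r$y_min < 0 |
      r$x_max > config$arena$width_px | r$y_max > config$arena$height_px
    if (any(bad)) {
      abort(sprintf("reader zone(s) outside arena bounds: %s",
                    paste(r$reader_id[bad], collapse = ", ")))
    }
    stopifnot(all(r$range_radius > 0))
  }
  invisible(config)
}
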