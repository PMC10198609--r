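# Per-identity trajectory construction and the kinematic / turn-angle /
# occupancy / social-interaction measures computed from tracked output.
#
# Duration convention (used for active duration, centre occupancy and ITC
# episodes alike): frame i contributes the interval to the next frame,
# t[i+1] - t[i]; the last frame contributes the nominal frame interval.

frame_durations <- function(t, fps = NULL) {
  n <- length(t)
  if (n == 0) return(numeric(0))
  dt <- diff(t)
  last <- if (!is.null(fps)) 1 / fps else if (n > 1) median(dt) else 0
  c(dt, last)
}

#' Build per-tag trajectories from tracked output
#'
#' Keeps rows with an assigned RFID tag and returns the time-stamped
#' centroid sequence per tag, the input to all behavior metrics.
#'
#' @param tracked Tagged tracked tibble (from [match_rfid()]).
#' @return Tibble `tag, t, x, y, x_min, y_min, x_max, y_max`, ordered by
#'   tag then time.
#' @export
trajectories <- function(tracked) {
  tr <- filter(tracked, !is.na(.data$tag))
  tibble(tag = tr$tag, t = tr$time, x = tr$cx, y = tr$cy,
         x_min = tr$x_min, y_min = tr$y_min,
         x_max = tr$x_max, y_max = tr$y_max) %>%
    arrange(.data$tag, .data$t)
}

#' Ramer-Douglas-Peucker polyline simplification
#'
#' Recursively keeps the point farthest from the chord between the current
#' endpoints whenever its perpendicular distance exceeds `epsilon`, so
#' every removed point lies within `epsilon` of the simplified polyline.
#' Trajectories are simplified (default `epsilon` 10 px) before turn-angle
#' analysis, since raw centroid jitter manufactures spurious sharp turns.
#'
#' @param traj Data frame with columns `x`, `y` (rows in path order).
#' @param epsilon Tolerance in pixels (>= 0).
#' @return The simplified subsequence of rows.
#' @export
rdp_simplify <- function(traj, epsilon) {
  stopifnot(epsilon >= 0, all(c("x", "y") %in% names(traj)))
  n <- nrow(traj)
  if (n < 3) return(traj)
  x <- traj$x
  y <- traj$y
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  # iterative stack form of the recursion
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2L) next
    idx <- (i + 1L):(j - 1L)
    d <- point_segment_distance(x[idx], y[idx], x[i], y[i], x[j], y[j])
    kmax <- which.max(d)
    if (d[kmax] > epsilon) {
      k <- idx[kmax]
      keep[k] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  traj[keep, , drop = FALSE]
}

# perpendicular distance from points to the segment (x1,y1)-(x2,y2);
# degenerates to point distance when the endpoints coincide
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Trajectory kinematics
#'
#' Per-step speed and acceleration plus totals, in centimetres via the
#' calibration. Steps with zero time difference are dropped (logged).
#'
#' @param traj Data frame with `t`, `x`, `y` for one animal.
#' @param px_per_cm Calibration.
#' @return A list with `steps` (tibble `t, dist_cm, speed_cms, accel_cms2`)
#'   and `summary` (one-row tibble: `total_distance_cm, mean_speed_cms,
#'   mean_accel_cms2, duration_s`).
#' @export
kinematics <- function(traj, px_per_cm) {
  stopifnot(nrow(traj) >= 2)
  dtv <- diff(traj$t)
  ok <- dtv > 0
  if (any(!ok)) {
    inform(sprintf("%d zero-interval step(s) dropped from kinematics", sum(!ok)))
  }
  dist_px <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  dist_cm <- px_to_cm(dist_px[ok], px_per_cm)
  dtv <- dtv[ok]
  speed <- dist_cm / dtv
  accel <- if (length(speed) >= 2) diff(speed) / dtv[-1] else numeric(0)
  steps <- tibble(
    t = traj$t[-1][ok],
    dist_cm = dist_cm,
    speed_cms = speed,
    accel_cms2 = c(NA_real_, accel)
  )
  list(
    steps = steps,
    summary = tibble(
      total_distance_cm = sum(dist_cm),
      mean_speed_cms = if (length(speed)) mean(speed) else 0,
      mean_accel_cms2 = if (length(accel)) mean(accel) else NA_real_,
      duration_s = max(traj$t) - min(traj$t)
    )
  )
}

#' Turn angles along a trajectory
#'
#' At each interior vertex, the angle in degrees (0-180) between successive
#' displacement vectors: 0 for straight-ahead motion, 180 for a full
#' reversal. Turning events are classified sharp (angle below the
#' threshold) or wide (at or above it; an angle exactly at the threshold
#' counts as wide). Straight segments (angle ~ 0) are not turning events,
#' and zero-length steps are skipped.
#'
#' Apply [rdp_simplify()] first; typical thresholds are 90 degrees
#' (home-cage activity) or 45 degrees (fine motor assessment).
#'
#' @param traj Data frame with `x`, `y` (ideally simplified).
#' @param sharp_threshold_deg Sharp/wide partition angle, degrees.
#' @param straight_tol_deg Angles at or below this are straight, not turns.
#' @return List: `angles` (degrees, one per turning event), `n_sharp`,
#'   `n_wide`.
#' @export
turn_angles <- function(traj, sharp_threshold_deg = 90,
                        straight_tol_deg = 1e-6) {
  x <- traj$x
  y <- traj$y
  n <- length(x)
  if (n < 3) return(list(angles = numeric(0), n_sharp = 0L, n_wide = 0L))
  dx <- diff(x)
  dy <- diff(y)
  len <- sqrt(dx^2 + dy^2)
  a <- seq_len(n - 2L)
  b <- a + 1L
  ok <- len[a] > 0 & len[b] > 0
  dot <- dx[a] * dx[b] + dy[a] * dy[b]
  cosang <- pmin(1, pmax(-1, dot / (len[a] * len[b])))
  ang <- acos(cosang[ok]) * 180 / pi
  ang <- ang[ang > straight_tol_deg]
  list(
    angles = ang,
    n_sharp = sum(ang < sharp_threshold_deg),
    n_wide = sum(ang >= sharp_threshold_deg)
  )
}

#' Time spent in the arena centre
#'
#' The centre region is the axis-aligned rectangle of size 0.5 x width by
#' 0.5 x height centred in the arena; occupancy sums the per-sample
#' durations of samples whose centroid falls inside it.
#'
#' @param traj Data frame with `t`, `x`, `y`.
#' @param arena_w,arena_h Arena extent, pixels.
#' @param fps Nominal frame rate for the final sample's duration.
#' @return Seconds.
#' @export
time_in_center <- function(traj, arena_w, arena_h, fps = NULL) {
  if (nrow(traj) == 0) return(0)
  inside <- abs(traj$x - arena_w / 2) <= arena_w / 4 &
    abs(traj$y - arena_h / 2) <= arena_h / 4
  sum(frame_durations(traj$t, fps)[inside])
}

#' Social-interaction (ITC) episodes
#'
#' Two animals interact on a frame when their 25%-area-enlarged bounding
#' boxes overlap (IOU > 0). Maximal runs of interaction frames form
#' episodes; each frame contributes its inter-frame interval to the episode
#' duration.
#'
#' @param tracked Tagged tracked tibble (>= 2 tags).
#' @param area_factor Box area enlargement before the overlap test.
#' @param fps Nominal frame rate for trailing-frame durations.
#' @return List with `episodes` (tibble `tag_a, tag_b, onset, offset,
#'   duration, n_frames`), `pair_totals` and `animal_totals` summaries.
#' @export
itc_episodes <- function(tracked, area_factor = 1.25, fps = NULL) {
  tr <- filter(tracked, !is.na(.data$tag))
  tags <- sort(unique(tr$tag))
  episodes <- list()
  if (length(tags) >= 2) {
    k <- sqrt(area_factor)
    tr <- mutate(tr,
      hw = (.data$x_max - .data$x_min) / 2 * k,
      hh = (.data$y_max - .data$y_min) / 2 * k,
      ex_min = .data$cx - .data$hw, ex_max = .data$cx + .data$hw,
      ey_min = .data$cy - .data$hh, ey_max = .data$cy + .data$hh
    )
    for (i in seq_len(length(tags) - 1L)) {
      for (j in (i + 1L):length(tags)) {
        a <- filter(tr, .data$tag == tags[i])
        b <- filter(tr, .data$tag == tags[j])
        ab <- dplyr::inner_join(a, b, by = "frame", suffix = c(".a", ".b"))
        if (nrow(ab) == 0) next
        ab <- arrange(ab, .data$frame)
        ov <- pmin(ab$ex_max.a, ab$ex_max.b) > pmax(ab$ex_min.a, ab$ex_min.b) &
          pmin(ab$ey_max.a, ab$ey_max.b) > pmax(ab$ey_min.a, ab$ey_min.b)
        if (!any(ov)) next
        dur <- frame_durations(ab$time.a, fps)
        r <- rle(ov)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (q in which(r$values)) {
          s <- starts[q]; e <- ends[q]
          episodes[[length(episodes) + 1L]] <- tibble(
            tag_a = tags[i], tag_b = tags[j],
            onset = ab$time.a[s],
            duration = sum(dur[s:e]),
            n_frames = e - s + 1L
          )
        }
      }
    }
  }
  eps <- bind_rows(episodes)
  if (nrow(eps)) {
    eps$offset <- eps$onset + eps$duration
    eps <- eps[, c("tag_a", "tag_b", "onset", "offset", "duration", "n_frames")]
    pair_totals <- eps %>%
      group_by(.data$tag_a, .data$tag_b) %>%
      summarise(total_duration = sum(.data$duration),
                n_episodes = dplyr::n(),
                mean_duration = mean(.data$duration), .groups = "drop")
    animal_totals <- bind_rows(
      select(pair_totals, tag = "tag_a", "total_duration", "n_episodes"),
      select(pair_totals, tag = "tag_b", "total_duration", "n_episodes")
    ) %>%
      group_by(.data$tag) %>%
      summarise(total_duration = sum(.data$total_duration),
                n_episodes = sum(.data$n_episodes), .groups = "drop")
  } else {
    eps <- tibble(tag_a = character(0), tag_b = character(0),
                  onset = numeric(0), offset = numeric(0),
                  duration = numeric(0), n_frames = integer(0))
    pair_totals <- tibble(tag_a = character(0), tag_b = character(0),
                          total_duration = numeric(0), n_episodes = integer(0),
                          mean_duration = numeric(0))
    animal_totals <- tibble(tag = character(0), total_duration = numeric(0),
                            n_episodes = integer(0))
  }
  list(episodes = eps, pair_totals = pair_totals, animal_totals = animal_totals)
}

#' Per-animal session metrics
#'
#' One row per identified animal: total distance, mean speed and
#' acceleration, sharp and wide turn counts (on the RDP-simplified path),
#' centre-region occupancy and total social-interaction duration.
#'
#' @param tracked Tagged tracked tibble.
#' @param config An `mt_config` (calibration, arena extent, analytics
#'   thresholds).
#' @return Tibble, one row per tag.
#' @export
session_metrics <- function(tracked, config = default_config()) {
  validate_config(config)
  an <- config$analytics
  trj <- trajectories(tracked)
  tags <- unique(trj$tag)
  itc <- itc_episodes(tracked, an$itc_area_factor, config$fps)
  rows <- lapply(tags, function(tg) {
    tt <- filter(trj, .data$tag == tg)
    if (nrow(tt) < 2) {
      return(tibble(tag = tg, n_samples = nrow(tt),
                    total_distance_cm = 0, mean_speed_cms = 0,
                    mean_accel_cms2 = NA_real_, n_sharp_turns = 0L,
                    n_wide_turns = 0L, center_s = 0, itc_total_s = 0,
                    itc_episodes = 0L))
    }
    kin <- kinematics(tt, config$arena$px_per_cm)
    simp <- rdp_simplify(tt, an$rdp_epsilon)
    ta <- turn_angles(simp, an$sharp_turn_threshold_deg)
    ctr <- time_in_center(tt, config$arena$width_px, config$arena$height_px,
                          config$fps)
    at <- filter(itc$animal_totals, .data$tag == tg)
    tibble(
      tag = tg, n_samples = nrow(tt),
      total_distance_cm = kin$summary$total_distance_cm,
      mean_speed_cms = kin$summary$mean_speed_cms,
      mean_accel_cms2 = kin$summary$mean_accel_cms2,
      n_sharp_turns = ta$n_sharp, n_wide_turns = ta$n_wide,
      center_s = ctr,
      itc_total_s = if (nrow(at)) at$total_duration else 0,
      itc_episodes = if (nrow(at)) at$n_episodes else 0L
    )
  })
  bind_rows(rows)
}
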