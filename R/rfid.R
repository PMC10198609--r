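# RFID-to-track identity assignment. Every tag read triggers one of four
# scenarios: (1) the single in-range track is unassigned -> the tag is
# written to the track's whole history, past and future; (2) it already
# carries this tag -> no-op; (3) more than one track is in range -> the read
# is ambiguous, no-op; (4) it carries a different tag -> the assignment is
# corrected, backwards only up to the most recent frame where the track was
# in proximity with another track (where a swap could have occurred) and
# forwards up to the next such proximity event. Every decision is appended
# to an audit log from which the final table can be replayed.

#' Is a box within range of a reader zone?
#'
#' A detection counts as in range when its centroid lies within
#' `range_radius` of the zone centre OR its box overlaps the zone rectangle
#' (IOU > 0) — both criteria the matcher uses, combined as a disjunction.
#'
#' @param box Box `c(x_min, y_min, x_max, y_max)`.
#' @param zone One-row data frame / list with `x_min, y_min, x_max, y_max`
#'   and `range_radius` (pixels).
#' @return Logical.
#' @export
in_range <- function(box, zone) {
  zc <- c((zone$x_min + zone$x_max) / 2, (zone$y_min + zone$y_max) / 2)
  ctr <- bbox_centroid(box)
  if (sqrt(sum((ctr - zc)^2)) <= zone$range_radius) return(TRUE)
  bbox_iou(box, c(zone$x_min, zone$y_min, zone$x_max, zone$y_max)) > 0
}

# proximity frames per sort_id: frames on which the track's box had
# IOU > proximity_iou OR centroid distance < proximity_dist with any other
# track's box (coasted boxes included — they are first-class outputs)
proximity_frames <- function(tracked, proximity_iou, proximity_dist) {
  ids <- unique(tracked$sort_id)
  res <- setNames(vector("list", length(ids)), as.character(ids))
  for (i in seq_along(res)) res[[i]] <- integer(0)
  multi <- tracked %>%
    dplyr::add_count(.data$frame, name = "..k") %>%
    filter(.data$..k > 1)
  if (nrow(multi) == 0) return(res)
  a <- multi[, c("frame", "sort_id", box_cols, "cx", "cy")]
  pairs <- dplyr::inner_join(a, a, by = "frame", suffix = c(".a", ".b"),
                             relationship = "many-to-many")
  pairs <- filter(pairs, .data$sort_id.a < .data$sort_id.b)
  iw <- pmax(pmin(pairs$x_max.a, pairs$x_max.b) -
               pmax(pairs$x_min.a, pairs$x_min.b), 0)
  ih <- pmax(pmin(pairs$y_max.a, pairs$y_max.b) -
               pmax(pairs$y_min.a, pairs$y_min.b), 0)
  inter <- iw * ih
  areaA <- (pairs$x_max.a - pairs$x_min.a) * (pairs$y_max.a - pairs$y_min.a)
  areaB <- (pairs$x_max.b - pairs$x_min.b) * (pairs$y_max.b - pairs$y_min.b)
  iou <- inter / (areaA + areaB - inter)
  dist <- sqrt((pairs$cx.a - pairs$cx.b)^2 + (pairs$cy.a - pairs$cy.b)^2)
  hit <- iou > proximity_iou | dist < proximity_dist
  if (!any(hit)) return(res)
  ph <- pairs[hit, c("frame", "sort_id.a", "sort_id.b")]
  for (id in ids) {
    f <- ph$frame[ph$sort_id.a == id | ph$sort_id.b == id]
    res[[as.character(id)]] <- sort(unique(f))
  }
  res
}

#' Correction boundary for a retroactive identity fix
#'
#' The latest frame at or before `read_frame` on which the track was in
#' proximity with another track (IOU above `proximity_iou` or centroid
#' distance below `proximity_dist`) — the point past which an identity swap
#' could have occurred, so corrections do not reach beyond it. If the track
#' was never in proximity, its birth frame is returned.
#'
#' @param tracked Tracked tibble (all tracks).
#' @param sort_id Track whose boundary is sought.
#' @param read_frame Frame index of the triggering read.
#' @param proximity_iou,proximity_dist Proximity thresholds (see
#'   [default_config()]`$matcher`).
#' @return A frame index.
#' @export
find_correction_boundary <- function(tracked, sort_id, read_frame,
                                     proximity_iou = 0.3,
                                     proximity_dist = 60) {
  own <- filter(tracked, .data$sort_id == !!sort_id)
  if (nrow(own) == 0) abort(sprintf("no track with sort_id %s", sort_id))
  if (!read_frame %in% own$frame) {
    abort("read_frame is not within the track's history")
  }
  pf <- proximity_frames(tracked, proximity_iou, proximity_dist)[[as.character(sort_id)]]
  pf <- pf[pf <= read_frame]
  if (length(pf)) max(pf) else min(own$frame)
}

#' Match RFID reads to tracked identities
#'
#' Processes the read log chronologically through the four matching
#' scenarios (see module header), maintaining the per-frame
#' sort-id-to-tag table and an audit log of every event. In home-cage mode
#' (`config$entrance`), reads from cage readers are ignored while the
#' in-range track sits within `stop_distance_px` of the entrance zone, and
#' tracks ending inside the entrance zone are reported as closed (the
#' animal entered the housing area).
#'
#' Reads are mapped to frames by nearest clock timestamp; reads farther
#' than one nominal frame interval from any frame, or outside the session
#' span, are discarded with a warning.
#'
#' @param tracked Tracked tibble from [track_sort()].
#' @param reads RFID read tibble from [read_rfid_log()] (columns `time`,
#'   `reader_id`, `tag`).
#' @param clock Frame clock tibble.
#' @param config An `mt_config` with `readers` zones.
#' @return An object of class `mt_match`: list with `tracked` (the input
#'   plus a `tag` column), `audit` (one row per read event), and
#'   `closed_tracks`.
#' @export
match_rfid <- function(tracked, reads, clock, config) {
  validate_config(config)
  if (is.null(config$readers)) abort("config has no reader zones; cannot match")
  n <- nrow(tracked)
  tags <- rep(NA_character_, n)
  rows_by_frame <- split(seq_len(n), tracked$frame)
  rows_by_id <- split(seq_len(n), tracked$sort_id)
  frames_vec <- tracked$frame
  boxes <- boxes_from_df(tracked)
  ids <- tracked$sort_id

  pf <- proximity_frames(tracked, config$matcher$proximity_iou,
                         config$matcher$proximity_dist_px)

  nominal_dt <- if (nrow(clock) > 1) median(diff(clock$time)) else 1 / config$fps
  ent <- config$entrance
  ent_on <- !is.null(ent$reader_id) && !is.null(ent$stop_distance_px)
  if (ent_on) {
    ez <- config$readers[config$readers$reader_id == ent$reader_id, ]
    if (nrow(ez) != 1) abort("entrance reader_id not found among reader zones")
    ez_center <- c((ez$x_min + ez$x_max) / 2, (ez$y_min + ez$y_max) / 2)
  }

  audit <- vector("list", nrow(reads))
  log_event <- function(k, time, frame, reader_id, tag, scenario, sort_id = NA,
                        corrected_from = NA_character_,
                        boundary_past = NA, boundary_fwd = NA, n_changed = 0L) {
    audit[[k]] <<- tibble(
      time = time, frame = as.integer(frame), reader_id = reader_id,
      tag = tag, scenario = scenario, sort_id = as.integer(sort_id),
      corrected_from = corrected_from,
      boundary_past = as.double(boundary_past),
      boundary_fwd = as.double(boundary_fwd),
      n_changed = as.integer(n_changed)
    )
  }

  # assign `tag` to track `id` on its rows `rows_t`; clear any other track
  # holding the same tag on the affected frames (one tag labels at most one
  # sort_id per frame)
  assign_tag <- function(rows_t, id, tag) {
    af <- frames_vec[rows_t]
    conflict <- which(tags == tag & ids != id & frames_vec %in% af)
    if (length(conflict)) tags[conflict] <<- NA_character_
    tags[rows_t] <<- tag
    length(rows_t) + length(conflict)
  }

  reads <- arrange(reads, .data$time)
  n_discarded <- 0L
  n_s1_cross <- 0L
  for (k in seq_len(nrow(reads))) {
    rd <- reads[k, ]
    # nearest frame
    j <- which.min(abs(clock$time - rd$time))
    if (abs(clock$time[j] - rd$time) > nominal_dt) {
      n_discarded <- n_discarded + 1L
      log_event(k, rd$time, NA, rd$reader_id, rd$tag, "discarded")
      next
    }
    f <- clock$frame[j]
    zone <- config$readers[config$readers$reader_id == rd$reader_id, ]
    if (nrow(zone) != 1) {
      log_event(k, rd$time, f, rd$reader_id, rd$tag, "unknown_reader")
      next
    }
    rows_f <- rows_by_frame[[as.character(f)]]
    cand <- rows_f[vapply(rows_f, function(r) in_range(boxes[r, ], zone),
                          logical(1))]
    if (ent_on && rd$reader_id != ent$reader_id && length(cand)) {
      d_ent <- sqrt((tracked$cx[cand] - ez_center[1])^2 +
                      (tracked$cy[cand] - ez_center[2])^2)
      near <- d_ent <= ent$stop_distance_px
      if (any(near)) {
        log_event(k, rd$time, f, rd$reader_id, rd$tag, "suppressed_entrance")
        next
      }
    }
    if (length(cand) == 0) {
      log_event(k, rd$time, f, rd$reader_id, rd$tag, "no_track")
    } else if (length(cand) > 1) {
      # more than one animal in range: ambiguous, no matching (scenario 3)
      log_event(k, rd$time, f, rd$reader_id, rd$tag, "3")
    } else {
      r <- cand
      id <- ids[r]
      cur <- tags[r]
      rows_t <- rows_by_id[[as.character(id)]]
      if (is.na(cur) && all(is.na(tags[rows_t]))) {
        # scenario 1: the track has never been matched to any tag — tag
        # the full history, past and future
        nc <- assign_tag(rows_t, id, rd$tag)
        prox <- pf[[as.character(id)]]
        if (length(prox) && any(prox < f)) {
          # retroactive full-history tagging crossed an earlier proximity
          # event; tallied because a pre-read swap cannot be excluded
          n_s1_cross <- n_s1_cross + 1L
        }
        log_event(k, rd$time, f, rd$reader_id, rd$tag, "1", id,
                  n_changed = nc)
      } else if (is.na(cur)) {
        # the track carries tags elsewhere in its history but none on this
        # frame (an earlier bounded correction or a one-tag-per-frame
        # conflict cleared it): fill only the proximity-bounded
        # neighbourhood of the read, like a scenario-4 correction —
        # overwriting the whole history would discard assignments that
        # were confirmed by other reads
        prox <- pf[[as.character(id)]]
        past <- prox[prox <= f]
        b_past <- if (length(past)) max(past) else -Inf
        fwd <- prox[prox > f]
        b_fwd <- if (length(fwd)) min(fwd) else Inf
        tf <- frames_vec[rows_t]
        aff <- rows_t[tf > b_past & tf < b_fwd & is.na(tags[rows_t])]
        nc <- assign_tag(aff, id, rd$tag)
        log_event(k, rd$time, f, rd$reader_id, rd$tag, "1b", id,
                  boundary_past = b_past, boundary_fwd = b_fwd,
                  n_changed = nc)
      } else if (cur == rd$tag) {
        log_event(k, rd$time, f, rd$reader_id, rd$tag, "2", id)
      } else {
        # scenario 4: bounded retroactive + forward correction
        prox <- pf[[as.character(id)]]
        past <- prox[prox <= f]
        b_past <- if (length(past)) max(past) else -Inf
        fwd <- prox[prox > f]
        b_fwd <- if (length(fwd)) min(fwd) else Inf
        tf <- frames_vec[rows_t]
        aff <- rows_t[tf > b_past & tf < b_fwd]
        nc <- assign_tag(aff, id, rd$tag)
        log_event(k, rd$time, f, rd$reader_id, rd$tag, "4", id,
                  corrected_from = cur, boundary_past = b_past,
                  boundary_fwd = b_fwd, n_changed = nc)
      }
    }
  }
  if (n_discarded > 0) {
    warn(sprintf("%d RFID read(s) discarded: no frame within one nominal interval",
                 n_discarded))
  }
  if (n_s1_cross > 0) {
    inform(sprintf(
      "%d scenario-1 read(s) tagged a full track history across an earlier proximity event",
      n_s1_cross))
  }

  # bridging pass: inside one track, an unread stretch flanked by the SAME
  # confirmed tag on both sides inherits that tag (the identity cannot
  # have changed unless two swaps exactly cancelled); frames where another
  # track already holds the tag are left unassigned
  bridge_audit <- list()
  for (id_chr in names(rows_by_id)) {
    rows_t <- rows_by_id[[id_chr]]
    rows_t <- rows_t[order(frames_vec[rows_t])]
    tg <- tags[rows_t]
    if (!anyNA(tg) || all(is.na(tg))) next
    r <- rle(is.na(tg))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    fill <- function(fill_rows, tag_val) {
      ff <- frames_vec[fill_rows]
      taken <- tags == tag_val & ids != as.integer(id_chr) &
        frames_vec %in% ff
      ok <- !(ff %in% frames_vec[which(taken)])
      if (!any(ok)) return(invisible(NULL))
      tags[fill_rows[ok]] <<- tag_val
      bridge_audit[[length(bridge_audit) + 1L]] <<- tibble(
        time = NA_real_, frame = as.integer(min(ff)), reader_id = NA_integer_,
        tag = tag_val, scenario = "bridge", sort_id = as.integer(id_chr),
        corrected_from = NA_character_,
        boundary_past = min(ff) - 1, boundary_fwd = max(ff) + 1,
        n_changed = sum(ok)
      )
    }
    prox <- pf[[id_chr]]
    for (q in which(r$values)) {
      left <- if (starts[q] > 1L) tg[starts[q] - 1L] else NA_character_
      right <- if (ends[q] < length(tg)) tg[ends[q] + 1L] else NA_character_
      if (is.na(left) && is.na(right)) next
      fill_rows <- rows_t[starts[q]:ends[q]]
      ff <- frames_vec[fill_rows]
      if (is.na(left) || is.na(right) || left == right) {
        # edge run, or interior gap with agreeing flanks: the identity is
        # determined throughout ("all previous and future frames")
        fill(fill_rows, if (is.na(left)) right else left)
      } else {
        # flanks disagree: a swap occurred inside this run, and it can
        # only have happened at a proximity event — the left tag holds up
        # to the run's first proximity event, the right tag from its last
        # one onward; the stretch in between stays unassigned
        pin <- prox[prox >= min(ff) & prox <= max(ff)]
        if (!length(pin)) next
        lo <- fill_rows[ff < min(pin)]
        hi <- fill_rows[ff > max(pin)]
        if (length(lo)) fill(lo, left)
        if (length(hi)) fill(hi, right)
      }
    }
  }

  tracked$tag <- tags
  closed <- integer(0)
  if (ent_on) {
    last_rows <- tracked %>%
      group_by(.data$sort_id) %>%
      filter(.data$frame == max(.data$frame)) %>%
      ungroup()
    inside <- last_rows$cx >= ez$x_min & last_rows$cx <= ez$x_max &
      last_rows$cy >= ez$y_min & last_rows$cy <= ez$y_max
    closed <- last_rows$sort_id[inside]
  }
  structure(list(
    tracked = tracked,
    audit = bind_rows(c(audit, bridge_audit)),
    closed_tracks = closed
  ), class = "mt_match")
}

#' Replay an audit log against an untagged tracked table
#'
#' Re-applies every matching event recorded in an audit log, in order,
#' reproducing the final identity table exactly. The audit log is thus a
#' complete, replayable record of the matcher's decisions.
#'
#' @param tracked Tracked tibble without tags (or tags ignored).
#' @param audit Audit tibble from [match_rfid()].
#' @return The tracked tibble with the replayed `tag` column.
#' @export
replay_audit <- function(tracked, audit) {
  n <- nrow(tracked)
  tags <- rep(NA_character_, n)
  frames_vec <- tracked$frame
  ids <- tracked$sort_id
  rows_by_id <- split(seq_len(n), tracked$sort_id)
  for (k in seq_len(nrow(audit))) {
    ev <- audit[k, ]
    if (!ev$scenario %in% c("1", "1b", "4", "bridge")) next
    rows_t <- rows_by_id[[as.character(ev$sort_id)]]
    if (ev$scenario %in% c("1b", "4", "bridge")) {
      tf <- frames_vec[rows_t]
      rows_t <- rows_t[tf > ev$boundary_past & tf < ev$boundary_fwd]
      if (ev$scenario %in% c("1b", "bridge")) {
        rows_t <- rows_t[is.na(tags[rows_t])]
      }
    }
    af <- frames_vec[rows_t]
    conflict <- which(tags == ev$tag & ids != ev$sort_id & frames_vec %in% af)
    if (ev$scenario == "bridge") {
      # bridging never overrides another track's claim on the tag
      if (length(conflict)) {
        rows_t <- rows_t[!frames_vec[rows_t] %in% frames_vec[conflict]]
      }
      tags[rows_t] <- ev$tag
      next
    }
    if (length(conflict)) tags[conflict] <- NA_character_
    tags[rows_t] <- ev$tag
  }
  tracked$tag <- tags
  tracked
}

#' @export
print.mt_match <- function(x, ...) {
  tagged <- sum(!is.na(x$tracked$tag))
  cat(sprintf("<mt_match> %d tracked rows, %.1f%% tagged, %d audit events\n",
              nrow(x$tracked), 100 * tagged / max(1, nrow(x$tracked)),
              nrow(x$audit)))
  sc <- table(x$audit$scenario)
  cat("  events:", paste(sprintf("%s=%d", names(sc), sc), collapse = ", "), "\n")
  invisible(x)
}
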