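# Modified SORT tracker: Hungarian IOU association over Kalman-predicted
# boxes, plus the two behaviours that matter for rodent tracking —
# (1) coasting: a track that loses its detection keeps emitting the Kalman
#     prediction for up to max_coast_frames, so short detector failures
#     (occlusion, clustering) do not break the identity;
# (2) re-association: a freshly spawned track whose first box overlaps the
#     predicted box of a recently lost track adopts that track's id and
#     history, recovering identities discarded by sudden direction changes.
# Everything is deterministic: equal-cost assignment ties resolve to the
# lowest index and re-association ties to the most recently lost track.

#' Run the modified SORT tracker over a session's detections
#'
#' Processes frames in increasing order. On every frame each active track's
#' state is advanced one step by the constant-velocity Kalman model;
#' detections are assigned to predictions by maximising total IOU; matched
#' tracks are corrected with the observation, unmatched tracks coast
#' (emitting the predicted box, flagged `coasted`) for up to
#' `max_coast_frames`, then enter a lost pool where they remain eligible
#' for re-association for `reassoc_window_frames`.
#'
#' @param detections Tibble with columns `frame, x_min, y_min, x_max,
#'   y_max, confidence` (see [read_detections()]).
#' @param clock Tibble `frame`, `time` covering every session frame.
#' @param config An `mt_config`; the `tracker` element holds all knobs.
#' @return Tracked tibble: one row per emitted (frame, sort_id) with the
#'   box, centroid, timestamp and `coasted` flag.
#' @export
track_sort <- function(detections, clock, config = default_config()) {
  # re-association criterion: IOU at or above the threshold ranks highest
  # (scores in [1 + thr, 2]); failing that, a centroid distance within half
  # the mean box diagonal still counts (scores in (0, 1]) — a track that
  # re-emerges next to where it vanished is the same animal even when the
  # boxes no longer overlap. Score 0 means no continuation.
  reassoc_score <- function(box, cand_box, iou_thr) {
    v <- bbox_iou(box, cand_box)
    if (v >= iou_thr) return(1 + v)
    d <- sqrt(((box[1] + box[3]) - (cand_box[1] + cand_box[3]))^2 +
                ((box[2] + box[4]) - (cand_box[2] + cand_box[4]))^2) / 2
    diag2 <- (sqrt((box[3] - box[1])^2 + (box[4] - box[2])^2) +
                sqrt((cand_box[3] - cand_box[1])^2 +
                       (cand_box[4] - cand_box[2])^2)) / 2
    if (d <= diag2 / 2) return(1 - d / diag2)
    0
  }
  # is any other live track within one box diagonal of this box's centre?
  # (used to veto distance-only re-association in crowded scenes, where a
  # nearby track makes the continuation ambiguous)
  crowded <- function(tracks, box, exclude) {
    cx <- (box[1] + box[3]) / 2
    cy <- (box[2] + box[4]) / 2
    r <- sqrt((box[3] - box[1])^2 + (box[4] - box[2])^2)
    for (k in seq_along(tracks)) {
      if (k %in% exclude) next
      pb <- tracks[[k]]$pred
      if (sqrt(((pb[1] + pb[3]) / 2 - cx)^2 +
                 ((pb[2] + pb[4]) / 2 - cy)^2) <= r) {
        return(TRUE)
      }
    }
    FALSE
  }
  validate_config(config)
  p <- config$tracker
  frames <- sort(clock$frame)
  if (nrow(detections) > 0) {
    if (is.unsorted(detections$frame)) {
      abort("detections must be sorted by frame (frames processed in order)")
    }
    if (!all(detections$frame %in% frames)) {
      abort("detections reference frames absent from the clock")
    }
  }
  det_boxes_all <- boxes_from_df(detections)
  det_rows_by_frame <- split(seq_len(nrow(detections)), detections$frame)

  # emission buffer: frame, id, box(4), coasted
  cap <- nrow(detections) + length(frames) * 2L + 64L
  out <- matrix(NA_real_, cap, 7L)
  n_out <- 0L
  emit <- function(frame, id, box, coasted) {
    n_out <<- n_out + 1L
    if (n_out > nrow(out)) out <<- rbind(out, matrix(NA_real_, nrow(out), 7L))
    out[n_out, ] <<- c(frame, id, box, coasted)
  }

  tracks <- list()   # active (incl. coasting)
  lost <- list()     # lost, awaiting re-association
  next_id <- 1L

  for (f in frames) {
    # 1. advance every live filter one frame (lost tracks too, so their
    #    predicted boxes stay current for the re-association test)
    for (i in seq_along(tracks)) {
      tracks[[i]]$kf <- kf_predict(tracks[[i]]$kf)
      tracks[[i]]$pred <- kf_box(tracks[[i]]$kf)
    }
    # lost tracks keep the box last predicted for them (at loss time);
    # extrapolating a stale velocity for seconds only drifts away from
    # wherever the animal actually re-emerges

    rows <- det_rows_by_frame[[as.character(f)]]
    D <- det_boxes_all[rows, , drop = FALSE]

    preds <- if (length(tracks)) {
      do.call(rbind, lapply(tracks, `[[`, "pred"))
    } else matrix(numeric(0), 0, 4)
    asc <- associate_detections(D, preds, p$iou_match_threshold)

    matched_track <- rep(FALSE, length(tracks))
    apply_match <- function(di, ti) {
      tr <- tracks[[ti]]
      tr$kf <- kf_update(tr$kf, D[di, ])
      tr$fsu <- 0L
      tr$hits <- tr$hits + 1L
      tr$last_obs <- D[di, ]
      tracks[[ti]] <<- tr
      matched_track[ti] <<- TRUE
      if (tr$hits >= p$min_hits) emit(f, tr$id, D[di, ], 0)
    }
    if (nrow(asc$matches)) {
      for (k in seq_len(nrow(asc$matches))) {
        apply_match(asc$matches[k, "det"], asc$matches[k, "track"])
      }
    }
    unmatched_dets <- asc$unmatched_dets

    # 1b. second-chance association: a coasting track's Kalman prediction
    # drifts during occlusion, so when the animal re-emerges its detection
    # can miss the IOU gate against the prediction while still overlapping
    # the track's last *observed* box. Re-run the assignment for leftover
    # detections against leftover tracks anchored on last observations.
    if (length(unmatched_dets) && any(!matched_track)) {
      ut <- which(!matched_track &
                    vapply(tracks, function(tr) tr$fsu >= 1L &&
                             !is.null(tr$last_obs), logical(1)))
      if (length(ut)) {
        OB <- do.call(rbind, lapply(tracks[ut], `[[`, "last_obs"))
        asc2 <- associate_detections(
          D[unmatched_dets, , drop = FALSE], OB, p$reassoc_iou_threshold)
        if (nrow(asc2$matches)) {
          for (k in seq_len(nrow(asc2$matches))) {
            apply_match(unmatched_dets[asc2$matches[k, "det"]],
                        ut[asc2$matches[k, "track"]])
          }
          unmatched_dets <- unmatched_dets[asc2$unmatched_dets]
        }
      }
    }

    # 2. unmatched detections: re-associate against the lost pool, else spawn
    if (length(unmatched_dets)) {
      for (di in unmatched_dets) {
        box <- D[di, ]
        adopted <- 0L
        if (length(lost)) {
          scores <- vapply(lost, function(l) {
            reassoc_score(box, l$pred, p$reassoc_iou_threshold)
          }, numeric(1))
          best_score <- 0
          best_j <- 0L
          for (j in seq_along(lost)) {
            v <- scores[j]
            if (v > 0 &&
                (v > best_score ||
                 (v == best_score && lost[[j]]$lost_frame >
                    lost[[best_j]]$lost_frame))) {
              best_score <- v
              best_j <- j
            }
          }
          # the distance-only branch (score <= 1) is taken only when the
          # continuation is unambiguous: one candidate, no crowd around
          if (best_j > 0L && best_score <= 1 &&
              (sum(scores > 0) > 1L ||
                 crowded(tracks, box, exclude = integer(0)))) {
            best_j <- 0L
          }
          if (best_j > 0L) {
            tr <- lost[[best_j]]
            lost[[best_j]] <- NULL
            tr$kf <- kf_update(tr$kf, box)
            tr$fsu <- 0L
            tr$hits <- tr$hits + 1L
            tr$last_obs <- box
            tr$lost_frame <- NA_integer_
            tracks[[length(tracks) + 1L]] <- tr
            matched_track <- c(matched_track, TRUE)
            emit(f, tr$id, box, 0)
            adopted <- tr$id
          }
        }
        if (adopted == 0L) {
          tr <- list(id = next_id, kf = kf_new(box), fsu = 0L, hits = 1L,
                     lost_frame = NA_integer_, pred = box,
                     birth = f, first_box = box, last_obs = box)
          next_id <- next_id + 1L
          tracks[[length(tracks) + 1L]] <- tr
          matched_track <- c(matched_track, TRUE)
          if (tr$hits >= p$min_hits) emit(f, tr$id, box, 0)
        }
      }
    }

    # 3. unmatched tracks: coast, then fall into the lost pool
    drop_idx <- integer(0)
    for (ti in which(!matched_track)) {
      tr <- tracks[[ti]]
      tr$fsu <- tr$fsu + 1L
      if (tr$hits < p$min_hits) {
        # tentative track missed before confirmation: discard
        drop_idx <- c(drop_idx, ti)
        next
      }
      coast_ok <- tr$hits >= (p$coast_min_hits %||% 1L)
      if (coast_ok && tr$fsu <= p$max_coast_frames) {
        emit(f, tr$id, tr$pred, 1)
        tracks[[ti]] <- tr
      } else {
        # before parking the track in the lost pool, check whether a
        # younger track spatially continues it: a detection that slipped
        # below the association gate (sudden turn) spawns a new id while
        # the old track coasts on as a ghost. If the young track's first
        # box overlaps the old track's coasted box at the spawn frame, the
        # young track adopts the old id and the ghost boxes are removed.
        last_det_frame <- f - tr$fsu
        old_row <- which(out[seq_len(n_out), 2] == tr$id &
                           out[seq_len(n_out), 1] == last_det_frame &
                           out[seq_len(n_out), 7] == 0)
        old_box <- if (length(old_row)) out[old_row[1], 3:6] else tr$pred
        scores <- numeric(length(tracks))
        for (yi in seq_along(tracks)) {
          if (yi == ti) next
          y <- tracks[[yi]]
          if (is.null(y$birth) || y$birth <= last_det_frame) next
          if (f - y$birth > p$reassoc_window_frames) next
          scores[yi] <- reassoc_score(y$first_box, old_box,
                                      p$reassoc_iou_threshold)
        }
        best_score <- 0
        best_yi <- 0L
        for (yi in seq_along(tracks)) {
          v <- scores[yi]
          if (v > 0 &&
              (v > best_score ||
               (v == best_score && best_yi > 0L &&
                  tracks[[yi]]$birth > tracks[[best_yi]]$birth))) {
            best_score <- v
            best_yi <- yi
          }
        }
        if (best_yi > 0L && best_score <= 1 &&
            (sum(scores > 0) > 1L ||
               crowded(tracks, old_box, exclude = c(ti, best_yi)))) {
          best_yi <- 0L
        }
        if (best_yi > 0L) {
          y <- tracks[[best_yi]]
          live <- seq_len(n_out)
          ghost <- live[out[live, 2] == tr$id & out[live, 1] >= y$birth]
          if (length(ghost)) out[ghost, 1] <- NA   # drop ghost coasted boxes
          relab <- live[out[live, 2] == y$id]
          out[relab, 2] <- tr$id
          tracks[[best_yi]]$id <- tr$id
          tracks[[best_yi]]$birth <- tr$birth
          drop_idx <- c(drop_idx, ti)
        } else {
          tr$lost_frame <- f
          lost[[length(lost) + 1L]] <- tr
          drop_idx <- c(drop_idx, ti)
        }
      }
    }
    if (length(drop_idx)) tracks[drop_idx] <- NULL

    # 4. expire lost tracks beyond the re-association window
    if (length(lost)) {
      expired <- vapply(lost, function(tr) f - tr$lost_frame >=
                          p$reassoc_window_frames, logical(1))
      if (any(expired)) lost[which(expired)] <- NULL
    }
  }

  out <- out[seq_len(n_out), , drop = FALSE]
  out <- out[!is.na(out[, 1]), , drop = FALSE]
  res <- tibble(
    frame = as.integer(out[, 1]),
    sort_id = as.integer(out[, 2]),
    x_min = out[, 3], y_min = out[, 4], x_max = out[, 5], y_max = out[, 6],
    coasted = out[, 7] > 0
  )
  res$cx <- (res$x_min + res$x_max) / 2
  res$cy <- (res$y_min + res$y_max) / 2
  res <- left_join(res, clock, by = "frame")
  res <- arrange(res, .data$frame, .data$sort_id)
  res[, c("frame", "time", "sort_id", box_cols, "cx", "cy", "coasted")]
}
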