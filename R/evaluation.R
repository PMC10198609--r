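# Tracking-quality metrics against ground truth. Hypothesis boxes (tracker
# output, coasted boxes included) are paired with ground-truth boxes frame
# by frame with best-IOU one-to-one matching (IOU >= 0.5 counts as the
# same animal). From the pairing: FN (ground-truth animals missed), FP
# (hypothesis boxes with no animal), identity errors (paired boxes whose
# RFID tag disagrees with truth), coverage and the MOTA summary.

#' Multiple Object Tracking Accuracy
#'
#' `MOTA = 1 - (sum FN + sum FP + sum identity errors) / (sum ground-truth
#' animals)`, summed over frames. 1 only when all three error counts are
#' zero; not floored, so error totals exceeding the ground-truth count give
#' a negative value.
#'
#' @param counts Data frame with per-frame columns `fn`, `fp`, `id_error`,
#'   `gt`.
#' @return A number `<= 1`.
#' @export
mota <- function(counts) {
  need <- c("fn", "fp", "id_error", "gt")
  stopifnot(all(need %in% names(counts)))
  gt <- sum(counts$gt)
  if (gt <= 0) abort("MOTA undefined: zero ground-truth animals")
  1 - (sum(counts$fn) + sum(counts$fp) + sum(counts$id_error)) / gt
}

#' False positive / negative rates
#'
#' Error totals as a percentage of ground-truth animals and per minute of
#' video.
#'
#' @param counts Per-frame counts as for [mota()].
#' @param duration_min Video duration in minutes (> 0).
#' @return One-row tibble: `fp_pct, fn_pct, fp_per_min, fn_per_min`.
#' @export
detection_rates <- function(counts, duration_min) {
  stopifnot(duration_min > 0)
  gt <- sum(counts$gt)
  tibble(
    fp_pct = 100 * sum(counts$fp) / gt,
    fn_pct = 100 * sum(counts$fn) / gt,
    fp_per_min = sum(counts$fp) / duration_min,
    fn_per_min = sum(counts$fn) / duration_min
  )
}

# pair hypothesis rows with ground-truth rows on one frame: best-IOU
# one-to-one matching, a pair counts when IOU >= iou_match
match_frame <- function(hyp_boxes, gt_boxes, iou_match) {
  n <- nrow(hyp_boxes)
  m <- nrow(gt_boxes)
  if (n == 0L || m == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("hyp", "gt"))))
  }
  asc <- associate_detections(hyp_boxes, gt_boxes, iou_match)
  colnames(asc$matches) <- c("hyp", "gt")
  asc$matches
}

#' Evaluate tracked output against ground truth
#'
#' @param tracked Tagged tracked tibble (hypotheses; coasted rows count
#'   like observed ones).
#' @param truth Ground-truth tibble with columns `frame, tag, x_min, y_min,
#'   x_max, y_max` (one row per animal per frame), e.g. from
#'   [simulate_session()] or a human-annotation CSV in the same schema.
#' @param clock Frame clock (for per-minute rates); optional.
#' @param iou_match Minimum IOU for a hypothesis box and a ground-truth box
#'   to denote the same animal.
#' @return An object of class `mt_eval`: per-frame counts, totals, MOTA,
#'   coverage, identity-error rate and wrong-tag episodes. Use [tidy()] for
#'   the per-frame table and [glance()] for the one-row summary.
#' @export
evaluate_tracking <- function(tracked, truth, clock = NULL, iou_match = 0.5) {
  need <- c("frame", "tag", box_cols)
  stopifnot(all(need %in% names(truth)))
  if (nrow(truth) == 0) abort("ground truth is empty")
  if (!"tag" %in% names(tracked)) tracked$tag <- NA_character_

  frames <- sort(union(unique(tracked$frame), unique(truth$frame)))
  hyp_by_frame <- split(seq_len(nrow(tracked)), tracked$frame)
  gt_by_frame <- split(seq_len(nrow(truth)), truth$frame)
  hyp_boxes <- boxes_from_df(tracked)
  gt_boxes <- boxes_from_df(truth)

  nf <- length(frames)
  fn <- fp <- id_err <- gt_n <- det_n <- integer(nf)
  n_tagged <- n_tagged_paired <- n_wrong <- 0L
  # per-row truth tag for episode extraction
  row_gt_tag <- rep(NA_character_, nrow(tracked))

  for (i in seq_len(nf)) {
    f <- frames[i]
    hr <- hyp_by_frame[[as.character(f)]]
    gr <- gt_by_frame[[as.character(f)]]
    nh <- length(hr)
    ng <- length(gr)
    det_n[i] <- nh
    gt_n[i] <- ng
    mm <- match_frame(hyp_boxes[hr, , drop = FALSE],
                      gt_boxes[gr, , drop = FALSE], iou_match)
    fn[i] <- ng - nrow(mm)
    fp[i] <- nh - nrow(mm)
    if (nrow(mm)) {
      ht <- tracked$tag[hr[mm[, "hyp"]]]
      gt_t <- truth$tag[gr[mm[, "gt"]]]
      row_gt_tag[hr[mm[, "hyp"]]] <- gt_t
      wrong <- !is.na(ht) & ht != gt_t
      id_err[i] <- sum(wrong)
      n_tagged_paired <- n_tagged_paired + sum(!is.na(ht))
      n_wrong <- n_wrong + sum(wrong)
    }
    n_tagged <- n_tagged + sum(!is.na(tracked$tag[hr]))
  }

  counts <- tibble(frame = frames, fn = fn, fp = fp, id_error = id_err,
                   gt = gt_n, detections = det_n)
  total_det <- nrow(tracked)
  coverage <- if (total_det > 0) 100 * n_tagged / total_det else NA_real_
  id_rate <- if (n_tagged > 0) 100 * n_wrong / n_tagged else
    if (total_det > 0) 0 else NA_real_

  duration_min <- if (!is.null(clock) && nrow(clock) > 1) {
    (max(clock$time) - min(clock$time)) / 60
  } else NA_real_
  rates <- if (!is.na(duration_min) && duration_min > 0) {
    detection_rates(counts, duration_min)
  } else {
    tibble(fp_pct = 100 * sum(fp) / sum(gt_n),
           fn_pct = 100 * sum(fn) / sum(gt_n),
           fp_per_min = NA_real_, fn_per_min = NA_real_)
  }

  eps <- wrong_tag_episodes(tracked, row_gt_tag)

  structure(list(
    counts = counts,
    mota = mota(counts),
    coverage = coverage,
    identity_error_rate = id_rate,
    rates = rates,
    episodes = eps,
    duration_min = duration_min,
    n_tagged = n_tagged,
    n_wrong = n_wrong
  ), class = "mt_eval")
}

# maximal consecutive runs of wrong assignment per sort_id
wrong_tag_episodes <- function(tracked, row_gt_tag) {
  wrong <- !is.na(tracked$tag) & !is.na(row_gt_tag) &
    tracked$tag != row_gt_tag
  df <- tibble(sort_id = tracked$sort_id, frame = tracked$frame,
               wrong = wrong) %>%
    arrange(.data$sort_id, .data$frame)
  out <- list()
  for (id in unique(df$sort_id)) {
    d <- df[df$sort_id == id, ]
    r <- rle(d$wrong)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      out[[length(out) + 1L]] <- tibble(
        sort_id = id,
        start_frame = d$frame[starts[q]],
        length = r$lengths[q]
      )
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(sort_id = integer(0), start_frame = integer(0), length = integer(0))
}

#' Coverage and identity-error rate of a tagged tracked table
#'
#' Coverage is the percentage of detections (tracked rows, coasted
#' included) carrying an RFID tag. With ground truth, the identity-error
#' rate is the percentage of tagged detections whose tag disagrees with
#' the ground-truth animal they overlap (best-IOU pairing); without ground
#' truth only coverage is reported.
#'
#' @inheritParams evaluate_tracking
#' @return One-row tibble `coverage`, `identity_error_rate`.
#' @export
coverage_identity <- function(tracked, truth = NULL, iou_match = 0.5) {
  total <- nrow(tracked)
  has_tag <- "tag" %in% names(tracked)
  n_tagged <- if (has_tag) sum(!is.na(tracked$tag)) else 0L
  coverage <- if (total > 0) 100 * n_tagged / total else NA_real_
  if (is.null(truth)) {
    return(tibble(coverage = coverage, identity_error_rate = NA_real_))
  }
  ev <- evaluate_tracking(tracked, truth, iou_match = iou_match)
  tibble(coverage = ev$coverage, identity_error_rate = ev$identity_error_rate)
}

#' Wrong-tag episodes
#'
#' Maximal consecutive runs of frames on which a track carried a tag
#' disagreeing with ground truth.
#'
#' @inheritParams evaluate_tracking
#' @return Tibble `sort_id, start_frame, length`.
#' @export
identity_episodes <- function(tracked, truth, iou_match = 0.5) {
  evaluate_tracking(tracked, truth, iou_match = iou_match)$episodes
}

#' @export
print.mt_eval <- function(x, ...) {
  cat("<mt_eval>\n")
  cat(sprintf("  MOTA:                %.4f\n", x$mota))
  cat(sprintf("  coverage:            %.2f%%\n", x$coverage))
  cat(sprintf("  identity error rate: %.2f%%\n", x$identity_error_rate))
  cat(sprintf("  FP: %.2f%% (%s/min)  FN: %.2f%% (%s/min)\n",
              x$rates$fp_pct, signif(x$rates$fp_per_min, 3),
              x$rates$fn_pct, signif(x$rates$fn_per_min, 3)))
  cat(sprintf("  wrong-tag episodes:  %d (mean length %s frames)\n",
              nrow(x$episodes),
              if (nrow(x$episodes)) signif(mean(x$episodes$length), 3) else "-"))
  invisible(x)
}

#' Tidy per-frame evaluation counts
#'
#' @param x An `mt_eval` object.
#' @param ... Unused.
#' @return Tibble of per-frame `fn`, `fp`, `id_error`, `gt`, `detections`.
#' @export
tidy.mt_eval <- function(x, ...) x$counts

#' One-row evaluation summary
#'
#' @param x An `mt_eval` object.
#' @param ... Unused.
#' @return One-row tibble with MOTA, coverage, identity-error rate and
#'   FP/FN rates.
#' @export
glance.mt_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble(mota = x$mota, coverage = x$coverage,
           identity_error_rate = x$identity_error_rate,
           n_episodes = nrow(x$episodes)),
    x$rates
  )
}
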