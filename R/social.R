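# Social-stimulus trajectory comparison: the travel paths of two animals
# are cut into contemporaneous 5-s segments; a segment pair is scored only
# when both animals actually travelled (start-end displacement > 1 cm) and
# the paths are of comparable length (neither more than 35% longer than the
# other). Eligible pairs get a track-pattern-difference score — dynamic time
# warping distance between the z-normalised coordinate sequences, so shape
# is compared regardless of location and scale — and a spatial-proximity
# (SP) value on the raw coordinates, stratifying pairs into proximal
# (SP < 300) and distal (SP > 300).

#' Cut a trajectory into fixed-length segments
#'
#' Consecutive non-overlapping windows aligned to the trajectory start; a
#' trailing fragment shorter than the window is discarded, as are windows
#' with fewer than two samples.
#'
#' @param traj Data frame with `t`, `x`, `y` for one animal.
#' @param window Window length, seconds.
#' @param origin Time origin of the window grid; defaults to the
#'   trajectory's own start. Pass a shared origin to make windows
#'   contemporaneous across animals.
#' @return The trajectory rows with a `segment` index column (0-based
#'   window index), eligible rows only.
#' @export
segment_trajectory <- function(traj, window = 5, origin = NULL) {
  stopifnot(window > 0)
  if (nrow(traj) == 0) return(mutate(traj, segment = integer(0)))
  t0 <- if (is.null(origin)) min(traj$t) else origin
  span <- max(traj$t) - t0
  n_full <- floor(span / window + 1e-9)
  out <- mutate(traj, segment = as.integer(floor((.data$t - t0) / window)))
  out <- filter(out, .data$segment < n_full)
  out %>%
    group_by(.data$segment) %>%
    filter(dplyr::n() >= 2) %>%
    ungroup()
}

path_length <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))

#' Is a contemporaneous segment pair eligible for scoring?
#'
#' Both segments must have start-end displacement above
#' `displacement_min_cm` and path lengths within the ratio bound:
#' `max(L_a, L_b) <= (1 + ratio_max) * min(L_a, L_b)`.
#'
#' @param a,b Data frames with `x`, `y` for the two segments.
#' @param px_per_cm Calibration.
#' @param displacement_min_cm Minimum start-end displacement, cm.
#' @param ratio_max Maximum fractional length difference (0.35 = one path
#'   may be at most 35% longer than the other).
#' @return Logical.
#' @export
pair_eligible <- function(a, b, px_per_cm, displacement_min_cm = 1,
                          ratio_max = 0.35) {
  disp <- function(s) {
    n <- nrow(s)
    px_to_cm(sqrt((s$x[n] - s$x[1])^2 + (s$y[n] - s$y[1])^2), px_per_cm)
  }
  if (disp(a) <= displacement_min_cm || disp(b) <= displacement_min_cm) {
    return(FALSE)
  }
  la <- path_length(a$x, a$y)
  lb <- path_length(b$x, b$y)
  max(la, lb) <= (1 + ratio_max) * min(la, lb)
}

#' Z-normalise a coordinate sequence
#'
#' Each axis is centred by its segment mean and divided by its segment
#' standard deviation, making the downstream DTW score invariant to
#' translation and uniform scaling. A zero-variance axis maps to all zeros.
#'
#' @param xy Matrix or data frame with two coordinate columns.
#' @return A numeric matrix (n x 2).
#' @export
znorm <- function(xy) {
  m <- as.matrix(xy)
  stopifnot(ncol(m) == 2, nrow(m) >= 2)
  for (j in 1:2) {
    s <- sd(m[, j])
    m[, j] <- if (is.na(s) || s == 0) 0 else (m[, j] - mean(m[, j])) / s
  }
  unname(m)
}

#' Dynamic-time-warping distance between two 2-D sequences
#'
#' Classic DTW over the full alignment lattice (no window constraint) with
#' squared Euclidean local cost and the usual match/insert/delete steps,
#' boundary-aligned; the returned score is the square root of the optimal
#' accumulated cost, so it is expressed in Euclidean-distance units and is
#' exactly 0 for identical sequences.
#'
#' @param a,b Numeric matrices (n x 2, m x 2), typically [znorm()] output.
#' @return Non-negative score.
#' @export
dtw_distance <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  n <- nrow(a)
  m <- nrow(b)
  stopifnot(n >= 1, m >= 1, ncol(a) == 2, ncol(b) == 2)
  prev <- c(0, rep(Inf, m))
  cur <- numeric(m + 1)
  for (i in seq_len(n)) {
    cost <- (a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2
    cur[1] <- Inf
    for (j in seq_len(m)) {
      cur[j + 1] <- cost[j] + min(prev[j], prev[j + 1], cur[j])
    }
    prev <- cur
  }
  sqrt(prev[m + 1])
}

#' Spatial proximity of two segments
#'
#' Symmetrised mean of minimal point-to-trajectory Euclidean distances, on
#' raw pixel coordinates: the average of (mean over points of `a` of the
#' distance to the closest point of `b`) and the reverse.
#'
#' @param a,b Data frames with `x`, `y`.
#' @return Non-negative pixels.
#' @export
spatial_proximity <- function(a, b) {
  stopifnot(nrow(a) >= 1, nrow(b) >= 1)
  d2 <- outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2
  d <- sqrt(d2)
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

#' Score all eligible contemporaneous segment pairs of a two-animal trial
#'
#' Segments both trajectories on a shared window grid (aligned to the
#' earlier trajectory start), filters pairs through [pair_eligible()], and
#' computes the track-pattern-difference score (DTW on z-normalised
#' coordinates) and spatial proximity (raw coordinates) for each survivor.
#'
#' @param tracked Tagged tracked tibble containing exactly two tags (extra
#'   tags are an error).
#' @param config An `mt_config`; thresholds from `config$analytics`.
#' @return Tibble: `segment, tag_a, tag_b, dtw_score, sp, class`
#'   (`proximal` when `sp <= sp_split`, else `distal`).
#' @export
score_segment_pairs <- function(tracked, config = default_config()) {
  validate_config(config)
  an <- config$analytics
  trj <- trajectories(tracked)
  tags <- sort(unique(trj$tag))
  if (length(tags) != 2) {
    abort(sprintf("segment-pair scoring needs exactly 2 identified animals, got %d",
                  length(tags)))
  }
  t0 <- min(trj$t)
  segs <- trj %>%
    group_by(.data$tag) %>%
    dplyr::group_modify(~ segment_trajectory(.x, an$segment_seconds,
                                             origin = t0)) %>%
    ungroup()
  a_all <- filter(segs, .data$tag == tags[1])
  b_all <- filter(segs, .data$tag == tags[2])
  shared <- intersect(unique(a_all$segment), unique(b_all$segment))
  rows <- lapply(sort(shared), function(w) {
    a <- filter(a_all, .data$segment == w)
    b <- filter(b_all, .data$segment == w)
    if (!pair_eligible(a, b, config$arena$px_per_cm,
                       an$displacement_min_cm, an$length_ratio_max)) {
      return(NULL)
    }
    score <- dtw_distance(znorm(cbind(a$x, a$y)), znorm(cbind(b$x, b$y)))
    sp <- spatial_proximity(a, b)
    tibble(segment = w, tag_a = tags[1], tag_b = tags[2],
           dtw_score = score, sp = sp,
           class = if (sp <= an$sp_split) "proximal" else "distal")
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(segment = integer(0), tag_a = character(0),
                  tag_b = character(0), dtw_score = numeric(0),
                  sp = numeric(0), class = character(0))
  }
  out
}

#' Trial-level summary of segment-pair scores
#'
#' Arithmetic means of the track-pattern-difference score over all pairs
#' and over the proximal / distal strata. Strata with no pairs are
#' reported as `NA`.
#'
#' @param pairs Tibble from [score_segment_pairs()].
#' @return One-row tibble: `n_pairs, mean_dtw, mean_dtw_proximal,
#'   mean_dtw_distal, n_proximal, n_distal`.
#' @export
trial_summary <- function(pairs) {
  prox <- pairs$dtw_score[pairs$class == "proximal"]
  dist <- pairs$dtw_score[pairs$class == "distal"]
  tibble(
    n_pairs = nrow(pairs),
    mean_dtw = if (nrow(pairs)) mean(pairs$dtw_score) else NA_real_,
    mean_dtw_proximal = if (length(prox)) mean(prox) else NA_real_,
    mean_dtw_distal = if (length(dist)) mean(dist) else NA_real_,
    n_proximal = length(prox),
    n_distal = length(dist)
  )
}
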