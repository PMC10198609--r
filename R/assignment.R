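# Linear-sum assignment (Hungarian algorithm, potentials formulation).
# Used for detection-to-track association and for pairing tracker output
# with ground truth during evaluation. Deterministic: rows and columns are
# scanned in index order, so equal-cost ties resolve to the lowest index.

#' Solve the square linear-sum assignment problem
#'
#' Minimises the total cost of a one-to-one row-to-column assignment.
#' O(n^3) shortest-augmenting-path implementation.
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`.
#' @keywords internal
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n + 1L)        # row potentials (index r + 1, virtual row 0)
  v <- numeric(n + 1L)        # column potentials (index c + 1, virtual col 0)
  p <- integer(n + 1L)        # p[c + 1] = row matched to column c (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      red <- cost[i0, ] - u[i0 + 1L] - v[2L:(n + 1L)]
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          if (red[j] < minv[j + 1L]) {
            minv[j + 1L] <- red[j]
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0L:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Associate detections with track predictions by IOU
#'
#' Optimal one-to-one pairing that maximises total intersection-over-union
#' (Hungarian algorithm on negated IOU). Pairs whose IOU falls below
#' `iou_threshold` are returned as unmatched.
#'
#' @param det_boxes Numeric matrix (n x 4) of detection boxes.
#' @param pred_boxes Numeric matrix (m x 4) of predicted track boxes.
#' @param iou_threshold Minimum IOU for a pair to count as a match, in (0, 1).
#' @return A list with integer matrix `matches` (columns `det`, `track`),
#'   and integer vectors `unmatched_dets`, `unmatched_tracks` (row indices).
#' @export
associate_detections <- function(det_boxes, pred_boxes, iou_threshold = 0.3) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  n <- nrow(det_boxes)
  m <- nrow(pred_boxes)
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("det", "track")))
  if (n == 0L || m == 0L) {
    return(list(matches = empty,
                unmatched_dets = seq_len(n),
                unmatched_tracks = seq_len(m)))
  }
  iou <- iou_matrix(det_boxes, pred_boxes)
  k <- max(n, m)
  cost <- matrix(1, k, k)              # padded cells: cost 1 > any -iou
  cost[seq_len(n), seq_len(m)] <- -iou
  a <- solve_assignment(cost)
  det_idx <- seq_len(n)
  trk_idx <- a[seq_len(n)]
  keep <- trk_idx <= m & trk_idx > 0L
  keep[keep] <- iou[cbind(det_idx[keep], trk_idx[keep])] >= iou_threshold
  matches <- cbind(det = det_idx[keep], track = trk_idx[keep])
  list(
    matches = matches,
    unmatched_dets = setdiff(det_idx, matches[, "det"]),
    unmatched_tracks = setdiff(seq_len(m), matches[, "track"])
  )
}
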