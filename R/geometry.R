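# Axis-aligned bounding-box geometry shared by every module.
#
# Convention (used package-wide): pixel coordinates, image origin at the
# top-left, x rightward, y downward. A box is the numeric vector
# c(x_min, y_min, x_max, y_max) or the equivalent four columns of a tibble.

#' Validate a bounding box
#'
#' A valid box has `x_min < x_max`, `y_min < y_max` and hence strictly
#' positive area. Degenerate (zero-area) boxes are an error because they make
#' the intersection-over-union test meaningless.
#'
#' @param box Numeric vector `c(x_min, y_min, x_max, y_max)`.
#' @return The box, invisibly, if valid; otherwise an error.
#' @keywords internal
validate_bbox <- function(box) {
  if (length(box) != 4L || !is.numeric(box) || anyNA(box)) {
    abort("a bounding box is a numeric vector c(x_min, y_min, x_max, y_max)")
  }
  if (box[1] >= box[3] || box[2] >= box[4]) {
    abort(sprintf(
      "degenerate bounding box: need x_min < x_max and y_min < y_max, got (%s)",
      paste(signif(box, 6), collapse = ", ")
    ))
  }
  invisible(box)
}

#' Intersection over union of two boxes
#'
#' The overlap criterion used both for detection-to-track association and for
#' the RFID reader range test. Returns 0 for disjoint boxes and 1 only for
#' identical boxes.
#'
#' @param a,b Boxes, `c(x_min, y_min, x_max, y_max)`.
#' @return A number in `[0, 1]`.
#' @examples
#' bbox_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)) # 1/3
#' @export
bbox_iou <- function(a, b) {
  validate_bbox(a)
  validate_bbox(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# IOU of every row of A against every row of B (n x 4, m x 4 matrices),
# without per-pair validation; the tracker's hot path.
iou_matrix <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  ix1 <- outer(A[, 1], B[, 1], pmax)
  iy1 <- outer(A[, 2], B[, 2], pmax)
  ix2 <- outer(A[, 3], B[, 3], pmin)
  iy2 <- outer(A[, 4], B[, 4], pmin)
  w <- pmax(ix2 - ix1, 0)
  h <- pmax(iy2 - iy1, 0)
  inter <- w * h
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  inter / (outer(areaA, areaB, `+`) - inter)
}

#' Centroid of a box
#'
#' @param box Box `c(x_min, y_min, x_max, y_max)`.
#' @return Numeric `c(x, y)` in pixels.
#' @export
bbox_centroid <- function(box) {
  validate_bbox(box)
  c((box[1] + box[3]) / 2, (box[2] + box[4]) / 2)
}

#' Enlarge a box by an area factor
#'
#' Scales each side by `sqrt(area_factor)` about the box centroid, so the
#' area is multiplied exactly by `area_factor`. Social-interaction episodes
#' use 25% area enlargement (`area_factor = 1.25`) before testing overlap.
#'
#' @param box Box `c(x_min, y_min, x_max, y_max)`.
#' @param area_factor Positive multiplier for the area.
#' @return The enlarged box.
#' @export
bbox_enlarge <- function(box, area_factor) {
  validate_bbox(box)
  if (!is.numeric(area_factor) || length(area_factor) != 1L ||
      is.na(area_factor) || area_factor <= 0) {
    abort("`area_factor` must be a single positive number")
  }
  k <- sqrt(area_factor)
  cx <- (box[1] + box[3]) / 2
  cy <- (box[2] + box[4]) / 2
  hw <- (box[3] - box[1]) / 2 * k
  hh <- (box[4] - box[2]) / 2 * k
  c(cx - hw, cy - hh, cx + hw, cy + hh)
}

#' Convert pixels to centimetres (and back)
#'
#' @param d Distance(s) in pixels (`px_to_cm`) or centimetres (`cm_to_px`).
#' @param px_per_cm Calibration, pixels per centimetre (> 0).
#' @return Converted distance(s).
#' @export
px_to_cm <- function(d, px_per_cm) {
  stopifnot(is.numeric(px_per_cm), length(px_per_cm) == 1L,
            is.finite(px_per_cm), px_per_cm > 0)
  d / px_per_cm
}

#' @rdname px_to_cm
#' @export
cm_to_px <- function(d, px_per_cm) {
  stopifnot(is.numeric(px_per_cm), length(px_per_cm) == 1L,
            is.finite(px_per_cm), px_per_cm > 0)
  d * px_per_cm
}

# helpers to move between tibble columns and box matrices
box_cols <- c("x_min", "y_min", "x_max", "y_max")

boxes_from_df <- function(df) {
  as.matrix(df[, box_cols, drop = FALSE])
}
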