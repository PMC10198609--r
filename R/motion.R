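# Motion detector: background subtraction against an accumulated running
# average. Each grayscale frame is Gaussian-smoothed (21 x 21 kernel), the
# absolute difference against the accumulated background is thresholded,
# and connected foreground components of sufficient area mark the frame as
# containing motion. Smoothing and component labelling use EBImage.

#' Detect motion across a grayscale image stack
#'
#' The background starts as the first smoothed frame and is updated as
#' `B <- (1 - alpha) * B + alpha * frame` after each comparison. Frames
#' within the warm-up period (first second, while the background is still
#' being built) are never flagged, nor is the first frame.
#'
#' @param frames 3-D numeric array `[row, col, frame]`, single channel
#'   (0-255 or 0-1 scale; the threshold must match).
#' @param fps Frame rate (drives the warm-up length).
#' @param alpha Background accumulation weight in (0, 1].
#' @param diff_threshold Absolute-intensity difference above which a pixel
#'   is foreground.
#' @param min_contour_area Minimum connected-component area (pixels^2) for
#'   a region to count as motion.
#' @param kernel_size,kernel_sigma Gaussian smoothing kernel (pixels).
#' @param warmup_s Warm-up in seconds.
#' @return An object of class `mt_motion`: tibble `flags` (`frame`,
#'   `motion`, `fg_pixels`, `n_components`) and list `contours` of
#'   per-frame component bounding boxes.
#' @export
detect_motion <- function(frames, fps,
                          alpha = 0.05, diff_threshold = 25,
                          min_contour_area = 50,
                          kernel_size = 21, kernel_sigma = 3.5,
                          warmup_s = 1) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a 3-D array [row, col, frame]")
  }
  nf <- dim(frames)[3]
  if (nf < 2) abort("need at least 2 frames")
  stopifnot(alpha > 0, alpha <= 1, fps > 0)
  brush <- EBImage::makeBrush(kernel_size, shape = "Gaussian",
                              sigma = kernel_sigma)
  warmup <- max(1L, ceiling(warmup_s * fps))
  motion <- logical(nf)
  fg <- integer(nf)
  ncomp <- integer(nf)
  contours <- vector("list", nf)
  B <- NULL
  for (i in seq_len(nf)) {
    sm <- EBImage::filter2(frames[, , i], brush)
    if (i == 1L) {
      B <- sm
      contours[[i]] <- empty_contours()
      next
    }
    mask <- abs(sm - B) > diff_threshold
    B <- (1 - alpha) * B + alpha * sm
    if (i <= warmup) {
      contours[[i]] <- empty_contours()
      next
    }
    fg[i] <- sum(mask)
    if (fg[i] > 0) {
      lab <- EBImage::bwlabel(mask)
      areas <- tabulate(lab[lab > 0])
      keep <- which(areas >= min_contour_area)
      ncomp[i] <- length(keep)
      if (length(keep)) {
        motion[i] <- TRUE
        contours[[i]] <- component_boxes(lab, keep)
      } else {
        contours[[i]] <- empty_contours()
      }
    } else {
      contours[[i]] <- empty_contours()
    }
  }
  structure(list(
    flags = tibble(frame = seq_len(nf) - 1L, motion = motion,
                   fg_pixels = fg, n_components = ncomp),
    contours = contours,
    params = list(alpha = alpha, diff_threshold = diff_threshold,
                  min_contour_area = min_contour_area, fps = fps,
                  warmup_frames = warmup)
  ), class = "mt_motion")
}

empty_contours <- function() {
  tibble(x_min = numeric(0), y_min = numeric(0),
         x_max = numeric(0), y_max = numeric(0), area = numeric(0))
}

component_boxes <- function(lab, keep) {
  rows <- list()
  m <- lab
  for (k in keep) {
    idx <- which(m == k, arr.ind = TRUE)
    rows[[length(rows) + 1L]] <- tibble(
      x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
      x_max = max(idx[, 2]), y_max = max(idx[, 1]),
      area = nrow(idx)
    )
  }
  bind_rows(rows)
}

#' Total active duration from motion flags
#'
#' Sums the inter-frame intervals of flagged frames (each flagged frame
#' contributes the interval to the next frame; the last frame the nominal
#' interval).
#'
#' @param result An `mt_motion` object.
#' @param clock Frame clock tibble covering the stack's frames; when `NULL`
#'   the nominal fps from the detector parameters is used.
#' @return Seconds.
#' @export
active_duration <- function(result, clock = NULL) {
  stopifnot(inherits(result, "mt_motion"))
  fl <- result$flags
  t <- if (!is.null(clock)) {
    clock$time[match(fl$frame, clock$frame)]
  } else {
    fl$frame / result$params$fps
  }
  sum(frame_durations(t, result$params$fps)[fl$motion])
}
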