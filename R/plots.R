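# ggplot2 views of the pipeline's tables.

#' Plot tracked trajectories
#'
#' Centroid paths coloured by RFID tag (untagged stretches in grey), with
#' reader zones overlaid when a config is supplied.
#'
#' @param tracked Tracked tibble (tagged or not).
#' @param config Optional `mt_config` for reader-zone overlays.
#' @return A ggplot.
#' @export
plot_tracks <- function(tracked, config = NULL) {
  df <- tracked
  if (!"tag" %in% names(df)) df$tag <- NA_character_
  df$identity <- ifelse(is.na(df$tag), "unassigned", df$tag)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cx, y = .data$cy,
                                        group = .data$sort_id,
                                        colour = .data$identity)) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::scale_y_reverse() +    # image coordinates: y grows downward
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "identity")
  if (!is.null(config) && !is.null(config$readers)) {
    p <- p + ggplot2::geom_rect(
      data = config$readers,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = .data$y_min, ymax = .data$y_max),
      inherit.aes = FALSE, fill = NA, colour = "grey40", linetype = 2)
  }
  p
}

#' Plot segment pair scores
#'
#' Track-pattern-difference score against spatial proximity, coloured by
#' the proximal/distal stratification.
#'
#' @param pairs Tibble from [score_segment_pairs()].
#' @param sp_split Proximal/distal threshold to mark.
#' @return A ggplot.
#' @export
plot_pair_scores <- function(pairs, sp_split = 300) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$sp, y = .data$dtw_score,
                                      colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = sp_split, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "spatial proximity (px)",
                  y = "track pattern difference score",
                  colour = NULL)
}

#' Autoplot a simulated session
#'
#' Ground-truth trajectories with the reader layout.
#'
#' @param object An `mt_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mt_sim <- function(object, ...) {
  ggplot2::ggplot(object$truth,
                  ggplot2::aes(x = .data$cx, y = .data$cy,
                               colour = .data$tag)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::geom_rect(
      data = object$config$readers,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = .data$y_min, ymax = .data$y_max),
      inherit.aes = FALSE, fill = NA, colour = "grey40", linetype = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "animal")
}

#' Autoplot per-frame evaluation counts
#'
#' @param object An `mt_eval`.
#' @param ... Unused.
#' @return A ggplot of cumulative FN / FP / identity errors over frames.
#' @export
autoplot.mt_eval <- function(object, ...) {
  df <- object$counts %>%
    mutate(FN = cumsum(.data$fn), FP = cumsum(.data$fp),
           `identity errors` = cumsum(.data$id_error)) %>%
    tidyr::pivot_longer(c("FN", "FP", "identity errors"),
                        names_to = "error", values_to = "cumulative")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$cumulative,
                                   colour = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "cumulative count", colour = NULL)
}
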