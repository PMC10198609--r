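# Synthetic multi-mouse arena sessions with ground truth: mice follow a
# correlated random walk inside the arena, detections are the true boxes
# degraded by Bernoulli dropout, corner jitter, Poisson spurious boxes and
# occlusion merging (two strongly overlapping animals reported as one box,
# the clustering failure mode the tracker's coasting addresses), and RFID
# reads are emitted per reader for in-range mice under a Bernoulli model
# with a refractory interval emulating reader polling. Everything flows
# from a single seeded generator, so a seed fully reproduces a session.

#' Simulation presets
#'
#' Geometry mirroring the three demonstration arenas: a modified shoebox
#' home-cage (19 x 29 cm, six readers, 512 x 400 px at 15 fps), a 32 x 32
#' cm open field (nine readers, 960 x 960 px), and a three-chamber arena
#' (60 x 20 cm, four readers, 640 x 480 px). `noise` selects `"none"`
#' (ideal detector and reader) or `"noisy"` (detector and reader
#' degradation at realistic rates).
#'
#' @param preset `"homecage"`, `"openfield6"` or `"threechamber"`.
#' @param noise `"none"` or `"noisy"`.
#' @return A list of simulation parameters accepted by
#'   [simulate_session()].
#' @export
sim_preset <- function(preset = c("homecage", "openfield6", "threechamber"),
                       noise = c("none", "noisy")) {
  preset <- match.arg(preset)
  noise <- match.arg(noise)
  base <- switch(preset,
    homecage = list(
      arena_w_cm = 29, arena_h_cm = 19, px_per_cm = 512 / 29,
      n_mice = 3, fps = 15, reader_grid = c(3, 2), min_spacing_cm = 9
    ),
    openfield6 = list(
      arena_w_cm = 32, arena_h_cm = 32, px_per_cm = 960 / 32,
      n_mice = 6, fps = 15, reader_grid = c(3, 3), min_spacing_cm = 10
    ),
    threechamber = list(
      arena_w_cm = 60, arena_h_cm = 20, px_per_cm = 640 / 60,
      n_mice = 3, fps = 15, reader_grid = c(4, 1), min_spacing_cm = 12
    )
  )
  noise_par <- switch(noise,
    none = list(dropout_prob = 0, jitter_sd_px = 0, fp_rate_per_min = 0,
                occl_merge_iou = 1, occl_merge_prob = 0),
    noisy = list(dropout_prob = 0.02, jitter_sd_px = 1.5,
                     fp_rate_per_min = 10, occl_merge_iou = 0.15,
                     occl_merge_prob = 0.5)
  )
  c(base, noise_par, list(
    duration_s = 600,
    box_w_cm = 5, box_h_cm = 3,
    speed_mean_cms = 8, speed_sd_cms = 4, heading_persistence = 0.85,
    active_bout_s = 8, rest_bout_s = 12,
    reader_zone_cm = 4, read_radius_cm = 6,
    min_separation_cm = 3,
    read_prob = if (noise == "none") 1 else 0.1,
    read_refractory_s = 1
  ))
}

#' Simulate a multi-mouse session with ground truth
#'
#' @param params Parameter list, typically from [sim_preset()]; any element
#'   can be overridden via `...`.
#' @param seed Integer seed; the whole session (walks, detector noise,
#'   reads) is reproducible from it.
#' @param ... Overrides for individual elements of `params`.
#' @return A list of class `mt_sim` with elements `detections`, `clock`,
#'   `reads` (the session file set), `truth` (per frame per mouse true box
#'   and tag), `read_truth` (the emitting mouse of each read), and `config`
#'   (an `mt_config` matching the arena).
#' @export
simulate_session <- function(params = sim_preset(), seed = 1, ...) {
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(params))
    if (length(bad)) abort(sprintf("unknown simulation parameter(s): %s",
                                   paste(bad, collapse = ", ")))
    params[names(over)] <- over
  }
  p <- params
  stopifnot(p$n_mice >= 0, p$duration_s > 0, p$fps > 0,
            p$dropout_prob >= 0, p$dropout_prob <= 1,
            p$read_prob >= 0, p$read_prob <= 1,
            p$occl_merge_prob >= 0, p$occl_merge_prob <= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  ppc <- p$px_per_cm
  W <- p$arena_w_cm * ppc
  H <- p$arena_h_cm * ppc
  n_frames <- as.integer(round(p$duration_s * p$fps))
  frames <- seq_len(n_frames) - 1L
  clock <- tibble(frame = frames, time = frames / p$fps)

  # reader layout: grid of zones, spacing validated against the minimum
  readers <- reader_layout(p, W, H, ppc)

  hw <- p$box_w_cm * ppc / 2
  hh <- p$box_h_cm * ppc / 2
  tags <- if (p$n_mice > 0) sprintf("tag%02d", seq_len(p$n_mice)) else character(0)

  # --- correlated random walks -------------------------------------------
  # per-mouse heading random walk + truncated-Gaussian speed, gated by a
  # two-state move/rest bout structure (home-cage locomotion is
  # intermittent, not continuous); walls reflect specularly, and mice are
  # solid bodies: a soft repulsion keeps centroids at least
  # min_separation_cm apart, so boxes can overlap but never coincide
  truth_list <- vector("list", max(p$n_mice, 1))
  pos <- vector("list", p$n_mice)   # per mouse n_frames x 2 centroids (px)
  if (p$n_mice > 0) {
    nm <- p$n_mice
    headings <- matrix(0, n_frames, nm)
    steps <- matrix(0, n_frames, nm)
    for (m in seq_len(nm)) {
      headings[, m] <- runif(1, 0, 2 * pi) +
        cumsum(c(0, rnorm(n_frames - 1, 0, (1 - p$heading_persistence) * pi)))
      speed <- pmax(0, rnorm(n_frames, p$speed_mean_cms, p$speed_sd_cms))
      active <- logical(n_frames)
      state <- runif(1) < p$active_bout_s / (p$active_bout_s + p$rest_bout_s)
      p_stop <- 1 / max(1, p$active_bout_s * p$fps)
      p_go <- 1 / max(1, p$rest_bout_s * p$fps)
      flips <- runif(n_frames)
      for (i in seq_len(n_frames)) {
        active[i] <- state
        state <- if (state) flips[i] >= p_stop else flips[i] < p_go
      }
      steps[, m] <- speed * active * ppc / p$fps
    }
    min_sep <- p$min_separation_cm * ppc
    P <- matrix(0, nm, 2)
    for (try in 1:200) {
      P[, 1] <- runif(nm, hw, W - hw)
      P[, 2] <- runif(nm, hh, H - hh)
      if (nm == 1 || min(stats::dist(P)) >= min_sep) break
    }
    sx <- rep(1, nm)   # velocity mirror signs from wall reflections
    sy <- rep(1, nm)
    traj <- array(NA_real_, c(n_frames, 2, nm))
    for (i in seq_len(n_frames)) {
      if (i > 1) {
        px <- P[, 1] + sx * steps[i - 1, ] * cos(headings[i - 1, ])
        py <- P[, 2] + sy * steps[i - 1, ] * sin(headings[i - 1, ])
        # specular wall reflection mirrors the future velocity component
        lo <- px < hw; hi <- px > W - hw
        px[lo] <- 2 * hw - px[lo]; px[hi] <- 2 * (W - hw) - px[hi]
        sx[lo | hi] <- -sx[lo | hi]
        lo <- py < hh; hi <- py > H - hh
        py[lo] <- 2 * hh - py[lo]; py[hi] <- 2 * (H - hh) - py[hi]
        sy[lo | hi] <- -sy[lo | hi]
        P <- cbind(pmin(pmax(px, hw), W - hw), pmin(pmax(py, hh), H - hh))
      }
      if (nm > 1) {
        for (it in 1:2) {
          moved <- FALSE
          for (a in seq_len(nm - 1)) {
            for (b in (a + 1):nm) {
              dvec <- P[b, ] - P[a, ]
              d <- sqrt(sum(dvec^2))
              if (d < min_sep) {
                u <- if (d > 1e-9) dvec / d else
                  c(cos(2 * pi * a / nm), sin(2 * pi * a / nm))
                push <- (min_sep - d) / 2
                P[a, ] <- P[a, ] - u * push
                P[b, ] <- P[b, ] + u * push
                moved <- TRUE
              }
            }
          }
          if (!moved) break
        }
        P <- cbind(pmin(pmax(P[, 1], hw), W - hw),
                   pmin(pmax(P[, 2], hh), H - hh))
      }
      traj[i, , ] <- t(P)
    }
    for (m in seq_len(nm)) {
      pos[[m]] <- cbind(traj[, 1, m], traj[, 2, m])
      truth_list[[m]] <- tibble(
        frame = frames, tag = tags[m],
        x_min = pos[[m]][, 1] - hw, y_min = pos[[m]][, 2] - hh,
        x_max = pos[[m]][, 1] + hw, y_max = pos[[m]][, 2] + hh
      )
    }
  }
  truth <- if (p$n_mice > 0) bind_rows(truth_list) else
    tibble(frame = integer(0), tag = character(0),
           x_min = numeric(0), y_min = numeric(0),
           x_max = numeric(0), y_max = numeric(0))
  truth <- arrange(truth, .data$frame, .data$tag)
  truth$cx <- (truth$x_min + truth$x_max) / 2
  truth$cy <- (truth$y_min + truth$y_max) / 2

  # --- detections: merge, dropout, jitter, spurious boxes ----------------
  det <- truth[, c("frame", box_cols)]
  det$src <- truth$tag
  if (p$n_mice >= 2 && p$occl_merge_prob > 0) {
    det <- apply_occlusion_merge(det, p$occl_merge_iou, p$occl_merge_prob)
  }
  if (p$dropout_prob > 0 && nrow(det)) {
    det <- det[runif(nrow(det)) >= p$dropout_prob, , drop = FALSE]
  }
  if (p$jitter_sd_px > 0 && nrow(det)) {
    n <- nrow(det)
    det$x_min <- det$x_min + rnorm(n, 0, p$jitter_sd_px)
    det$y_min <- det$y_min + rnorm(n, 0, p$jitter_sd_px)
    det$x_max <- det$x_max + rnorm(n, 0, p$jitter_sd_px)
    det$y_max <- det$y_max + rnorm(n, 0, p$jitter_sd_px)
    # corner jitter cannot be allowed to invert a box
    bad <- det$x_min >= det$x_max | det$y_min >= det$y_max
    if (any(bad)) det <- det[!bad, , drop = FALSE]
  }
  det$confidence <- if (nrow(det)) runif(nrow(det), 0.85, 1) else numeric(0)
  if (p$fp_rate_per_min > 0) {
    n_fp <- rpois(1, p$fp_rate_per_min * p$duration_s / 60)
    if (n_fp > 0) {
      fx <- runif(n_fp, hw, W - hw)
      fy <- runif(n_fp, hh, H - hh)
      det <- bind_rows(det, tibble(
        frame = sample(frames, n_fp, replace = TRUE),
        x_min = fx - hw, y_min = fy - hh, x_max = fx + hw, y_max = fy + hh,
        src = NA_character_, confidence = runif(n_fp, 0.5, 0.9)
      ))
    }
  }
  detections <- det %>%
    select("frame", all_of(box_cols), "confidence") %>%
    arrange(.data$frame)

  # --- RFID reads --------------------------------------------------------
  rr <- simulate_reads(p, pos, tags, clock, readers)

  config <- default_config(
    fps = p$fps, arena_w_px = W, arena_h_px = H, px_per_cm = ppc,
    readers = readers,
    typical_box_px = c(p$box_w_cm, p$box_h_cm) * ppc
  )
  structure(list(
    detections = detections, clock = clock, reads = rr$reads,
    truth = truth, read_truth = rr$read_truth,
    config = config, params = p, seed = seed
  ), class = "mt_sim")
}

# fold an unbounded coordinate into [lo, hi] by specular reflection
reflect_into <- function(x, lo, hi) {
  L <- hi - lo
  if (L <= 0) abort("arena too small for the mouse box")
  z <- (x - lo) %% (2 * L)
  lo + pmin(z, 2 * L - z)
}

reader_layout <- function(p, W, H, ppc) {
  gx <- p$reader_grid[1]
  gy <- p$reader_grid[2]
  cx <- (seq_len(gx) - 0.5) / gx * W
  cy <- (seq_len(gy) - 0.5) / gy * H
  centers <- expand.grid(cx = cx, cy = cy)
  if (nrow(centers) > 1) {
    dmat <- as.matrix(stats::dist(centers)) / ppc
    min_d <- min(dmat[upper.tri(dmat)])
    if (min_d < p$min_spacing_cm) {
      abort(sprintf(
        "infeasible reader layout: spacing %.1f cm below the %.1f cm minimum",
        min_d, p$min_spacing_cm))
    }
  }
  zr <- p$reader_zone_cm * ppc / 2
  tibble(
    reader_id = seq_len(nrow(centers)) - 1L,
    x_min = centers$cx - zr, y_min = centers$cy - zr,
    x_max = centers$cx + zr, y_max = centers$cy + zr,
    # the matcher's range test must cover every position that can
    # physically emit a read (plus a margin for box jitter and coasting
    # drift), otherwise a boundary read gets attributed to whichever other
    # track happens to sit inside the test region
    range_radius = p$read_radius_cm * ppc * 1.1
  )
}

# detection merging during occlusion: when two animals' true boxes exceed
# the merge IOU they form a contact episode (maximal run of overlap
# frames); with the configured probability the detector reports one merged
# (union) box for the whole episode. The draw is per episode, not per
# frame — real detectors fail persistently while the geometry persists,
# they do not flicker between one and two boxes frame by frame.
apply_occlusion_merge <- function(det, merge_iou, merge_prob) {
  tags <- sort(unique(det$src[!is.na(det$src)]))
  drop <- rep(FALSE, nrow(det))
  add <- list()
  merged_frame <- setNames(vector("list", length(tags)), tags)
  for (tg in tags) merged_frame[[tg]] <- integer(0)
  for (a in seq_len(length(tags) - 1L)) {
    for (b in (a + 1L):length(tags)) {
      ra <- which(det$src == tags[a])
      rb <- which(det$src == tags[b])
      fa <- det$frame[ra]
      common <- intersect(fa, det$frame[rb])
      if (!length(common)) next
      ia <- ra[match(common, fa)]
      ib <- rb[match(common, det$frame[rb])]
      iw <- pmax(pmin(det$x_max[ia], det$x_max[ib]) -
                   pmax(det$x_min[ia], det$x_min[ib]), 0)
      ih <- pmax(pmin(det$y_max[ia], det$y_max[ib]) -
                   pmax(det$y_min[ia], det$y_min[ib]), 0)
      inter <- iw * ih
      aa <- (det$x_max[ia] - det$x_min[ia]) * (det$y_max[ia] - det$y_min[ia])
      ab <- (det$x_max[ib] - det$x_min[ib]) * (det$y_max[ib] - det$y_min[ib])
      contact <- inter / (aa + ab - inter) > merge_iou
      if (!any(contact)) next
      r <- rle(contact)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (q in which(r$values)) {
        if (runif(1) >= merge_prob) next
        for (k in starts[q]:ends[q]) {
          i <- ia[k]
          j <- ib[k]
          if (drop[i] || drop[j]) next   # animal already merged elsewhere
          drop[i] <- drop[j] <- TRUE
          add[[length(add) + 1L]] <- tibble(
            frame = det$frame[i],
            x_min = min(det$x_min[i], det$x_min[j]),
            y_min = min(det$y_min[i], det$y_min[j]),
            x_max = max(det$x_max[i], det$x_max[j]),
            y_max = max(det$y_max[i], det$y_max[j]),
            src = NA_character_
          )
        }
      }
    }
  }
  bind_rows(det[!drop, , drop = FALSE], bind_rows(add))
}

simulate_reads <- function(p, pos, tags, clock, readers) {
  empty <- list(
    reads = tibble(time = numeric(0), reader_id = integer(0),
                   tag = character(0)),
    read_truth = tibble(time = numeric(0), reader_id = integer(0),
                        tag = character(0))
  )
  if (p$n_mice == 0 || p$read_prob == 0) return(empty)
  radius <- p$read_radius_cm * p$px_per_cm
  n_frames <- nrow(clock)
  rcx <- (readers$x_min + readers$x_max) / 2
  rcy <- (readers$y_min + readers$y_max) / 2
  out_t <- numeric(0)
  out_r <- integer(0)
  out_tag <- character(0)
  for (r in seq_len(nrow(readers))) {
    # in-range indicator per frame per mouse, then Bernoulli successes
    in_rng <- sapply(seq_len(p$n_mice), function(m) {
      sqrt((pos[[m]][, 1] - rcx[r])^2 + (pos[[m]][, 2] - rcy[r])^2) <= radius
    })
    in_rng <- matrix(in_rng, nrow = n_frames)
    succ <- in_rng & matrix(runif(length(in_rng)) < p$read_prob,
                            nrow = n_frames)
    cand_frames <- which(rowSums(succ) > 0)
    next_ok <- -Inf
    for (fi in cand_frames) {
      t <- clock$time[fi]
      if (t < next_ok) next
      mice <- which(succ[fi, ])
      m <- if (length(mice) == 1) mice else sample(mice, 1)
      out_t <- c(out_t, t)
      out_r <- c(out_r, readers$reader_id[r])
      out_tag <- c(out_tag, tags[m])
      next_ok <- t + p$read_refractory_s
    }
  }
  o <- order(out_t, out_r)
  reads <- tibble(time = out_t[o], reader_id = out_r[o], tag = out_tag[o])
  list(reads = reads, read_truth = reads)
}

#' Render a simulated session as a grayscale image stack
#'
#' Bright ellipses on a dark background at the true box locations (or the
#' inverse for low-contrast stress cases). Intended as motion-detector
#' input; rendering at a reduced `scale` keeps the stack small.
#'
#' @param sim An `mt_sim` from [simulate_session()].
#' @param scale Spatial down-scaling factor in (0, 1].
#' @param invert Render dark mice on a bright background.
#' @param frames Frame indices to render (default: all).
#' @return 3-D array `[row, col, frame]`, intensities 0-255.
#' @export
render_frames <- function(sim, scale = 0.25, invert = FALSE, frames = NULL) {
  stopifnot(inherits(sim, "mt_sim"), scale > 0, scale <= 1)
  W <- max(2L, as.integer(round(sim$config$arena$width_px * scale)))
  H <- max(2L, as.integer(round(sim$config$arena$height_px * scale)))
  if (is.null(frames)) frames <- sim$clock$frame
  bg <- if (invert) 220 else 30
  fgv <- if (invert) 30 else 220
  stack <- array(bg, dim = c(H, W, length(frames)))
  tr <- sim$truth
  xs <- seq_len(W) - 0.5
  ys <- seq_len(H) - 0.5
  for (k in seq_along(frames)) {
    rows <- which(tr$frame == frames[k])
    for (i in rows) {
      cx <- (tr$cx[i]) * scale
      cy <- (tr$cy[i]) * scale
      a <- (tr$x_max[i] - tr$x_min[i]) / 2 * scale
      b <- (tr$y_max[i] - tr$y_min[i]) / 2 * scale
      if (a < 0.5) a <- 0.5
      if (b < 0.5) b <- 0.5
      inside <- outer((ys - cy)^2 / b^2, (xs - cx)^2 / a^2, `+`) <= 1
      frame <- stack[, , k]
      frame[inside] <- fgv
      stack[, , k] <- frame
    }
  }
  stack
}

#' @export
print.mt_sim <- function(x, ...) {
  cat(sprintf(
    "<mt_sim> %d mice, %.0f s at %g fps: %d detections, %d RFID reads, %d readers\n",
    x$params$n_mice, x$params$duration_s, x$params$fps,
    nrow(x$detections), nrow(x$reads), nrow(x$config$readers)))
  invisible(x)
}

#' Write a simulated session's file set
#'
#' Emits the detections, clock, RFID-log and ground-truth CSVs plus the
#' run configuration (YAML) into a directory.
#'
#' @param sim An `mt_sim`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_session <- function(sim, dir) {
  stopifnot(inherits(sim, "mt_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    detections = file.path(dir, "detections.csv"),
    clock = file.path(dir, "frame_times.csv"),
    rfid = file.path(dir, "rfid_reads.csv"),
    truth = file.path(dir, "ground_truth.csv"),
    config = file.path(dir, "config.yaml")
  )
  readr::write_csv(sim$detections, paths["detections"], na = "")
  readr::write_csv(sim$clock, paths["clock"], na = "")
  readr::write_csv(
    tibble(timestamp = sim$reads$time, reader_id = sim$reads$reader_id,
           tag = sim$reads$tag),
    paths["rfid"], na = "")
  readr::write_csv(sim$truth, paths["truth"], na = "")
  write_config(sim$config, paths["config"])
  invisible(paths)
}
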