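# Shared builders and independent oracles.

make_clock <- function(n, fps = 15) {
  tibble::tibble(frame = 0:(n - 1L), time = (0:(n - 1L)) / fps)
}

# detections of one object moving at constant velocity
linear_detections <- function(n, x0 = 100, y0 = 100, vx = 5, vy = 0,
                              w = 50, h = 40, drop_frames = integer(0)) {
  f <- 0:(n - 1L)
  d <- tibble::tibble(
    frame = f,
    x_min = x0 + vx * f, y_min = y0 + vy * f,
    x_max = x0 + w + vx * f, y_max = y0 + h + vy * f,
    confidence = 1
  )
  d[!d$frame %in% drop_frames, ]
}

test_config <- function(fps = 15, readers = NULL, ...) {
  default_config(fps = fps, arena_w_px = 1000, arena_h_px = 1000,
                 px_per_cm = 10, readers = readers, ...)
}

one_zone <- function(cx, cy, half = 20, radius = 80, id = 0L) {
  tibble::tibble(reader_id = id, x_min = cx - half, y_min = cy - half,
                 x_max = cx + half, y_max = cy + half, range_radius = radius)
}

# ---- independent oracles ---------------------------------------------------

# assignment by exhaustive permutation enumeration (n <= ~6)
perm_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  best_p <- NULL
  for (p in perms(seq_len(n))) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) {
      best <- s
      best_p <- p
    }
  }
  list(cost = best, assignment = best_p)
}

# DTW by exhaustive recursion over the alignment lattice (lengths <= 8)
dtw_oracle <- function(a, b) {
  n <- nrow(a)
  m <- nrow(b)
  cost <- function(i, j) sum((a[i, ] - b[j, ])^2)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(cost(1, 1))
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    best + cost(i, j)
  }
  sqrt(rec(n, m))
}

# plain recursive Ramer-Douglas-Peucker
rdp_oracle <- function(xy, eps) {
  n <- nrow(xy)
  if (n < 3) return(xy)
  d <- numeric(n)
  for (k in 2:(n - 1)) {
    x1 <- xy[1, 1]; y1 <- xy[1, 2]; x2 <- xy[n, 1]; y2 <- xy[n, 2]
    L2 <- (x2 - x1)^2 + (y2 - y1)^2
    if (L2 == 0) {
      d[k] <- sqrt((xy[k, 1] - x1)^2 + (xy[k, 2] - y1)^2)
    } else {
      t <- ((xy[k, 1] - x1) * (x2 - x1) + (xy[k, 2] - y1) * (y2 - y1)) / L2
      t <- min(1, max(0, t))
      d[k] <- sqrt((xy[k, 1] - (x1 + t * (x2 - x1)))^2 +
                     (xy[k, 2] - (y1 + t * (y2 - y1)))^2)
    }
  }
  kmax <- which.max(d)
  if (d[kmax] > eps) {
    left <- rdp_oracle(xy[1:kmax, , drop = FALSE], eps)
    right <- rdp_oracle(xy[kmax:n, , drop = FALSE], eps)
    rbind(left[-nrow(left), , drop = FALSE], right)
  } else {
    xy[c(1, n), , drop = FALSE]
  }
}
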