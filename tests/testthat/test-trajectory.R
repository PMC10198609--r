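test_that("RDP keeps endpoints and respects the tolerance", {
  col <- tibble::tibble(x = c(0, 5, 10), y = c(0, 0, 0))
  expect_equal(nrow(rdp_simplify(col, 1)), 2L)

  v <- tibble::tibble(x = c(0, 5, 10), y = c(0, 1, 0))  # max deviation 1
  expect_equal(nrow(rdp_simplify(v, 2)), 2L)
  expect_equal(nrow(rdp_simplify(v, 0.5)), 3L)

  jag <- tibble::tibble(x = c(0, 1, 2, 3, 4), y = c(0, 2, -1, 3, 0))
  expect_equal(as.data.frame(rdp_simplify(jag, 0)), as.data.frame(jag))
})

test_that("RDP agrees with the plain recursive oracle on random paths", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:15, 1)
    xy <- cbind(cumsum(rnorm(n)), cumsum(rnorm(n)))
    eps <- runif(1, 0.1, 2)
    got <- rdp_simplify(tibble::tibble(x = xy[, 1], y = xy[, 2]), eps)
    want <- rdp_oracle(xy, eps)
    expect_equal(cbind(got$x, got$y), unname(want))
  }
})

test_that("RDP output shrinks with epsilon and stays within tolerance", {
  set.seed(32)
  xy <- tibble::tibble(x = cumsum(rnorm(60)), y = cumsum(rnorm(60)))
  prev <- nrow(xy)
  for (eps in c(0.2, 0.5, 1, 3)) {
    s <- rdp_simplify(xy, eps)
    expect_lte(nrow(s), prev)
    prev <- nrow(s)
    # every original point lies within eps of the simplified polyline
    dmax <- 0
    for (k in seq_len(nrow(xy))) {
      dk <- min(vapply(seq_len(nrow(s) - 1L), function(j) {
        mousetrackr:::point_segment_distance(xy$x[k], xy$y[k],
                                             s$x[j], s$y[j],
                                             s$x[j + 1], s$y[j + 1])
      }, numeric(1)))
      dmax <- max(dmax, dk)
    }
    expect_lte(dmax, eps + 1e-9)
    # simplification cannot lengthen the path
    expect_lte(sum(sqrt(diff(s$x)^2 + diff(s$y)^2)),
               sum(sqrt(diff(xy$x)^2 + diff(xy$y)^2)) + 1e-9)
  }
})

test_that("kinematics recover closed-form speed and acceleration", {
  still <- tibble::tibble(t = 0:9 / 10, x = rep(5, 10), y = rep(7, 10))
  k0 <- kinematics(still, 10)
  expect_equal(k0$summary$total_distance_cm, 0)
  expect_equal(k0$summary$mean_speed_cms, 0)

  # 5 px/frame at 10 fps with 10 px/cm -> 0.5 cm every 0.1 s = 5 cm/s
  f <- 0:19
  uni <- tibble::tibble(t = f / 10, x = 5 * f, y = 0)
  k1 <- kinematics(uni, 10)
  expect_equal(unique(round(k1$steps$speed_cms, 10)), 5)
  expect_equal(k1$summary$mean_speed_cms, 5)
  expect_equal(k1$summary$mean_accel_cms2, 0)
  expect_equal(k1$summary$total_distance_cm, sum(k1$steps$dist_cm))
})

test_that("turn angles classify sharp and wide events and skip straights", {
  straight <- tibble::tibble(x = 0:10, y = rep(0, 11))
  ta <- turn_angles(straight, 90)
  expect_equal(length(ta$angles), 0L)

  corner <- tibble::tibble(x = c(0, 1, 1), y = c(0, 0, 1))
  tc <- turn_angles(corner, 90)
  expect_equal(tc$angles, 90)
  expect_equal(tc$n_wide, 1L)       # exactly 90 degrees counts as wide
  expect_equal(tc$n_sharp, 0L)

  square <- tibble::tibble(x = c(0, 1, 1, 0, 0, 1), y = c(0, 0, 1, 1, 0, 0))
  ts <- turn_angles(square, 90)
  expect_equal(ts$angles, rep(90, 4))

  # sharp + wide partitions all turning events at any threshold
  set.seed(41)
  wig <- tibble::tibble(x = cumsum(rnorm(40)), y = cumsum(rnorm(40)))
  for (thr in c(30, 45, 90, 120)) {
    tw <- turn_angles(wig, thr)
    expect_equal(tw$n_sharp + tw$n_wide, length(tw$angles))
  }
})

test_that("centre occupancy uses the half-size central rectangle", {
  w <- 400; h <- 200; fps <- 10
  centre <- tibble::tibble(t = 0:9 / fps, x = rep(w / 2, 10), y = rep(h / 2, 10))
  expect_equal(time_in_center(centre, w, h, fps), 1)
  wall <- tibble::tibble(t = 0:9 / fps, x = rep(5, 10), y = rep(5, 10))
  expect_equal(time_in_center(wall, w, h, fps), 0)
  # half the samples inside -> half the span
  half <- tibble::tibble(t = 0:9 / fps,
                         x = rep(c(w / 2, 5), 5), y = rep(h / 2, 10))
  expect_equal(time_in_center(half, w, h, fps), 0.5)
})

test_that("interaction episodes follow run-length structure of overlaps", {
  # overlap pattern T T F T at 1 fps -> 2 episodes, 3 s total, mean 1.5 s
  mk <- function(tag, xs) {
    tibble::tibble(frame = 0:3, time = 0:3, sort_id = ifelse(tag == "a", 1L, 2L),
                   tag = tag,
                   x_min = xs, y_min = 0, x_max = xs + 10, y_max = 10,
                   cx = xs + 5, cy = 5, coasted = FALSE)
  }
  a <- mk("a", rep(0, 4))
  b <- mk("b", c(5, 5, 100, 5))
  itc <- itc_episodes(dplyr::bind_rows(a, b), area_factor = 1.25, fps = 1)
  expect_equal(nrow(itc$episodes), 2L)
  expect_equal(sum(itc$episodes$duration), 3)
  expect_equal(itc$pair_totals$mean_duration, 1.5)

  # disjoint animals -> nothing
  far <- mk("b", rep(500, 4))
  itc0 <- itc_episodes(dplyr::bind_rows(a, far), 1.25, 1)
  expect_equal(nrow(itc0$episodes), 0L)

  # boxes 1 px apart only touch after 25% enlargement
  near <- mk("b", rep(11, 4))   # gap 1 px; enlargement adds ~0.59 px per side
  itc1 <- itc_episodes(dplyr::bind_rows(a, near), 1.25, 1)
  expect_equal(nrow(itc1$episodes), 1L)
  itc1b <- itc_episodes(dplyr::bind_rows(a, near), 1.0, 1)
  expect_equal(nrow(itc1b$episodes), 0L)
})

test_that("per-animal session metrics aggregate all measures", {
  sim <- simulate_session(sim_preset("homecage", "none"), seed = 15,
                          n_mice = 3, duration_s = 30)
  tr <- track_sort(sim$detections, sim$clock, sim$config)
  res <- suppressMessages(match_rfid(tr, sim$reads, sim$clock, sim$config))
  m <- session_metrics(res$tracked, sim$config)
  expect_equal(sort(m$tag), sort(unique(stats::na.omit(res$tracked$tag))))
  expect_true(all(m$total_distance_cm >= 0))
  expect_true(all(m$n_sharp_turns >= 0))
})
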