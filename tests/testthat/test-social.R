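mk_seg <- function(t, x, y) tibble::tibble(t = t, x = x, y = y)

test_that("segmentation drops trailing fragments and keeps window alignment", {
  traj <- mk_seg(seq(0, 30, by = 0.2), 1:151, 0)
  s30 <- segment_trajectory(traj, 5)
  expect_equal(sort(unique(s30$segment)), 0:5)          # 6 full windows

  s4 <- segment_trajectory(mk_seg(seq(0, 4, by = 0.2), 1:21, 0), 5)
  expect_equal(nrow(s4), 0L)                            # shorter than window

  s12 <- segment_trajectory(mk_seg(seq(0, 12, by = 0.5), 1:25, 0), 5)
  expect_equal(sort(unique(s12$segment)), 0:1)
  expect_lt(max(s12$t[s12$segment == 0]), 5)
})

test_that("pair eligibility needs displacement from both and similar lengths", {
  px_per_cm <- 10
  run <- mk_seg(0:10, seq(0, 100, by = 10), 0)          # 10 cm displacement
  loop <- mk_seg(0:10, c(rep(c(0, 5), 5), 0), 0)        # ends where it began
  expect_false(pair_eligible(loop, loop, px_per_cm))
  expect_false(pair_eligible(run, loop, px_per_cm))     # resting partner fails

  # path lengths 100 and 130 satisfy the 35% bound; 100 and 140 do not
  len <- function(L) mk_seg(0:10, seq(0, L, length.out = 11), 0)
  expect_true(pair_eligible(len(100), len(130), px_per_cm))
  expect_false(pair_eligible(len(100), len(140), px_per_cm))
  # symmetry
  expect_equal(pair_eligible(len(130), len(100), px_per_cm),
               pair_eligible(len(100), len(130), px_per_cm))
})

test_that("z-normalisation is translation and scale invariant", {
  set.seed(51)
  xy <- cbind(cumsum(rnorm(20)), cumsum(rnorm(20)))
  z <- znorm(xy)
  expect_equal(colMeans(z), c(0, 0))
  expect_equal(apply(z, 2, sd), c(1, 1))
  expect_equal(znorm(xy + 100), z)
  expect_equal(znorm(xy * 7), z)
  # zero-variance axis maps to zeros
  flat <- cbind(1:10, rep(3, 10))
  expect_true(all(znorm(flat)[, 2] == 0))
})

test_that("DTW distance matches its defining examples and the brute-force oracle", {
  set.seed(52)
  x <- cbind(cumsum(rnorm(6)), cumsum(rnorm(6)))
  expect_identical(dtw_distance(x, x), 0)
  expect_equal(dtw_distance(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  for (rep in 1:15) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    a <- cbind(rnorm(n), rnorm(n))
    b <- cbind(rnorm(m), rnorm(m))
    expect_equal(dtw_distance(a, b), dtw_oracle(a, b))
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
  }
})

test_that("spatial proximity is the symmetrised mean minimal distance", {
  a <- mk_seg(0:9, 0:9, 0)
  expect_equal(spatial_proximity(a, a), 0)
  b <- mk_seg(0:9, 0:9, 7)                              # parallel, offset 7
  expect_equal(spatial_proximity(a, b), 7)
  expect_equal(spatial_proximity(b, a), spatial_proximity(a, b))
})

test_that("pair scoring pipeline filters, scores and stratifies", {
  # two animals on a shared clock: parallel active motion with some noise
  set.seed(53)
  n <- 301                                              # 20 s at 15 fps
  t <- (0:(n - 1)) / 15
  xa <- 100 + cumsum(runif(n, 5, 9)); ya <- 300 + cumsum(rnorm(n, 0, 2))
  xb <- 100 + cumsum(runif(n, 5, 9)); yb <- 500 + cumsum(rnorm(n, 0, 2))
  mk_tr <- function(id, tag, x, y) {
    tibble::tibble(frame = 0:(n - 1), time = t, sort_id = id, tag = tag,
                   x_min = x - 25, y_min = y - 15, x_max = x + 25,
                   y_max = y + 15, cx = x, cy = y, coasted = FALSE)
  }
  tk <- dplyr::bind_rows(mk_tr(1L, "a", xa, ya), mk_tr(2L, "b", xb, yb))
  cfg <- test_config()
  ps <- score_segment_pairs(tk, cfg)
  expect_equal(nrow(ps), 4L)                            # 4 full 5-s windows
  expect_true(all(ps$dtw_score >= 0))
  expect_true(all(ps$class == ifelse(ps$sp <= 300, "proximal", "distal")))

  ts <- trial_summary(ps)
  expect_equal(ts$mean_dtw, mean(ps$dtw_score))
  # hand-listed mean for three pairs
  expect_equal(trial_summary(ps[1:3, ])$mean_dtw, mean(ps$dtw_score[1:3]))
  if (all(ps$class == "distal")) expect_true(is.na(ts$mean_dtw_proximal))

  # a third identified animal is rejected
  tk3 <- dplyr::bind_rows(tk, mk_tr(3L, "c", xb, yb + 100))
  expect_error(score_segment_pairs(tk3, cfg), "exactly 2")
})

test_that("translation of one raw segment moves SP but not the DTW score", {
  set.seed(54)
  n <- 40
  x <- cumsum(runif(n, 2, 6)); y <- cumsum(rnorm(n))
  a <- mk_seg(seq_len(n), x, y)
  b <- mk_seg(seq_len(n), x, y + 50)
  za <- znorm(cbind(a$x, a$y)); zb <- znorm(cbind(b$x, b$y))
  expect_equal(dtw_distance(za, zb), 0)                 # same shape
  # the raw offset survives in SP (bounded by the 50 px translation)
  sp <- spatial_proximity(a, b)
  expect_gt(sp, 0)
  expect_lte(sp, 50)
})
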