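test_that("the same seed reproduces a session exactly", {
  s1 <- simulate_session(sim_preset("homecage", "noisy"), seed = 19,
                         n_mice = 3, duration_s = 20)
  s2 <- simulate_session(sim_preset("homecage", "noisy"), seed = 19,
                         n_mice = 3, duration_s = 20)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_session(sim_preset("homecage", "noisy"), seed = 20,
                         n_mice = 3, duration_s = 20)
  expect_false(identical(s1$detections, s3$detections))
})

test_that("an empty cage yields a valid empty session", {
  s <- simulate_session(sim_preset("homecage", "none"), seed = 1,
                        n_mice = 0, duration_s = 5)
  expect_equal(nrow(s$detections), 0L)
  expect_equal(nrow(s$truth), 0L)
  expect_equal(nrow(s$reads), 0L)
  expect_equal(nrow(s$clock), 75L)
})

test_that("ground truth is continuous and boxes stay inside the arena", {
  p <- sim_preset("homecage", "none")
  s <- simulate_session(p, seed = 21, n_mice = 3, duration_s = 30)
  ppc <- s$config$arena$px_per_cm
  # per-frame displacement bounded by a generous speed bound plus the
  # solid-body repulsion adjustment
  max_step <- (p$speed_mean_cms + 6 * p$speed_sd_cms) * ppc / p$fps +
    p$min_separation_cm * ppc
  for (tg in unique(s$truth$tag)) {
    tt <- s$truth[s$truth$tag == tg, ]
    d <- sqrt(diff(tt$cx)^2 + diff(tt$cy)^2)
    expect_lte(max(d), max_step)
  }
  expect_true(all(s$truth$x_min >= -1e-9))
  expect_true(all(s$truth$x_max <= s$config$arena$width_px + 1e-9))
  # exactly n_mice boxes per frame
  expect_true(all(table(s$truth$frame) == 3))
})

test_that("mice never overlap beyond the solid-body limit", {
  p <- sim_preset("homecage", "none")
  s <- simulate_session(p, seed = 22, n_mice = 4, duration_s = 20)
  ppc <- s$config$arena$px_per_cm
  min_sep <- p$min_separation_cm * ppc
  by_f <- split(seq_len(nrow(s$truth)), s$truth$frame)
  viol <- 0
  for (rows in by_f) {
    P <- cbind(s$truth$cx[rows], s$truth$cy[rows])
    if (min(stats::dist(P)) < min_sep - 1e-6) viol <- viol + 1
  }
  # the two-iteration relaxation resolves almost every contact exactly
  # (wall clamping after a push can leave a small residue)
  expect_lte(viol, length(by_f) * 0.05)
})

test_that("every read is emitted by a mouse inside the reader's range", {
  p <- sim_preset("homecage", "noisy")
  s <- simulate_session(p, seed = 23, n_mice = 3, duration_s = 60)
  ppc <- s$config$arena$px_per_cm
  radius <- p$read_radius_cm * ppc
  rd <- s$read_truth
  expect_gt(nrow(rd), 0)
  for (k in seq_len(nrow(rd))) {
    fr <- round(rd$time[k] * p$fps)
    m <- s$truth[s$truth$frame == fr & s$truth$tag == rd$tag[k], ]
    z <- s$config$readers[s$config$readers$reader_id == rd$reader_id[k], ]
    d <- sqrt((m$cx - (z$x_min + z$x_max) / 2)^2 +
                (m$cy - (z$y_min + z$y_max) / 2)^2)
    expect_lte(d, radius + 1e-6)
  }
})

test_that("reader refractory period spaces reads on each reader", {
  p <- sim_preset("homecage", "none")
  s <- simulate_session(p, seed = 24, n_mice = 2, duration_s = 60)
  for (r in unique(s$reads$reader_id)) {
    t <- sort(s$reads$time[s$reads$reader_id == r])
    if (length(t) > 1) expect_gte(min(diff(t)), p$read_refractory_s - 1e-9)
  }
})

test_that("infeasible reader layouts are refused", {
  p <- sim_preset("homecage", "none")
  p$min_spacing_cm <- 30                     # impossible in a 29x19 cage grid
  expect_error(simulate_session(p, seed = 1, duration_s = 5),
               "infeasible reader layout")
})

test_that("noise controls produce the configured artefacts", {
  clean <- simulate_session(sim_preset("homecage", "none"), seed = 25,
                            n_mice = 2, duration_s = 30)
  expect_equal(nrow(clean$detections), 2 * nrow(clean$clock))
  noisy <- simulate_session(sim_preset("homecage", "noisy"), seed = 25,
                            n_mice = 2, duration_s = 30,
                            fp_rate_per_min = 60, dropout_prob = 0.2)
  per_frame <- table(factor(noisy$detections$frame,
                            levels = clean$clock$frame))
  expect_gt(sum(per_frame > 2), 0)           # spurious boxes appear
  expect_gt(sum(per_frame < 2), 0)           # dropouts appear
})

test_that("session files round-trip through the io layer", {
  dir <- withr::local_tempdir()
  sim <- simulate_session(sim_preset("homecage", "noisy"), seed = 26,
                          n_mice = 2, duration_s = 10)
  paths <- write_session(sim, dir)
  ses <- read_session(paths["detections"], paths["clock"], paths["rfid"],
                      paths[["config"]])
  expect_equal(nrow(ses$detections), nrow(sim$detections))
  expect_equal(ses$clock$time, sim$clock$time)
  expect_equal(ses$reads$tag, sim$reads$tag)
  expect_equal(ses$config$tracker$iou_match_threshold,
               sim$config$tracker$iou_match_threshold)
})

test_that("rendering is deterministic and sized by the scale factor", {
  sim <- simulate_session(sim_preset("homecage", "none"), seed = 27,
                          n_mice = 1, duration_s = 2, fps = 5)
  st1 <- render_frames(sim, scale = 0.1)
  st2 <- render_frames(sim, scale = 0.1)
  expect_identical(st1, st2)
  expect_equal(dim(st1)[3], 10L)
  expect_equal(dim(st1)[1:2],
               round(c(sim$config$arena$height_px,
                       sim$config$arena$width_px) * 0.1))
})
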