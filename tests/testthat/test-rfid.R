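# helper: a ready-made two-track session on a 1000x1000 px arena.
# Track A sits near the reader at (150, 150); track B far away, except in
# scenarios that bring them together.
two_track_session <- function(n = 200, bA = c(120, 120, 180, 180),
                              bB = c(700, 700, 760, 760)) {
  mk <- function(b, vx = 0) {
    f <- 0:(n - 1L)
    tibble::tibble(frame = f, x_min = b[1] + vx * f, y_min = b[2],
                   x_max = b[3] + vx * f, y_max = b[4], confidence = 1)
  }
  d <- dplyr::arrange(dplyr::bind_rows(mk(bA), mk(bB)), frame)
  cfg <- test_config(readers = one_zone(150, 150))
  clock <- make_clock(n)
  list(tracked = track_sort(d, clock, cfg), clock = clock, cfg = cfg)
}

test_that("reader range test combines centroid distance and zone overlap", {
  zone <- one_zone(100, 100, half = 20, radius = 50)
  expect_true(in_range(c(80, 80, 120, 120), zone))      # centred on zone
  expect_false(in_range(c(500, 500, 560, 560), zone))   # far, no overlap
  # centroid outside the radius but a corner overlaps the zone rectangle:
  # the IOU arm of the disjunction must catch it
  box <- c(115, 115, 215, 215)   # centroid (165,165), distance ~92 > 50
  expect_gt(sqrt(2) * 65, zone$range_radius)
  expect_true(in_range(box, zone))
  pure_centroid <- sqrt(sum((bbox_centroid(box) - c(100, 100))^2)) <= 50
  expect_false(pure_centroid)                           # disjunction matters
})

test_that("scenario 1 tags the full track history, past and future", {
  s <- two_track_session()
  reads <- tibble::tibble(time = 150 / 15, reader_id = 0L, tag = "m1")
  res <- match_rfid(s$tracked, reads, s$clock, s$cfg)
  idA <- s$tracked$sort_id[s$tracked$frame == 0 & s$tracked$x_min == 120]
  tagged <- res$tracked[res$tracked$sort_id == idA, ]
  expect_true(all(tagged$tag == "m1"))                  # all 200 frames
  other <- res$tracked[res$tracked$sort_id != idA, ]
  expect_true(all(is.na(other$tag)))
  expect_equal(res$audit$scenario, "1")
})

test_that("scenario 2 (already matched) and scenario 3 (ambiguous) are no-ops", {
  # scenario 2: second read of the same tag changes nothing
  s <- two_track_session()
  reads <- tibble::tibble(time = c(5, 9), reader_id = 0L, tag = "m1")
  res <- match_rfid(s$tracked, reads, s$clock, s$cfg)
  expect_equal(res$audit$scenario, c("1", "2"))

  # scenario 3: both tracks in range of the reader -> table untouched
  s2 <- two_track_session(bB = c(130, 60, 190, 120))    # B also near reader
  reads3 <- tibble::tibble(time = 5, reader_id = 0L, tag = "m1")
  res3 <- match_rfid(s2$tracked, reads3, s2$clock, s2$cfg)
  expect_equal(res3$audit$scenario, "3")
  expect_true(all(is.na(res3$tracked$tag)))
})

test_that("scenario 4 corrects up to the most recent proximity event only", {
  n <- 200
  # B passes through A's neighbourhood around frame 80, then A sits on the
  # reader; a later read of a different tag must correct frames > 80 only
  f <- 0:(n - 1L)
  yB <- 150 + 20 * abs(f - 80)                           # dips to A at f=80
  dA <- tibble::tibble(frame = f, x_min = 120, y_min = 120, x_max = 180,
                       y_max = 180, confidence = 1)
  dB <- tibble::tibble(frame = f, x_min = 620, y_min = yB, x_max = 680,
                       y_max = yB + 60, confidence = 1)
  d <- dplyr::arrange(dplyr::bind_rows(dA, dB), frame)
  cfg <- test_config(readers = one_zone(150, 150))
  cfg$matcher$proximity_dist_px <- 600                  # wide: flags f ~ 80
  clock <- make_clock(n)
  tracked <- track_sort(d, clock, cfg)
  idA <- tracked$sort_id[tracked$frame == 0 & tracked$x_min == 120]

  prox <- mousetrackr:::proximity_frames(tracked, cfg$matcher$proximity_iou,
                                         cfg$matcher$proximity_dist_px)
  boundary <- max(prox[[as.character(idA)]])
  expect_equal(
    find_correction_boundary(tracked, idA, 120,
                             cfg$matcher$proximity_iou,
                             cfg$matcher$proximity_dist_px),
    boundary)

  reads <- tibble::tibble(time = c(10, 120) / 15, reader_id = 0L,
                          tag = c("mWRONG", "mRIGHT"))
  res <- match_rfid(tracked, reads, clock, cfg)
  expect_equal(res$audit$scenario, c("1", "4"))
  a <- res$tracked[res$tracked$sort_id == idA, ]
  a <- a[order(a$frame), ]
  expect_true(all(a$tag[a$frame > boundary] == "mRIGHT"))
  expect_true(all(a$tag[a$frame <= boundary] == "mWRONG"))
})

test_that("correction boundary falls back to birth and takes the latest contact", {
  s <- two_track_session()
  idA <- s$tracked$sort_id[1]
  # never in proximity: birth frame
  expect_equal(find_correction_boundary(s$tracked, idA, 100, 0.3, 60), 0L)

  # two contacts at ~40 and ~80 (oracle: linear scan over frames)
  n <- 150
  f <- 0:(n - 1L)
  # B shares A's x band and approaches A's y twice, at frames 40 and 80
  yB <- 720 - pmax(0, pmax(600 - 50 * abs(f - 40), 600 - 50 * abs(f - 80)))
  dA <- tibble::tibble(frame = f, x_min = 120, y_min = 120, x_max = 180,
                       y_max = 180, confidence = 1)
  dB <- tibble::tibble(frame = f, x_min = 120, y_min = yB, x_max = 180,
                       y_max = yB + 60, confidence = 1)
  d <- dplyr::arrange(dplyr::bind_rows(dA, dB), frame)
  cfg <- test_config(readers = one_zone(150, 150))
  tracked <- track_sort(d, make_clock(n), cfg)
  idA <- tracked$sort_id[tracked$frame == 0 & tracked$y_min == 120]
  # linear-scan oracle over per-frame proximity
  dist_thr <- cfg$matcher$proximity_dist_px
  scan <- vapply(f, function(fr) {
    rows <- tracked[tracked$frame == fr, ]
    a <- rows[rows$sort_id == idA, ]
    others <- rows[rows$sort_id != idA, ]
    if (nrow(a) != 1 || nrow(others) == 0) return(FALSE)
    any(vapply(seq_len(nrow(others)), function(i) {
      dd <- sqrt((a$cx - others$cx[i])^2 + (a$cy - others$cy[i])^2)
      iou <- bbox_iou(
        as.numeric(a[, c("x_min", "y_min", "x_max", "y_max")]),
        as.numeric(others[i, c("x_min", "y_min", "x_max", "y_max")]))
      iou > cfg$matcher$proximity_iou || dd < dist_thr
    }, logical(1)))
  }, logical(1))
  oracle <- max(f[scan & f <= 120])
  expect_equal(
    find_correction_boundary(tracked, idA, 120, cfg$matcher$proximity_iou,
                             dist_thr),
    oracle)
})

test_that("the audit log replays to the final identity table", {
  sim <- simulate_session(sim_preset("homecage", "noisy"), seed = 12,
                          n_mice = 3, duration_s = 60)
  tr <- track_sort(sim$detections, sim$clock, sim$config)
  res <- suppressMessages(match_rfid(tr, sim$reads, sim$clock, sim$config))
  replayed <- replay_audit(tr, res$audit)
  expect_identical(replayed$tag, res$tracked$tag)
})

test_that("tags form a partial injection on every frame", {
  sim <- simulate_session(sim_preset("homecage", "noisy"), seed = 13,
                          n_mice = 4, duration_s = 60)
  tr <- track_sort(sim$detections, sim$clock, sim$config)
  res <- suppressMessages(match_rfid(tr, sim$reads, sim$clock, sim$config))
  tk <- res$tracked[!is.na(res$tracked$tag), ]
  expect_equal(anyDuplicated(tk[, c("frame", "tag")]), 0L)
})

test_that("reads with no matching frame are discarded with a warning", {
  s <- two_track_session(n = 30)
  reads <- tibble::tibble(time = c(1, 500), reader_id = 0L, tag = "m1")
  expect_warning(res <- match_rfid(s$tracked, reads, s$clock, s$cfg),
                 "discarded")
  expect_equal(res$audit$scenario, c("1", "discarded"))
})

test_that("home-cage mode suppresses cage reads near the entrance", {
  n <- 60
  # one track parked right next to the entrance zone, also in range of the
  # cage reader
  d <- linear_detections(n, x0 = 120, y0 = 120, vx = 0, w = 60, h = 60)
  readers <- dplyr::bind_rows(one_zone(150, 150, id = 0L),
                              one_zone(210, 150, id = 1L))
  cfg <- test_config(readers = readers,
                     entrance_reader_id = 1L,
                     entrance_stop_distance_px = 100)
  clock <- make_clock(n)
  tracked <- track_sort(d, clock, cfg)
  cage_read <- tibble::tibble(time = 1, reader_id = 0L, tag = "m1")
  res <- match_rfid(tracked, cage_read, clock, cfg)
  expect_equal(res$audit$scenario, "suppressed_entrance")
  expect_true(all(is.na(res$tracked$tag)))
  # the entrance reader itself still matches
  ent_read <- tibble::tibble(time = 1, reader_id = 1L, tag = "m1")
  res2 <- match_rfid(tracked, ent_read, clock, cfg)
  expect_equal(res2$audit$scenario, "1")
  expect_true(all(res2$tracked$tag == "m1"))
  # the parked track's last centroid is outside the entrance rectangle, so
  # it is not reported as closed (the animal did not enter the housing)
  expect_equal(length(res2$closed_tracks), 0L)
})

test_that("consistent extra reads never hurt coverage or identity", {
  sim <- simulate_session(sim_preset("homecage", "none"), seed = 14,
                          n_mice = 2, duration_s = 60)
  tr <- track_sort(sim$detections, sim$clock, sim$config)
  half <- sim$reads[seq_len(floor(nrow(sim$reads) / 2)), ]
  r1 <- suppressMessages(match_rfid(tr, half, sim$clock, sim$config))
  r2 <- suppressMessages(match_rfid(tr, sim$reads, sim$clock, sim$config))
  e1 <- evaluate_tracking(r1$tracked, sim$truth, sim$clock)
  e2 <- evaluate_tracking(r2$tracked, sim$truth, sim$clock)
  expect_gte(e2$coverage, e1$coverage)
  expect_lte(e2$n_wrong, e1$n_wrong)
})
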