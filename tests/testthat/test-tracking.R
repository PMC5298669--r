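test_that("heading confirmation accepts aligned pairs and rejects reversals", {
  pairs_of <- function(m) hungarian_assign(m)
  a <- pairs_of(matrix(c(0, 9, 9, 0), 2))

  same <- list(c(1, 0), c(0, 1))
  hc <- heading_check(a, same, same, tolerance = 0)
  expect_equal(nrow(hc$accepted), 2)

  anti <- list(c(-1, 0), c(0, -1))
  hc2 <- heading_check(a, same, anti, tolerance = pi / 2)
  expect_equal(nrow(hc2$accepted), 0)
  expect_equal(nrow(hc2$rejected), 2)

  # unavailable headings are confirmatory-only: pair accepted
  hc3 <- heading_check(a, list(NULL, c(1, 0)), list(c(1, 0), c(-1, 0)),
                       tolerance = pi / 2)
  expect_equal(sort(hc3$accepted$worker), 1)
  expect_equal(hc3$rejected$worker, 2)
})

test_that("a lone tracker keeps its identity through a trivial step", {
  tr <- posed_tracker(3, c(50, 50), vel = c(2, 0), heading = c(1, 0))
  det <- tibble::tibble(x = 52, y = 50, heading_dx = 1, heading_dy = 0,
                        heading_valid = TRUE)
  st <- track_step(list(tr), det, track_config())
  expect_length(st$trackers, 1)
  expect_equal(st$trackers[[1]]$id, 3L)
  expect_true(st$trackers[[1]]$matched)
  expect_equal(st$trackers[[1]]$state[1:2], c(52, 50), tolerance = 0.5)

  # empty detections: the tracker coasts and ages
  st2 <- track_step(list(tr), NULL, track_config())
  expect_false(st2$trackers[[1]]$matched)
  expect_equal(st2$trackers[[1]]$missed, 1L)
  expect_equal(st2$trackers[[1]]$state[1:2], c(52, 50))  # prediction

  # unmatched detections spawn identities with zero velocity
  st3 <- track_step(list(), det, track_config())
  expect_length(st3$trackers, 1)
  expect_equal(st3$trackers[[1]]$state[3:4], c(0, 0))
  expect_equal(st3$next_id, 2L)
})

test_that("the five-fly crossing narrative resolves through the heading gate", {
  # three obvious pairs far away, plus a problematic pair: flies 4 and 5
  # approach head-on, then both double back; prediction overshoots so the
  # optimal-by-distance pairing is the swap
  cfg <- track_config()
  trackers <- list(
    posed_tracker(1, c(50, 200), heading = c(0, 1)),
    posed_tracker(2, c(100, 200), heading = c(0, 1)),
    posed_tracker(3, c(150, 200), heading = c(0, 1)),
    posed_tracker(4, c(0, 0), vel = c(10, 0), heading = c(1, 0)),
    posed_tracker(5, c(14, 0), vel = c(-10, 0), heading = c(-1, 0)))
  dets <- tibble::tibble(
    x = c(50, 100, 150, -6, 20), y = c(200, 200, 200, 0, 0),
    heading_dx = c(0, 0, 0, 1, -1), heading_dy = c(1, 1, 1, 0, 0),
    heading_valid = TRUE)

  # ablation first: Hungarian-only pairs (4, e) and (5, d)
  st_abl <- track_step(trackers, dets,
                       track_config(use_heading_gate = FALSE))
  pos_abl <- vapply(st_abl$trackers, function(t) t$state[1], numeric(1))
  expect_gt(pos_abl[4], pos_abl[5])  # tracker 4 went to the east detection

  # full tracker: heading check rejects the swap, closest-neighbor on the
  # pre-prediction states restores (4, d) and (5, e)
  st <- track_step(trackers, dets, cfg)
  expect_true(all(vapply(st$trackers, function(t) t$matched, logical(1))))
  pos <- t(vapply(st$trackers, function(t) t$state[1:2], numeric(2)))
  expect_lt(abs(pos[1, 1] - 50) + abs(pos[2, 1] - 100) + abs(pos[3, 1] - 150),
            1)
  expect_lt(pos[4, 1], pos[5, 1])
  expect_lt(abs(pos[4, 1] - (-6)), 6)   # pulled toward d
  expect_lt(abs(pos[5, 1] - 20), 6)     # pulled toward e
  expect_length(st$trackers, 5)
})

test_that("the heading gate prevents the anti-parallel retreat swap", {
  gated <- run_antiparallel(use_gate = TRUE)
  ablated <- run_antiparallel(use_gate = FALSE)
  expect_equal(unname(gated), c(1, 2))     # identities preserved
  expect_equal(unname(ablated), c(2, 1))   # Hungarian-only swaps them
})

test_that("trackers retire after max_missed frames and ids never repeat", {
  cfg <- track_config(max_missed = 3)
  det <- tibble::tibble(x = 10, y = 10, heading_dx = NA_real_,
                        heading_dy = NA_real_, heading_valid = FALSE)
  st <- track_step(list(), det, cfg)
  for (k in 1:4) st <- track_step(st$trackers, NULL, cfg, st$next_id)
  expect_length(st$trackers, 0)
  # a new detection later gets a fresh id
  st2 <- track_step(st$trackers, det, cfg, st$next_id)
  expect_equal(st2$trackers[[1]]$id, 2L)
})

test_that("track_all folds steps into sorted per-frame trajectories", {
  # single static fly: one identity, velocity decaying to zero
  dets <- dplyr::bind_rows(lapply(1:40, function(f)
    tibble::tibble(frame = f, x = 100 + rnorm(1, 0, 0.1), y = 100,
                   heading_dx = 1, heading_dy = 0, heading_valid = TRUE)))
  set.seed(55)
  trk <- track_all(dets, track_config(fps = 20))
  tr <- tidy(trk)
  expect_equal(unique(tr$id), 1L)
  expect_equal(nrow(tr), 40)
  expect_true(!is.unsorted(tr$frame))
  late <- tr[tr$frame > 30, ]
  expect_lt(max(abs(late$vx)), 2)  # px/s, essentially static
  g <- glance(trk)
  expect_equal(g$n_identities, 1L)
  expect_equal(g$dt, 0.05)

  # a missing frame makes trackers coast, not die
  gap <- dets[dets$frame != 20, ]
  trg <- track_all(gap, track_config(fps = 20))
  tg <- tidy(trg)
  expect_false(tg$matched[tg$frame == 20])
  expect_equal(unique(tg$id), 1L)
})

test_that("live identities label at most one detection per frame", {
  spec <- scene_spec(n_flies = 6, n_frames = 40, rng_seed = 31)
  sv <- synth_video(spec)
  dets <- detect_all(sv$stack)
  trk <- track_all(dets, track_config(fps = spec$fps))
  tr <- tidy(trk)
  dup <- dplyr::count(tr, .data$frame, .data$id)
  expect_true(all(dup$n == 1))
})

test_that("two coasting trackers share an unsplittable merged detection", {
  cfg <- track_config()
  trackers <- list(
    posed_tracker(1, c(100, 100), vel = c(1, 0), heading = c(1, 0)),
    posed_tracker(2, c(110, 100), vel = c(-1, 0), heading = c(-1, 0)),
    posed_tracker(3, c(200, 200), vel = c(0, 0), heading = c(0, 1)),
    posed_tracker(4, c(40, 40), vel = c(0, 0), heading = c(0, 1)))
  # one oversized blob at the pair's midpoint plus two normal blobs
  dets <- tibble::tibble(
    x = c(105, 200, 40), y = c(100, 200, 40),
    heading_dx = c(NA, 0, 0), heading_dy = c(NA, 1, 1),
    heading_valid = c(FALSE, TRUE, TRUE),
    area = c(230L, 110L, 112L), a = c(28, 16, 16), b = c(6, 6, 6))
  st <- track_step(trackers, dets, cfg)
  expect_length(st$trackers, 4)          # no births from the merged blob
  expect_equal(st$next_id, 5L)
  m <- vapply(st$trackers, function(t) t$matched, logical(1))
  expect_equal(m, c(FALSE, FALSE, TRUE, TRUE))
  # shared trackers coast without aging their missed counters
  missed <- vapply(st$trackers, function(t) t$missed, integer(1))
  expect_equal(missed[1:2], c(0L, 0L))
})
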