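test_that("EPM matches the mean-vector magnitude", {
  # radially symmetric unit flows -> exactly 0
  expect_equal(effective_propagation(rep(1, 4),
                                     c(0, pi / 2, pi, 3 * pi / 2)),
               0, tolerance = 1e-12)
  # aligned unit flows -> 1
  expect_equal(effective_propagation(rep(1, 7), rep(0, 7)), 1)
  # two unit flows at 0 and 90 degrees
  expect_equal(effective_propagation(c(1, 1), c(0, pi / 2)),
               sqrt(0.5), tolerance = 1e-12)
  # oracle: naive mean-vector magnitude on 1000 random flow sets
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(1:20, 1)
    mag <- runif(n, 0, 5)
    ang <- runif(n, -pi, pi)
    naive <- sqrt(sum(mag * cos(ang) / n)^2 + sum(mag * sin(ang) / n)^2)
    expect_equal(effective_propagation(mag, ang), naive, tolerance = 1e-12)
  }
  expect_true(is.na(effective_propagation(numeric(0), numeric(0))))
})

test_that("EPM never exceeds the mean flow magnitude", {
  set.seed(12)
  for (i in 1:200) {
    mag <- runif(8, 0, 3); ang <- runif(8, -pi, pi)
    expect_lte(effective_propagation(mag, ang), mean(mag) + 1e-12)
  }
})

mk_flow <- function(grid, ang, mag = 1) {
  # uniform flow field with given orientation (in spherical mm/frame)
  list(vx = matrix(mag * cos(ang), grid$n_rows, grid$n_cols),
       vy = matrix(mag * sin(ang), grid$n_rows, grid$n_cols))
}

test_that("OBBox extraction drops pop-up components and splits by direction", {
  m <- toy_montage()
  grid <- pixel_grid(16, 32)
  bw <- matrix(0, 16, 32); bw[6:9, 10:14] <- 1
  # radial (pop-up) flows around the blob centre
  rows <- matrix(seq_len(16), 16, 32)
  cols <- matrix(seq_len(32), 16, 32, byrow = TRUE)
  vy <- (7.5 - rows); vx <- (cols - 12)
  nrm <- sqrt(vx^2 + vy^2); nrm[nrm == 0] <- 1
  pop <- list(vx = vx / nrm, vy = vy / nrm)
  expect_equal(nrow(make_obboxes(bw, pop, thr2 = 0.6, grid = grid,
                                 montage = m)), 0)
  # coherent translation -> a single OBBox in bin 0
  ob <- make_obboxes(bw, mk_flow(grid, 0, 1.5), thr2 = 0.6, grid = grid,
                     montage = m)
  expect_equal(nrow(ob), 1)
  expect_equal(ob$bin, 0L)
  # bimodal flows with equal mass in opposite bins -> two OBBoxes
  vx <- matrix(0, 16, 32); vx[, 1:12] <- 1; vx[, 13:32] <- -1
  bim <- list(vx = vx, vy = matrix(0, 16, 32))
  ob2 <- make_obboxes(bw, bim, thr2 = 0, grid = grid, montage = m)
  expect_setequal(ob2$bin, c(0L, 4L))
})

chain_boxes <- function(n_frames, bin = 0, speed = 3, phi0 = 0.3,
                        dphi = 0.005) {
  tibble::tibble(frame = seq_len(n_frames), bin = bin,
                 phi = phi0 + dphi * seq_len(n_frames), theta = 0.3,
                 speed_mm_min = speed, epm = 0.9, n_flows = 10L)
}

test_that("spatiotemporal scoring rewards consistent chains and gates speed", {
  m <- toy_montage()
  # lone box: no neighbours -> score 0
  lone <- score_obboxes(chain_boxes(1), m)
  expect_equal(lone$score, 0)
  # chain over 4 min (8 frames, 30 s apart): interior boxes score > 0
  ch <- chain_boxes(9)
  sc <- score_obboxes(ch, m, thr3_min = 2, thr4 = 0.5)
  expect_gt(sc$score[5], 0)
  # brute-force neighbour count for the middle box
  d <- great_circle_mm(m, cbind(ch$phi[5], ch$theta[5]),
                       cbind(ch$phi, ch$theta))
  expected <- sum(abs(ch$frame - 5) <= 4 & seq_len(9) != 5 & d <= 70)
  expect_equal(sc$score[5], expected)
  # out-of-range propagation speed -> removed entirely
  fast <- chain_boxes(9, speed = 12)
  expect_equal(nrow(score_obboxes(fast, m)), 0)
  slow <- chain_boxes(9, speed = 0.2)
  expect_equal(nrow(score_obboxes(slow, m)), 0)
})

test_that("temporal-consistency fraction below Thr4 zeroes the score", {
  m <- toy_montage()
  # boxes only on every third frame: 3 of 9 window frames contribute
  ch <- chain_boxes(15)[c(1, 4, 7, 10, 13), ]
  sc <- score_obboxes(ch, m, thr3_min = 2, thr4 = 0.69)
  expect_true(all(sc$score == 0))
  sc2 <- score_obboxes(ch, m, thr3_min = 2, thr4 = 0.2)
  expect_gt(max(sc2$score), 0)
})

test_that("stitching merges nearby frames and splits distant ones", {
  times <- seq(0, by = 30, length.out = 40)
  # no surviving boxes -> all-zero trace
  none <- stitch_detections(chain_boxes(0)[0, ], times)
  expect_true(all(none$trace$detected == 0))
  mk <- function(frames) {
    tibble::tibble(frame = frames, bin = 0L, phi = 0.3, theta = 0.3,
                   speed_mm_min = 3, epm = 0.9, n_flows = 10L,
                   score = 5)
  }
  # two selected frames 90 s apart -> one merged run
  one <- stitch_detections(mk(c(10, 13)), times)
  expect_equal(nrow(one$runs), 1)
  expect_true(all(one$trace$detected[10:13] == 1))
  # 10 min apart -> two runs
  two <- stitch_detections(mk(c(5, 25)), times)
  expect_equal(nrow(two$runs), 2)
})

test_that("raising Thr2 or Thr4 never adds detected frames", {
  set.seed(13)
  m <- toy_montage()
  grid <- pixel_grid(16, 32)
  # random box population with mixed coherence
  boxes <- tibble::tibble(
    frame = sample(1:40, 120, replace = TRUE),
    bin = sample(0:7, 120, replace = TRUE, prob = c(4, 2, 1, 1, 1, 1, 1, 1)),
    phi = runif(120, 0, 0.6), theta = runif(120, 0.2, 0.5),
    speed_mm_min = runif(120, 0.3, 10), epm = runif(120, 0.3, 1),
    n_flows = 5L)
  times <- seq(0, by = 30, length.out = 40)
  detected_at <- function(thr2, thr4) {
    b <- boxes[boxes$epm >= thr2, ]
    sc <- score_obboxes(b, m, thr4 = thr4)
    which(stitch_detections(sc, times)$trace$detected == 1)
  }
  base <- detected_at(0.3, 0.3)
  expect_true(all(detected_at(0.6, 0.3) %in% base))
  expect_true(all(detected_at(0.3, 0.6) %in% base))
})
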