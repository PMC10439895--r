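test_that("projection assigns electrode values and the median elsewhere", {
  m <- toy_montage()
  grid <- pixel_grid()
  # all electrodes zero -> uniform zero image
  dep0 <- ipsi_series(matrix(0, 11, 2))
  t0 <- project_frames(dep0, m, grid, dhc_side = "right")
  expect_true(all(t0$frames == 0))
  expect_equal(t0$n_active, c(11L, 11L))
  # one electrode at 1, ten at 0 -> its pixel 1, elsewhere median 0
  v <- matrix(0, 11, 1); v[1, 1] <- 1
  t1 <- project_frames(ipsi_series(v), m, grid, dhc_side = "right")
  px <- electrode_to_pixel(m, grid, "Fp2")
  expect_equal(t1$frames[px[1, 1], px[1, 2], 1], 1)
  expect_equal(sum(t1$frames[, , 1]), 1)
  # masked channels are excluded and counted out
  valid <- matrix(TRUE, 11, 1); valid[1:6, 1] <- FALSE
  t2 <- project_frames(ipsi_series(matrix(1, 11, 1), valid = valid),
                       m, grid, dhc_side = "right")
  expect_equal(t2$n_active, 5L)
})

test_that("Gaussian interpolation preserves constants, shape and mass", {
  m <- toy_montage()
  grid <- pixel_grid()
  dep <- ipsi_series(matrix(1, 11, 1))
  tp <- project_frames(dep, m, grid, dhc_side = "right")
  sm <- interpolate_frames(tp, m)
  expect_equal(sm$frames[, , 1], matrix(1, 32, 64), tolerance = 1e-9)

  # single hot pixel decays like a Gaussian along the row axis
  tp2 <- project_frames(ipsi_series(matrix(0, 11, 1)), m, grid,
                        dhc_side = "right")
  tp2$frames[16, 32, 1] <- 1
  sigma_mm <- 26.2
  sm2 <- interpolate_frames(tp2, m, sigma_mm = sigma_mm)
  s_col <- sigma_mm / (m$head_radius_mm * grid$dphi)
  off <- round(s_col)
  ratio <- sm2$frames[16, 32 + off, 1] / sm2$frames[16, 32, 1]
  expect_equal(ratio, exp(-off^2 / (2 * s_col^2)), tolerance = 0.05)
  # mass of a blob well inside the image is preserved (median pad is 0);
  # use a kernel whose 3-sigma support stays interior
  tp3 <- project_frames(ipsi_series(matrix(0, 11, 1)), m, grid,
                        dhc_side = "right")
  tp3$frames[16, 32, 1] <- 1
  sm3 <- interpolate_frames(tp3, m, sigma_mm = 7)
  expect_equal(sum(sm3$frames[, , 1]), 1, tolerance = 0.01)
})

test_that("three-stage thresholding follows the median/max rule", {
  m <- toy_montage()
  grid <- pixel_grid(16, 32)
  mk <- function(img, n_active = 11) {
    structure(list(frames = array(img, c(nrow(img), ncol(img), 1)),
                   times = 0, n_active = n_active, rejected = FALSE,
                   grid = grid, frame_dt = 30,
                   electrode_px = cbind(1, 1), labels = "Cz",
                   stage = "smooth"),
              class = "sd_topo")
  }
  # constant frame: H = M -> everything at or below threshold -> all zero
  expect_true(all(threshold_frames(mk(matrix(5, 16, 32)))$frames == 0))
  # blob on 10% of pixels survives with n_active = 11
  img <- matrix(0, 16, 32); img[6:9, 10:22] <- 1   # ~10%
  bw <- threshold_frames(mk(img), thr1 = 0.3)
  expect_equal(sum(bw$frames[, , 1]), sum(img))
  # fewer than 5 active electrodes -> frame rejected
  bw4 <- threshold_frames(mk(img, n_active = 4), thr1 = 0.3)
  expect_true(all(bw4$frames == 0))
  expect_true(bw4$rejected[1])
  # the half-cover safety rule: because thresholding is strictly above the
  # whole-image median, a surviving frame can never have more than half its
  # pixels set (random frames confirm the invariant)
  set.seed(21)
  for (i in 1:20) {
    bwr <- threshold_frames(mk(matrix(rnorm(16 * 32), 16, 32)),
                            thr1 = runif(1, 0, 0.5))
    expect_lte(sum(bwr$frames), 16 * 32 / 2)
  }
})

test_that("pixel sets shrink as Thr1 rises and ignore constant offsets", {
  set.seed(10)
  m <- toy_montage()
  grid <- pixel_grid(16, 32)
  img <- matrix(rnorm(16 * 32), 16, 32)
  mk <- function(img) {
    structure(list(frames = array(img, c(16, 32, 1)), times = 0,
                   n_active = 11, rejected = FALSE, grid = grid,
                   frame_dt = 30, electrode_px = cbind(1, 1),
                   labels = "Cz", stage = "smooth"),
              class = "sd_topo")
  }
  sets <- lapply(c(0.2, 0.4, 0.6), function(th) {
    which(threshold_frames(mk(img), thr1 = th)$frames[, , 1] == 1)
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  shifted <- threshold_frames(mk(img + 17.3), thr1 = 0.4)$frames
  expect_equal(shifted, threshold_frames(mk(img), thr1 = 0.4)$frames)
})
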