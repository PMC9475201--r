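test_that("background model is the per-pixel median ignoring dropouts", {
  fr <- matrix(700L, 10, 10)
  bg <- build_background(list(fr, fr, fr))
  expect_equal(bg$depth_mm, matrix(700, 10, 10))
  expect_true(all(bg$valid_mask))

  # one pixel invalid in every frame -> masked
  fr0 <- fr; fr0[3, 4] <- 0L
  bg <- build_background(list(fr0, fr0, fr0))
  expect_false(bg$valid_mask[3, 4])
  expect_equal(bg$depth_mm[3, 4], 0)

  # median over {500,500,500,900,900} is 500
  mk <- function(v) { f <- matrix(700L, 4, 4); f[2, 2] <- v; f }
  bg <- build_background(lapply(c(500L, 500L, 500L, 900L, 900L), mk))
  expect_equal(bg$depth_mm[2, 2], 500)

  expect_error(build_background(list()), "at least one")
})

test_that("a frame identical to the background yields an invalid point", {
  g <- test_geometry()
  bg <- flat_background(1000L)
  pt <- segment_foreground(matrix(1000L, 60, 80), bg, g)
  expect_false(pt$valid)
  expect_equal(pt$blob_px, 0L)
})

test_that("only the largest component above min_blob_px is used", {
  g <- test_geometry()
  bg <- flat_background(1000L)
  big <- list(rows = 20:39, cols = 30:49, depth = 700L)   # 400 px
  small <- list(rows = 5:9, cols = 5:12, depth = 700L)    # 40 px
  both <- segment_foreground(blob_frame(blobs = list(big, small)), bg, g,
                             min_blob_px = 100)
  only_big <- segment_foreground(blob_frame(blobs = list(big)), bg, g,
                                 min_blob_px = 100)
  expect_true(both$valid)
  expect_equal(both$blob_px, 400L)
  expect_identical(both[c("x_cm", "y_cm", "z_cm")],
                   only_big[c("x_cm", "y_cm", "z_cm")])

  # largest component below min_blob_px -> invalid, size reported
  sub <- segment_foreground(blob_frame(blobs = list(small)), bg, g,
                            min_blob_px = 100)
  expect_false(sub$valid)
  expect_equal(sub$blob_px, 40L)
})

test_that("segmentation is 8-connected", {
  g <- test_geometry()
  bg <- flat_background(1000L)
  # two 5x5 squares touching only at a corner: one 50-px component
  fr <- blob_frame(blobs = list(list(rows = 10:14, cols = 10:14,
                                     depth = 700L),
                                list(rows = 15:19, cols = 15:19,
                                     depth = 700L)))
  pt <- segment_foreground(fr, bg, g, min_blob_px = 40)
  expect_true(pt$valid)
  expect_equal(pt$blob_px, 50L)
})

test_that("shifting the blob shifts the centroid by the same pixels", {
  g <- test_geometry()
  bg <- flat_background(1000L)
  k <- 7
  a <- segment_foreground(blob_frame(blobs = list(
    list(rows = 20:29, cols = 30:39, depth = 700L))), bg, g)
  b <- segment_foreground(blob_frame(blobs = list(
    list(rows = 20:29, cols = (30 + k):(39 + k), depth = 700L))), bg, g)
  # k pixels at the blob depth correspond to k * Z / f mm laterally
  Z <- a$y_cm * 10 + g$camera_distance_mm
  expect_equal(b$x_cm - a$x_cm, k * Z / g$focal_px / 10, tolerance = 1e-6)
  expect_equal(b$z_cm, a$z_cm, tolerance = 1e-9)
  expect_equal(b$y_cm, a$y_cm, tolerance = 1e-9)
})

test_that("noiseless rendered blob is recovered near the true centre", {
  g <- test_geometry()
  pos <- c(20, 25, 35)
  tr <- make_traj(x = pos[1], y = pos[2], z = pos[3])
  rec <- render_depth_recording(tr, g, animal_radius_mm = 40)
  bgm <- build_background(list(marmobehav:::cage_background_depth(g)))
  # the reduced-resolution test geometry projects the body to ~50 px
  pt <- segment_foreground(rec$frames[[1]], bgm, g, min_blob_px = 25)
  expect_true(pt$valid)
  err <- sqrt((pt$x_cm - pos[1])^2 + (pt$y_cm - pos[2])^2 +
                (pt$z_cm - pos[3])^2)
  expect_lt(err, 1)   # within max(one back-projected pixel, 1 cm)
})

test_that("linking is the identity for fully valid input", {
  pts <- data.frame(time_s = (0:9) * 0.2, x_cm = 1:10, y_cm = rep(2, 10),
                    z_cm = rep(3, 10), valid = TRUE)
  out <- link_trajectory(pts)
  expect_equal(out$x_cm, pts$x_cm)
  expect_true(all(out$valid))
})

test_that("short gaps are linearly interpolated, long gaps left invalid", {
  pts <- data.frame(time_s = c(0, 0.2, 0.4, 0.6), x_cm = c(0, NA, NA, 9),
                    y_cm = c(0, NA, NA, 0), z_cm = c(5, NA, NA, 5),
                    valid = c(TRUE, FALSE, FALSE, TRUE))
  out <- link_trajectory(pts, max_gap_frames = 3)
  expect_true(all(out$valid))
  expect_equal(out$x_cm, c(0, 3, 6, 9))

  # gap longer than max_gap_frames stays invalid
  out2 <- link_trajectory(pts, max_gap_frames = 1)
  expect_equal(out2$valid, c(TRUE, FALSE, FALSE, TRUE))

  # interpolation never extrapolates beyond flanking valid points
  lead <- data.frame(time_s = (0:3) * 0.2, x_cm = c(NA, NA, 1, 2),
                     y_cm = 0, z_cm = 0,
                     valid = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(link_trajectory(lead)$valid, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("teleporting detections are invalidated by the step guard", {
  pts <- data.frame(time_s = (0:4) * 0.2,
                    x_cm = c(10, 10, 110, 10, 10),
                    y_cm = 20, z_cm = 10, valid = TRUE)
  out <- link_trajectory(pts, max_step_cm = 50, max_gap_frames = 0)
  expect_equal(out$valid, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # without the guard the point survives
  out2 <- link_trajectory(pts, max_step_cm = 1000)
  expect_true(all(out2$valid))
})

test_that("linking never loses valid points except via the step guard", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 40
    pts <- data.frame(time_s = (0:(n - 1)) * 0.2,
                      x_cm = cumsum(rnorm(n, 0, 2)),
                      y_cm = cumsum(rnorm(n, 0, 2)),
                      z_cm = cumsum(rnorm(n, 0, 1)),
                      valid = runif(n) > 0.3)
    out <- link_trajectory(pts, max_step_cm = 1e6)
    expect_gte(sum(out$valid), sum(pts$valid))
  }
})

test_that("end-to-end tracking recovers a noisy rendered session", {
  g <- test_geometry()
  s <- simulate_session(behavior_params(seed = 51), g, duration_s = 60,
                        fps = 5)
  tr <- track_session(s, g, noise_sd_mm = 10, dropout_rate = 0.05,
                      seed = 52, min_blob_px = 25)
  gt <- s$trajectory
  ok <- tr$valid
  expect_gt(mean(ok), 0.95)
  rms <- sqrt(mean(((tr$x_cm - gt$x_cm)^2 + (tr$y_cm - gt$y_cm)^2 +
                      (tr$z_cm - gt$z_cm)^2)[ok]))
  expect_lt(rms, 2)
})
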