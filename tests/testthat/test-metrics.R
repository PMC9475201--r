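test_that("speed series arithmetic on hand-built trajectories", {
  # one 30 cm vertical step over 0.2 s
  tr <- make_traj(x = c(10, 10), z = c(0, 30))
  sp <- compute_speeds(tr)
  expect_equal(sp$speed_cm_s, 150)
  expect_equal(sp$vz_cm_s, 150)
  expect_true(sp$moving)

  # stationary: all speeds zero, never moving
  tr <- make_traj(x = rep(5, 10))
  sp <- compute_speeds(tr)
  expect_equal(sp$speed_cm_s, rep(0, 9))
  expect_false(any(sp$moving))
})

test_that("only adjacent valid pairs produce speed entries", {
  valid <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  tr <- make_traj(x = 1:6, valid = valid)
  sp <- compute_speeds(tr)
  expect_equal(nrow(sp), 1)           # only the (3,4) pair is adjacent-valid
  expect_equal(sp$time_s, 0.6)
  tr2 <- make_traj(x = 1:6, valid = rep(c(TRUE, FALSE), 3))
  expect_warning(sp2 <- compute_speeds(make_traj(x = 1:2,
                                                 valid = c(TRUE, FALSE))),
                 "fewer than 2")
  expect_equal(nrow(sp2), 0)
  expect_equal(nrow(compute_speeds(tr2)), 0)
})

test_that("straight-walk session metrics match closed forms", {
  tr <- straight_walk(step_cm = 10, n_steps = 20)   # 50 cm/s at 5 fps
  m <- session_metrics(tr)
  expect_equal(m$distance_cm, 200)
  expect_equal(m$median_moving_speed_cm_s, 50)
  expect_equal(m$activity_time_s, 4.0)
  expect_equal(m$jump_climb_frames, 0L)
})

test_that("jump/climb counting is strict, upward-only by default", {
  sp <- compute_speeds(vz_traj(c(150, 100, -150)))
  expect_equal(sp$vz_cm_s, c(150, 100, -150))
  m_up <- session_metrics(vz_traj(c(150, 100, -150)))
  expect_equal(m_up$jump_climb_frames, 1L)
  m_abs <- session_metrics(vz_traj(c(150, 100, -150)),
                           metrics_config(vz_mode = "abs"))
  expect_equal(m_abs$jump_climb_frames, 2L)

  # threshold behavior at peaks 119 / 120 / 121 (strictly above 120)
  counts <- vapply(c(119, 120, 121), function(pk)
    session_metrics(vz_traj(c(pk, -pk)))$jump_climb_frames, integer(1))
  expect_equal(counts, c(0L, 0L, 1L))
  counts_abs <- vapply(c(119, 120, 121), function(pk)
    session_metrics(vz_traj(c(pk, -pk)),
                    metrics_config(vz_mode = "abs"))$jump_climb_frames,
    integer(1))
  expect_equal(counts_abs, c(0L, 0L, 2L))
})

test_that("median moving speed cannot fall below the movement threshold", {
  set.seed(31)
  x <- cumsum(rnorm(200, 0, 0.4))
  m <- session_metrics(make_traj(x = x))
  if (!is.na(m$median_moving_speed_cm_s))
    expect_gt(m$median_moving_speed_cm_s, 2)
})

test_that("distance is rotation-invariant; jumps ignore horizontal motion", {
  set.seed(32)
  n <- 100
  x <- 15 + cumsum(rnorm(n, 0, 1)); y <- 20 + cumsum(rnorm(n, 0, 1))
  z <- 20 + cumsum(rnorm(n, 0, 0.5))
  tr <- make_traj(x = x, y = y, z = z)
  th <- 0.7
  cx <- 17; cy <- 25
  xr <- cx + cos(th) * (x - cx) - sin(th) * (y - cy)
  yr <- cy + sin(th) * (x - cx) + cos(th) * (y - cy)
  trr <- make_traj(x = xr, y = yr, z = z)
  expect_equal(session_metrics(trr)$distance_cm,
               session_metrics(tr)$distance_cm, tolerance = 1e-10)
  # adding fast horizontal drift leaves the jump count unchanged
  jumps0 <- session_metrics(tr)$jump_climb_frames
  tr_fast <- make_traj(x = x + 30 * seq_len(n), y = y, z = z)
  expect_equal(session_metrics(tr_fast)$jump_climb_frames, jumps0)
})

test_that("splitting a session loses at most the one bridging step", {
  set.seed(33)
  n <- 120
  tr <- make_traj(x = cumsum(rnorm(n, 0, 2)), y = cumsum(rnorm(n, 0, 2)))
  full <- session_metrics(tr)$distance_cm
  half1 <- session_metrics(make_traj(x = tr$x_cm[1:60], y = tr$y_cm[1:60]))
  half2 <- session_metrics(make_traj(x = tr$x_cm[61:n], y = tr$y_cm[61:n]))
  gap <- sqrt((tr$x_cm[61] - tr$x_cm[60])^2 + (tr$y_cm[61] - tr$y_cm[60])^2)
  expect_equal(half1$distance_cm + half2$distance_cm + gap, full,
               tolerance = 1e-10)
})

test_that("occupancy grid counts and coverage behave", {
  # all points in one cell
  m <- trajectory_occupancy_map(make_traj(x = rep(2.5, 50)), cell_cm = 5)
  expect_equal(sum(m$counts), 50)
  expect_equal(sum(m$counts > 0), 1)
  expect_equal(m$range_fraction_visited, 1 / length(m$counts))

  # nested uniform samples: coverage grows with point count
  set.seed(34)
  dims <- cage_dim_cm(cage_geometry())
  x <- runif(1000, 0, dims[1]); y <- runif(1000, 0, dims[2])
  z <- runif(1000, 0, dims[3])
  cov_n <- vapply(c(50, 200, 1000), function(k)
    trajectory_occupancy_map(make_traj(x = x[1:k], y = y[1:k], z = z[1:k]),
                             cell_cm = 5)$range_fraction_visited,
    numeric(1))
  expect_true(all(diff(cov_n) > 0))

  # total counts = number of valid points only
  v <- rep(c(TRUE, FALSE), 25)
  mo <- trajectory_occupancy_map(make_traj(x = runif(50, 0, 30), valid = v))
  expect_equal(sum(mo$counts), 25)
})

test_that("restricted post-stroke range shows as reduced coverage", {
  g <- cage_geometry()
  healthy <- simulate_session(behavior_params(range_fraction = 1, seed = 41),
                              g, duration_s = 600, fps = 5)
  restricted <- simulate_session(behavior_params(range_fraction = 0.2,
                                                 seed = 41),
                                 g, duration_s = 600, fps = 5)
  ch <- session_metrics(healthy$trajectory)$range_fraction_visited
  cr <- session_metrics(restricted$trajectory)$range_fraction_visited
  expect_lt(cr, ch)
})

test_that("parameter recovery: measured speed ratio tracks the deficit", {
  g <- cage_geometry()
  base <- behavior_params(seed = 61)
  d <- 0.5
  deficit <- behavior_params(speed_scale_cm_s = base$speed_scale_cm_s *
                               (1 - d), seed = 62)
  pre <- session_metrics(simulate_session(base, g, 3600, 5)$trajectory)
  post <- session_metrics(simulate_session(deficit, g, 3600, 5)$trajectory)
  ratio <- post$median_moving_speed_cm_s / pre$median_moving_speed_cm_s
  expect_lt(abs(ratio - (1 - d)), 0.1)
})
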