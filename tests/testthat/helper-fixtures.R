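# shared fixtures: hand-constructed trajectories and flat-background frames

# trajectory from coordinate vectors at the nominal 5 fps
make_traj <- function(x, y = rep(20, length(x)), z = rep(10, length(x)),
                      valid = rep(TRUE, length(x)), dt = 0.2, day = 0L,
                      animal = "t") {
  trajectory((seq_along(x) - 1) * dt, x, y, z, valid = valid,
             animal_id = animal, session_day = day, nominal_dt_s = dt)
}

# straight walk along x: step_cm per frame, n_steps intervals
straight_walk <- function(step_cm = 10, n_steps = 20, dt = 0.2) {
  make_traj(x = seq(0, by = step_cm, length.out = n_steps + 1), dt = dt)
}

# trajectory whose vertical velocity sequence is exactly vz (cm/s);
# x, y held fixed so all speed comes from z
vz_traj <- function(vz, dt = 0.2, z0 = 10) {
  make_traj(x = rep(10, length(vz) + 1), z = z0 + c(0, cumsum(vz * dt)),
            dt = dt)
}

# flat constant-depth background model over an h x w frame
flat_background <- function(depth = 1000L, h = 60, w = 80) {
  build_background(list(matrix(as.integer(depth), h, w)))
}

# frame = flat background with rectangular blobs at given depth
blob_frame <- function(bg_depth = 1000L, h = 60, w = 80, blobs = list()) {
  fr <- matrix(as.integer(bg_depth), h, w)
  for (b in blobs) fr[b$rows, b$cols] <- as.integer(b$depth)
  fr
}

# small geometry for fast render tests (still >= 1e4 pixels per frame)
test_geometry <- function() cage_geometry(depth_image_shape = c(120L, 160L),
                                          focal_px = 74)

# independent midrank + Pearson brute-force Spearman (sum formulas only)
brute_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (u in unique(v)) r[v == u] <- mean(which(sort(v) == u))
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# closed-form paired t oracle
brute_paired_t <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}
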