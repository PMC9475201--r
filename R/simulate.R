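#' Simulate one recording session of marmoset-like behavior
#'
#' Generates a ground-truth trajectory for one animal-session. A two-state
#' (rest/locomote) Markov chain with per-frame transition probabilities
#' drives horizontal motion: while locomoting the heading performs a random
#' walk and the per-frame speed is drawn from a gamma distribution
#' (shape 4) with mean `speed_scale_cm_s`; at rest the animal does not move.
#' Jump/climb events are scheduled as a Poisson process at
#' `jump_rate_per_min` and superimpose a symmetric rise-and-fall triangular
#' vertical excursion of 0.6 s whose rise and fall rates equal
#' `jump_peak_speed_cm_s`. A small vertical wander (2 cm/s SD) accompanies
#' locomotion so the animal explores the cage height. Positions are
#' reflected to stay inside `range_fraction` of the cage volume, inset from
#' every wall by `wall_margin_cm` (the body centre cannot reach a wall).
#'
#' Identical `seed` and parameters give identical output.
#'
#' @param params A [behavior_params()].
#' @param geometry A [cage_geometry()].
#' @param duration_s Session duration (s), > 0.
#' @param fps Frame rate (Hz), > 0; the nominal sensor rate is 5.
#' @param day_index Integer study day stored on the trajectory
#'   (negative = preoperative).
#' @param animal_id Animal identifier stored on the trajectory.
#' @param seed RNG seed; defaults to `params$seed`. `NULL` uses the current
#'   RNG stream.
#' @param wall_margin_cm Minimal distance of the body centre from any cage
#'   wall (cm); defaults to a typical marmoset body radius.
#' @return An object of class `ground_truth_session`: a list with elements
#'   `trajectory` (all frames valid), `params_used`, `day_index`,
#'   `n_jump_events` and `jump_event_times_s`.
#' @export
simulate_session <- function(params, geometry = cage_geometry(),
                             duration_s = 600, fps = 5, day_index = 0L,
                             animal_id = "sim", seed = params$seed,
                             wall_margin_cm = 4) {
  validate_behavior_params(params)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("simulate_session: 'duration_s' must be > 0", call. = FALSE)
  if (!is.numeric(fps) || fps <= 0)
    stop("simulate_session: 'fps' must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n <- floor(duration_s * fps)
  dt <- 1 / fps
  time_s <- (seq_len(n) - 1) * dt

  moving <- simulate_states(n, params$p_rest_to_move, params$p_move_to_rest)
  nm <- sum(moving)

  # horizontal motion: random-walk heading, gamma speeds while locomoting
  dtheta <- numeric(n); dtheta[moving] <- stats::rnorm(nm, 0, 0.6)
  theta <- stats::runif(1, 0, 2 * pi) + cumsum(dtheta)
  v <- numeric(n)
  if (nm > 0 && params$speed_scale_cm_s > 0)
    v[moving] <- stats::rgamma(nm, shape = 4,
                               rate = 4 / params$speed_scale_cm_s)
  dx <- v * dt * cos(theta)
  dy <- v * dt * sin(theta)
  dz <- numeric(n); dz[moving] <- stats::rnorm(nm, 0, 2 * dt)

  # Poisson jump/climb events: 0.6 s triangular z excursion at the peak rate
  lam <- params$jump_rate_per_min * duration_s / 60
  n_events <- if (lam > 0) stats::rpois(1, lam) else 0L
  ev_t <- if (n_events > 0)
    sort(stats::runif(n_events, 0, max(duration_s - 0.6, 0))) else numeric(0)
  jz <- numeric(n)
  for (t0 in ev_t) {
    i <- which(time_s >= t0 & time_s <= t0 + 0.6)
    u <- time_s[i] - t0
    jz[i] <- jz[i] +
      params$jump_peak_speed_cm_s * pmin(u, 0.6 - u)
  }

  # allowed box: range_fraction of the wall-inset cage volume
  dims <- cage_dim_cm(geometry)
  m <- wall_margin_cm
  s <- params$range_fraction^(1 / 3)
  half_x <- s * max(dims[1] - 2 * m, 0) / 2
  half_y <- s * max(dims[2] - 2 * m, 0) / 2
  z_lo <- m
  z_hi <- m + s * max(dims[3] - 2 * m, 0)

  x <- fold_into(dims[1] / 2 + cumsum(dx), dims[1] / 2 - half_x,
                 dims[1] / 2 + half_x)
  y <- fold_into(dims[2] / 2 + cumsum(dy), dims[2] / 2 - half_y,
                 dims[2] / 2 + half_y)
  z <- fold_into(z_lo + cumsum(dz) + jz, z_lo, z_hi)

  traj <- trajectory(time_s, x, y, z, valid = rep(TRUE, n),
                     animal_id = animal_id, session_day = day_index,
                     nominal_dt_s = dt)
  out <- list(trajectory = traj, params_used = params,
              day_index = as.integer(day_index),
              n_jump_events = n_events, jump_event_times_s = ev_t)
  class(out) <- "ground_truth_session"
  out
}

#' @export
print.ground_truth_session <- function(x, ...) {
  cat(sprintf("<ground_truth_session> day %d, %d frames, %d jump events\n",
              x$day_index, nrow(x$trajectory), x$n_jump_events))
  invisible(x)
}

# Alternating geometric rest/locomote bouts; start state is rest.
# p == 0 makes a state absorbing.
simulate_states <- function(n, p_rest_to_move, p_move_to_rest) {
  moving <- logical(n)
  i <- 1L
  state_moving <- FALSE
  while (i <= n) {
    p <- if (state_moving) p_move_to_rest else p_rest_to_move
    len <- if (p <= 0) n else if (p >= 1) 1L else stats::rgeom(1, p) + 1L
    j <- min(i + len - 1L, n)
    moving[i:j] <- state_moving
    i <- j + 1L
    state_moving <- !state_moving
  }
  moving
}

#' Simulate daily 4-sign neurological score records
#'
#' Generates observational score records whose expected total decays from the
#' maximum of 4 at `onset_day` back toward 0: each of the four signs is
#' present independently with probability `exp(-(day - onset_day) / tau_days)`
#' (1 at onset, so the onset-day score is 4), and preoperative days score 0.
#'
#' @param animal_ids Character vector of animals.
#' @param days Integer vector of study days (negative = preoperative).
#' @param onset_day Day of maximal deficit.
#' @param tau_days Score recovery time constant (days).
#' @param side Scored body side, default the affected (right) side.
#' @param seed RNG seed (`NULL` = current stream).
#' @return A data frame with columns
#'   `animal, day, side, slip, dangle, midline, uncoordinated` (0/1 flags).
#' @export
simulate_scores <- function(animal_ids, days, onset_day = 2L, tau_days = 9,
                            side = "right", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(animal = animal_ids, day = as.integer(days),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$animal, grid$day), , drop = FALSE]
  p <- ifelse(grid$day < onset_day, 0,
              exp(-(grid$day - onset_day) / tau_days))
  flags <- matrix(stats::rbinom(4 * nrow(grid), 1, rep(p, 4)),
                  ncol = 4)
  out <- data.frame(animal = grid$animal, day = grid$day, side = side,
                    slip = flags[, 1], dangle = flags[, 2],
                    midline = flags[, 3], uncoordinated = flags[, 4],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
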