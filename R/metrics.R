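#' Configuration for the per-session behavioral metrics
#'
#' @param movement_threshold_cm_s Frame-to-frame speed above which the
#'   animal counts as moving (cm/s). Separates sensor jitter from
#'   locomotion; "speed" and "activity time" are defined over moving frames
#'   only.
#' @param jump_threshold_cm_s Vertical speed above which a frame counts as a
#'   jump/climb (cm/s); the field convention is 120.
#' @param vz_mode `"up"` counts only upward vertical motion (strictly
#'   `vz > threshold`); `"abs"` counts `|vz| > threshold`.
#' @param occupancy_cell_cm Edge length of the cubic occupancy cells (cm).
#' @param fps Nominal frame rate (Hz); speeds always use actual timestamp
#'   differences, this is only carried as metadata.
#' @return An object of class `metrics_config`.
#' @export
metrics_config <- function(movement_threshold_cm_s = 2,
                           jump_threshold_cm_s = 120,
                           vz_mode = c("up", "abs"),
                           occupancy_cell_cm = 5, fps = 5) {
  vz_mode <- match.arg(vz_mode)
  if (movement_threshold_cm_s <= 0 || jump_threshold_cm_s <= 0 ||
      occupancy_cell_cm <= 0 || fps <= 0)
    stop("metrics_config: thresholds must be > 0", call. = FALSE)
  structure(list(movement_threshold_cm_s = movement_threshold_cm_s,
                 jump_threshold_cm_s = jump_threshold_cm_s,
                 vz_mode = vz_mode, occupancy_cell_cm = occupancy_cell_cm,
                 fps = fps),
            class = "metrics_config")
}

#' Frame-to-frame speed series of a trajectory
#'
#' One entry per pair of *adjacent* valid frames: 3D speed (Euclidean
#' displacement over the actual timestamp difference), the signed vertical
#' velocity component, and the moving flag
#' (`speed > movement_threshold_cm_s`). Pairs spanning invalid frames
#' produce no entry. Fewer than two valid points give an empty series with
#' a warning, not an error.
#'
#' @param traj A [trajectory()].
#' @param cfg A [metrics_config()].
#' @return A data frame of class `speed_series` with columns
#'   `time_s` (time of the later frame), `dt_s`, `speed_cm_s`, `vz_cm_s`,
#'   `moving`.
#' @export
compute_speeds <- function(traj, cfg = metrics_config()) {
  stopifnot(is_trajectory(traj))
  empty <- data.frame(time_s = numeric(0), dt_s = numeric(0),
                      speed_cm_s = numeric(0), vz_cm_s = numeric(0),
                      moving = logical(0))
  class(empty) <- c("speed_series", "data.frame")
  if (sum(traj$valid) < 2) {
    warning("compute_speeds: fewer than 2 valid points; empty series",
            call. = FALSE)
    return(empty)
  }
  n <- nrow(traj)
  ok <- traj$valid[-n] & traj$valid[-1]
  if (!any(ok)) return(empty)
  dt <- diff(traj$time_s)[ok]
  dx <- diff(traj$x_cm)[ok]; dy <- diff(traj$y_cm)[ok]
  dz <- diff(traj$z_cm)[ok]
  speed <- sqrt(dx^2 + dy^2 + dz^2) / dt
  out <- data.frame(time_s = traj$time_s[-1][ok], dt_s = dt,
                    speed_cm_s = speed, vz_cm_s = dz / dt,
                    moving = speed > cfg$movement_threshold_cm_s)
  class(out) <- c("speed_series", "data.frame")
  out
}

#' Per-session behavioral metrics
#'
#' The headline daily metrics of depth-camera home-cage monitoring:
#' * `distance_cm` — total path length over adjacent valid frames;
#' * `median_moving_speed_cm_s` — median speed over moving frames (`NA` if
#'   the animal never moved);
#' * `activity_time_s` — summed frame intervals spent moving, also reported
#'   as `activity_fraction` of the recorded time;
#' * `jump_climb_frames` — frames whose vertical speed exceeds the
#'   120 cm/s threshold (strictly; upward only by default, `|vz|` with
#'   `vz_mode = "abs"`);
#' * `range_fraction_visited` — fraction of occupancy cells of the cage the
#'   animal visited.
#'
#' @param traj A [trajectory()].
#' @param cfg A [metrics_config()].
#' @param geometry A [cage_geometry()] fixing the occupancy grid extent.
#' @return An object of class `session_metrics` (list; also carries
#'   `animal_id`, `day` and the occupancy map).
#' @export
session_metrics <- function(traj, cfg = metrics_config(),
                            geometry = cage_geometry()) {
  sp <- compute_speeds(traj, cfg)
  occ <- trajectory_occupancy_map(traj, cell_cm = cfg$occupancy_cell_cm,
                                  geometry = geometry)
  mov <- sp$moving
  vz <- sp$vz_cm_s
  exceed <- if (cfg$vz_mode == "abs") abs(vz) > cfg$jump_threshold_cm_s
            else vz > cfg$jump_threshold_cm_s
  duration <- if (nrow(traj) > 1) diff(range(traj$time_s)) else 0
  out <- list(
    animal_id = attr(traj, "animal_id"),
    day = attr(traj, "session_day"),
    distance_cm = sum(sp$speed_cm_s * sp$dt_s),
    median_moving_speed_cm_s =
      if (any(mov)) stats::median(sp$speed_cm_s[mov]) else NA_real_,
    activity_time_s = sum(sp$dt_s[mov]),
    activity_fraction =
      if (duration > 0) sum(sp$dt_s[mov]) / duration else NA_real_,
    jump_climb_frames = sum(exceed),
    range_fraction_visited = occ$range_fraction_visited,
    n_speed_frames = nrow(sp),
    occupancy = occ)
  class(out) <- "session_metrics"
  out
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<session_metrics> animal %s, day %d\n",
           "  distance %.1f cm | median moving speed %.2f cm/s | ",
           "activity %.1f s\n  jump/climb frames %d | range visited %.3f\n"),
    x$animal_id, x$day, x$distance_cm, x$median_moving_speed_cm_s,
    x$activity_time_s, x$jump_climb_frames, x$range_fraction_visited))
  invisible(x)
}

#' Occupancy map of a trajectory on a cubic cell grid
#'
#' Counts valid trajectory points in cubic cells tiling the cage, plus the
#' 2D projections used for trajectory-range plots (top view: x-y; side
#' view: y-z).
#'
#' @param traj A [trajectory()].
#' @param cell_cm Cell edge length (cm), > 0.
#' @param geometry A [cage_geometry()].
#' @return An object of class `occupancy_map`: list with `counts` (3D
#'   array), `top` and `side` projections, `cell_cm`,
#'   `range_fraction_visited` and `n_points`.
#' @export
trajectory_occupancy_map <- function(traj, cell_cm = 5,
                                     geometry = cage_geometry()) {
  stopifnot(is_trajectory(traj))
  if (!is.numeric(cell_cm) || cell_cm <= 0)
    stop("trajectory_occupancy_map: 'cell_cm' must be > 0", call. = FALSE)
  dims <- cage_dim_cm(geometry)
  nx <- max(1L, ceiling(dims[1] / cell_cm))
  ny <- max(1L, ceiling(dims[2] / cell_cm))
  nz <- max(1L, ceiling(dims[3] / cell_cm))
  counts <- array(0L, dim = c(nx, ny, nz))
  v <- traj[traj$valid, , drop = FALSE]
  if (nrow(v)) {
    ix <- pmin(pmax(floor(v$x_cm / cell_cm) + 1L, 1L), nx)
    iy <- pmin(pmax(floor(v$y_cm / cell_cm) + 1L, 1L), ny)
    iz <- pmin(pmax(floor(v$z_cm / cell_cm) + 1L, 1L), nz)
    t3 <- table(factor(ix, 1:nx), factor(iy, 1:ny), factor(iz, 1:nz))
    counts <- array(as.integer(t3), dim = c(nx, ny, nz))
  }
  out <- list(counts = counts,
              top = apply(counts, c(1, 2), sum),
              side = apply(counts, c(2, 3), sum),
              cell_cm = cell_cm,
              range_fraction_visited = mean(counts > 0L),
              n_points = nrow(v))
  class(out) <- "occupancy_map"
  out
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map> %s cells of %g cm; %.3f visited (%d points)\n",
              paste(dim(x$counts), collapse = " x "), x$cell_cm,
              x$range_fraction_visited, x$n_points))
  invisible(x)
}

# flatten a list of session_metrics into the long table the stats layer uses
metric_names <- c("distance_cm", "median_moving_speed_cm_s",
                  "activity_time_s", "jump_climb_frames",
                  "range_fraction_visited")

#' Collect per-session metrics into a long table
#'
#' @param metrics_list List of [session_metrics()] objects.
#' @return Data frame `animal, day, metric, value` covering the five daily
#'   metrics.
#' @export
metrics_table <- function(metrics_list) {
  do.call(rbind, lapply(metrics_list, function(m) {
    data.frame(animal = m$animal_id, day = m$day, metric = metric_names,
               value = vapply(metric_names, function(f) as.numeric(m[[f]]),
                              numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}
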