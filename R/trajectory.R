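#' Construct a trajectory object
#'
#' A trajectory is the pivot type between tracking and metrics: a time-ordered
#' table of 3D positions (cage frame, cm, `z` vertical) with per-frame
#' validity flags, at a nominal 200 ms frame interval.
#'
#' @param time_s,x_cm,y_cm,z_cm Numeric vectors of equal length.
#' @param valid Logical vector; `FALSE` marks frames with no usable position.
#' @param animal_id Animal identifier.
#' @param session_day Integer study day (negative = preoperative).
#' @param nominal_dt_s Nominal frame interval (s), default 0.2 (5 fps).
#' @return A data frame of class `trajectory` with columns
#'   `time_s, x_cm, y_cm, z_cm, valid`.
#' @export
trajectory <- function(time_s, x_cm, y_cm, z_cm,
                       valid = rep(TRUE, length(time_s)),
                       animal_id = "animal", session_day = 0L,
                       nominal_dt_s = 0.2) {
  n <- length(time_s)
  if (any(c(length(x_cm), length(y_cm), length(z_cm), length(valid)) != n))
    stop("trajectory: all columns must have equal length", call. = FALSE)
  if (n > 1 && any(diff(time_s) <= 0))
    stop("trajectory: 'time_s' must be strictly increasing", call. = FALSE)
  if (!is.numeric(nominal_dt_s) || nominal_dt_s <= 0)
    stop("trajectory: 'nominal_dt_s' must be > 0", call. = FALSE)
  df <- data.frame(time_s = as.numeric(time_s), x_cm = as.numeric(x_cm),
                   y_cm = as.numeric(y_cm), z_cm = as.numeric(z_cm),
                   valid = as.logical(valid))
  attr(df, "animal_id") <- as.character(animal_id)
  attr(df, "session_day") <- as.integer(session_day)
  attr(df, "nominal_dt_s") <- nominal_dt_s
  class(df) <- c("trajectory", "data.frame")
  df
}

is_trajectory <- function(x) inherits(x, "trajectory")

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> animal %s, day %d: %d frames (%.1f%% valid), %.1f s\n",
    attr(x, "animal_id"), attr(x, "session_day"), nrow(x),
    100 * mean(x$valid), if (nrow(x)) diff(range(x$time_s)) else 0))
  invisible(x)
}

#' Plot a trajectory as top and side views
#'
#' Draws the horizontal (x-y) and vertical (y-z) projections of the valid
#' part of a trajectory, the standard view for judging how much of the cage
#' an animal used in a session.
#'
#' @param x A [trajectory()].
#' @param geometry A [cage_geometry()] fixing the cage outline.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.trajectory <- function(x, geometry = cage_geometry(), ...) {
  v <- x[x$valid, , drop = FALSE]
  dims <- cage_dim_cm(geometry)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(v$x_cm, v$y_cm, type = "l", col = "steelblue",
                 xlim = c(0, dims[1]), ylim = c(0, dims[2]),
                 xlab = "x (cm)", ylab = "y (cm)", main = "top view", ...)
  graphics::plot(v$y_cm, v$z_cm, type = "l", col = "steelblue",
                 xlim = c(0, dims[2]), ylim = c(0, dims[3]),
                 xlab = "y (cm)", ylab = "z (cm)", main = "side view", ...)
  invisible(x)
}

# Reflect values into [lo, hi] (elastic boundaries). Folding an unconstrained
# cumulative path equals step-by-step specular reflection.
fold_into <- function(x, lo, hi) {
  L <- hi - lo
  if (L <= 0) return(rep(lo, length(x)))
  y <- (x - lo) %% (2 * L)
  lo + ifelse(y > L, 2 * L - y, y)
}
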