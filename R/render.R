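#' Render a trajectory into a synthetic depth recording
#'
#' Produces what the depth sensor would see: for every trajectory frame, the
#' static empty-cage background depth map plus a spheroidal foreground blob
#' of radius `animal_radius_mm` centred at the animal's 3D position,
#' projected through the pinhole intrinsics. Zero-mean Gaussian depth noise
#' is added to every measured pixel and a `dropout_rate` fraction of pixels
#' is invalidated (depth 0, the sensor convention for missing returns).
#' Pixels whose ray misses the open front face see the front panel at the
#' camera distance.
#'
#' @param session A `ground_truth_session` (or bare [trajectory()]).
#' @param geometry A [cage_geometry()].
#' @param animal_radius_mm Body radius of the rendered spheroid (mm), > 0.
#' @param noise_sd_mm SD of per-pixel Gaussian depth noise (mm).
#' @param dropout_rate Fraction `[0, 1)` of pixels invalidated per frame.
#' @param seed RNG seed (`NULL` = current stream).
#' @return An object of class `depth_recording`: list with `frames` (list of
#'   integer H x W matrices, depth in mm, 0 = invalid), `time_s`, `geometry`
#'   and the render settings.
#' @export
render_depth_recording <- function(session, geometry = cage_geometry(),
                                   animal_radius_mm = 40, noise_sd_mm = 0,
                                   dropout_rate = 0, seed = NULL) {
  traj <- if (inherits(session, "ground_truth_session"))
    session$trajectory else session
  if (!is_trajectory(traj))
    stop("render_depth_recording: need a ground_truth_session or trajectory",
         call. = FALSE)
  check_render_args(animal_radius_mm, dropout_rate)
  if (!is.null(seed)) set.seed(seed)

  bg <- cage_background_depth(geometry)
  n <- nrow(traj)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    frames[[i]] <- render_depth_frame(
      bg, c(traj$x_cm[i], traj$y_cm[i], traj$z_cm[i]), geometry,
      animal_radius_mm = animal_radius_mm, noise_sd_mm = noise_sd_mm,
      dropout_rate = dropout_rate, frame_index = i)
  }
  depth_recording(frames, traj$time_s, geometry,
                  animal_radius_mm = animal_radius_mm,
                  noise_sd_mm = noise_sd_mm, dropout_rate = dropout_rate)
}

depth_recording <- function(frames, time_s, geometry, ...) {
  if (length(frames) != length(time_s))
    stop("depth_recording: frame count must equal timestamp count",
         call. = FALSE)
  if (length(time_s) > 1 && any(diff(time_s) <= 0))
    stop("depth_recording: timestamps must be strictly increasing",
         call. = FALSE)
  rec <- list(frames = frames, time_s = as.numeric(time_s),
              geometry = geometry, render = list(...))
  class(rec) <- "depth_recording"
  rec
}

#' @export
print.depth_recording <- function(x, ...) {
  cat(sprintf("<depth_recording> %d frames of %d x %d px\n",
              length(x$frames), x$geometry$depth_image_shape[1],
              x$geometry$depth_image_shape[2]))
  invisible(x)
}

check_render_args <- function(animal_radius_mm, dropout_rate) {
  if (!is.numeric(animal_radius_mm) || animal_radius_mm <= 0)
    stop("render: 'animal_radius_mm' must be > 0", call. = FALSE)
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stop("render: 'dropout_rate' must lie in [0, 1)", call. = FALSE)
}

# One rendered frame. center_cm = NULL renders the empty cage (background
# only, still with noise/dropout), used for background-model frames.
render_depth_frame <- function(bg, center_cm, geometry, animal_radius_mm = 40,
                               noise_sd_mm = 0, dropout_rate = 0,
                               frame_index = NA_integer_) {
  d <- bg
  if (!is.null(center_cm)) {
    f <- geometry$focal_px
    pr <- project_to_pixels(center_cm[1], center_cm[2], center_cm[3],
                            geometry)
    Z <- pr$depth_mm
    r <- animal_radius_mm
    rpx <- f * r / Z
    H <- nrow(d); W <- ncol(d)
    r0 <- floor(pr$row - rpx - 1); r1 <- ceiling(pr$row + rpx + 1)
    c0 <- floor(pr$col - rpx - 1); c1 <- ceiling(pr$col + rpx + 1)
    if (r1 < 1 || r0 > H || c1 < 1 || c0 > W)
      stop("render_depth_frame: animal projects outside the image at frame ",
           frame_index, call. = FALSE)
    rows <- max(r0, 1):min(r1, H)
    cols <- max(c0, 1):min(c1, W)
    dxm <- (cols - pr$col) * Z / f     # lateral offsets in mm
    dym <- (rows - pr$row) * Z / f
    rho2 <- outer(dym^2, dxm^2, `+`)
    inside <- rho2 <= r^2
    if (any(inside)) {
      blob <- Z - sqrt(pmax(r^2 - rho2, 0))
      patch <- d[rows, cols, drop = FALSE]
      patch[inside] <- as.integer(round(pmin(patch[inside], blob[inside])))
      d[rows, cols] <- patch
    }
  }
  if (noise_sd_mm > 0) {
    valid <- d > 0L
    d[valid] <- pmax(1L, as.integer(round(
      d[valid] + stats::rnorm(sum(valid), 0, noise_sd_mm))))
  }
  if (dropout_rate > 0) {
    drop <- stats::runif(length(d)) < dropout_rate
    d[drop] <- 0L
  }
  d
}

#' Render empty-cage reference frames
#'
#' Frames of the cage with no animal, under the same noise and dropout model
#' as [render_depth_recording()]; the standard input for
#' [build_background()].
#'
#' @inheritParams render_depth_recording
#' @param n_frames Number of reference frames.
#' @return A `depth_recording` with `n_frames` frames at the nominal 5 fps.
#' @export
render_empty_recording <- function(geometry = cage_geometry(), n_frames = 25,
                                   noise_sd_mm = 0, dropout_rate = 0,
                                   seed = NULL) {
  check_render_args(1, dropout_rate)
  if (!is.null(seed)) set.seed(seed)
  bg <- cage_background_depth(geometry)
  frames <- lapply(seq_len(n_frames), function(i)
    render_depth_frame(bg, NULL, geometry, noise_sd_mm = noise_sd_mm,
                       dropout_rate = dropout_rate, frame_index = i))
  depth_recording(frames, (seq_len(n_frames) - 1) * 0.2, geometry,
                  noise_sd_mm = noise_sd_mm, dropout_rate = dropout_rate)
}
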