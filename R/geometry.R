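#' Cage and depth-camera geometry
#'
#' Describes the home cage and the depth camera viewing it face-on. The cage
#' frame is right-handed with its origin at the floor corner nearest the
#' camera: `x` runs along the cage width (image horizontal), `y` along the
#' camera axis into the cage (the cage "length"), and `z` is vertical.
#' Trajectories are expressed in centimetres; depth maps in millimetres.
#'
#' The camera is modeled as an ideal pinhole centred on the front cage face at
#' `camera_distance_mm` in front of it, at half cage width/height. Default
#' intrinsics place the whole cage inside the image frame.
#'
#' @param length_mm Cage extent along the camera axis (mm).
#' @param width_mm Cage extent across the image (mm).
#' @param height_mm Cage height (mm).
#' @param camera_distance_mm Distance from the pinhole to the front cage
#'   face (mm).
#' @param depth_image_shape Integer vector `c(rows, cols)` of the sensor grid.
#' @param focal_px Pinhole focal length in pixels.
#' @param principal_point Numeric `c(row, col)` of the principal point;
#'   defaults to the image centre.
#' @return An object of class `cage_geometry`.
#' @export
cage_geometry <- function(length_mm = 525, width_mm = 356, height_mm = 776,
                          camera_distance_mm = 500,
                          depth_image_shape = c(240L, 320L),
                          focal_px = 150,
                          principal_point = (depth_image_shape + 1) / 2) {
  g <- list(
    length_mm = length_mm, width_mm = width_mm, height_mm = height_mm,
    camera_distance_mm = camera_distance_mm,
    depth_image_shape = as.integer(depth_image_shape),
    focal_px = focal_px,
    principal_point = as.numeric(principal_point)
  )
  class(g) <- "cage_geometry"
  validate_cage_geometry(g)
  g
}

validate_cage_geometry <- function(g) {
  for (f in c("length_mm", "width_mm", "height_mm", "camera_distance_mm",
              "focal_px")) {
    v <- g[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("cage_geometry: field '", f, "' must be a positive finite number",
           call. = FALSE)
  }
  if (length(g$depth_image_shape) != 2 || any(g$depth_image_shape < 8))
    stop("cage_geometry: 'depth_image_shape' must be c(rows, cols) >= 8",
         call. = FALSE)
  # the near cage face (largest projection) must fit in the frame
  zn <- g$camera_distance_mm
  half_u <- g$focal_px * (g$width_mm / 2) / zn
  half_v <- g$focal_px * (g$height_mm / 2) / zn
  if (half_u > g$depth_image_shape[2] / 2 || half_v > g$depth_image_shape[1] / 2)
    stop("cage_geometry: cage does not project inside the image frame; ",
         "reduce focal_px or enlarge depth_image_shape", call. = FALSE)
  invisible(g)
}

#' @export
print.cage_geometry <- function(x, ...) {
  cat(sprintf("<cage_geometry> %g x %g x %g mm (L x W x H), camera at %g mm\n",
              x$length_mm, x$width_mm, x$height_mm, x$camera_distance_mm))
  cat(sprintf("  sensor %d x %d px, f = %g px, pp = (%g, %g)\n",
              x$depth_image_shape[1], x$depth_image_shape[2], x$focal_px,
              x$principal_point[1], x$principal_point[2]))
  invisible(x)
}

#' Cage extents in centimetres, as c(x, y, z) = (width, length, height)
#' @param geometry A [cage_geometry()].
#' @return Numeric length-3 vector (cm).
#' @export
cage_dim_cm <- function(geometry) {
  c(geometry$width_mm, geometry$length_mm, geometry$height_mm) / 10
}

# Project cage-frame points (cm) to pixel coordinates and sensor depth (mm).
# Returns list(row, col, depth_mm). Camera looks along +y.
project_to_pixels <- function(x_cm, y_cm, z_cm, geometry) {
  xm <- x_cm * 10; ym <- y_cm * 10; zm <- z_cm * 10
  Xc <- xm - geometry$width_mm / 2
  Yc <- geometry$height_mm / 2 - zm          # image rows grow downward
  Zc <- ym + geometry$camera_distance_mm
  list(
    row = geometry$principal_point[1] + geometry$focal_px * Yc / Zc,
    col = geometry$principal_point[2] + geometry$focal_px * Xc / Zc,
    depth_mm = Zc
  )
}

# Back-project pixel coordinates + depth (mm) into cage-frame cm.
backproject_pixels <- function(row, col, depth_mm, geometry) {
  Xc <- (col - geometry$principal_point[2]) * depth_mm / geometry$focal_px
  Yc <- (row - geometry$principal_point[1]) * depth_mm / geometry$focal_px
  list(
    x_cm = (Xc + geometry$width_mm / 2) / 10,
    y_cm = (depth_mm - geometry$camera_distance_mm) / 10,
    z_cm = (geometry$height_mm / 2 - Yc) / 10
  )
}

# Static empty-cage depth map (mm, integer). Rays are cast from the pinhole;
# rays through the open front face see the first interior wall hit, all
# others see the front panel at the camera distance.
cage_background_depth <- function(geometry) {
  H <- geometry$depth_image_shape[1]; W <- geometry$depth_image_shape[2]
  f <- geometry$focal_px
  cpr <- geometry$principal_point[1]; cpc <- geometry$principal_point[2]
  dist <- geometry$camera_distance_mm
  w <- geometry$width_mm; l <- geometry$length_mm; h <- geometry$height_mm

  col <- matrix(rep(seq_len(W), each = H), H, W)
  row <- matrix(rep(seq_len(H), times = W), H, W)
  a <- (col - cpc) / f        # dx per unit depth
  b <- -(row - cpr) / f       # dz per unit depth (rows grow downward)

  # entry point on the front face plane (depth = dist)
  x0 <- w / 2 + a * dist
  z0 <- h / 2 + b * dist
  inside <- x0 >= 0 & x0 <= w & z0 >= 0 & z0 <= h

  t_back <- dist + l
  t_x <- ifelse(a > 0, (w / 2) / a, ifelse(a < 0, (-w / 2) / a, Inf))
  t_z <- ifelse(b > 0, (h / 2) / b, ifelse(b < 0, (-h / 2) / b, Inf))
  t_hit <- pmin(t_back, t_x, t_z)

  d <- ifelse(inside & t_hit >= dist, t_hit, dist)
  matrix(as.integer(round(d)), H, W)
}
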