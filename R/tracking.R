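#' Build a per-pixel background model from depth frames
#'
#' The background is the per-pixel median depth over the supplied frames,
#' ignoring invalid (0) measurements; pixels invalid in every frame are
#' masked. Use a dedicated empty-cage segment when one exists (see
#' [render_empty_recording()]), or the recording's own frames — the animal
#' occupies any one pixel rarely, so the temporal median recovers the cage.
#'
#' @param frames A `depth_recording` or a list of integer depth matrices.
#' @return An object of class `background_model`: list with `depth_mm`
#'   (matrix, 0 where masked) and `valid_mask` (logical matrix).
#' @export
build_background <- function(frames) {
  if (inherits(frames, "depth_recording")) frames <- frames$frames
  if (!length(frames))
    stop("build_background: need at least one frame", call. = FALSE)
  dm <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), dm), logical(1))))
    stop("build_background: all frames must share one shape", call. = FALSE)
  M <- vapply(frames, as.vector, numeric(prod(dm)))
  M <- matrix(M, nrow = prod(dm))
  M[M == 0] <- NA_real_
  med <- apply(M, 1, stats::median, na.rm = TRUE)
  valid <- !is.na(med)
  med[!valid] <- 0
  bg <- list(depth_mm = matrix(med, dm[1], dm[2]),
             valid_mask = matrix(valid, dm[1], dm[2]))
  class(bg) <- "background_model"
  bg
}

#' Detect the animal in one depth frame
#'
#' Foreground pixels are those measured nearer than the background by more
#' than `delta_mm`. Connected components are taken with 8-connectivity; if
#' the largest component reaches `min_blob_px` pixels, its 3D centroid is
#' back-projected into cage coordinates. The centroid over the visible
#' (near-side) surface of a convex body lies ~2/3 of the body radius in
#' front of its centre, so the reported position is pushed back along the
#' camera axis by 2/3 of a radius estimated from the blob's pixel area.
#' Equal-sized largest components are resolved in favour of the nearer
#' (smaller mean depth) blob.
#'
#' @param frame Integer depth matrix (mm, 0 = invalid).
#' @param bg A [build_background()] model of the same shape.
#' @param geometry A [cage_geometry()] supplying the intrinsics.
#' @param delta_mm Foreground threshold (mm), > 0.
#' @param min_blob_px Minimal component size accepted as the animal.
#' @param time_s Timestamp copied onto the returned point.
#' @return A one-row data frame `time_s, x_cm, y_cm, z_cm, valid, blob_px`;
#'   invalid points carry the size of the largest component found.
#' @export
segment_foreground <- function(frame, bg, geometry, delta_mm = 40,
                               min_blob_px = 50, time_s = NA_real_) {
  if (is.null(geometry$focal_px) || is.null(geometry$principal_point))
    stop("segment_foreground: geometry lacks intrinsics", call. = FALSE)
  if (!is.numeric(delta_mm) || delta_mm <= 0)
    stop("segment_foreground: 'delta_mm' must be > 0", call. = FALSE)
  if (!identical(dim(frame), dim(bg$depth_mm)))
    stop("segment_foreground: frame and background shapes differ",
         call. = FALSE)

  invalid_point <- function(npx) data.frame(
    time_s = time_s, x_cm = NA_real_, y_cm = NA_real_, z_cm = NA_real_,
    valid = FALSE, blob_px = as.integer(npx))

  fg <- frame > 0L & bg$valid_mask & (bg$depth_mm - frame) > delta_mm
  if (!any(fg)) return(invalid_point(0L))

  # label inside the foreground bounding box only
  idx <- which(fg, arr.ind = TRUE)
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  sub <- fg[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  lab <- label_components_8(sub)
  sizes <- tabulate(lab[lab > 0L])
  biggest <- max(sizes)
  if (biggest < min_blob_px) return(invalid_point(biggest))
  cand <- which(sizes == biggest)
  if (length(cand) > 1) {          # tie: nearer blob wins
    subd <- frame[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    meand <- vapply(cand, function(k) mean(subd[lab == k]), numeric(1))
    cand <- cand[which.min(meand)]
  }
  sel <- which(lab == cand[1], arr.ind = TRUE)
  rows <- sel[, 1] + rr[1] - 1L
  cols <- sel[, 2] + cc[1] - 1L
  d <- as.numeric(frame[cbind(rows, cols)])

  # pixel centroid back-projected at the body-centre depth: the mean depth
  # over the visible near surface of a convex body sits ~2/3 radius in
  # front of its centre, and using per-pixel surface depths would shrink
  # the lateral coordinates toward the optical axis by the same amount
  f <- geometry$focal_px
  cpr <- geometry$principal_point[1]; cpc <- geometry$principal_point[2]
  r_est <- sqrt(biggest / pi) * mean(d) / f        # body radius, mm
  Zc <- mean(d) + (2 / 3) * r_est                  # surface -> centre
  Xc <- (mean(cols) - cpc) * Zc / f
  Yc <- (mean(rows) - cpr) * Zc / f
  data.frame(
    time_s = time_s,
    x_cm = (Xc + geometry$width_mm / 2) / 10,
    y_cm = (Zc - geometry$camera_distance_mm) / 10,
    z_cm = (geometry$height_mm / 2 - Yc) / 10,
    valid = TRUE, blob_px = as.integer(biggest))
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge any labels
# that touch diagonally with a union-find pass.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (!nrow(pairs)) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

#' Link detections into a trajectory with spurious-step and gap handling
#'
#' Two cleaning passes over time-sorted detections: (1) a spurious-detection
#' guard — a valid point whose displacement from the previous surviving
#' valid point exceeds `max_step_cm` per intervening frame is invalidated;
#' (2) gap filling — runs of at most `max_gap_frames` consecutive invalid
#' points flanked by valid points are linearly interpolated in time and
#' flagged valid. Longer gaps remain invalid; interpolation never
#' extrapolates beyond flanking valid points.
#'
#' @param points Data frame with columns
#'   `time_s, x_cm, y_cm, z_cm, valid` (and optionally `blob_px`),
#'   time-sorted.
#' @param max_gap_frames Longest invalid run filled by interpolation.
#' @param max_step_cm Largest plausible displacement per frame (cm).
#' @param animal_id,session_day,nominal_dt_s Metadata for the returned
#'   [trajectory()].
#' @return A [trajectory()].
#' @export
link_trajectory <- function(points, max_gap_frames = 5, max_step_cm = 60,
                            animal_id = "animal", session_day = 0L,
                            nominal_dt_s = 0.2) {
  pts <- as.data.frame(points)
  n <- nrow(pts)
  valid <- as.logical(pts$valid)

  # spurious-step guard against the last surviving valid point
  anchor <- NA_integer_
  for (i in seq_len(n)) {
    if (!valid[i]) next
    if (!is.na(anchor)) {
      gap <- i - anchor
      step <- sqrt((pts$x_cm[i] - pts$x_cm[anchor])^2 +
                     (pts$y_cm[i] - pts$y_cm[anchor])^2 +
                     (pts$z_cm[i] - pts$z_cm[anchor])^2)
      if (step > max_step_cm * gap) { valid[i] <- FALSE; next }
    }
    anchor <- i
  }

  # fill short invalid runs between valid flanks
  x <- pts$x_cm; y <- pts$y_cm; z <- pts$z_cm
  vi <- which(valid)
  if (length(vi) >= 2) {
    for (k in seq_len(length(vi) - 1)) {
      a <- vi[k]; b <- vi[k + 1]
      gap <- b - a - 1L
      if (gap >= 1L && gap <= max_gap_frames) {
        j <- (a + 1L):(b - 1L)
        w <- (pts$time_s[j] - pts$time_s[a]) /
          (pts$time_s[b] - pts$time_s[a])
        x[j] <- pts$x_cm[a] + w * (pts$x_cm[b] - pts$x_cm[a])
        y[j] <- pts$y_cm[a] + w * (pts$y_cm[b] - pts$y_cm[a])
        z[j] <- pts$z_cm[a] + w * (pts$z_cm[b] - pts$z_cm[a])
        valid[j] <- TRUE
      }
    }
  }
  trajectory(pts$time_s, x, y, z, valid = valid, animal_id = animal_id,
             session_day = session_day, nominal_dt_s = nominal_dt_s)
}

#' Track an in-memory depth recording
#'
#' Runs the full tracker: background model (supplied, or the recording's own
#' per-pixel median over up to 101 evenly spaced frames), per-frame
#' foreground segmentation, and gap-aware linking.
#'
#' @param recording A `depth_recording`.
#' @param background A [build_background()] model, or `NULL` to estimate one
#'   from the recording itself.
#' @inheritParams segment_foreground
#' @inheritParams link_trajectory
#' @return A [trajectory()] with attribute `valid_fraction` (fraction of
#'   frames with an accepted detection before gap filling).
#' @export
track_recording <- function(recording, background = NULL, delta_mm = 40,
                            min_blob_px = 50, max_gap_frames = 5,
                            max_step_cm = 60, animal_id = "animal",
                            session_day = 0L) {
  stopifnot(inherits(recording, "depth_recording"))
  if (is.null(background)) {
    pick <- unique(round(seq(1, length(recording$frames),
                             length.out = min(101, length(recording$frames)))))
    background <- build_background(recording$frames[pick])
  }
  pts <- do.call(rbind, lapply(seq_along(recording$frames), function(i)
    segment_foreground(recording$frames[[i]], background,
                       recording$geometry, delta_mm = delta_mm,
                       min_blob_px = min_blob_px,
                       time_s = recording$time_s[i])))
  traj <- link_trajectory(pts, max_gap_frames = max_gap_frames,
                          max_step_cm = max_step_cm, animal_id = animal_id,
                          session_day = session_day,
                          nominal_dt_s = stats::median(diff(recording$time_s)))
  attr(traj, "valid_fraction") <- mean(pts$valid)
  traj
}

#' Render and track a simulated session without storing frames
#'
#' Streams the render-and-track loop frame by frame: a background model is
#' built from noisy empty-cage reference frames, then each trajectory frame
#' is rendered, segmented and discarded. Equivalent to
#' [render_depth_recording()] followed by [track_recording()] but with
#' constant memory, which matters for 6 h sessions.
#'
#' @param session A `ground_truth_session`.
#' @inheritParams render_depth_recording
#' @inheritParams track_recording
#' @param n_background_frames Empty-cage frames used for the background.
#' @return A [trajectory()] with attribute `valid_fraction`.
#' @export
track_session <- function(session, geometry = cage_geometry(),
                          animal_radius_mm = 40, noise_sd_mm = 0,
                          dropout_rate = 0, seed = NULL,
                          n_background_frames = 25, delta_mm = 40,
                          min_blob_px = 50, max_gap_frames = 5,
                          max_step_cm = 60) {
  stopifnot(inherits(session, "ground_truth_session"))
  check_render_args(animal_radius_mm, dropout_rate)
  if (!is.null(seed)) set.seed(seed)
  traj <- session$trajectory
  bg_static <- cage_background_depth(geometry)
  ref <- lapply(seq_len(n_background_frames), function(i)
    render_depth_frame(bg_static, NULL, geometry, noise_sd_mm = noise_sd_mm,
                       dropout_rate = dropout_rate, frame_index = i))
  background <- build_background(ref)
  pts <- vector("list", nrow(traj))
  for (i in seq_len(nrow(traj))) {
    fr <- render_depth_frame(bg_static,
                             c(traj$x_cm[i], traj$y_cm[i], traj$z_cm[i]),
                             geometry, animal_radius_mm = animal_radius_mm,
                             noise_sd_mm = noise_sd_mm,
                             dropout_rate = dropout_rate, frame_index = i)
    pts[[i]] <- segment_foreground(fr, background, geometry,
                                   delta_mm = delta_mm,
                                   min_blob_px = min_blob_px,
                                   time_s = traj$time_s[i])
  }
  pts <- do.call(rbind, pts)
  out <- link_trajectory(pts, max_gap_frames = max_gap_frames,
                         max_step_cm = max_step_cm,
                         animal_id = attr(traj, "animal_id"),
                         session_day = attr(traj, "session_day"),
                         nominal_dt_s = attr(traj, "nominal_dt_s"))
  attr(out, "valid_fraction") <- mean(pts$valid)
  out
}
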