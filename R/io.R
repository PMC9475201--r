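#' Read and write trajectory CSV files
#'
#' The trajectory interchange format is a CSV with header
#' `time_s,x_cm,y_cm,z_cm,valid` (`valid` in {0,1}). Reads validate the
#' header, the validity flags and strict time monotonicity, naming the
#' first offending row.
#'
#' @param path File path.
#' @param animal_id,session_day,nominal_dt_s Metadata attached on read.
#' @return `read_trajectory_csv()` returns a [trajectory()].
#' @export
read_trajectory_csv <- function(path, animal_id = "animal",
                                session_day = 0L, nominal_dt_s = 0.2) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "x_cm", "y_cm", "z_cm", "valid")
  if (!identical(names(df)[seq_along(need)], need))
    stop("trajectory CSV '", path, "': header must be ",
         paste(need, collapse = ","), call. = FALSE)
  if (!all(df$valid %in% c(0, 1)))
    stop("trajectory CSV '", path, "': column 'valid' must be 0/1; first ",
         "offending row ", which(!(df$valid %in% c(0, 1)))[1], call. = FALSE)
  if (nrow(df) > 1 && any(diff(df$time_s) <= 0))
    stop("trajectory CSV '", path, "': column 'time_s' not strictly ",
         "increasing at row ", which(diff(df$time_s) <= 0)[1] + 1,
         call. = FALSE)
  trajectory(df$time_s, df$x_cm, df$y_cm, df$z_cm, valid = df$valid == 1,
             animal_id = animal_id, session_day = session_day,
             nominal_dt_s = nominal_dt_s)
}

#' @rdname read_trajectory_csv
#' @param traj A [trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(is_trajectory(traj))
  df <- as.data.frame(traj)
  df$valid <- as.integer(df$valid)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write neurological-score CSV files
#'
#' Format: `animal,day,side,slip,dangle,midline,uncoordinated` with 0/1
#' sign flags and `side` in {left, right}.
#'
#' @param path File path.
#' @return `read_scores_csv()` returns the validated records data frame.
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "day", "side", "slip", "dangle", "midline",
            "uncoordinated")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("score CSV '", path, "': missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$side %in% c("left", "right")))
    stop("score CSV '", path, "': 'side' must be left/right; first ",
         "offending row ", which(!(df$side %in% c("left", "right")))[1],
         call. = FALSE)
  for (s in c("slip", "dangle", "midline", "uncoordinated"))
    if (!all(df[[s]] %in% c(0, 1)))
      stop("score CSV '", path, "': sign '", s, "' must be 0/1; first ",
           "offending row ", which(!(df[[s]] %in% c(0, 1)))[1],
           call. = FALSE)
  df$day <- as.integer(df$day)
  df
}

#' @rdname read_scores_csv
#' @param records Score records data frame.
#' @export
write_scores_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write per-session metrics CSV files
#'
#' Long format `animal,day,metric,value` as produced by [metrics_table()].
#'
#' @param path File path.
#' @return `read_metrics_csv()` returns the validated data frame.
#' @export
read_metrics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "day", "metric", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metrics CSV '", path, "': missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$day <- as.integer(df$day)
  df
}

#' @rdname read_metrics_csv
#' @param daily_metrics Long metric table.
#' @export
write_metrics_csv <- function(daily_metrics, path) {
  utils::write.csv(daily_metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read a depth recording on disk
#'
#' The on-disk container is a directory of 16-bit grayscale TIFF frames
#' (`frame_000001.tif`, ..., depth in mm, 0 = invalid) plus a `meta.json`
#' sidecar holding the frame count, timestamps and geometry. Reads
#' validate that the frame count matches the timestamps.
#'
#' @param recording A `depth_recording`.
#' @param dir Directory to create/read.
#' @return `read_depth_recording()` returns a `depth_recording`.
#' @export
write_depth_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "depth_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(recording$frames)) {
    tiff::writeTIFF(recording$frames[[i]] / 65535,
                    file.path(dir, sprintf("frame_%06d.tif", i)),
                    bits.per.sample = 16L)
  }
  g <- recording$geometry
  meta <- list(
    n_frames = length(recording$frames),
    time_s = recording$time_s,
    fps = if (length(recording$time_s) > 1)
      1 / stats::median(diff(recording$time_s)) else NA,
    depth_unit = "mm",
    geometry = list(length_mm = g$length_mm, width_mm = g$width_mm,
                    height_mm = g$height_mm,
                    camera_distance_mm = g$camera_distance_mm,
                    depth_image_shape = g$depth_image_shape,
                    focal_px = g$focal_px,
                    principal_point = g$principal_point))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_depth_recording
#' @export
read_depth_recording <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    stop("read_depth_recording: no meta.json in '", dir, "'", call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.tif$",
                           full.names = TRUE))
  if (length(files) != meta$n_frames ||
      length(meta$time_s) != meta$n_frames)
    stop("read_depth_recording: frame count (", length(files),
         ") does not match meta.json timestamps (", length(meta$time_s),
         ")", call. = FALSE)
  g <- meta$geometry
  geometry <- cage_geometry(length_mm = g$length_mm, width_mm = g$width_mm,
                            height_mm = g$height_mm,
                            camera_distance_mm = g$camera_distance_mm,
                            depth_image_shape = g$depth_image_shape,
                            focal_px = g$focal_px,
                            principal_point = g$principal_point)
  frames <- lapply(files, function(f) {
    m <- tiff::readTIFF(f)
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  })
  depth_recording(frames, meta$time_s, geometry)
}
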