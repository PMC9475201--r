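#' Full-study pipeline configuration
#'
#' One object holding everything a run needs: the study design (animals,
#' preoperative and postoperative days, session length), cage geometry,
#' healthy baseline behavior, the deficit/recovery schedule, metric and
#' statistics options, render/track options and the master seed. A config
#' round-trips losslessly through [write_config()] / [read_config()].
#'
#' The default design mirrors the stroke-study protocol — 3 animals, 3
#' preoperative baseline days, postoperative recording from day 2 to day 28
#' — at 10 minutes per session so a full run completes in minutes; 6 h
#' sessions are supported via `session_minutes = 360`.
#'
#' @param animals Character vector of animal ids.
#' @param preop_days,postop_days Integer day vectors (preop days negative).
#' @param session_minutes Session length (min).
#' @param fps Frame rate (Hz).
#' @param geometry A [cage_geometry()].
#' @param baseline A [behavior_params()] for the healthy state.
#' @param deficit,recovery_tau_days,onset_day See [recovery_schedule()].
#' @param metrics A [metrics_config()].
#' @param score_tau_days Recovery time constant of the simulated
#'   neurological score (days).
#' @param bin_days,alpha,pairing Statistics options (see [analyze_study()]).
#' @param render If `TRUE`, sessions are rendered to depth frames and
#'   re-tracked; if `FALSE` the ground-truth trajectories feed the metrics
#'   directly.
#' @param animal_radius_mm,noise_sd_mm,dropout_rate Render options.
#' @param tracker Named list of tracker settings
#'   (`delta_mm`, `min_blob_px`, `max_gap_frames`, `max_step_cm`); missing
#'   entries keep the tracker defaults.
#' @param seed Master RNG seed; all per-session seeds derive from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(animals = c("m1", "m2", "m3"),
                            preop_days = -3:-1, postop_days = 2:28,
                            session_minutes = 10, fps = 5,
                            geometry = cage_geometry(),
                            baseline = behavior_params(),
                            deficit = c(speed = 0.8, activity = 0.8,
                                        jump = 0.9, range = 0.8),
                            recovery_tau_days = 7, onset_day = 2L,
                            metrics = metrics_config(),
                            score_tau_days = 9,
                            bin_days = 3, alpha = 0.05,
                            pairing = c("mean", "animal-day"),
                            render = FALSE, animal_radius_mm = 40,
                            noise_sd_mm = 0, dropout_rate = 0,
                            tracker = list(), seed = 1L) {
  pairing <- match.arg(pairing)
  tracker_defaults <- list(delta_mm = 40, min_blob_px = 50,
                           max_gap_frames = 5, max_step_cm = 60)
  bad <- setdiff(names(tracker), names(tracker_defaults))
  if (length(bad))
    stop("pipeline_config: unknown tracker settings: ",
         paste(bad, collapse = ", "), call. = FALSE)
  tracker <- utils::modifyList(tracker_defaults, tracker)
  cfg <- list(animals = animals, preop_days = as.integer(preop_days),
              postop_days = as.integer(postop_days),
              session_minutes = session_minutes, fps = fps,
              geometry = geometry, baseline = baseline,
              schedule = recovery_schedule(baseline, deficit,
                                           recovery_tau_days, onset_day),
              metrics = metrics, score_tau_days = score_tau_days,
              bin_days = bin_days, alpha = alpha, pairing = pairing,
              render = render, animal_radius_mm = animal_radius_mm,
              noise_sd_mm = noise_sd_mm, dropout_rate = dropout_rate,
              tracker = tracker, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<pipeline_config> %d animals, preop {%s}, postop %d..%d, ",
    "%g min/session at %g fps\n  render %s, seed %d\n"),
    length(x$animals), paste(x$preop_days, collapse = ","),
    min(x$postop_days), max(x$postop_days), x$session_minutes, x$fps,
    if (x$render) sprintf("on (noise %g mm, dropout %g)", x$noise_sd_mm,
                          x$dropout_rate) else "off", x$seed))
  invisible(x)
}

#' Write or read a pipeline configuration as YAML
#' @param cfg A [pipeline_config()].
#' @param path File path.
#' @return `read_config()` returns the reconstructed [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  flat <- list(
    animals = cfg$animals, preop_days = cfg$preop_days,
    postop_days = cfg$postop_days, session_minutes = cfg$session_minutes,
    fps = cfg$fps,
    geometry = unclass(cfg$geometry),
    baseline = unclass(cfg$baseline),
    deficit = as.list(cfg$schedule$deficit),
    recovery_tau_days = cfg$schedule$recovery_tau_days,
    onset_day = cfg$schedule$onset_day,
    metrics = unclass(cfg$metrics),
    score_tau_days = cfg$score_tau_days, bin_days = cfg$bin_days,
    alpha = cfg$alpha, pairing = cfg$pairing, render = cfg$render,
    animal_radius_mm = cfg$animal_radius_mm,
    noise_sd_mm = cfg$noise_sd_mm, dropout_rate = cfg$dropout_rate,
    tracker = cfg$tracker, seed = cfg$seed)
  flat$baseline$seed <- NULL
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- y$geometry
  b <- y$baseline
  pipeline_config(
    animals = y$animals, preop_days = y$preop_days,
    postop_days = y$postop_days, session_minutes = y$session_minutes,
    fps = y$fps,
    geometry = cage_geometry(g$length_mm, g$width_mm, g$height_mm,
                             g$camera_distance_mm, g$depth_image_shape,
                             g$focal_px, g$principal_point),
    baseline = behavior_params(b$p_rest_to_move, b$p_move_to_rest,
                               b$speed_scale_cm_s, b$jump_rate_per_min,
                               b$jump_peak_speed_cm_s, b$range_fraction),
    deficit = unlist(y$deficit), recovery_tau_days = y$recovery_tau_days,
    onset_day = y$onset_day,
    metrics = metrics_config(y$metrics$movement_threshold_cm_s,
                             y$metrics$jump_threshold_cm_s,
                             y$metrics$vz_mode, y$metrics$occupancy_cell_cm,
                             y$metrics$fps),
    score_tau_days = y$score_tau_days, bin_days = y$bin_days,
    alpha = y$alpha, pairing = y$pairing, render = y$render,
    animal_radius_mm = y$animal_radius_mm, noise_sd_mm = y$noise_sd_mm,
    dropout_rate = y$dropout_rate,
    tracker = if (is.null(y$tracker)) list() else y$tracker,
    seed = y$seed)
}

# deterministic per-session seed below 2^31
derive_seed <- function(seed, animal_index, day, salt = 0L) {
  v <- (as.numeric(seed) * 7919 + animal_index * 104729 +
          (day + 1000) * 613 + salt * 31) %% 2147483629
  as.integer(v) + 1L
}

#' Simulate a whole multi-animal study
#'
#' Generates one ground-truth session per animal-day under the deficit/
#' recovery schedule (preoperative days use the healthy baseline), plus the
#' simulated neurological-score records. Per-session seeds derive from the
#' master seed, so the study is reproducible as a whole.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `sessions` (list of `ground_truth_session`), `scores`
#'   (records data frame) and `days` (all study days).
#' @export
simulate_study <- function(cfg) {
  days <- c(cfg$preop_days, cfg$postop_days)
  sessions <- list()
  for (a in seq_along(cfg$animals)) {
    for (d in days) {
      p <- apply_recovery(cfg$schedule, d)
      s <- simulate_session(p, cfg$geometry,
                            duration_s = cfg$session_minutes * 60,
                            fps = cfg$fps, day_index = d,
                            animal_id = cfg$animals[a],
                            seed = derive_seed(cfg$seed, a, d))
      sessions[[paste0(cfg$animals[a], "_day", d)]] <- s
    }
  }
  scores <- simulate_scores(cfg$animals, days,
                            onset_day = cfg$schedule$onset_day,
                            tau_days = cfg$score_tau_days,
                            seed = derive_seed(cfg$seed, 0L, 0L, salt = 9L))
  list(sessions = sessions, scores = scores, days = days)
}

#' Run the full pipeline: simulate, (render and track), metrics, analyze
#'
#' Executes the stages in order and writes every stage output under
#' `out_dir`: per-session trajectory CSVs, the long metrics CSV, score
#' records and daily score series, ratio/binned/test/correlation tables,
#' and a `manifest.json` with the config hash, per-file checksums and
#' per-session valid-frame fractions. Identical config and seed give
#' byte-identical outputs. A stage failure aborts with the stage named;
#' outputs written so far are retained and the manifest marks the run
#' incomplete.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param scores Optional score records data frame replacing the simulated
#'   scores (e.g. real observations); `NA` to skip scoring and
#'   correlations.
#' @return Invisibly, a list of class `pipeline_result` with `manifest`,
#'   `analysis`, `metrics` and `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir, scores = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "trajectories"), showWarnings = FALSE)
  warnings_log <- character(0)
  stage <- "simulate"
  manifest <- list(complete = FALSE, failed_stage = NULL)

  fail <- function(e) {
    manifest$failed_stage <- stage
    manifest$warnings <- warnings_log
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop("run_pipeline: stage '", stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  }

  tryCatch({
    study <- simulate_study(cfg)

    stage <- "track"
    valid_fraction <- list()
    trajectories <- list()
    for (nm in names(study$sessions)) {
      s <- study$sessions[[nm]]
      if (cfg$render) {
        a <- match(attr(s$trajectory, "animal_id"), cfg$animals)
        tr <- track_session(s, cfg$geometry,
                            animal_radius_mm = cfg$animal_radius_mm,
                            noise_sd_mm = cfg$noise_sd_mm,
                            dropout_rate = cfg$dropout_rate,
                            seed = derive_seed(cfg$seed, a, s$day_index,
                                               salt = 1L),
                            delta_mm = cfg$tracker$delta_mm,
                            min_blob_px = cfg$tracker$min_blob_px,
                            max_gap_frames = cfg$tracker$max_gap_frames,
                            max_step_cm = cfg$tracker$max_step_cm)
        valid_fraction[[nm]] <- attr(tr, "valid_fraction")
      } else {
        tr <- s$trajectory
        valid_fraction[[nm]] <- 1
      }
      trajectories[[nm]] <- tr
      write_trajectory_csv(tr, file.path(out_dir, "trajectories",
                                         paste0(nm, ".csv")))
    }

    stage <- "metrics"
    ml <- lapply(trajectories, session_metrics, cfg = cfg$metrics,
                 geometry = cfg$geometry)
    daily <- metrics_table(ml)
    write_metrics_csv(daily, file.path(out_dir, "metrics.csv"))

    stage <- "score"
    score_series <- NULL
    if (!identical(scores, NA)) {
      rec <- if (is.null(scores)) study$scores else scores
      write_scores_csv(rec, file.path(out_dir, "scores.csv"))
      score_series <- score_timecourse(rec, affected_side = "right")
      utils::write.csv(score_series,
                       file.path(out_dir, "daily_scores.csv"),
                       row.names = FALSE, quote = FALSE)
    }

    stage <- "analyze"
    ana <- withCallingHandlers(
      analyze_study(daily, score_series, preop_days = cfg$preop_days,
                    bin_days = cfg$bin_days, alpha = cfg$alpha,
                    pairing = cfg$pairing),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    utils::write.csv(ana$ratios, file.path(out_dir, "ratios.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(ana$binned, file.path(out_dir, "binned.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(ana$tests, file.path(out_dir, "tests.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(ana$correlations))
      utils::write.csv(ana$correlations,
                       file.path(out_dir, "correlations.csv"),
                       row.names = FALSE, quote = FALSE)
    if (!is.null(ana$score_binned))
      utils::write.csv(ana$score_binned,
                       file.path(out_dir, "score_binned.csv"),
                       row.names = FALSE, quote = FALSE)

    stage <- "manifest"
    cfg_file <- tempfile(fileext = ".yaml")
    write_config(cfg, cfg_file)
    cfg_hash <- unname(tools::md5sum(cfg_file))
    unlink(cfg_file)
    outputs <- sort(setdiff(
      list.files(out_dir, recursive = TRUE),
      c("manifest.json")))
    checksums <- as.list(tools::md5sum(file.path(out_dir, outputs)))
    names(checksums) <- outputs
    manifest <- list(
      complete = TRUE, failed_stage = NULL,
      config_hash = cfg_hash,
      package_version = as.character(utils::packageVersion("marmobehav")),
      seed = cfg$seed,
      valid_frame_fraction = valid_fraction,
      checksums = checksums,
      warnings = warnings_log)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

    out <- list(manifest = manifest, analysis = ana, metrics = daily,
                out_dir = out_dir)
    class(out) <- "pipeline_result"
    invisible(out)
  }, error = fail)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> outputs in ", x$out_dir, "\n", sep = "")
  print(x$analysis)
  invisible(x)
}
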