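#' Baseline-ratio normalization of daily metrics
#'
#' Locomotor metrics vary greatly between individuals, so postoperative
#' values are expressed as ratios against each animal's own healthy
#' baseline: the mean of the metric over its preoperative sessions. A zero
#' or missing baseline makes the ratio undefined (`NA`, with a warning);
#' the rest of the table is unaffected.
#'
#' @param daily_metrics Long data frame `animal, day, metric, value`
#'   (see [metrics_table()]).
#' @param preop_days Integer vector of preoperative day indices.
#' @return Data frame of class `baseline_ratio_series`:
#'   `animal, metric, day, value, baseline, ratio`, postoperative days only.
#' @export
baseline_ratio <- function(daily_metrics, preop_days) {
  need <- c("animal", "day", "metric", "value")
  miss <- setdiff(need, names(daily_metrics))
  if (length(miss))
    stop("baseline_ratio: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  pre <- daily_metrics[daily_metrics$day %in% preop_days, , drop = FALSE]
  if (!nrow(pre))
    stop("baseline_ratio: no preoperative sessions in 'daily_metrics'",
         call. = FALSE)
  pre <- pre[is.finite(pre$value), , drop = FALSE]
  if (!nrow(pre))
    stop("baseline_ratio: no finite preoperative values", call. = FALSE)
  base <- stats::aggregate(value ~ animal + metric, data = pre, FUN = mean)
  names(base)[names(base) == "value"] <- "baseline"
  post <- daily_metrics[!(daily_metrics$day %in% preop_days), , drop = FALSE]
  out <- merge(post, base, by = c("animal", "metric"), all.x = TRUE)
  bad <- is.na(out$baseline) | out$baseline == 0
  if (any(bad))
    warning("baseline_ratio: zero or missing baseline for ",
            paste(unique(paste(out$animal[bad], out$metric[bad])),
                  collapse = "; "), "; ratios set to NA", call. = FALSE)
  out$ratio <- ifelse(bad, NA_real_, out$value / out$baseline)
  out <- out[order(out$metric, out$animal, out$day),
             c("animal", "metric", "day", "value", "baseline", "ratio")]
  rownames(out) <- NULL
  class(out) <- c("baseline_ratio_series", "data.frame")
  out
}

#' Bin a daily series into consecutive 3-day windows
#'
#' Groups postoperative days as `[1-3], [4-6], ...` (anchored at
#' `anchor_day`) and reports the mean, SEM (sample SD over \eqn{\sqrt{n}})
#' and n of all contributing animal-day values in each bin. Because
#' recording resumes on postoperative day 2, the first bin may hold only
#' days 2-3. Empty bins inside the covered range are reported with `n = 0`
#' and missing mean.
#'
#' @param series Data frame with columns `day` and a value column —
#'   `ratio` (as from [baseline_ratio()]), `score`, or `value`, searched in
#'   that order.
#' @param bin_days Bin width in days, >= 1.
#' @param anchor_day First day of the first bin.
#' @return Data frame of class `binned_series`: one row per (metric,) bin
#'   with `bin, day_lo, day_hi, mean, sem, n`.
#' @export
bin_timecourse <- function(series, bin_days = 3, anchor_day = 1L) {
  if (bin_days < 1) stop("bin_timecourse: 'bin_days' must be >= 1",
                         call. = FALSE)
  vcol <- intersect(c("ratio", "score", "value"), names(series))[1]
  if (is.na(vcol))
    stop("bin_timecourse: no ratio/score/value column found", call. = FALSE)
  df <- data.frame(day = series$day, value = series[[vcol]])
  if ("metric" %in% names(series)) df$metric <- series$metric
  df <- df[df$day >= anchor_day, , drop = FALSE]
  if (!nrow(df))
    stop("bin_timecourse: no days at or after 'anchor_day'", call. = FALSE)
  df$bin_idx <- (df$day - anchor_day) %/% bin_days

  one_group <- function(g) {
    idx <- seq(0, max(g$bin_idx))
    do.call(rbind, lapply(idx, function(b) {
      v <- g$value[g$bin_idx == b & !is.na(g$value)]
      lo <- anchor_day + b * bin_days
      hi <- lo + bin_days - 1
      data.frame(bin = paste0(lo, "-", hi), day_lo = lo, day_hi = hi,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
                       else if (length(v) == 1) NA_real_ else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  }
  out <- if ("metric" %in% names(df)) {
    res <- do.call(rbind, lapply(split(df, df$metric), function(g) {
      cbind(metric = g$metric[1], one_group(g), stringsAsFactors = FALSE)
    }))
    res
  } else one_group(df)
  rownames(out) <- NULL
  class(out) <- c("binned_series", "data.frame")
  out
}

#' Paired pre/post t-test
#'
#' Two-sided paired t-test of per-animal postoperative bin values against
#' the same animals' preoperative baselines. Identical pre and post values
#' give t = 0, p = 1; a non-zero but constant difference has zero variance
#' and is flagged degenerate (no finite t) rather than reported as
#' infinite. Fewer than 2 complete pairs is flagged not computable.
#'
#' @param pre,post Numeric vectors paired by animal (same order).
#' @param bin Optional bin label carried into the result.
#' @param alpha Significance level, default 0.05.
#' @return An object of class `paired_test_result`: list with `bin`, `t`,
#'   `p`, `n`, `significant`, `degenerate`, `computable`.
#' @export
paired_pre_post_test <- function(pre, post, bin = NA_character_,
                                 alpha = 0.05) {
  if (length(pre) != length(post))
    stop("paired_pre_post_test: 'pre' and 'post' must pair up",
         call. = FALSE)
  ok <- is.finite(pre) & is.finite(post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  res <- list(bin = bin, t = NA_real_, p = NA_real_, n = n,
              significant = FALSE, degenerate = FALSE, computable = FALSE)
  class(res) <- "paired_test_result"
  if (n < 2) return(res)
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      res$t <- 0; res$p <- 1; res$computable <- TRUE
    } else {
      res$degenerate <- TRUE
    }
    return(res)
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  res$t <- unname(tt$statistic)
  res$p <- tt$p.value
  res$computable <- TRUE
  res$significant <- res$p < alpha
  res
}

#' @export
print.paired_test_result <- function(x, ...) {
  if (!x$computable && !x$degenerate)
    cat(sprintf("<paired_test> bin %s: not computable (n = %d)\n",
                x$bin, x$n))
  else if (x$degenerate)
    cat(sprintf("<paired_test> bin %s: degenerate (constant difference)\n",
                x$bin))
  else
    cat(sprintf("<paired_test> bin %s: t = %.3f, p = %.4f, n = %d%s\n",
                x$bin, x$t, x$p, x$n, if (x$significant) " *" else ""))
  invisible(x)
}

#' Spearman rank correlation of a metric ratio against the score
#'
#' Ranks with midrank ties and correlates; by default the paired series are
#' the across-animal means per postoperative day (the convention for
#' small-cohort instrument-vs-score comparisons), with per-animal-day
#' pairing available. The p-value uses the t approximation
#' \eqn{t = r_s \sqrt{(n-2)/(1-r_s^2)}} on n - 2 degrees of freedom. An
#' all-tied variable leaves the correlation undefined (flagged).
#'
#' @param ratios A [baseline_ratio()] table (or any data frame with
#'   `animal, day, ratio`), for one metric.
#' @param scores A [score_timecourse()] table (`animal, day, score`).
#' @param pairing `"mean"` (across-animal daily means) or `"animal-day"`.
#' @param metric Metric label carried into the result.
#' @return An object of class `correlation_result`: list with `metric`,
#'   `r_s`, `p`, `n`, `defined`, `pairing`.
#' @export
spearman_metric_vs_score <- function(ratios, scores,
                                     pairing = c("mean", "animal-day"),
                                     metric = NA_character_) {
  pairing <- match.arg(pairing)
  if ("metric" %in% names(ratios) && length(unique(ratios$metric)) > 1)
    stop("spearman_metric_vs_score: pass one metric at a time",
         call. = FALSE)
  ratios <- ratios[is.finite(ratios$ratio), , drop = FALSE]
  scores <- scores[is.finite(scores$score), , drop = FALSE]
  if (!nrow(ratios) || !nrow(scores)) {
    res <- list(metric = metric, r_s = NA_real_, p = NA_real_, n = 0L,
                defined = FALSE, pairing = pairing)
    class(res) <- "correlation_result"
    return(res)
  }
  if (pairing == "mean") {
    r <- stats::aggregate(ratio ~ day, data = ratios, FUN = mean)
    s <- stats::aggregate(score ~ day, data = scores, FUN = mean)
    m <- merge(r, s, by = "day")
  } else {
    m <- merge(ratios[, c("animal", "day", "ratio")],
               scores[, c("animal", "day", "score")],
               by = c("animal", "day"))
  }
  m <- m[is.finite(m$ratio) & is.finite(m$score), , drop = FALSE]
  n <- nrow(m)
  res <- list(metric = metric, r_s = NA_real_, p = NA_real_, n = n,
              defined = FALSE, pairing = pairing)
  class(res) <- "correlation_result"
  if (n < 3) return(res)
  if (stats::sd(m$ratio) == 0 || stats::sd(m$score) == 0) return(res)
  rs <- stats::cor(rank(m$ratio), rank(m$score))
  res$r_s <- rs
  res$defined <- TRUE
  if (abs(rs) >= 1) {
    res$p <- 0
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    res$p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  if (!x$defined)
    cat(sprintf("<correlation> %s: undefined (n = %d)\n", x$metric, x$n))
  else
    cat(sprintf("<correlation> %s: r_s = %.3f, p = %.4g, n = %d (%s)\n",
                x$metric, x$r_s, x$p, x$n, x$pairing))
  invisible(x)
}

#' Full statistical analysis of a study
#'
#' Runs the whole stats layer for every metric: baseline ratios, 3-day
#' binned means with SEM, per-bin paired pre/post t-tests (per-animal
#' pairing: each animal's preoperative baseline against its bin mean), the
#' binned score time course, and Spearman correlations of the four
#' locomotor metric ratios against the neurological score. Correlations
#' are skipped (with a note) when `scores` is `NULL`.
#'
#' @param daily_metrics Long metric table (see [metrics_table()]).
#' @param scores A [score_timecourse()] table, or `NULL`.
#' @param preop_days Integer vector of preoperative days.
#' @param bin_days Bin width (days).
#' @param alpha Significance level.
#' @param pairing Pairing rule for the correlations, see
#'   [spearman_metric_vs_score()].
#' @param anchor_day First day of the first postoperative bin.
#' @return An object of class `study_analysis`: list with `ratios`,
#'   `binned`, `tests` (data frame), `score_binned`, `correlations`
#'   (data frame or `NULL`).
#' @export
analyze_study <- function(daily_metrics, scores = NULL, preop_days,
                          bin_days = 3, alpha = 0.05,
                          pairing = c("mean", "animal-day"),
                          anchor_day = 1L) {
  pairing <- match.arg(pairing)
  ratios <- baseline_ratio(daily_metrics, preop_days)
  binned <- bin_timecourse(ratios, bin_days = bin_days,
                           anchor_day = anchor_day)

  pre <- daily_metrics[daily_metrics$day %in% preop_days &
                         is.finite(daily_metrics$value), , drop = FALSE]
  base <- stats::aggregate(value ~ animal + metric, data = pre, FUN = mean)
  post <- daily_metrics[!(daily_metrics$day %in% preop_days) &
                          is.finite(daily_metrics$value), , drop = FALSE]
  post$bin_idx <- (post$day - anchor_day) %/% bin_days
  tests <- do.call(rbind, lapply(split(post, post[c("metric", "bin_idx")],
                                       drop = TRUE), function(g) {
    if (!nrow(g)) return(NULL)
    bm <- stats::aggregate(value ~ animal, data = g, FUN = mean)
    b <- base[base$metric == g$metric[1], ]
    m <- merge(b, bm, by = "animal", suffixes = c("_pre", "_post"))
    lo <- anchor_day + g$bin_idx[1] * bin_days
    r <- paired_pre_post_test(m$value_pre, m$value_post,
                              bin = paste0(lo, "-", lo + bin_days - 1),
                              alpha = alpha)
    data.frame(metric = g$metric[1], bin = r$bin, day_lo = lo, t = r$t,
               p = r$p, n = r$n, significant = r$significant,
               degenerate = r$degenerate, stringsAsFactors = FALSE)
  }))
  if (is.null(tests))
    tests <- data.frame(metric = character(0), bin = character(0),
                        day_lo = numeric(0), t = numeric(0), p = numeric(0),
                        n = integer(0), significant = logical(0),
                        degenerate = logical(0))
  tests <- tests[order(tests$metric, tests$day_lo), ]
  rownames(tests) <- NULL

  score_binned <- NULL
  correlations <- NULL
  if (!is.null(scores)) {
    post_scores <- scores[scores$day >= anchor_day, , drop = FALSE]
    score_binned <- bin_timecourse(post_scores, bin_days = bin_days,
                                   anchor_day = anchor_day)
    corr_metrics <- c("distance_cm", "median_moving_speed_cm_s",
                      "activity_time_s", "jump_climb_frames")
    correlations <- do.call(rbind, lapply(corr_metrics, function(mn) {
      r <- spearman_metric_vs_score(
        ratios[ratios$metric == mn, , drop = FALSE], scores,
        pairing = pairing, metric = mn)
      data.frame(metric = mn, r_s = r$r_s, p = r$p, n = r$n,
                 defined = r$defined, stringsAsFactors = FALSE)
    }))
  }
  out <- list(ratios = ratios, binned = binned, tests = tests,
              score_binned = score_binned, correlations = correlations,
              preop_days = preop_days, bin_days = bin_days, alpha = alpha,
              pairing = pairing, anchor_day = anchor_day)
  class(out) <- "study_analysis"
  out
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("<study_analysis>\n")
  cat(sprintf("  %d animals, preop days {%s}, %d-day bins, alpha %.2f\n",
              length(unique(x$ratios$animal)),
              paste(x$preop_days, collapse = ", "), x$bin_days, x$alpha))
  cat("  binned ratio means (first and last bin per metric):\n")
  for (mn in unique(x$binned$metric)) {
    b <- x$binned[x$binned$metric == mn & x$binned$n > 0, ]
    cat(sprintf("    %-26s %s: %.3f -> %s: %.3f\n", mn,
                b$bin[1], b$mean[1], b$bin[nrow(b)], b$mean[nrow(b)]))
  }
  if (!is.null(x$correlations)) {
    cat("  Spearman vs neurological score:\n")
    for (i in seq_len(nrow(x$correlations)))
      cat(sprintf("    %-26s r_s = %+.3f, p = %.4g, n = %d\n",
                  x$correlations$metric[i], x$correlations$r_s[i],
                  x$correlations$p[i], x$correlations$n[i]))
  } else cat("  correlations skipped (no scores supplied)\n")
  invisible(x)
}
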