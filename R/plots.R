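#' Plot a binned ratio or score time course
#'
#' Bars of bin means with SEM whiskers — the standard recovery time-course
#' display (baseline ratio 1.0, or score 0, marked with a dashed line).
#'
#' @param binned A [bin_timecourse()] table; if it has a `metric` column,
#'   `metric` selects one.
#' @param metric Metric to plot when several are present.
#' @param baseline_level Reference level drawn as a dashed line (1 for
#'   ratios, 0 for scores).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_binned_timecourse <- function(binned, metric = NULL,
                                   baseline_level = 1, ...) {
  b <- binned
  if (!is.null(metric) && "metric" %in% names(b))
    b <- b[b$metric == metric, , drop = FALSE]
  b <- b[b$n > 0, , drop = FALSE]
  ylim <- range(0, baseline_level, b$mean + ifelse(is.na(b$sem), 0, b$sem),
                na.rm = TRUE) * c(1, 1.1)
  mid <- graphics::barplot(b$mean, names.arg = b$bin, ylim = ylim,
                           xlab = "postoperative days", col = "grey80",
                           main = metric, ...)
  ok <- !is.na(b$sem) & b$sem > 0
  if (any(ok))
    graphics::arrows(mid[ok], b$mean[ok] - b$sem[ok], mid[ok],
                     b$mean[ok] + b$sem[ok], angle = 90, code = 3,
                     length = 0.04)
  graphics::abline(h = baseline_level, lty = 2)
  invisible(b)
}

#' Scatter plot of a metric ratio against the neurological score
#'
#' Per-animal-day points, discriminated by animal, with the Spearman
#' correlation in the title.
#'
#' @param ratios A [baseline_ratio()] table for one metric.
#' @param scores A [score_timecourse()] table.
#' @param metric Metric label for the title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_metric_vs_score <- function(ratios, scores, metric = NULL, ...) {
  if (!is.null(metric) && "metric" %in% names(ratios))
    ratios <- ratios[ratios$metric == metric, , drop = FALSE]
  m <- merge(ratios[, c("animal", "day", "ratio")],
             scores[, c("animal", "day", "score")],
             by = c("animal", "day"))
  m <- m[is.finite(m$ratio) & is.finite(m$score), , drop = FALSE]
  cr <- spearman_metric_vs_score(ratios, scores, pairing = "animal-day",
                                 metric = metric)
  ids <- sort(unique(m$animal))
  graphics::plot(jitter(m$score, 0.3), m$ratio,
                 col = match(m$animal, ids), pch = 16,
                 xlab = "neurological score",
                 ylab = "postoperative / preoperative ratio",
                 main = sprintf("%s  (r_s = %.2f, p = %.3g)", metric,
                                cr$r_s, cr$p), ...)
  graphics::legend("topright", legend = ids, col = seq_along(ids),
                   pch = 16, bty = "n")
  invisible(cr)
}
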