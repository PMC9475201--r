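make_daily <- function(animal, days, metric, values) {
  data.frame(animal = animal, day = days, metric = metric, value = values,
             stringsAsFactors = FALSE)
}

test_that("baseline ratios divide by the preoperative mean", {
  daily <- rbind(
    make_daily("a", c(-3, -2, -1), "distance_cm", c(100, 110, 120)),
    make_daily("a", c(2, 3), "distance_cm", c(55, 110)))
  r <- baseline_ratio(daily, preop_days = -3:-1)
  expect_equal(r$baseline, c(110, 110))
  expect_equal(r$ratio, c(0.5, 1.0))
})

test_that("a zero baseline flags ratios missing without stopping the run", {
  daily <- rbind(
    make_daily("a", c(-2, -1), "jump_climb_frames", c(0, 0)),
    make_daily("a", 2, "jump_climb_frames", 3),
    make_daily("a", c(-2, -1), "distance_cm", c(100, 100)),
    make_daily("a", 2, "distance_cm", 50))
  expect_warning(r <- baseline_ratio(daily, preop_days = c(-2, -1)),
                 "zero or missing baseline")
  expect_true(is.na(r$ratio[r$metric == "jump_climb_frames"]))
  expect_equal(r$ratio[r$metric == "distance_cm"], 0.5)
})

test_that("3-day bins report mean, SEM and n", {
  s <- data.frame(day = c(2, 2, 3), ratio = c(0.4, 0.4, 0.4))
  b <- bin_timecourse(s)
  expect_equal(b$bin, "1-3")
  expect_equal(b$mean, 0.4)
  expect_equal(b$sem, 0)
  expect_equal(b$n, 3)

  s2 <- data.frame(day = c(4, 5, 6), ratio = c(0.2, 0.4, 0.6))
  b2 <- bin_timecourse(s2)
  expect_equal(b2$mean[b2$bin == "4-6"], 0.4)
  expect_equal(b2$sem[b2$bin == "4-6"], 0.2 / sqrt(3), tolerance = 1e-12)
  # the skipped first window is reported empty, with missing mean
  expect_equal(b2$n[b2$bin == "1-3"], 0)
  expect_true(is.na(b2$mean[b2$bin == "1-3"]))

  # day 28 alone in the final [28-30] bin: n = number of animals
  s3 <- data.frame(day = rep(c(26, 27, 28), each = 3),
                   ratio = runif(9, 0.8, 1.2))
  b3 <- bin_timecourse(s3)
  expect_equal(b3$n[b3$bin == "28-30"], 3)
})

test_that("paired pre/post t-test handles degenerate inputs", {
  same <- paired_pre_post_test(c(3, 5, 7), c(3, 5, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  const <- paired_pre_post_test(c(3, 5, 7), c(2, 4, 6))   # diffs all -1
  expect_true(const$degenerate)
  expect_true(is.na(const$t))

  short <- paired_pre_post_test(10, 5)
  expect_false(short$computable)
})

test_that("paired t matches the closed-form oracle", {
  pre <- c(10, 12, 14); post <- c(6, 7, 8)
  r <- paired_pre_post_test(pre, post)
  o <- brute_paired_t(pre, post)
  expect_equal(r$t, o$t, tolerance = 1e-12)
  expect_equal(r$p, o$p, tolerance = 1e-12)
  expect_true(r$significant == (o$p < 0.05))
})

test_that("Spearman correlation: exact values, ties, degenerate input", {
  ratios <- data.frame(animal = "a", day = 2:7,
                       ratio = c(0.9, 0.8, 0.6, 0.5, 0.3, 0.2))
  scores <- data.frame(animal = "a", day = 2:7, score = 0:5)
  r <- spearman_metric_vs_score(ratios, scores, pairing = "animal-day")
  expect_equal(r$r_s, -1)
  expect_equal(r$p, 0)

  # constant score -> undefined, flagged
  sc <- scores; sc$score <- 2
  ru <- spearman_metric_vs_score(ratios, sc, pairing = "animal-day")
  expect_false(ru$defined)
  expect_true(is.na(ru$r_s))

  # tie handling equals brute-force midrank Pearson
  ratios$ratio <- c(0.9, 0.8, 0.8, 0.5, 0.3, 0.2)
  rt <- spearman_metric_vs_score(ratios, scores, pairing = "animal-day")
  expect_equal(rt$r_s, brute_spearman(ratios$ratio, scores$score),
               tolerance = 1e-12)
})

test_that("Spearman and paired t agree with oracles on all small n", {
  set.seed(81)
  for (case in 1:40) {
    n <- sample(3:8, 1)
    x <- sample(seq(0.1, 2, by = 0.1), n, replace = TRUE)  # ties likely
    y <- sample(0:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    ratios <- data.frame(animal = "a", day = seq_len(n), ratio = x)
    scores <- data.frame(animal = "a", day = seq_len(n), score = y)
    r <- spearman_metric_vs_score(ratios, scores, pairing = "animal-day")
    expect_equal(r$r_s, brute_spearman(x, y), tolerance = 1e-10)
    expect_equal(r$r_s, unname(cor(x, y, method = "spearman")),
                 tolerance = 1e-10)
    if (abs(r$r_s) < 1) {
      tstat <- r$r_s * sqrt((n - 2) / (1 - r$r_s^2))
      expect_equal(r$p, 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
    }

    pre <- rnorm(n, 10); post <- rnorm(n, 8)
    rp <- paired_pre_post_test(pre, post)
    op <- brute_paired_t(pre, post)
    expect_equal(rp$t, op$t, tolerance = 1e-10)
    expect_equal(rp$p, op$p, tolerance = 1e-10)
  }
})

test_that("mean pairing correlates across-animal daily means", {
  ratios <- rbind(
    data.frame(animal = "a", day = 2:5, ratio = c(0.2, 0.4, 0.6, 0.8)),
    data.frame(animal = "b", day = 2:5, ratio = c(0.4, 0.6, 0.8, 1.0)))
  scores <- rbind(
    data.frame(animal = "a", day = 2:5, score = c(4, 3, 2, 1)),
    data.frame(animal = "b", day = 2:5, score = c(4, 2, 2, 0)))
  r <- spearman_metric_vs_score(ratios, scores, pairing = "mean")
  expect_equal(r$n, 4)
  expect_equal(r$r_s, -1)
})

test_that("null (healthy-equal-to-baseline) data stay near ratio 1", {
  set.seed(82)
  g <- cage_geometry()
  p <- behavior_params()
  daily <- do.call(rbind, lapply(c("a", "b", "c"), function(an) {
    do.call(rbind, lapply(c(-3:-1, 2:7), function(d) {
      s <- simulate_session(p, g, duration_s = 120, fps = 5, seed = NULL,
                            animal_id = an, day_index = d)
      m <- session_metrics(s$trajectory, geometry = g)
      data.frame(animal = an, day = d, metric = "distance_cm",
                 value = m$distance_cm)
    }))
  }))
  ana <- analyze_study(daily, NULL, preop_days = -3:-1)
  b <- ana$binned[ana$binned$n > 0, ]
  expect_true(all(abs(b$mean - 1) < 3 * b$sem + 0.35))
})
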