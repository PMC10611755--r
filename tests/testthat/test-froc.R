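scene_match <- function(best_scores, fp_scores, n_scans) {
  # build a match_result-shaped scene through the public geometry:
  # one target per best score on its own scan, FPs on scan 1
  targets <- do.call(rbind, lapply(seq_along(best_scores), function(i) {
    make_target(sprintf("s%03d", i), sprintf("n%02d", i), 0, d = 10)
  }))
  scans <- make_manifest(n_scans)
  preds <- rbind(
    do.call(rbind, lapply(which(!is.na(best_scores)), function(i) {
      make_pred(sprintf("s%03d", i), 0, score = best_scores[i])
    })),
    if (length(fp_scores)) {
      make_pred("s001", 200 + 50 * seq_along(fp_scores), score = fp_scores)
    })
  match_predictions(preds, make_view(targets, scans = scans))
}

test_that("FROC operating points enumerate thresholds with an anchor", {
  m <- scene_match(0.8, numeric(0), 10)
  cv <- froc_curve(m)
  expect_equal(cv$points$threshold, c(Inf, 0.8))
  expect_equal(cv$points$fp_per_scan, c(0, 0))
  expect_equal(cv$points$sensitivity, c(0, 1))

  m2 <- scene_match(c(0.9, 0.6), c(0.7, 0.7, 0.5), 4)
  cv2 <- froc_curve(m2)
  i <- which(cv2$points$threshold == 0.6)
  expect_equal(cv2$points$sensitivity[i], 1.0)
  expect_equal(cv2$points$fp_per_scan[i], 0.5)

  expect_error(froc_curve(match_predictions(make_pred("s001", 0),
    make_view(make_target("s001", "n01", 0)[0, ],
              scans = make_manifest(1)))), "no target")
})

test_that("FROC invariants hold on random scored scenes", {
  withr::local_seed(606)
  for (rep in 1:20) {
    nt <- sample(2:20, 1)
    best <- ifelse(runif(nt) < 0.8, runif(nt), NA)
    fp <- runif(sample(0:30, 1))
    cv <- froc_curve(scene_match(best, fp, nt))
    expect_true(all(diff(cv$points$threshold) < 0))
    expect_true(all(diff(cv$points$fp_per_scan) >= 0))
    expect_true(all(diff(cv$points$sensitivity) >= 0))
  }
})

test_that("sensitivity_at interpolates linearly and extends constantly", {
  cv <- froc_curve_from_points(1.0, 0.8)
  expect_equal(sensitivity_at(cv, 0.5), 0.4)

  cv2 <- froc_curve_from_points(c(0.5, 2.0), c(0.6, 0.95))
  expect_equal(sensitivity_at(cv2, 8), 0.95)      # carry forward
  expect_equal(sensitivity_at(cv2, 0.25), 0.3)    # from the zero anchor
  # non-decreasing in the queried rate
  q <- sensitivity_at(cv2, sort(runif(20, 0.01, 10)))
  expect_true(all(diff(q) >= 0))
})

test_that("sensitivity_at agrees with dense re-thresholding on random scenes", {
  withr::local_seed(707)
  for (rep in 1:10) {
    nt <- 15
    best <- ifelse(runif(nt) < 0.8, runif(nt), NA)
    fp <- runif(40)
    n_scans <- 20
    m <- scene_match(best, fp, n_scans)
    cv <- froc_curve(m)
    rates <- c(0.125, 0.25, 0.5, 1, 1.5, 2)
    got <- sensitivity_at(cv, rates)
    # oracle: counts over a dense threshold grid, then linear interpolation
    grid <- sort(unique(c(best[!is.na(best)], fp, seq(0, 1, by = 1e-3))),
                 decreasing = TRUE)
    fps_g <- vapply(grid, function(t) sum(fp >= t) / n_scans, 0)
    sen_g <- vapply(grid, function(t) sum(best >= t, na.rm = TRUE) / nt, 0)
    keep <- !duplicated(fps_g, fromLast = TRUE)
    want <- approx(c(0, fps_g[keep]), c(0, sen_g[keep]), xout = rates,
                   rule = 2, ties = max)$y
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("CPM is the mean sensitivity over the seven predefined rates", {
  s1 <- c(60.8, 72.1, 82.1, 90.9, 95.6, 97.5, 99.1) / 100
  cv <- froc_curve_from_points(c(0.125, 0.25, 0.5, 1, 2, 4, 8), s1)
  expect_equal(nodeval:::as_percent(cpm(cv)), 85.4)
  expect_equal(cpm(froc_curve_from_points(c(0.125, 8), c(1, 1))), 1.0)
  # invariant under duplication of every scan
  m <- scene_match(c(0.9, 0.6, NA), c(0.7, 0.5), 4)
  fp <- m$predictions$score[m$predictions$label == "FP"]
  pts1 <- nodeval:::froc_points_from_scores(m$targets$best_score, fp, 4, 3)
  pts2 <- nodeval:::froc_points_from_scores(rep(m$targets$best_score, 2),
                                            rep(fp, 2), 8, 6)
  expect_equal(pts1, pts2)
})

test_that("threshold calibration picks the deepest point within budget", {
  cv <- froc_curve_from_points(c(0.4, 0.9, 1.3), c(0.5, 0.7, 0.9),
                               thresholds = c(0.8, 0.6, 0.4))
  cal <- calibrate_threshold(cv, 1.0)
  expect_equal(cal$threshold, 0.6)
  expect_equal(cal$fp_per_scan, 0.9)
  expect_equal(cal$sensitivity, 0.7)

  # budget below the smallest nonzero FP/s: the zero anchor
  cal0 <- calibrate_threshold(cv, 0.2)
  expect_equal(cal0$sensitivity, 0)

  # engineered set: exactly 100 FPs over 100 scans at score >= 0.5
  withr::local_seed(808)
  best <- runif(50, 0.55, 1)
  fp <- c(0.5, runif(99, 0.51, 1), runif(300, 0, 0.45))
  cv2 <- froc_curve(scene_match(best, fp, 100))
  cal2 <- calibrate_threshold(cv2, 1.0)
  expect_lte(cal2$threshold, 0.5)
  expect_equal(cal2$fp_per_scan, 1.0)
})

test_that("point sensitivity reproduces printed percentages", {
  expect_equal(point_sensitivity(82, 87), 94.3)
  expect_equal(point_sensitivity(290, 319), 90.9)
  expect_equal(point_sensitivity(0, 5), 0.0)
  expect_error(point_sensitivity(1, 0), "n_targets")
  expect_error(point_sensitivity(6, 5), "n_detected")
})

test_that("permutation p-values match exact enumeration", {
  expect_equal(paired_permutation_test(rep(1, 10), rep(1, 10),
                                       seed = 1)$p_value, 1.0)

  a <- rep(1, 8); b <- rep(0, 8)
  p_exact <- exact_permutation_p(a, b)
  expect_equal(p_exact, 2 / 256)
  res <- paired_permutation_test(a, b, n_iter = 4000, seed = 2)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 2 / 4001)

  # concordant pairs contribute nothing to the exact p
  a2 <- c(a, rep(1, 100)); b2 <- c(b, rep(1, 100))
  # enumeration over the 8 discordant pairs only (concordant d = 0)
  expect_equal(exact_permutation_p(a2[1:8], b2[1:8]), p_exact)
  res2 <- paired_permutation_test(a2, b2, n_iter = 4000, seed = 3)
  expect_lt(abs(res2$p_value - p_exact), 3 * se + 2 / 4001)

  expect_error(paired_permutation_test(1:3, 1:2, seed = 1), "equal length")
})

test_that("permutation p-values are super-uniform under the null", {
  withr::local_seed(909)
  p <- replicate(200, {
    a <- rbinom(30, 1, 0.7); b <- rbinom(30, 1, 0.7)
    paired_permutation_test(a, b, n_iter = 199,
                            seed = sample.int(1e6, 1))$p_value
  })
  for (alpha in c(0.05, 0.1)) {
    slack <- 3 * sqrt(alpha * (1 - alpha) / 200)
    expect_lte(mean(p <= alpha), alpha + slack)
  }
})

test_that("scan-level bootstrap is deterministic and degenerates correctly", {
  withr::local_seed(111)
  # identical results on every scan -> zero-width CI
  targets <- do.call(rbind, lapply(1:10, function(i) {
    make_target(sprintf("s%03d", i), sprintf("n%02d", i), 0, d = 10)
  }))
  view <- make_view(targets, scans = make_manifest(10))
  preds <- make_pred(sprintf("s%03d", 1:10), 0, score = 0.9)
  ci <- bootstrap_ci(preds, view, fp_rates = c(0.5, 1), n_boot = 50, seed = 5)
  expect_equal(ci$ci[1, ], ci$ci[2, ])
  expect_equal(ci$cpm_ci[1], ci$cpm_ci[2])

  ci2 <- bootstrap_ci(preds, view, fp_rates = c(0.5, 1), n_boot = 50, seed = 5)
  expect_identical(ci, ci2)

  # n_boot = 1 with a fixed seed equals the directly recomputed resample
  sc <- random_scene(n_targets = 5, n_preds = 12)
  m <- match_predictions(sc$preds, sc$view)
  ci3 <- bootstrap_ci(sc$preds, sc$view, fp_rates = 1, n_boot = 1, seed = 7)
  sm <- nodeval:::match_by_scan(m, sc$view$scans$scan_id)
  want <- withr::with_seed(7, {
    idx <- sample.int(nrow(sc$view$scans), nrow(sc$view$scans), replace = TRUE)
    nodeval:::boot_replicate_stats(sm, idx, 1)
  })
  expect_equal(unname(ci3$ci[1, 1]), want[1])
  expect_equal(unname(ci3$ci[2, 1]), want[1])
})
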