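#' @name froc_stats
#' @title FROC analysis: curves, CPM, calibration, bootstrap, permutation test
#'
#' @description
#' Free-response ROC (FROC) analysis sweeps a score threshold and plots
#' lesion-level sensitivity against the mean number of false positives per
#' scan (FP/s). Sensitivity is summarised at seven predefined rates
#' (0.125, 0.25, 0.5, 1, 2, 4, 8 FP/s); their mean is the Competition
#' Performance Metric (CPM). Confidence intervals come from scan-level
#' bootstrap resampling; reader-vs-AI differences are tested with a paired
#' permutation test over per-nodule detection indicators.
NULL

# Operating points from per-target best scores (NA = undetected) and FP
# scores. One point per distinct finite score, thresholds descending, plus
# the (Inf, 0, 0) anchor so interpolation below the smallest achieved FP/s
# starts from zero.
froc_points_from_scores <- function(best_scores, fp_scores, n_scans, n_targets) {
  tp <- best_scores[!is.na(best_scores)]
  all <- c(tp, fp_scores)
  anchor <- data.frame(threshold = Inf, fp_per_scan = 0, sensitivity = 0)
  if (length(all) == 0) return(anchor)
  o <- order(all, decreasing = TRUE)
  s <- all[o]
  is_tp <- c(rep(TRUE, length(tp)), rep(FALSE, length(fp_scores)))[o]
  cum_tp <- cumsum(is_tp)
  cum_fp <- cumsum(!is_tp)
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  rbind(anchor, data.frame(threshold = s[last],
                           fp_per_scan = cum_fp[last] / n_scans,
                           sensitivity = cum_tp[last] / n_targets))
}

new_froc_curve <- function(points, n_scans, n_targets) {
  rownames(points) <- NULL
  structure(list(points = points, n_scans = n_scans, n_targets = n_targets),
            class = "froc_curve")
}

#' FROC curve from a match result
#'
#' For each distinct score threshold `t` (descending), sensitivity is the
#' fraction of target nodules whose best matching score is `>= t`, and the
#' FP/s is the number of false-positive predictions scoring `>= t` divided
#' by the number of scans. An anchor point at threshold `Inf` (0 FP/s,
#' 0 sensitivity) is prepended.
#'
#' @param match A `match_result` from [match_predictions()].
#' @return An object of class `froc_curve`: list with `points`
#'   (`threshold`, `fp_per_scan`, `sensitivity`), `n_scans`, `n_targets`.
#' @export
froc_curve <- function(match) {
  stopifnot(inherits(match, "match_result"))
  if (match$n_scans <= 0) stop("no scans", call. = FALSE)
  if (match$n_targets == 0) {
    stop("no target nodules in this subset; sensitivity is undefined - ",
         "summarise the false-positive rate alone instead", call. = FALSE)
  }
  fp_scores <- match$predictions$score[match$predictions$label == "FP"]
  pts <- froc_points_from_scores(match$targets$best_score, fp_scores,
                                 match$n_scans, match$n_targets)
  new_froc_curve(pts, match$n_scans, match$n_targets)
}

#' Assemble a FROC curve from externally supplied operating points
#'
#' Useful for worked examples and for re-analysing published operating
#' points: supply the FP/s values and sensitivities directly.
#'
#' @param fp_per_scan Non-decreasing FP/s values.
#' @param sensitivity Sensitivities in `[0, 1]`, same length.
#' @param thresholds Optional strictly decreasing thresholds; defaults to a
#'   descending ramp.
#' @param n_scans,n_targets Problem sizes (informational).
#' @return A `froc_curve`.
#' @export
froc_curve_from_points <- function(fp_per_scan, sensitivity,
                                   thresholds = NULL,
                                   n_scans = NA_integer_,
                                   n_targets = NA_integer_) {
  stopifnot(length(fp_per_scan) == length(sensitivity),
            !is.unsorted(fp_per_scan),
            all(sensitivity >= 0 & sensitivity <= 1))
  if (is.null(thresholds)) {
    thresholds <- seq(1, 0, length.out = length(fp_per_scan))
  }
  pts <- rbind(data.frame(threshold = Inf, fp_per_scan = 0, sensitivity = 0),
               data.frame(threshold = thresholds, fp_per_scan = fp_per_scan,
                          sensitivity = sensitivity))
  new_froc_curve(pts, n_scans, n_targets)
}

#' @export
print.froc_curve <- function(x, ...) {
  cat(sprintf("FROC curve: %d operating points, %s scans, %s targets\n",
              nrow(x$points), x$n_scans, x$n_targets))
  cat(sprintf("  max FP/s %.3f, max sensitivity %.3f\n",
              max(x$points$fp_per_scan), max(x$points$sensitivity)))
  invisible(x)
}

#' Sensitivity at given false-positive rates
#'
#' Linear interpolation of sensitivity in FP/s between adjacent operating
#' points. Beyond the largest achieved FP/s the final sensitivity is
#' carried forward (a system producing few false positives is not
#' penalised at high-rate queries); below the smallest, interpolation
#' starts from the zero anchor.
#'
#' @param curve A `froc_curve`.
#' @param fp_rates Positive FP/s values to query.
#' @return Numeric vector of sensitivities in `[0, 1]`.
#' @export
sensitivity_at <- function(curve, fp_rates = DEFAULT_FP_RATES) {
  stopifnot(inherits(curve, "froc_curve"), all(fp_rates > 0))
  pts <- curve$points
  # per distinct FP/s keep the best sensitivity (deepest threshold)
  agg <- tapply(pts$sensitivity, pts$fp_per_scan, max)
  x <- as.numeric(names(agg))
  y <- as.numeric(agg)
  if (length(x) == 1) return(rep(y, length(fp_rates)))
  stats::approx(x, y, xout = fp_rates, rule = 2, ties = max)$y
}

#' Competition Performance Metric
#'
#' The mean sensitivity over the predefined FP/s rates (default 0.125,
#' 0.25, 0.5, 1, 2, 4, 8).
#'
#' @inheritParams sensitivity_at
#' @return A fraction in `[0, 1]`.
#' @export
cpm <- function(curve, fp_rates = DEFAULT_FP_RATES) {
  mean(sensitivity_at(curve, fp_rates))
}

#' Sensitivity report at the predefined rates
#'
#' @inheritParams sensitivity_at
#' @return An object of class `sensitivity_report`: list with `fp_rates`,
#'   `sensitivities` and `cpm` (= their mean), plus `ci` once filled in by
#'   [bootstrap_ci()].
#' @export
sensitivity_report <- function(curve, fp_rates = DEFAULT_FP_RATES) {
  s <- sensitivity_at(curve, fp_rates)
  structure(list(fp_rates = fp_rates, sensitivities = s, cpm = mean(s),
                 ci = NULL),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity at predefined FP/s rates (%):\n")
  print(setNames(as_percent(x$sensitivities), format(x$fp_rates)))
  cat(sprintf("CPM: %.1f\n", as_percent(x$cpm)))
  invisible(x)
}

#' Calibrate a detection threshold to a target FP/s
#'
#' Picks the deepest operating point still within budget: the smallest
#' threshold whose FP/s does not exceed the target. Reported table
#' sensitivities at a rate use interpolation ([sensitivity_at()]); the
#' calibrated threshold is what a deployment would actually set, so both
#' are exposed.
#'
#' @param curve A `froc_curve`.
#' @param target_fp_per_scan Positive FP/s budget (default 1).
#' @return List with `threshold`, `fp_per_scan` and `sensitivity` of the
#'   achieved operating point.
#' @export
calibrate_threshold <- function(curve, target_fp_per_scan = 1.0) {
  stopifnot(inherits(curve, "froc_curve"), target_fp_per_scan > 0)
  pts <- curve$points
  if (nrow(pts) == 0) stop("empty FROC curve", call. = FALSE)
  ok <- which(pts$fp_per_scan <= target_fp_per_scan + 1e-12)
  i <- ok[length(ok)]  # deepest admissible point (thresholds descending)
  list(threshold = pts$threshold[i], fp_per_scan = pts$fp_per_scan[i],
       sensitivity = pts$sensitivity[i])
}

#' Point sensitivity as a printed percentage
#'
#' @param n_detected,n_targets Detection counts, `0 <= n_detected <=
#'   n_targets`, `n_targets > 0`.
#' @return `100 * n_detected / n_targets`, rounded half-up to 1 decimal.
#' @examples
#' point_sensitivity(82, 87) # 94.3
#' @export
point_sensitivity <- function(n_detected, n_targets) {
  if (any(n_targets <= 0)) stop("n_targets must be > 0", call. = FALSE)
  if (any(n_detected < 0 | n_detected > n_targets)) {
    stop("need 0 <= n_detected <= n_targets", call. = FALSE)
  }
  round_half_up(100 * n_detected / n_targets, 1)
}

# Per-scan match summaries for scan-level resampling: for each scan the
# best scores of its targets (NA = undetected) and its FP scores.
match_by_scan <- function(match, scan_ids) {
  best <- split(match$targets$best_score,
                factor(match$targets$scan_id, levels = scan_ids))
  fp <- match$predictions[match$predictions$label == "FP", ]
  fps <- split(fp$score, factor(fp$scan_id, levels = scan_ids))
  list(best = best, fp = fps, scan_ids = scan_ids)
}

boot_replicate_stats <- function(sm, idx, fp_rates, target_fp = NULL) {
  best <- unlist(sm$best[idx], use.names = FALSE)
  fpsc <- unlist(sm$fp[idx], use.names = FALSE)
  n_targets <- length(best)
  if (n_targets == 0) return(NULL)
  pts <- froc_points_from_scores(best, fpsc, length(idx), n_targets)
  curve <- new_froc_curve(pts, length(idx), n_targets)
  s <- sensitivity_at(curve, fp_rates)
  out <- c(s, mean(s))
  if (!is.null(target_fp)) {
    cal <- calibrate_threshold(curve, target_fp)
    out <- c(out, cal$sensitivity, cal$fp_per_scan)
  }
  out
}

#' Scan-level bootstrap confidence intervals
#'
#' Resamples scan ids with replacement; a scan drawn `k` times contributes
#' its targets and predictions `k` times. The FROC curve and the queried
#' sensitivities are recomputed per replicate; intervals are the 2.5th and
#' 97.5th percentiles. Replicates containing zero targets are redrawn (the
#' count is reported).
#'
#' @param predictions Prediction data.frame.
#' @param view A `subset_view`.
#' @param fp_rates FP/s values to summarise (default the seven predefined).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @param conf Confidence level (default 0.95).
#' @return List with `fp_rates`, `ci` (2 x length(fp_rates) matrix of
#'   bounds), `cpm_ci`, `n_boot`, `n_redrawn`, `seed`.
#' @export
bootstrap_ci <- function(predictions, view, fp_rates = DEFAULT_FP_RATES,
                         n_boot = 1000, seed, conf = 0.95) {
  stopifnot(n_boot >= 1)
  match <- match_predictions(predictions, view)
  bootstrap_ci_from_match(match, view$scans$scan_id, fp_rates, n_boot, seed,
                          conf)
}

bootstrap_ci_from_match <- function(match, scan_ids, fp_rates = DEFAULT_FP_RATES,
                                    n_boot = 1000, seed, conf = 0.95) {
  sm <- match_by_scan(match, scan_ids)
  n <- length(scan_ids)
  stats_mat <- matrix(NA_real_, nrow = n_boot, ncol = length(fp_rates) + 1)
  n_redrawn <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        st <- boot_replicate_stats(sm, idx, fp_rates)
        if (!is.null(st)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 1000L) {
          stop("bootstrap: too many zero-target replicates", call. = FALSE)
        }
      }
      stats_mat[b, ] <- st
    }
  })
  alpha <- (1 - conf) / 2
  qs <- apply(stats_mat, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  list(fp_rates = fp_rates,
       ci = qs[, seq_along(fp_rates), drop = FALSE],
       cpm_ci = qs[, length(fp_rates) + 1],
       n_boot = n_boot, n_redrawn = n_redrawn, seed = seed)
}

#' Two-sided paired permutation test on per-nodule detections
#'
#' The statistic is the difference in detection fractions,
#' `mean(a) - mean(b)`. The null distribution is generated by independently
#' swapping each pair (a sign flip of the per-nodule difference); the
#' two-sided p-value uses the add-one correction
#' `p = (1 + #\{|T_perm| >= |T_obs|\}) / (1 + n_iter)`, so `p > 0` always.
#'
#' @param detect_a,detect_b Equal-length binary (or logical) vectors over
#'   the same target nodules.
#' @param n_iter Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return An object of class `permutation_result`: list with `statistic`,
#'   `p_value`, `n_iter`, `seed`.
#' @export
paired_permutation_test <- function(detect_a, detect_b, n_iter = 1000, seed) {
  a <- as.numeric(detect_a)
  b <- as.numeric(detect_b)
  if (length(a) != length(b)) {
    stop("detection vectors must have equal length", call. = FALSE)
  }
  if (length(a) == 0) stop("empty detection vectors", call. = FALSE)
  d <- a - b
  t_obs <- mean(d)
  n <- length(d)
  withr::with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_iter, replace = TRUE),
                    nrow = n_iter, ncol = n)
    t_perm <- as.vector(signs %*% d) / n
  })
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_iter)
  structure(list(statistic = t_obs, p_value = p, n_iter = n_iter,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Paired permutation test: diff = %+.4f, p = %s (%d iterations)\n",
              x$statistic, format_p(x$p_value), x$n_iter))
  invisible(x)
}

# Table-style p formatting: 3 decimals with a "<0.001" floor.
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", round_half_up(p, 3)))
}
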