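#' @name reader_compare
#' @title Reader-vs-AI comparison with leave-one-out references
#'
#' @description
#' Each reader is scored against the consensus of the remaining readers
#' (so no self-confirmation), per nodule category. The AI is matched
#' against the same leave-one-out subset view, recalibrated to the target
#' FP/s for each comparison, and the per-nodule detection indicators are
#' compared with a paired permutation test.
NULL

# Shared scan-level bootstrap over a reader match and an AI match at a
# fixed calibrated threshold. Returns percentile CIs for reader
# sensitivity & FP/s and AI sensitivity & FP/s.
boot_reader_ai <- function(reader_match, ai_match, scan_ids, threshold,
                           n_boot, seed, conf = 0.95) {
  sid_f <- factor(scan_ids, levels = scan_ids)
  r_det <- split(reader_match$targets$detected,
                 factor(reader_match$targets$scan_id, levels = scan_ids))
  r_fp <- table(factor(reader_match$fp_scans, levels = scan_ids))
  sm <- match_by_scan(ai_match, scan_ids)
  n <- length(scan_ids)
  out <- matrix(NA_real_, n_boot, 4)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        det <- unlist(r_det[idx], use.names = FALSE)
        if (length(det) > 0) break
      }
      best <- unlist(sm$best[idx], use.names = FALSE)
      fpsc <- unlist(sm$fp[idx], use.names = FALSE)
      out[b, ] <- c(mean(det),
                    sum(r_fp[idx]) / n,
                    mean(!is.na(best) & best >= threshold - 1e-12),
                    sum(fpsc >= threshold - 1e-12) / n)
    }
  })
  alpha <- (1 - conf) / 2
  qs <- apply(out, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  list(reader_sens_ci = qs[, 1], reader_fp_ci = qs[, 2],
       ai_sens_ci = qs[, 3], ai_fp_ci = qs[, 4])
}

#' Operating point of one reader against the leave-one-out reference
#'
#' @param reader_id Reader to evaluate.
#' @param annotations Full-panel annotation data.frame.
#' @param manifest Manifest data.frame.
#' @param registry Registry data.frame or NULL.
#' @param min_diameter,class_filter Subset selection (see
#'   [select_subset()]).
#' @param min_agreement Majority threshold among the remaining readers.
#' @param n_boot Bootstrap replicates for the CIs.
#' @param seed Integer seed.
#' @return An object of class `reader_point`: `reader_id`, `class_filter`,
#'   `sensitivity` (fraction) with `sens_ci`, `fp_per_scan` with `fp_ci`,
#'   `n_targets`.
#' @export
reader_performance <- function(reader_id, annotations, manifest,
                               registry = NULL, min_diameter = 3,
                               class_filter = "all", min_agreement = 3,
                               n_boot = 1000, seed = 1L) {
  ref <- leave_one_out_reference(annotations, manifest, registry, reader_id,
                                 min_agreement)
  view <- select_subset(ref, min_diameter, class_filter)
  own <- annotations[annotations$reader_id == reader_id, , drop = FALSE]
  rm <- match_reader(own, view)
  n_targets <- nrow(rm$targets)
  sens <- if (n_targets > 0) mean(rm$targets$detected) else NA_real_
  fps <- rm$fp_count / rm$n_scans

  r_det <- split(rm$targets$detected,
                 factor(rm$targets$scan_id, levels = manifest$scan_id))
  r_fp <- table(factor(rm$fp_scans, levels = manifest$scan_id))
  n <- nrow(manifest)
  out <- matrix(NA_real_, n_boot, 2)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        det <- unlist(r_det[idx], use.names = FALSE)
        if (length(det) > 0 || n_targets == 0) break
      }
      out[b, ] <- c(if (length(det)) mean(det) else NA_real_,
                    sum(r_fp[idx]) / n)
    }
  })
  qs <- apply(out, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE, na.rm = TRUE)
  structure(list(reader_id = reader_id, class_filter = class_filter,
                 sensitivity = sens, sens_ci = qs[, 1],
                 fp_per_scan = fps, fp_ci = qs[, 2],
                 n_targets = n_targets),
            class = "reader_point")
}

#' @export
print.reader_point <- function(x, ...) {
  cat(sprintf("Reader %s [%s]: sensitivity %.1f%% (%.1f, %.1f), FP/s %.2f (%.2f, %.2f), %d targets\n",
              x$reader_id, x$class_filter, 100 * x$sensitivity,
              100 * x$sens_ci[1], 100 * x$sens_ci[2],
              x$fp_per_scan, x$fp_ci[1], x$fp_ci[2], x$n_targets))
  invisible(x)
}

#' Compare the AI system against one reader
#'
#' Builds the reader's leave-one-out reference, matches both the reader's
#' marks and the AI predictions against the same subset view, recalibrates
#' the AI threshold to the target FP/s on that view, and runs the paired
#' permutation test over the per-nodule detection indicators (including
#' registry-added, panel-missed nodules).
#'
#' @param predictions AI prediction data.frame.
#' @inheritParams reader_performance
#' @param target_fp FP/s budget for recalibration (default 1).
#' @param n_iter Permutation iterations (default 1000).
#' @return An object of class `ai_reader_comparison`: reader point, AI
#'   sensitivity/FP at the recalibrated threshold with CIs, the threshold,
#'   the p-value, `n_targets`, and both detection vectors.
#' @export
compare_ai_vs_reader <- function(predictions, reader_id, annotations,
                                 manifest, registry = NULL,
                                 min_diameter = 3, class_filter = "all",
                                 min_agreement = 3, target_fp = 1.0,
                                 n_boot = 1000, n_iter = 1000, seed = 1L) {
  ref <- leave_one_out_reference(annotations, manifest, registry, reader_id,
                                 min_agreement)
  view <- select_subset(ref, min_diameter, class_filter)
  if (nrow(view$targets) == 0) {
    stop("no target nodules in this leave-one-out subset", call. = FALSE)
  }
  own <- annotations[annotations$reader_id == reader_id, , drop = FALSE]
  rm_ <- match_reader(own, view)
  am <- match_predictions(predictions, view)
  curve <- froc_curve(am)
  cal <- calibrate_threshold(curve, target_fp)
  ai_det <- !is.na(am$targets$best_score) &
    am$targets$best_score >= cal$threshold - 1e-12
  reader_det <- rm_$targets$detected

  perm <- paired_permutation_test(ai_det, reader_det, n_iter = n_iter,
                                  seed = seed + 1L)
  cis <- boot_reader_ai(rm_, am, manifest$scan_id, cal$threshold,
                        n_boot, seed)
  structure(list(
    reader_id = reader_id, class_filter = class_filter,
    n_targets = nrow(view$targets),
    reader_sensitivity = mean(reader_det), reader_sens_ci = cis$reader_sens_ci,
    reader_fp_per_scan = rm_$fp_count / rm_$n_scans,
    reader_fp_ci = cis$reader_fp_ci,
    ai_sensitivity = mean(ai_det), ai_sens_ci = cis$ai_sens_ci,
    ai_fp_per_scan = cal$fp_per_scan, ai_fp_ci = cis$ai_fp_ci,
    threshold = cal$threshold,
    statistic = perm$statistic, p_value = perm$p_value,
    significant = perm$p_value < 0.05,
    ai_detected = ai_det, reader_detected = reader_det,
    curve = curve),
    class = "ai_reader_comparison")
}

#' @export
print.ai_reader_comparison <- function(x, ...) {
  cat(sprintf("AI vs reader %s [%s], %d targets\n",
              x$reader_id, x$class_filter, x$n_targets))
  cat(sprintf("  reader: sens %.1f%% (%.1f, %.1f), FP/s %.2f (%.2f, %.2f)\n",
              100 * x$reader_sensitivity, 100 * x$reader_sens_ci[1],
              100 * x$reader_sens_ci[2], x$reader_fp_per_scan,
              x$reader_fp_ci[1], x$reader_fp_ci[2]))
  cat(sprintf("  AI (thr %.3f): sens %.1f%% (%.1f, %.1f), FP/s %.2f (%.2f, %.2f)\n",
              x$threshold, 100 * x$ai_sensitivity, 100 * x$ai_sens_ci[1],
              100 * x$ai_sens_ci[2], x$ai_fp_per_scan, x$ai_fp_ci[1],
              x$ai_fp_ci[2]))
  cat(sprintf("  paired permutation p = %s\n", format_p(x$p_value)))
  invisible(x)
}

#' Full reader-vs-AI comparison table
#'
#' One comparison per (reader, category): the reader's operating point,
#' the recalibrated AI sensitivity, and the permutation p-value. Seeds are
#' derived deterministically per comparison.
#'
#' @inheritParams compare_ai_vs_reader
#' @param categories Nodule categories to compare (default the three
#'   clinically reported ones).
#' @return List with `table` (one row per comparison) and `comparisons`
#'   (the full `ai_reader_comparison` objects, for FROC export).
#' @export
comparison_table <- function(predictions, annotations, manifest,
                             registry = NULL,
                             categories = c("actionable_benign",
                                            "primary_cancer", "metastasis"),
                             min_diameter = 3, min_agreement = 3,
                             target_fp = 1.0, n_boot = 1000, n_iter = 1000,
                             seed = 1L) {
  readers <- sort(unique(annotations$reader_id))
  rows <- list()
  comps <- list()
  k <- 0L
  for (cat in categories) {
    for (r in readers) {
      k <- k + 1L
      cmp <- compare_ai_vs_reader(predictions, r, annotations, manifest,
                                  registry, min_diameter, cat,
                                  min_agreement, target_fp, n_boot, n_iter,
                                  seed = seed + 10L * k)
      comps[[paste(r, cat, sep = ".")]] <- cmp
      rows[[k]] <- data.frame(
        reader = r, category = cat, n_targets = cmp$n_targets,
        fp_per_scan = cmp$reader_fp_per_scan,
        fp_ci_lo = cmp$reader_fp_ci[1], fp_ci_hi = cmp$reader_fp_ci[2],
        sensitivity = as_percent(cmp$reader_sensitivity),
        sens_ci_lo = as_percent(cmp$reader_sens_ci[1]),
        sens_ci_hi = as_percent(cmp$reader_sens_ci[2]),
        ai_sensitivity = as_percent(cmp$ai_sensitivity),
        ai_ci_lo = as_percent(cmp$ai_sens_ci[1]),
        ai_ci_hi = as_percent(cmp$ai_sens_ci[2]),
        ai_fp_per_scan = cmp$ai_fp_per_scan,
        ai_fp_ci_lo = cmp$ai_fp_ci[1], ai_fp_ci_hi = cmp$ai_fp_ci[2],
        p_value = cmp$p_value, stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), comparisons = comps)
}
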