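#' @name matching
#' @title Hit-criterion matching of detections against a reference subset
#'
#' @description
#' A detection hits a reference nodule when its center lies within the
#' nodule's radius of the nodule's center (boundary inclusive). A detection
#' inside several targets is assigned to the nearest center; ties go to the
#' smaller `nodule_id`. Per target nodule only the highest-scoring hit is a
#' true positive; further hits are duplicates and count neither as true nor
#' false positives. Detections that hit only ignore regions (exclusion-list
#' findings or out-of-subset nodules) are ignored; everything else is a
#' false positive.
NULL

#' Match scored predictions against a subset view
#'
#' @param predictions Prediction data.frame ([read_predictions()]).
#' @param view A `subset_view` from [select_subset()].
#' @return An object of class `match_result`: list with
#'   * `predictions`: the input rows plus `label` (`TP`, `FP`, `ignored`,
#'     `duplicate`), `matched_nodule_id` and `distance_mm`;
#'   * `targets`: one row per target nodule with `best_score` (NA when
#'     undetected) and `detected`;
#'   * `n_scans`, `n_targets`.
#' @export
match_predictions <- function(predictions, view) {
  stopifnot(inherits(view, "subset_view"))
  unknown <- setdiff(predictions$scan_id, view$scans$scan_id)
  if (length(unknown) > 0) {
    stop("predictions reference scan_id(s) absent from the manifest: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  preds <- predictions
  n <- nrow(preds)
  label <- rep("FP", n)
  matched <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)

  targets <- view$targets
  best_score <- rep(NA_real_, nrow(targets))
  names(best_score) <- targets$nodule_id

  for (sid in unique(preds$scan_id)) {
    pi <- which(preds$scan_id == sid)
    pxyz <- as.matrix(preds[pi, COORD_COLS, drop = FALSE])
    ti <- which(targets$scan_id == sid)
    txyz <- as.matrix(targets[ti, COORD_COLS, drop = FALSE])
    gi <- which(view$ignore$scan_id == sid)
    gxyz <- as.matrix(view$ignore[gi, COORD_COLS, drop = FALSE])

    assigned <- rep(NA_integer_, length(pi))  # index into ti
    for (a in seq_along(pi)) {
      p <- pxyz[a, ]
      if (length(ti) > 0) {
        d <- dist_to_points(p, txyz)
        hit <- d <= targets$radius_mm[ti] + 1e-9
        if (any(hit)) {
          cand <- which(hit)
          # nearest center; exact ties broken by smaller nodule_id
          o <- order(d[cand], targets$nodule_id[ti][cand])
          assigned[a] <- cand[o[1]]
          distance[pi[a]] <- d[cand[o[1]]]
          next
        }
      }
      if (length(gi) > 0) {
        d <- dist_to_points(p, gxyz)
        if (any(d <= view$ignore$radius_mm[gi] + 1e-9)) {
          label[pi[a]] <- "ignored"
        }
      }
    }
    for (t in unique(assigned[!is.na(assigned)])) {
      hits <- which(assigned == t)
      sc <- preds$score[pi[hits]]
      top <- hits[which.max(sc)]
      label[pi[top]] <- "TP"
      label[pi[setdiff(hits, top)]] <- "duplicate"
      matched[pi[hits]] <- targets$nodule_id[ti[t]]
      best_score[ti[t]] <- max(sc)
    }
  }

  preds$label <- label
  preds$matched_nodule_id <- matched
  preds$distance_mm <- distance
  tdf <- targets
  tdf$best_score <- unname(best_score)
  tdf$detected <- !is.na(tdf$best_score)
  structure(list(predictions = preds, targets = tdf,
                 n_scans = nrow(view$scans), n_targets = nrow(targets)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  tab <- table(factor(x$predictions$label,
                      levels = c("TP", "FP", "ignored", "duplicate")))
  cat(sprintf("Match result: %d predictions on %d scans, %d targets\n",
              nrow(x$predictions), x$n_scans, x$n_targets))
  cat(sprintf("  TP %d | FP %d | ignored %d | duplicate %d | detected %d/%d\n",
              tab["TP"], tab["FP"], tab["ignored"], tab["duplicate"],
              sum(x$targets$detected), x$n_targets))
  invisible(x)
}

#' Match one reader's annotations against a subset view
#'
#' Reader marks are unscored; the same hit geometry applies with the mark's
#' center. Marks hitting ignore regions are not false positives. Several
#' marks by the reader on one nodule collapse to a single detection (a
#' warning reports the extras).
#'
#' @param reader_annotations Annotation rows of a single reader.
#' @param view A `subset_view` built without this reader's input (see
#'   [leave_one_out_reference()]).
#' @return An object of class `reader_match_result`: list with `targets`
#'   (per-nodule `detected` flag), `fp_count`, `fp_scans` (scan ids of the
#'   false-positive marks) and `n_scans`.
#' @export
match_reader <- function(reader_annotations, view) {
  stopifnot(inherits(view, "subset_view"))
  if (length(unique(reader_annotations$reader_id)) > 1) {
    stop("match_reader() expects annotations from a single reader",
         call. = FALSE)
  }
  preds <- reader_annotations[c("scan_id", COORD_COLS)]
  preds$score <- 1  # unscored: uniform pseudo-score
  m <- match_predictions(preds, view)
  n_dup <- sum(m$predictions$label == "duplicate")
  if (n_dup > 0) {
    warning(n_dup, " duplicate reader mark(s) on already-detected nodules ",
            "collapsed", call. = FALSE)
  }
  fp <- m$predictions$label == "FP"
  structure(list(targets = m$targets[c("nodule_id", "scan_id", "detected")],
                 fp_count = sum(fp),
                 fp_scans = m$predictions$scan_id[fp],
                 n_scans = m$n_scans),
            class = "reader_match_result")
}
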