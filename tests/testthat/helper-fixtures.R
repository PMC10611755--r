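# Small in-code fixtures and independent brute-force oracles.

make_manifest <- function(n_scans = 1, categories = "normal") {
  data.frame(scan_id = sprintf("s%03d", seq_len(n_scans)),
             category = rep_len(categories, n_scans),
             stringsAsFactors = FALSE)
}

make_ann <- function(scan_id, reader_id, x, y = 0, z = 0, d = 6,
                     type = "solid") {
  data.frame(scan_id = scan_id, reader_id = reader_id,
             coord_x_mm = x, coord_y_mm = y, coord_z_mm = z,
             volume_mm3 = volume_from_diameter(d), diameter_mm = d,
             nodule_type = type, lobe = NA_character_,
             stringsAsFactors = FALSE)
}

make_pred <- function(scan_id, x, y = 0, z = 0, score = 0.5) {
  data.frame(scan_id = scan_id, coord_x_mm = x, coord_y_mm = y,
             coord_z_mm = z, score = score, stringsAsFactors = FALSE)
}

# Build a subset_view directly from target/ignore tables (bypasses the
# consensus machinery for geometric unit tests).
make_view <- function(targets, ignore = NULL, scans = NULL) {
  if (is.null(scans)) {
    ids <- unique(c(targets$scan_id, ignore$scan_id))
    if (length(ids) == 0) ids <- "s001"
    scans <- data.frame(scan_id = ids,
                        category = rep("normal", length(ids)),
                        stringsAsFactors = FALSE)
  }
  if (is.null(ignore)) {
    ignore <- data.frame(scan_id = character(), coord_x_mm = numeric(),
                         coord_y_mm = numeric(), coord_z_mm = numeric(),
                         radius_mm = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(targets = targets, ignore = ignore, scans = scans,
                 min_diameter = 3, class_filter = "all"),
            class = "subset_view")
}

make_target <- function(scan_id, id, x, y = 0, z = 0, d = 10,
                        malignancy = "benign", type = "solid") {
  data.frame(nodule_id = id, scan_id = scan_id,
             coord_x_mm = x, coord_y_mm = y, coord_z_mm = z,
             volume_mm3 = volume_from_diameter(d), diameter_mm = d,
             radius_mm = d / 2, nodule_type = type, agreement = 5L,
             malignancy = malignancy, actionable = FALSE,
             detected_by_panel = TRUE, stringsAsFactors = FALSE)
}

# Independent matching oracle: per-prediction nested loops applying the
# hit criterion, nearest-center assignment, per-nodule best-score TP and
# the ignore rule. No shared code with match_predictions().
oracle_match_labels <- function(preds, targets, ignore) {
  n <- nrow(preds)
  label <- rep("FP", n)
  assigned <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (nrow(targets) > 0) {
      best_id <- NA_character_; best_d <- Inf
      for (j in seq_len(nrow(targets))) {
        if (targets$scan_id[j] != preds$scan_id[i]) next
        d <- sqrt((preds$coord_x_mm[i] - targets$coord_x_mm[j])^2 +
                  (preds$coord_y_mm[i] - targets$coord_y_mm[j])^2 +
                  (preds$coord_z_mm[i] - targets$coord_z_mm[j])^2)
        if (d <= targets$radius_mm[j] + 1e-9) {
          if (d < best_d - 1e-12 ||
              (abs(d - best_d) <= 1e-12 &&
               targets$nodule_id[j] < best_id)) {
            best_id <- targets$nodule_id[j]; best_d <- d
          }
        }
      }
      if (!is.na(best_id)) { assigned[i] <- best_id; next }
    }
    if (nrow(ignore) > 0) {
      for (j in seq_len(nrow(ignore))) {
        if (ignore$scan_id[j] != preds$scan_id[i]) next
        d <- sqrt((preds$coord_x_mm[i] - ignore$coord_x_mm[j])^2 +
                  (preds$coord_y_mm[i] - ignore$coord_y_mm[j])^2 +
                  (preds$coord_z_mm[i] - ignore$coord_z_mm[j])^2)
        if (d <= ignore$radius_mm[j] + 1e-9) { label[i] <- "ignored"; break }
      }
    }
  }
  for (id in unique(assigned[!is.na(assigned)])) {
    hits <- which(assigned == id)
    top <- hits[which.max(preds$score[hits])]
    label[top] <- "TP"
    label[setdiff(hits, top)] <- "duplicate"
  }
  label
}

# Random matching scene on one or more scans: well-formed but arbitrary
# geometry (predictions may fall anywhere).
random_scene <- function(n_targets = 4, n_preds = 8, n_ignore = 2,
                         box = 120) {
  targets <- if (n_targets > 0) {
    do.call(rbind, lapply(seq_len(n_targets), function(j) {
      make_target("s001", sprintf("n%02d", j), x = runif(1, 0, box),
                  y = runif(1, 0, box), z = runif(1, 0, box),
                  d = runif(1, 4, 20))
    }))
  } else {
    make_target("s001", "n00", 0)[0, ]
  }
  ignore <- if (n_ignore > 0) {
    data.frame(scan_id = "s001", coord_x_mm = runif(n_ignore, 0, box),
               coord_y_mm = runif(n_ignore, 0, box),
               coord_z_mm = runif(n_ignore, 0, box),
               radius_mm = runif(n_ignore, 1, 6), stringsAsFactors = FALSE)
  } else NULL
  # mix of predictions near targets and uniform background
  preds <- do.call(rbind, lapply(seq_len(n_preds), function(i) {
    if (n_targets > 0 && runif(1) < 0.6) {
      j <- sample.int(n_targets, 1)
      make_pred("s001",
                targets$coord_x_mm[j] + rnorm(1, 0, targets$radius_mm[j]),
                targets$coord_y_mm[j] + rnorm(1, 0, targets$radius_mm[j]),
                targets$coord_z_mm[j] + rnorm(1, 0, targets$radius_mm[j]),
                score = runif(1))
    } else {
      make_pred("s001", runif(1, 0, box), runif(1, 0, box),
                runif(1, 0, box), score = runif(1))
    }
  }))
  list(view = make_view(targets, ignore), preds = preds,
       targets = targets, ignore = make_view(targets, ignore)$ignore)
}

# Independent clustering oracle for well-separated scenes: connected
# components of the pairwise compatibility graph (different readers,
# centers within the larger radius). With sites separated far beyond all
# radii this is the uniquely optimal grouping.
oracle_cluster_components <- function(ann) {
  n <- nrow(ann)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (ann$reader_id[i] == ann$reader_id[j]) next
      d <- sqrt((ann$coord_x_mm[i] - ann$coord_x_mm[j])^2 +
                (ann$coord_y_mm[i] - ann$coord_y_mm[j])^2 +
                (ann$coord_z_mm[i] - ann$coord_z_mm[j])^2)
      if (d <= max(ann$diameter_mm[i], ann$diameter_mm[j]) / 2) {
        parent[find(i)] <- find(j)
      }
    }
  }
  split(seq_len(n), vapply(seq_len(n), find, 0L))
}

# Exact paired permutation p-value by full 2^n sign enumeration.
exact_permutation_p <- function(a, b) {
  d <- as.numeric(a) - as.numeric(b)
  n <- length(d)
  t_obs <- mean(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t_perm <- as.vector(signs %*% d) / n
  mean(abs(t_perm) >= abs(t_obs) - 1e-12)
}
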