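#' @name consensus
#' @title Majority-vote reference standard with exclusion list
#'
#' @description
#' A panel of readers independently annotates nodules per scan. Marks from
#' different readers are clustered when their centers fall within the larger
#' of the two mark radii; each cluster's measurements are averaged over its
#' contributing readers. Clusters whose averaged equivalent diameter falls
#' outside the size window (default 3-30 mm) or that were marked by fewer
#' than `min_agreement` readers are moved to an exclusion list of
#' indeterminate findings; detections matching these are later ignored
#' (neither true nor false positive).
NULL

canonical_order <- function(df) {
  df[order(df$scan_id, df$reader_id, df$coord_x_mm, df$coord_y_mm,
           df$coord_z_mm), , drop = FALSE]
}

#' Cluster one scan's annotations across readers
#'
#' Greedy agglomerative clustering over marks sorted by ascending center
#' distance: two clusters merge when their (running mean) centers are within
#' the larger of their mean radii and they share no reader. The input order
#' of rows never affects the result; annotations are sorted canonically
#' first.
#'
#' @param annotations Data.frame of annotations all sharing one `scan_id`.
#' @return A list of data.frames, one per cluster, each holding at most one
#'   annotation per reader; clusters ordered by mean center coordinates.
#' @export
cluster_annotations <- function(annotations) {
  if (nrow(annotations) == 0) return(list())
  if (length(unique(annotations$scan_id)) != 1) {
    stop("cluster_annotations() expects annotations from a single scan",
         call. = FALSE)
  }
  ann <- canonical_order(annotations)
  n <- nrow(ann)
  xyz <- as.matrix(ann[COORD_COLS])
  members <- as.list(seq_len(n))
  centers <- xyz
  radii <- ann$diameter_mm / 2
  readers <- as.list(ann$reader_id)

  repeat {
    k <- length(members)
    if (k < 2) break
    best <- NULL
    best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (length(intersect(readers[[i]], readers[[j]])) > 0) next
        d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
        if (d > max(radii[i], radii[j])) next
        if (d < best_d - 1e-12) {
          best <- c(i, j); best_d <- d
        } else if (abs(d - best_d) <= 1e-12 && !is.null(best)) {
          # exact tie: prefer the pair with the smallest member indices
          if (min(members[[i]]) < min(members[[best[1]]]) ||
              (min(members[[i]]) == min(members[[best[1]]]) &&
               min(members[[j]]) < min(members[[best[2]]]))) {
            best <- c(i, j)
          }
        }
      }
    }
    if (is.null(best)) break
    i <- best[1]; j <- best[2]
    mem <- c(members[[i]], members[[j]])
    members[[i]] <- mem
    centers[i, ] <- colMeans(xyz[mem, , drop = FALSE])
    radii[i] <- mean(ann$diameter_mm[mem]) / 2
    readers[[i]] <- c(readers[[i]], readers[[j]])
    members[[j]] <- NULL
    centers <- centers[-j, , drop = FALSE]
    radii <- radii[-j]
    readers[[j]] <- NULL
  }

  clusters <- lapply(members, function(m) ann[sort(m), , drop = FALSE])
  cx <- vapply(clusters, function(cl) mean(cl$coord_x_mm), 0)
  cy <- vapply(clusters, function(cl) mean(cl$coord_y_mm), 0)
  cz <- vapply(clusters, function(cl) mean(cl$coord_z_mm), 0)
  clusters[order(cx, cy, cz)]
}

consensus_type <- function(types) {
  tab <- table(factor(types, levels = NODULE_TYPES))
  winners <- names(tab)[tab == max(tab)]
  winners[which.min(TYPE_PRIORITY[winners])]
}

empty_nodules <- function() {
  data.frame(nodule_id = character(), scan_id = character(),
             coord_x_mm = numeric(), coord_y_mm = numeric(),
             coord_z_mm = numeric(), volume_mm3 = numeric(),
             diameter_mm = numeric(), radius_mm = numeric(),
             nodule_type = character(), agreement = integer(),
             malignancy = character(), actionable = logical(),
             detected_by_panel = logical(), stringsAsFactors = FALSE)
}

empty_exclusions <- function() {
  data.frame(scan_id = character(), coord_x_mm = numeric(),
             coord_y_mm = numeric(), coord_z_mm = numeric(),
             volume_mm3 = numeric(), diameter_mm = numeric(),
             nodule_type = character(), agreement = integer(),
             reason = character(), stringsAsFactors = FALSE)
}

is_actionable <- function(malignancy, diameter, type) {
  malignancy == "benign" & diameter >= 5 &
    !type %in% c("calcified", "perifissural")
}

#' Build the majority-vote reference standard
#'
#' @param annotations Annotation data.frame covering all readers.
#' @param manifest Manifest data.frame (defines the scan set; nodule-free
#'   scans stay in the false-positive denominator).
#' @param min_agreement Minimum number of readers that must mark a finding
#'   for it to enter the reference (default 3).
#' @param size_bounds Inclusive equivalent-diameter window in mm applied to
#'   the averaged diameter (default `c(3, 30)`).
#' @param n_readers Panel size; defaults to the number of distinct
#'   `reader_id`s present.
#' @return An object of class `reference_standard`: a list with `scans`,
#'   `nodules`, `exclusions`, `min_agreement`, `n_readers`, `n_clusters`
#'   and (after [link_malignancy()]) `missed_cancers`. All nodules start
#'   with `malignancy = "benign"`.
#' @export
build_reference_standard <- function(annotations, manifest,
                                     min_agreement = 3,
                                     size_bounds = c(3, 30),
                                     n_readers = NULL) {
  if (is.null(n_readers)) n_readers <- length(unique(annotations$reader_id))
  if (min_agreement > n_readers) {
    stop("min_agreement (", min_agreement, ") exceeds the number of readers (",
         n_readers, ")", call. = FALSE)
  }
  unknown <- setdiff(annotations$scan_id, manifest$scan_id)
  if (length(unknown) > 0) {
    stop("annotations reference scan_id(s) absent from the manifest: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  nod_rows <- list()
  exc_rows <- list()
  n_clusters <- 0L
  for (sid in sort(unique(annotations$scan_id))) {
    clusters <- cluster_annotations(
      annotations[annotations$scan_id == sid, , drop = FALSE])
    n_clusters <- n_clusters + length(clusters)
    for (cl in clusters) {
      diameter <- mean(cl$diameter_mm)
      row <- data.frame(
        scan_id = sid,
        coord_x_mm = mean(cl$coord_x_mm),
        coord_y_mm = mean(cl$coord_y_mm),
        coord_z_mm = mean(cl$coord_z_mm),
        volume_mm3 = mean(cl$volume_mm3),
        diameter_mm = diameter,
        nodule_type = consensus_type(cl$nodule_type),
        agreement = nrow(cl),
        stringsAsFactors = FALSE)
      if (diameter < size_bounds[1]) {
        row$reason <- "too_small"
        exc_rows[[length(exc_rows) + 1]] <- row
      } else if (diameter > size_bounds[2]) {
        row$reason <- "too_large"
        exc_rows[[length(exc_rows) + 1]] <- row
      } else if (nrow(cl) < min_agreement) {
        row$reason <- "minority"
        exc_rows[[length(exc_rows) + 1]] <- row
      } else {
        nod_rows[[length(nod_rows) + 1]] <- row
      }
    }
  }

  nodules <- if (length(nod_rows)) do.call(rbind, nod_rows) else NULL
  if (!is.null(nodules)) {
    nodules <- nodules[order(nodules$scan_id, nodules$coord_x_mm,
                             nodules$coord_y_mm, nodules$coord_z_mm), ]
    nodules$nodule_id <- sprintf("n%04d", seq_len(nrow(nodules)))
    nodules$radius_mm <- nodules$diameter_mm / 2
    nodules$malignancy <- "benign"
    nodules$actionable <- is_actionable(nodules$malignancy,
                                        nodules$diameter_mm,
                                        nodules$nodule_type)
    nodules$detected_by_panel <- TRUE
    nodules <- nodules[names(empty_nodules())]
    rownames(nodules) <- NULL
  } else {
    nodules <- empty_nodules()
  }
  exclusions <- if (length(exc_rows)) do.call(rbind, exc_rows) else empty_exclusions()
  exclusions <- exclusions[order(exclusions$scan_id, exclusions$coord_x_mm,
                                 exclusions$coord_y_mm, exclusions$coord_z_mm), ,
                           drop = FALSE]
  rownames(exclusions) <- NULL

  structure(list(scans = manifest, nodules = nodules, exclusions = exclusions,
                 min_agreement = min_agreement, n_readers = n_readers,
                 size_bounds = size_bounds, n_clusters = n_clusters,
                 missed_cancers = NULL),
            class = "reference_standard")
}

#' @export
print.reference_standard <- function(x, ...) {
  cat("Multi-reader reference standard\n")
  cat(sprintf("  scans: %d | readers: %d | majority: >=%d\n",
              nrow(x$scans), x$n_readers, x$min_agreement))
  cat(sprintf("  included nodules: %d (of %d clusters)\n",
              nrow(x$nodules), x$n_clusters))
  tab <- table(factor(x$exclusions$reason,
                      levels = c("too_small", "too_large", "minority")))
  cat(sprintf("  excluded: %d (too_small %d, too_large %d, minority %d)\n",
              nrow(x$exclusions), tab[1], tab[2], tab[3]))
  if (!is.null(x$missed_cancers)) {
    cat(sprintf("  panel-missed cancers: %d\n", nrow(x$missed_cancers)))
  }
  invisible(x)
}

#' Link registry malignancies to the reference standard
#'
#' Each registry record is linked to the nearest included nodule whose hit
#' criterion it satisfies (record center within the nodule radius), which
#' then takes the record's malignant status. A record with no included
#' match is a cancer missed by the panel majority: if a minority-excluded
#' finding satisfies the criterion, that finding is promoted into the
#' reference (its measurements kept, `detected_by_panel = FALSE`);
#' otherwise a nodule is appended at the registry coordinates. The promoted
#' and appended records are reported in `missed_cancers`.
#'
#' @param ref A `reference_standard`.
#' @param registry Registry data.frame ([read_registry()]).
#' @return The updated `reference_standard`, with the missed-cancer report
#'   in its `missed_cancers` element and `actionable` flags recomputed.
#' @export
link_malignancy <- function(ref, registry) {
  stopifnot(inherits(ref, "reference_standard"))
  if (!is.null(registry)) {
    bad <- !registry$status %in% c("primary_cancer", "metastasis")
    if (any(bad)) {
      stop("registry row ", which(bad)[1], ": malformed status '",
           registry$status[which(bad)[1]], "'", call. = FALSE)
    }
    unknown <- setdiff(registry$scan_id, ref$scans$scan_id)
    if (length(unknown) > 0) {
      stop("registry references scan_id(s) absent from the manifest: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  nodules <- ref$nodules
  exclusions <- ref$exclusions
  missed <- list()
  if (!is.null(registry) && nrow(registry) > 0) {
    registry <- registry[order(registry$scan_id, registry$coord_x_mm,
                               registry$coord_y_mm, registry$coord_z_mm), ]
    linked <- rep(FALSE, nrow(nodules))
    promoted <- rep(FALSE, nrow(exclusions))
    for (k in seq_len(nrow(registry))) {
      rec <- registry[k, ]
      p <- c(rec$coord_x_mm, rec$coord_y_mm, rec$coord_z_mm)
      cand <- which(nodules$scan_id == rec$scan_id & !linked)
      if (length(cand) > 0) {
        d <- dist_to_points(p, as.matrix(nodules[cand, COORD_COLS]))
        hit <- d <= nodules$radius_mm[cand] + 1e-9
        if (any(hit)) {
          i <- cand[hit][which.min(d[hit])]
          nodules$malignancy[i] <- rec$status
          linked[i] <- TRUE
          next
        }
      }
      # not found by the majority: try minority-excluded findings
      cand <- which(exclusions$scan_id == rec$scan_id &
                      exclusions$reason == "minority" & !promoted)
      hit_i <- NA_integer_
      if (length(cand) > 0) {
        d <- dist_to_points(p, as.matrix(exclusions[cand, COORD_COLS]))
        hit <- d <= exclusions$diameter_mm[cand] / 2 + 1e-9
        if (any(hit)) hit_i <- cand[hit][which.min(d[hit])]
      }
      if (!is.na(hit_i)) {
        ex <- exclusions[hit_i, ]
        promoted[hit_i] <- TRUE
        new_row <- data.frame(
          nodule_id = NA_character_, scan_id = ex$scan_id,
          coord_x_mm = ex$coord_x_mm, coord_y_mm = ex$coord_y_mm,
          coord_z_mm = ex$coord_z_mm, volume_mm3 = ex$volume_mm3,
          diameter_mm = ex$diameter_mm, radius_mm = ex$diameter_mm / 2,
          nodule_type = ex$nodule_type, agreement = ex$agreement,
          malignancy = rec$status, actionable = FALSE,
          detected_by_panel = FALSE, stringsAsFactors = FALSE)
        resolution <- "promoted_minority"
      } else {
        new_row <- data.frame(
          nodule_id = NA_character_, scan_id = rec$scan_id,
          coord_x_mm = rec$coord_x_mm, coord_y_mm = rec$coord_y_mm,
          coord_z_mm = rec$coord_z_mm,
          volume_mm3 = volume_from_diameter(rec$diameter_mm),
          diameter_mm = rec$diameter_mm, radius_mm = rec$diameter_mm / 2,
          nodule_type = "solid", agreement = 0L,
          malignancy = rec$status, actionable = FALSE,
          detected_by_panel = FALSE, stringsAsFactors = FALSE)
        resolution <- "added_from_registry"
      }
      nodules <- rbind(nodules, new_row)
      linked <- c(linked, TRUE)
      missed[[length(missed) + 1]] <- cbind(
        rec[c("scan_id", COORD_COLS, "diameter_mm", "status")],
        resolution = resolution, stringsAsFactors = FALSE)
    }
    exclusions <- exclusions[!promoted, , drop = FALSE]
    rownames(exclusions) <- NULL
    # stable ids for appended nodules, continuing the sequence
    new_id <- is.na(nodules$nodule_id)
    if (any(new_id)) {
      nodules$nodule_id[new_id] <- sprintf("n%04d",
        max(0L, nrow(nodules) - sum(new_id)) + seq_len(sum(new_id)))
    }
  }
  nodules$actionable <- is_actionable(nodules$malignancy, nodules$diameter_mm,
                                      nodules$nodule_type)
  rownames(nodules) <- NULL
  ref$nodules <- nodules
  ref$exclusions <- exclusions
  ref$missed_cancers <- if (length(missed)) {
    do.call(rbind, missed)
  } else {
    data.frame(scan_id = character(), coord_x_mm = numeric(),
               coord_y_mm = numeric(), coord_z_mm = numeric(),
               diameter_mm = numeric(), status = character(),
               resolution = character(), stringsAsFactors = FALSE)
  }
  ref
}

#' Select an evaluation subset of the reference standard
#'
#' Targets are the included nodules meeting the size and class filter.
#' Everything else that ever carried a mark stays visible as an ignore
#' region: the exclusion list plus the included nodules outside the subset.
#' Detections matching ignore regions count as neither true nor false
#' positives, so the false-positives-per-scan axis is identical across
#' subset analyses.
#'
#' @param ref A `reference_standard`.
#' @param min_diameter Minimum (inclusive) consensus equivalent diameter in
#'   mm; must be >= the lower size bound.
#' @param class_filter One of `"all"`, `"actionable_benign"`,
#'   `"primary_cancer"`, `"metastasis"`.
#' @return An object of class `subset_view`: list with `targets` (nodule
#'   rows), `ignore` (scan_id, coordinates, radius), and `scans`.
#' @export
select_subset <- function(ref, min_diameter = 3,
                          class_filter = c("all", "actionable_benign",
                                           "primary_cancer", "metastasis")) {
  stopifnot(inherits(ref, "reference_standard"))
  class_filter <- match.arg(class_filter)
  nod <- ref$nodules
  in_subset <- nod$diameter_mm >= min_diameter
  in_subset <- in_subset & switch(class_filter,
    all = TRUE,
    actionable_benign = nod$actionable,
    primary_cancer = nod$malignancy == "primary_cancer",
    metastasis = nod$malignancy == "metastasis")
  targets <- nod[in_subset, , drop = FALSE]
  rownames(targets) <- NULL

  ign_nod <- nod[!in_subset, c("scan_id", COORD_COLS, "radius_mm")]
  ign_exc <- ref$exclusions[, c("scan_id", COORD_COLS, "diameter_mm")]
  names(ign_exc)[5] <- "radius_mm"
  ign_exc$radius_mm <- ign_exc$radius_mm / 2
  ignore <- rbind(ign_nod, ign_exc)
  rownames(ignore) <- NULL

  structure(list(targets = targets, ignore = ignore, scans = ref$scans,
                 min_diameter = min_diameter, class_filter = class_filter),
            class = "subset_view")
}

#' @export
print.subset_view <- function(x, ...) {
  cat(sprintf("Evaluation subset: %s, diameter >= %g mm\n",
              x$class_filter, x$min_diameter))
  cat(sprintf("  targets: %d | ignore regions: %d | scans: %d\n",
              nrow(x$targets), nrow(x$ignore), nrow(x$scans)))
  invisible(x)
}

#' Leave-one-out reference standard for reader evaluation
#'
#' Rebuilds the consensus from the other readers so a reader is never
#' scored against their own marks. The majority threshold is kept at
#' `min_agreement` (3-of-4 for a five-reader panel), so the benign
#' reference and the exclusion list vary per reader; registry-linked
#' malignant nodules are retained regardless of remaining agreement via
#' [link_malignancy()]'s promotion rule.
#'
#' @param annotations Full-panel annotation data.frame.
#' @param manifest Manifest data.frame.
#' @param registry Registry data.frame, or NULL.
#' @param excluded_reader The `reader_id` being evaluated.
#' @inheritParams build_reference_standard
#' @return A `reference_standard` built from the remaining readers.
#' @export
leave_one_out_reference <- function(annotations, manifest, registry,
                                    excluded_reader, min_agreement = 3,
                                    size_bounds = c(3, 30)) {
  readers <- unique(annotations$reader_id)
  if (!excluded_reader %in% readers) {
    stop("unknown reader: ", excluded_reader, call. = FALSE)
  }
  if (length(readers) - 1 < min_agreement) {
    stop("cannot build a leave-one-out reference: ", length(readers) - 1,
         " remaining readers < min_agreement ", min_agreement, call. = FALSE)
  }
  rest <- annotations[annotations$reader_id != excluded_reader, , drop = FALSE]
  ref <- build_reference_standard(rest, manifest, min_agreement, size_bounds,
                                  n_readers = length(readers) - 1L)
  link_malignancy(ref, registry)
}

#' Write a reference standard to CSV files
#'
#' @param ref A `reference_standard`.
#' @param dir Output directory; `reference.csv` and `exclusions.csv` are
#'   written there (and `missed_cancers.csv` when linkage was run).
#' @export
write_reference_standard <- function(ref, dir) {
  stopifnot(inherits(ref, "reference_standard"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nod <- ref$nodules
  out <- data.frame(nodule_id = nod$nodule_id, scan_id = nod$scan_id,
                    coord_x_mm = num_fmt(nod$coord_x_mm),
                    coord_y_mm = num_fmt(nod$coord_y_mm),
                    coord_z_mm = num_fmt(nod$coord_z_mm),
                    volume_mm3 = num_fmt(nod$volume_mm3),
                    diameter_mm = num_fmt(nod$diameter_mm),
                    nodule_type = nod$nodule_type, agreement = nod$agreement,
                    malignancy = nod$malignancy, actionable = nod$actionable)
  utils::write.csv(out, file.path(dir, "reference.csv"), row.names = FALSE,
                   quote = FALSE)
  exc <- ref$exclusions
  out <- data.frame(scan_id = exc$scan_id,
                    coord_x_mm = num_fmt(exc$coord_x_mm),
                    coord_y_mm = num_fmt(exc$coord_y_mm),
                    coord_z_mm = num_fmt(exc$coord_z_mm),
                    diameter_mm = num_fmt(exc$diameter_mm),
                    agreement = exc$agreement, reason = exc$reason)
  utils::write.csv(out, file.path(dir, "exclusions.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(ref$missed_cancers)) {
    utils::write.csv(ref$missed_cancers, file.path(dir, "missed_cancers.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
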