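#' @name synthetic_cohort
#' @title Synthetic cohorts, reader panels and CAD predictions
#'
#' @description
#' Generates ground-truth cohorts with the structure of a four-category
#' clinical validation set (stage I lung cancer, pulmonary metastases,
#' actionable benign nodules, nodule-free controls; 25 scans each by
#' default), simulates a heterogeneous five-reader annotation panel and a
#' scored CAD system over them. All simulators are pure functions of their
#' inputs and a seed; a single pipeline seed is expanded into independent
#' per-stage streams by fixed offsets.
NULL

# Lognormal parameterized by its median and interquartile range:
# meanlog = log(median), sdlog solved from the 25th/75th quantile relation
# (qnorm(0.75) = 0.6745).
lognormal_params <- function(median, iqr) {
  list(meanlog = log(median), sdlog = log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75)))
}

#' Sample sizes from a median/IQR-parameterised lognormal
#'
#' @param n Number of draws.
#' @param median Target median.
#' @param iqr Length-2 vector, the 25th and 75th percentiles.
#' @return Numeric vector of draws.
#' @export
rlnorm_median_iqr <- function(n, median, iqr) {
  p <- lognormal_params(median, iqr)
  exp(stats::rnorm(n, p$meanlog, p$sdlog))
}

rlnorm_trunc <- function(n, median, iqr, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm_median_iqr(2 * (n - length(out)) + 10, median, iqr)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Cohort configuration
#'
#' Defaults emulate the study design: four balanced scan categories of 25
#' scans each, a per-scan nodule count with median 2 and IQR 1-4, a
#' lognormal diameter distribution with median 6.6 mm and IQR 4.7-11.9 mm,
#' the observed type mixture, and a cap of 15 metastases per scan.
#'
#' @param scans_per_category Named or unnamed length-4 integer vector
#'   (order: stage1_cancer, metastases, actionable_benign, normal).
#' @param count_median,count_iqr Per-scan nodule count distribution.
#' @param diameter_median,diameter_iqr Nodule diameter distribution (mm).
#' @param type_mixture Named probabilities over the five nodule types,
#'   summing to 1.
#' @param metastasis_cap Maximum metastases per scan (default 15).
#' @param scene_box Scene extents in mm (nodule centers are placed
#'   uniformly inside).
#' @param min_separation_factor Nodule centers are rejection-sampled until
#'   every pair is separated by more than this factor times the sum of
#'   their radii (> 1 so clustering and matching are unambiguous).
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(scans_per_category = c(stage1_cancer = 25,
                                                 metastases = 25,
                                                 actionable_benign = 25,
                                                 normal = 25),
                          count_median = 2, count_iqr = c(1, 4),
                          diameter_median = 6.6, diameter_iqr = c(4.7, 11.9),
                          type_mixture = c(solid = 0.815, part_solid = 0.063,
                                           non_solid = 0.033,
                                           perifissural = 0.056,
                                           calcified = 0.033),
                          metastasis_cap = 15,
                          scene_box = c(300, 250, 250),
                          min_separation_factor = 1.5,
                          seed = 1L) {
  if (is.null(names(scans_per_category))) {
    names(scans_per_category) <- SCAN_CATEGORIES
  }
  stopifnot(setequal(names(scans_per_category), SCAN_CATEGORIES),
            setequal(names(type_mixture), NODULE_TYPES),
            abs(sum(type_mixture) - 1) <= 1e-9,
            min_separation_factor > 1)
  structure(list(scans_per_category = scans_per_category[SCAN_CATEGORIES],
                 count_median = count_median, count_iqr = count_iqr,
                 diameter_median = diameter_median,
                 diameter_iqr = diameter_iqr,
                 type_mixture = type_mixture[NODULE_TYPES],
                 metastasis_cap = metastasis_cap, scene_box = scene_box,
                 min_separation_factor = min_separation_factor,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

sample_type <- function(n, mixture, allowed = names(mixture)) {
  p <- mixture[allowed]
  sample(allowed, n, replace = TRUE, prob = p / sum(p))
}

place_nodules <- function(diameters, box, sep_factor, max_tries = 2000) {
  n <- length(diameters)
  xyz <- matrix(NA_real_, n, 3)
  radii <- diameters / 2
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      p <- stats::runif(3) * box
      if (i == 1) { xyz[i, ] <- p; placed <- TRUE; break }
      d <- dist_to_points(p, xyz[seq_len(i - 1), , drop = FALSE])
      if (all(d > sep_factor * (radii[i] + radii[seq_len(i - 1)]))) {
        xyz[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed) {
      stop("could not place ", n, " nodules with the requested separation; ",
           "increase scene_box", call. = FALSE)
    }
  }
  xyz
}

#' Generate a ground-truth cohort
#'
#' Category rules: stage I cancer scans carry exactly one primary cancer
#' (6-30 mm) plus benign background nodules; metastasis scans carry 1 to
#' `metastasis_cap` metastases; actionable-benign scans carry at least one
#' benign nodule >= 5 mm that is neither calcified nor perifissural; normal
#' scans carry only sub-5 mm nodules or none. Malignant nodule types are
#' restricted to solid/part-solid/non-solid.
#'
#' @param config A [cohort_config()].
#' @return An object of class `ground_truth_cohort`: list with `scans`
#'   (manifest data.frame), `nodules` (latent truth table) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  scans <- data.frame(
    scan_id = character(), category = character(), stringsAsFactors = FALSE)
  nodules <- list()
  solid_ish <- c("solid", "part_solid", "non_solid")
  scan_no <- 0L
  for (cat in SCAN_CATEGORIES) {
    for (k in seq_len(cfg$scans_per_category[[cat]])) {
      scan_no <- scan_no + 1L
      sid <- sprintf("s%04d", scan_no)
      scans <- rbind(scans, data.frame(scan_id = sid, category = cat,
                                       stringsAsFactors = FALSE))
      n_raw <- round(rlnorm_median_iqr(1, cfg$count_median, cfg$count_iqr))
      dm <- cfg$diameter_median; di <- cfg$diameter_iqr
      if (cat == "stage1_cancer") {
        n <- max(1, n_raw)
        d <- c(rlnorm_trunc(1, dm, di, 6, 30),
               rlnorm_trunc(n - 1, dm, di, 3, 30))
        mal <- c("primary_cancer", rep("benign", n - 1))
        ty <- c(sample_type(1, cfg$type_mixture, solid_ish),
                sample_type(n - 1, cfg$type_mixture))
      } else if (cat == "metastases") {
        n <- min(cfg$metastasis_cap, max(1, n_raw))
        d <- rlnorm_trunc(n, dm, di, 3, 30)
        mal <- rep("metastasis", n)
        ty <- sample_type(n, cfg$type_mixture, solid_ish)
      } else if (cat == "actionable_benign") {
        n <- max(1, n_raw)
        d <- c(rlnorm_trunc(1, dm, di, 5, 30),
               rlnorm_trunc(n - 1, dm, di, 3, 30))
        mal <- rep("benign", n)
        ty <- c(sample_type(1, cfg$type_mixture, solid_ish),
                sample_type(n - 1, cfg$type_mixture))
      } else {  # normal: only sub-5 mm nodules, possibly none
        n <- max(0, n_raw - 1)
        d <- if (n > 0) rlnorm_trunc(n, dm, di, 3, 4.999) else numeric(0)
        mal <- rep("benign", n)
        ty <- sample_type(n, cfg$type_mixture)
      }
      if (n == 0) next
      xyz <- place_nodules(d, cfg$scene_box, cfg$min_separation_factor)
      nodules[[length(nodules) + 1]] <- data.frame(
        scan_id = sid, coord_x_mm = xyz[, 1], coord_y_mm = xyz[, 2],
        coord_z_mm = xyz[, 3], diameter_mm = d,
        volume_mm3 = volume_from_diameter(d), nodule_type = ty,
        malignancy = mal, stringsAsFactors = FALSE)
    }
  }
  nodules <- if (length(nodules)) do.call(rbind, nodules) else
    data.frame(scan_id = character(), coord_x_mm = numeric(),
               coord_y_mm = numeric(), coord_z_mm = numeric(),
               diameter_mm = numeric(), volume_mm3 = numeric(),
               nodule_type = character(), malignancy = character(),
               stringsAsFactors = FALSE)
  if (nrow(nodules) > 0) {
    nodules$nodule_id <- sprintf("t%04d", seq_len(nrow(nodules)))
  } else {
    nodules$nodule_id <- character(0)
  }
  rownames(nodules) <- NULL
  structure(list(scans = scans, nodules = nodules, config = cfg),
            class = "ground_truth_cohort")
}

#' @export
print.ground_truth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d scans, %d true nodules (seed %d)\n",
              nrow(x$scans), nrow(x$nodules), x$config$seed))
  print(table(x$scans$category))
  invisible(x)
}

#' Malignancy registry of a synthetic cohort
#'
#' @param cohort A `ground_truth_cohort`.
#' @return A registry data.frame with one record per malignant true nodule.
#' @export
truth_registry <- function(cohort) {
  m <- cohort$nodules[cohort$nodules$malignancy != "benign", , drop = FALSE]
  out <- data.frame(scan_id = m$scan_id, coord_x_mm = m$coord_x_mm,
                    coord_y_mm = m$coord_y_mm, coord_z_mm = m$coord_z_mm,
                    diameter_mm = m$diameter_mm, status = m$malignancy,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reader profile
#'
#' Detection follows a logistic model in log-diameter, scaled per nodule
#' type: `P(detect) = plogis(a + b * log(d)) * type_mult[type]`. Detected
#' nodules are annotated with isotropic Gaussian localisation jitter (sd a
#' fraction of the nodule radius) and relative size-measurement noise;
#' false-positive marks follow a per-scan Poisson process with their own
#' size distribution.
#'
#' @param reader_id Reader identifier.
#' @param a,b Logistic intercept and log-diameter slope.
#' @param type_mult Named multipliers per nodule type (in `[0, 1]`).
#' @param jitter_frac Localisation jitter sd as a fraction of radius (< 1).
#' @param size_noise_sd Relative sd of measured diameter.
#' @param fp_rate Poisson mean of false-positive marks per scan.
#' @param fp_diameter_median,fp_diameter_iqr Size distribution of
#'   false-positive marks (mm).
#' @return An object of class `reader_profile`.
#' @export
reader_profile <- function(reader_id, a = -3, b = 2.2,
                           type_mult = c(solid = 1, part_solid = 0.9,
                                         non_solid = 0.75,
                                         perifissural = 0.9,
                                         calcified = 0.95),
                           jitter_frac = 0.25, size_noise_sd = 0.1,
                           fp_rate = 0.4, fp_diameter_median = 3.6,
                           fp_diameter_iqr = c(2.8, 4.6)) {
  stopifnot(jitter_frac < 1, all(type_mult >= 0 & type_mult <= 1),
            fp_rate >= 0)
  structure(list(reader_id = reader_id, a = a, b = b,
                 type_mult = type_mult[NODULE_TYPES],
                 jitter_frac = jitter_frac, size_noise_sd = size_noise_sd,
                 fp_rate = fp_rate, fp_diameter_median = fp_diameter_median,
                 fp_diameter_iqr = fp_diameter_iqr),
            class = "reader_profile")
}

#' Default five-reader panel
#'
#' Heterogeneous profiles bracketing the range reported for clinical
#' panels: per-scan false-positive rates between 0.1 and 0.8 and
#' size-dependent sensitivities spanning roughly 30-90% on
#' metastasis-sized nodules. These are configuration choices, not
#' estimates.
#'
#' @return List of five `reader_profile` objects (`r1`..`r5`).
#' @export
default_reader_profiles <- function() {
  a <- c(r1 = -2.94, r2 = -4.90, r3 = -3.30, r4 = -4.35, r5 = -2.25)
  fp <- c(r1 = 0.7, r2 = 0.1, r3 = 0.2, r4 = 0.5, r5 = 0.8)
  lapply(names(a), function(r) reader_profile(r, a = a[[r]], fp_rate = fp[[r]]))
}

place_fp_marks <- function(n, box, truth_xyz, truth_radii, fp_radii,
                           sep_factor, max_tries = 2000) {
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    for (t in seq_len(max_tries)) {
      p <- stats::runif(3) * box
      ok <- if (NROW(truth_xyz) == 0) TRUE else {
        all(dist_to_points(p, truth_xyz) >
              sep_factor * (truth_radii + fp_radii[i]))
      }
      if (ok) { xyz[i, ] <- p; break }
    }
    if (is.na(xyz[i, 1])) {
      stop("could not place false-positive marks away from true nodules",
           call. = FALSE)
    }
  }
  xyz
}

#' Simulate a reader panel over a cohort
#'
#' @param cohort A `ground_truth_cohort`.
#' @param profiles List of [reader_profile()]s (default the five-reader
#'   panel of [default_reader_profiles()]).
#' @param seed Integer seed; defaults to the cohort seed plus a fixed
#'   stream offset.
#' @return An annotation data.frame in the [read_annotations()] layout.
#' @export
simulate_readers <- function(cohort, profiles = default_reader_profiles(),
                             seed = cohort$config$seed + 1000L) {
  stopifnot(inherits(cohort, "ground_truth_cohort"), length(profiles) >= 1)
  withr::with_seed(seed, simulate_readers_impl(cohort, profiles))
}

simulate_readers_impl <- function(cohort, profiles) {
  truth <- cohort$nodules
  box <- cohort$config$scene_box
  sep <- cohort$config$min_separation_factor
  rows <- list()
  for (pr in profiles) {
    p_det <- stats::plogis(pr$a + pr$b * log(truth$diameter_mm)) *
      pr$type_mult[truth$nodule_type]
    det <- stats::rbinom(nrow(truth), 1, p_det) == 1
    if (any(det)) {
      td <- truth[det, , drop = FALSE]
      r <- td$diameter_mm / 2
      jit <- matrix(stats::rnorm(3 * nrow(td), 0, 1), ncol = 3) *
        (pr$jitter_frac * r)
      dmeas <- pmax(td$diameter_mm *
                      (1 + stats::rnorm(nrow(td), 0, pr$size_noise_sd)),
                    0.2 * td$diameter_mm)
      rows[[length(rows) + 1]] <- data.frame(
        scan_id = td$scan_id, reader_id = pr$reader_id,
        coord_x_mm = td$coord_x_mm + jit[, 1],
        coord_y_mm = td$coord_y_mm + jit[, 2],
        coord_z_mm = td$coord_z_mm + jit[, 3],
        volume_mm3 = volume_from_diameter(dmeas), diameter_mm = dmeas,
        nodule_type = td$nodule_type, lobe = NA_character_,
        stringsAsFactors = FALSE)
    }
    # false-positive marks, placed away from any true nodule
    for (sid in cohort$scans$scan_id) {
      n_fp <- stats::rpois(1, pr$fp_rate)
      if (n_fp == 0) next
      dfp <- rlnorm_trunc(n_fp, pr$fp_diameter_median, pr$fp_diameter_iqr,
                          1.5, 10)
      ti <- truth$scan_id == sid
      xyz <- place_fp_marks(n_fp, box,
                            as.matrix(truth[ti, COORD_COLS, drop = FALSE]),
                            truth$diameter_mm[ti] / 2, dfp / 2, sep)
      rows[[length(rows) + 1]] <- data.frame(
        scan_id = sid, reader_id = pr$reader_id,
        coord_x_mm = xyz[, 1], coord_y_mm = xyz[, 2], coord_z_mm = xyz[, 3],
        volume_mm3 = volume_from_diameter(dfp), diameter_mm = dfp,
        nodule_type = sample_type(n_fp, cohort$config$type_mixture),
        lobe = NA_character_, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scan_id = character(), reader_id = character(),
               coord_x_mm = numeric(), coord_y_mm = numeric(),
               coord_z_mm = numeric(), volume_mm3 = numeric(),
               diameter_mm = numeric(), nodule_type = character(),
               lobe = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  canonical_order(out)
}

#' CAD profile
#'
#' Per true nodule a candidate is emitted with probability
#' `plogis(emission_a + emission_b * log(d))` and scored by
#' `plogis(score_a + score_b * log(d) + score_type[type] + e)`,
#' `e ~ N(0, score_sd)`, clipped to `[0, 1]`. False-positive candidates
#' follow a per-scan Poisson process with Beta-distributed (low,
#' right-skewed) scores, giving the FROC curve a full FP/s sweep.
#'
#' The defaults are calibrated so that, on the default cohort evaluated
#' against the default five-reader consensus, the simulated system
#' operates at about 90% sensitivity at 1 FP/s with a CPM in the high
#' 80s - the regime of a strong clinical nodule-detection system.
#'
#' @param emission_a,emission_b Candidate-emission logistic parameters.
#' @param score_a,score_b,score_sd True-positive score model parameters.
#' @param score_type Named additive type effects on the score logit.
#' @param jitter_frac Candidate localisation jitter sd as a fraction of
#'   nodule radius.
#' @param fp_rate Poisson mean of false-positive candidates per scan.
#' @param fp_shape1,fp_shape2 Beta parameters of false-positive scores.
#' @return An object of class `cad_profile`.
#' @export
cad_profile <- function(emission_a = 1.1, emission_b = 1.4,
                        score_a = -1.85, score_b = 1.5, score_sd = 1.1,
                        score_type = c(solid = 0, part_solid = -0.4,
                                       non_solid = -0.9, perifissural = -0.2,
                                       calcified = 0.2),
                        jitter_frac = 0.1, fp_rate = 10,
                        fp_shape1 = 1.2, fp_shape2 = 6) {
  stopifnot(jitter_frac < 1, fp_rate >= 0)
  structure(list(emission_a = emission_a, emission_b = emission_b,
                 score_a = score_a, score_b = score_b, score_sd = score_sd,
                 score_type = score_type[NODULE_TYPES],
                 jitter_frac = jitter_frac, fp_rate = fp_rate,
                 fp_shape1 = fp_shape1, fp_shape2 = fp_shape2),
            class = "cad_profile")
}

#' Simulate scored CAD predictions over a cohort
#'
#' @param cohort A `ground_truth_cohort`.
#' @param profile A [cad_profile()].
#' @param seed Integer seed; defaults to the cohort seed plus a fixed
#'   stream offset.
#' @return A prediction data.frame in the [read_predictions()] layout.
#' @export
simulate_cad <- function(cohort, profile = cad_profile(),
                         seed = cohort$config$seed + 2000L) {
  stopifnot(inherits(cohort, "ground_truth_cohort"),
            inherits(profile, "cad_profile"))
  withr::with_seed(seed, simulate_cad_impl(cohort, profile))
}

simulate_cad_impl <- function(cohort, pr) {
  truth <- cohort$nodules
  box <- cohort$config$scene_box
  sep <- cohort$config$min_separation_factor
  rows <- list()
  if (nrow(truth) > 0) {
    p_emit <- stats::plogis(pr$emission_a + pr$emission_b * log(truth$diameter_mm))
    emit <- stats::rbinom(nrow(truth), 1, p_emit) == 1
    if (any(emit)) {
      td <- truth[emit, , drop = FALSE]
      r <- td$diameter_mm / 2
      jit <- matrix(stats::rnorm(3 * nrow(td), 0, 1), ncol = 3) *
        (pr$jitter_frac * r)
      logit <- pr$score_a + pr$score_b * log(td$diameter_mm) +
        pr$score_type[td$nodule_type] +
        stats::rnorm(nrow(td), 0, pr$score_sd)
      rows[[length(rows) + 1]] <- data.frame(
        scan_id = td$scan_id,
        coord_x_mm = td$coord_x_mm + jit[, 1],
        coord_y_mm = td$coord_y_mm + jit[, 2],
        coord_z_mm = td$coord_z_mm + jit[, 3],
        score = pmin(pmax(stats::plogis(logit), 0), 1),
        stringsAsFactors = FALSE)
    }
  }
  for (sid in cohort$scans$scan_id) {
    n_fp <- stats::rpois(1, pr$fp_rate)
    if (n_fp == 0) next
    ti <- truth$scan_id == sid
    xyz <- place_fp_marks(n_fp, box,
                          as.matrix(truth[ti, COORD_COLS, drop = FALSE]),
                          truth$diameter_mm[ti] / 2, rep(2, n_fp), sep)
    rows[[length(rows) + 1]] <- data.frame(
      scan_id = sid, coord_x_mm = xyz[, 1], coord_y_mm = xyz[, 2],
      coord_z_mm = xyz[, 3],
      score = stats::rbeta(n_fp, pr$fp_shape1, pr$fp_shape2),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scan_id = character(), coord_x_mm = numeric(),
               coord_y_mm = numeric(), coord_z_mm = numeric(),
               score = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$scan_id, out$coord_x_mm, out$coord_y_mm,
                   out$coord_z_mm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort and its simulated data to CSV files
#'
#' Writes exactly the CSV dialects of the I/O module (`scans.csv`,
#' `annotations.csv`, `predictions.csv`, `registry.csv`) plus a
#' `truth.csv` with the latent nodules for oracle tests only.
#'
#' @param cohort A `ground_truth_cohort`.
#' @param dir Output directory.
#' @param annotations,predictions Optional simulated tables to write
#'   alongside.
#' @export
write_cohort <- function(cohort, dir, annotations = NULL, predictions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_scan_manifest(cohort$scans, file.path(dir, "scans.csv"))
  truth <- cohort$nodules
  for (cc in c(COORD_COLS, "volume_mm3", "diameter_mm")) {
    truth[[cc]] <- num_fmt(truth[[cc]])
  }
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  write_registry(truth_registry(cohort), file.path(dir, "registry.csv"))
  if (!is.null(annotations)) {
    write_annotations(annotations, file.path(dir, "annotations.csv"))
  }
  if (!is.null(predictions)) {
    write_predictions(predictions, file.path(dir, "predictions.csv"))
  }
  invisible(dir)
}

#' A noise-free panel and CAD for end-to-end identity checks
#'
#' `perfect_reader_profiles()` returns readers that detect every nodule
#' with no jitter, no size noise and no false positives;
#' `perfect_cad_profile()` emits every nodule with (near-)unit scores and
#' no false-positive process. With these, the consensus reference equals
#' the ground truth and CAD sensitivity is 1 at 0 FP/s.
#'
#' @param n_readers Panel size (default 5).
#' @return A list of `reader_profile`s / a `cad_profile`.
#' @export
perfect_reader_profiles <- function(n_readers = 5) {
  lapply(sprintf("r%d", seq_len(n_readers)), function(r) {
    reader_profile(r, a = 50, b = 0,
                   type_mult = c(solid = 1, part_solid = 1, non_solid = 1,
                                 perifissural = 1, calcified = 1),
                   jitter_frac = 0, size_noise_sd = 0, fp_rate = 0)
  })
}

#' @rdname perfect_reader_profiles
#' @export
perfect_cad_profile <- function() {
  cad_profile(emission_a = 50, emission_b = 0, score_a = 50, score_b = 0,
              score_sd = 0,
              score_type = c(solid = 0, part_solid = 0, non_solid = 0,
                             perifissural = 0, calcified = 0),
              jitter_frac = 0, fp_rate = 0)
}
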