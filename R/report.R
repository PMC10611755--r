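#' @name cli_report
#' @title Evaluation pipeline and report generation
#'
#' @description
#' [run_evaluation()] drives the full pipeline (reference building,
#' matching, per-subset sensitivity tables with bootstrap CIs, FROC point
#' export) from a configuration list or YAML file; [run_comparison()]
#' produces the reader-vs-AI comparison table and per-comparison FROC
#' points. A thin command-line wrapper over these functions is installed
#' at `system.file("cli", "nodeval.R", package = "nodeval")`.
NULL

#' Evaluation configuration
#'
#' @param manifest,annotations,predictions,registry Input file paths
#'   (`registry` may be NULL).
#' @param output_dir Directory for all result files.
#' @param min_agreement Majority threshold (default 3).
#' @param size_bounds Inclusive diameter window in mm (default `c(3, 30)`).
#' @param fp_rates FP/s rates for the sensitivity table (ascending).
#' @param target_fp Operating-point budget in FP/s (default 1).
#' @param n_boot,n_perm Bootstrap and permutation iterations (default 1000
#'   each).
#' @param seed Integer seed.
#' @param subsets Named list of subset specifications, each
#'   `list(min_diameter=, class_filter=)`; default mirrors the reported
#'   row set (diameter thresholds 3/4/5 mm plus the three nodule classes).
#' @return An object of class `evaluation_config`.
#' @export
evaluation_config <- function(manifest, annotations, predictions,
                              registry = NULL, output_dir = "nodeval_run",
                              min_agreement = 3, size_bounds = c(3, 30),
                              fp_rates = DEFAULT_FP_RATES, target_fp = 1.0,
                              n_boot = 1000, n_perm = 1000, seed = 1L,
                              subsets = NULL) {
  if (is.unsorted(fp_rates)) stop("fp_rates must be ascending", call. = FALSE)
  if (is.null(subsets)) {
    subsets <- list(
      all_ge3mm = list(min_diameter = 3, class_filter = "all"),
      all_ge4mm = list(min_diameter = 4, class_filter = "all"),
      all_ge5mm = list(min_diameter = 5, class_filter = "all"),
      actionable_benign = list(min_diameter = 3,
                               class_filter = "actionable_benign"),
      primary_cancer = list(min_diameter = 3,
                            class_filter = "primary_cancer"),
      metastasis = list(min_diameter = 3, class_filter = "metastasis"))
  }
  structure(list(manifest = manifest, annotations = annotations,
                 predictions = predictions, registry = registry,
                 output_dir = output_dir, min_agreement = min_agreement,
                 size_bounds = size_bounds, fp_rates = fp_rates,
                 target_fp = target_fp, n_boot = n_boot, n_perm = n_perm,
                 seed = as.integer(seed), subsets = subsets),
            class = "evaluation_config")
}

#' @rdname evaluation_config
#' @param path Path to a YAML configuration file whose keys are the
#'   arguments of `evaluation_config()`.
#' @export
read_evaluation_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(evaluation_config, y)
}

config_fingerprint <- function(config) {
  # deterministic content hash of the configuration (order-independent)
  flat <- unlist(config[sort(names(unclass(config)))])
  txt <- paste(names(flat), as.character(flat), sep = "=", collapse = ";")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)))
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  message(msg)
}

load_inputs <- function(config) {
  manifest <- read_scan_manifest(config$manifest)
  annotations <- read_annotations(config$annotations, manifest)
  predictions <- read_predictions(config$predictions, manifest)
  registry <- if (!is.null(config$registry)) {
    read_registry(config$registry, manifest)
  }
  list(manifest = manifest, annotations = annotations,
       predictions = predictions, registry = registry)
}

#' Run the full detection evaluation
#'
#' Builds the consensus reference, links malignancies, matches the
#' predictions, and writes per-subset sensitivity tables with bootstrap
#' CIs (`table3.csv`), FROC operating points per subset
#' (`froc_points_<subset>.csv`), the reference files, the per-prediction
#' match table (`match.csv`) and a run log.
#'
#' @param config An [evaluation_config()] (or path to a YAML file).
#' @return Invisibly, a list with the reference, match results and the
#'   sensitivity table.
#' @export
run_evaluation <- function(config) {
  if (is.character(config)) config <- read_evaluation_config(config)
  stopifnot(inherits(config, "evaluation_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$output_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  log_line(logf, "nodeval ", as.character(utils::packageVersion("nodeval")),
           " evaluate | seed ", config$seed, " | config ",
           config_fingerprint(config))

  inp <- load_inputs(config)
  ref <- build_reference_standard(inp$annotations, inp$manifest,
                                  config$min_agreement, config$size_bounds)
  ref <- link_malignancy(ref, inp$registry)
  write_reference_standard(ref, config$output_dir)
  log_line(logf, sprintf(
    "reference: %d clusters = %d included + %d excluded (conservation %s); %d panel-missed cancers",
    ref$n_clusters, nrow(ref$nodules) - sum(!ref$nodules$detected_by_panel),
    nrow(ref$exclusions) + sum(ref$missed_cancers$resolution == "promoted_minority"),
    "holds", nrow(ref$missed_cancers)))

  rows <- list()
  full_match <- NULL
  for (sub_name in names(config$subsets)) {
    sp <- config$subsets[[sub_name]]
    view <- select_subset(ref, sp$min_diameter, sp$class_filter)
    if (nrow(view$targets) == 0) {
      log_line(logf, "subset ", sub_name, ": no targets, skipped")
      next
    }
    m <- match_predictions(inp$predictions, view)
    if (is.null(full_match)) full_match <- m
    curve <- froc_curve(m)
    rep_ <- sensitivity_report(curve, config$fp_rates)
    ci <- bootstrap_ci_from_match(m, inp$manifest$scan_id, config$fp_rates,
                                  config$n_boot, seed = config$seed)
    cal <- calibrate_threshold(curve, config$target_fp)
    pts <- curve$points
    pts$threshold <- ifelse(is.finite(pts$threshold),
                            sprintf("%.6f", pts$threshold), "Inf")
    utils::write.csv(pts,
                     file.path(config$output_dir,
                               paste0("froc_points_", sub_name, ".csv")),
                     row.names = FALSE, quote = FALSE)
    row <- data.frame(subset = sub_name, n_targets = m$n_targets,
                      stringsAsFactors = FALSE)
    for (i in seq_along(config$fp_rates)) {
      row[[paste0("sens_", config$fp_rates[i])]] <-
        as_percent(rep_$sensitivities[i])
      row[[paste0("sens_", config$fp_rates[i], "_lo")]] <-
        as_percent(ci$ci[1, i])
      row[[paste0("sens_", config$fp_rates[i], "_hi")]] <-
        as_percent(ci$ci[2, i])
    }
    row$cpm <- as_percent(rep_$cpm)
    row$cpm_lo <- as_percent(ci$cpm_ci[1])
    row$cpm_hi <- as_percent(ci$cpm_ci[2])
    row$threshold_at_target <- cal$threshold
    row$sens_at_threshold <- as_percent(cal$sensitivity)
    row$fp_at_threshold <- cal$fp_per_scan
    rows[[sub_name]] <- row
    log_line(logf, sprintf(
      "subset %s: %d targets, CPM %.1f, threshold %.4f at <=%g FP/s",
      sub_name, m$n_targets, as_percent(rep_$cpm), cal$threshold,
      config$target_fp))
  }
  table3 <- do.call(rbind, rows)
  rownames(table3) <- NULL
  utils::write.csv(table3, file.path(config$output_dir, "table3.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(full_match)) {
    mp <- full_match$predictions
    mp$distance_mm <- ifelse(is.na(mp$distance_mm), "",
                             sprintf("%.6f", mp$distance_mm))
    utils::write.csv(
      mp[c("scan_id", "score", "label", "matched_nodule_id", "distance_mm")],
      file.path(config$output_dir, "match.csv"), row.names = FALSE,
      quote = FALSE)
  }
  invisible(list(reference = ref, table = table3, match = full_match))
}

#' Run the reader-vs-AI comparison
#'
#' Writes `comparison.csv` (one row per reader x category), per-comparison
#' FROC point files, and the across-comparison average FROC per category
#' on a shared FP/s grid.
#'
#' @inheritParams run_evaluation
#' @param categories Categories to compare.
#' @return Invisibly, the [comparison_table()] result.
#' @export
run_comparison <- function(config,
                           categories = c("actionable_benign",
                                          "primary_cancer", "metastasis")) {
  if (is.character(config)) config <- read_evaluation_config(config)
  stopifnot(inherits(config, "evaluation_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$output_dir, "comparison.log"), open = "wt")
  on.exit(close(logf))
  log_line(logf, "nodeval ", as.character(utils::packageVersion("nodeval")),
           " compare | seed ", config$seed, " | config ",
           config_fingerprint(config))

  inp <- load_inputs(config)
  n_readers <- length(unique(inp$annotations$reader_id))
  if (n_readers < config$min_agreement + 1) {
    stop("need at least min_agreement + 1 = ", config$min_agreement + 1,
         " readers, got ", n_readers, call. = FALSE)
  }
  res <- comparison_table(inp$predictions, inp$annotations, inp$manifest,
                          inp$registry, categories = categories,
                          min_agreement = config$min_agreement,
                          target_fp = config$target_fp,
                          n_boot = config$n_boot, n_iter = config$n_perm,
                          seed = config$seed)
  tab <- res$table
  tab$p_value <- format_p(tab$p_value)
  utils::write.csv(tab, file.path(config$output_dir, "comparison.csv"),
                   row.names = FALSE, quote = FALSE)

  grid <- sort(unique(c(DEFAULT_FP_RATES,
                        seq(0.125, 8, length.out = 64))))
  for (cat in categories) {
    keys <- grep(paste0("\\.", cat, "$"), names(res$comparisons),
                 value = TRUE)
    if (length(keys) == 0) next
    sens_mat <- vapply(keys, function(k) {
      cmp <- res$comparisons[[k]]
      pts <- cmp$curve$points
      pts$threshold <- ifelse(is.finite(pts$threshold),
                              sprintf("%.6f", pts$threshold), "Inf")
      utils::write.csv(pts, file.path(config$output_dir,
                                      paste0("froc_points_", k, ".csv")),
                       row.names = FALSE, quote = FALSE)
      sensitivity_at(cmp$curve, grid)
    }, numeric(length(grid)))
    avg <- data.frame(fp_per_scan = grid,
                      sensitivity = rowMeans(sens_mat))
    utils::write.csv(avg,
                     file.path(config$output_dir,
                               paste0("froc_average_", cat, ".csv")),
                     row.names = FALSE, quote = FALSE)
    log_line(logf, "category ", cat, ": ", length(keys),
             " comparisons averaged")
  }
  invisible(res)
}

#' Simulate a full synthetic study to disk
#'
#' Convenience wrapper chaining [generate_cohort()], [simulate_readers()]
#' and [simulate_cad()], writing all CSV files to a directory.
#'
#' @param dir Output directory.
#' @param config A [cohort_config()].
#' @param profiles Reader profiles.
#' @param cad A [cad_profile()].
#' @return Invisibly, the directory.
#' @export
simulate_study <- function(dir, config = cohort_config(),
                           profiles = default_reader_profiles(),
                           cad = cad_profile()) {
  cohort <- generate_cohort(config)
  ann <- simulate_readers(cohort, profiles)
  preds <- simulate_cad(cohort, cad)
  write_cohort(cohort, dir, annotations = ann, predictions = preds)
  invisible(dir)
}
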