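#' @name annotations_io
#' @title File formats for scan manifests, annotations, predictions and registry
#'
#' @description
#' All tables are comma-separated UTF-8 files with mandatory headers, using
#' world coordinates in millimetres (LUNA16-style):
#'
#' * `scans.csv`: `scan_id,category[,patient_id]`
#' * `annotations.csv`:
#'   `scan_id,reader_id,coord_x_mm,coord_y_mm,coord_z_mm,volume_mm3,nodule_type[,lobe]`
#'   (a `diameter_mm` column may stand in for, or accompany, `volume_mm3`)
#' * `predictions.csv`: `scan_id,coord_x_mm,coord_y_mm,coord_z_mm,score`
#' * `registry.csv`: `scan_id,coord_x_mm,coord_y_mm,coord_z_mm,diameter_mm,status`
#'
#' Unknown extra columns are ignored. Numeric fields are written with six
#' decimal places, so write-then-read round-trips are lossless to that
#' precision. Malformed rows are hard errors that name the offending row;
#' nothing is ever silently dropped.
NULL

COORD_COLS <- c("coord_x_mm", "coord_y_mm", "coord_z_mm")

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(what, " file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

num_fmt <- function(x) sprintf("%.6f", x)

#' Read a scan manifest
#'
#' The manifest enumerates every scan in the evaluation, including
#' nodule-free scans, which participate in the false-positives-per-scan
#' denominator.
#'
#' @param path Path to a `scans.csv` file (`scan_id,category[,patient_id]`).
#' @return A data.frame with columns `scan_id`, `category` and, when present
#'   in the file, `patient_id`.
#' @export
read_scan_manifest <- function(path) {
  df <- read_csv_checked(path, c("scan_id", "category"), "manifest")
  df$scan_id <- as.character(df$scan_id)
  dup <- unique(df$scan_id[duplicated(df$scan_id)])
  if (length(dup) > 0) {
    stop("duplicate scan_id in manifest: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- !df$category %in% SCAN_CATEGORIES
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unknown category '", df$category[i], "' in manifest row ", i,
         " (scan_id ", df$scan_id[i], ")", call. = FALSE)
  }
  keep <- intersect(c("scan_id", "category", "patient_id"), names(df))
  df[keep]
}

#' @rdname read_scan_manifest
#' @param scans Manifest data.frame as returned by `read_scan_manifest()`.
#' @export
write_scan_manifest <- function(scans, path) {
  utils::write.csv(scans, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Validate and complete size columns: every annotation ends up with both
# volume_mm3 and diameter_mm, mutually consistent via the sphere identity.
complete_sizes <- function(df, what) {
  has_vol <- "volume_mm3" %in% names(df)
  has_dia <- "diameter_mm" %in% names(df)
  if (!has_vol && !has_dia) {
    stop(what, ": need a volume_mm3 or diameter_mm column", call. = FALSE)
  }
  if (!has_vol) df$volume_mm3 <- NA_real_
  if (!has_dia) df$diameter_mm <- NA_real_
  df$volume_mm3 <- as.numeric(df$volume_mm3)
  df$diameter_mm <- as.numeric(df$diameter_mm)
  none <- is.na(df$volume_mm3) & is.na(df$diameter_mm)
  if (any(none)) {
    stop(what, " row ", which(none)[1], ": both volume and diameter missing",
         call. = FALSE)
  }
  bad <- (!is.na(df$volume_mm3) & df$volume_mm3 <= 0) |
    (!is.na(df$diameter_mm) & df$diameter_mm <= 0)
  if (any(bad)) {
    stop(what, " row ", which(bad)[1], ": non-positive nodule size",
         call. = FALSE)
  }
  i <- is.na(df$diameter_mm)
  df$diameter_mm[i] <- equivalent_diameter(df$volume_mm3[i])
  i <- is.na(df$volume_mm3)
  df$volume_mm3[i] <- volume_from_diameter(df$diameter_mm[i])
  df
}

check_scan_ids <- function(df, manifest, what) {
  if (is.null(manifest)) return(invisible())
  unknown <- setdiff(df$scan_id, manifest$scan_id)
  if (length(unknown) > 0) {
    stop(what, " references scan_id(s) absent from the manifest: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  invisible()
}

#' Read per-reader nodule annotations
#'
#' @param path Path to an `annotations.csv` file. Either `volume_mm3` or
#'   `diameter_mm` must be present; the other is derived via the
#'   volume-equivalent sphere identity.
#' @param manifest Optional manifest data.frame; when given, annotations on
#'   scans outside the manifest are an error.
#' @return A data.frame with one row per annotation and columns `scan_id`,
#'   `reader_id`, `coord_x_mm`, `coord_y_mm`, `coord_z_mm`, `volume_mm3`,
#'   `diameter_mm`, `nodule_type` and `lobe` (NA when absent from the file).
#' @export
read_annotations <- function(path, manifest = NULL) {
  df <- read_csv_checked(path, c("scan_id", "reader_id", COORD_COLS,
                                 "nodule_type"), "annotations")
  df$scan_id <- as.character(df$scan_id)
  df$reader_id <- as.character(df$reader_id)
  for (cc in COORD_COLS) df[[cc]] <- as.numeric(df[[cc]])
  df <- complete_sizes(df, "annotations")
  bad <- !df$nodule_type %in% NODULE_TYPES
  if (any(bad)) {
    stop("annotations row ", which(bad)[1], ": unknown nodule_type '",
         df$nodule_type[which(bad)[1]], "'", call. = FALSE)
  }
  if (!"lobe" %in% names(df)) df$lobe <- NA_character_
  check_scan_ids(df, manifest, "annotations")
  df[c("scan_id", "reader_id", COORD_COLS, "volume_mm3", "diameter_mm",
       "nodule_type", "lobe")]
}

#' @rdname read_annotations
#' @param annotations Annotation data.frame as returned by `read_annotations()`.
#' @export
write_annotations <- function(annotations, path) {
  out <- annotations
  for (cc in c(COORD_COLS, "volume_mm3", "diameter_mm")) {
    out[[cc]] <- num_fmt(out[[cc]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split an annotation table by reader
#'
#' @param annotations Annotation data.frame.
#' @return A named list mapping each `reader_id` to its annotation rows.
#' @export
annotations_by_reader <- function(annotations) {
  split(annotations, annotations$reader_id)
}

#' Read or write scored CAD predictions
#'
#' Each prediction is a world-coordinate point with a nodule-likelihood
#' score in `[0, 1]`. Rows with scores outside that range, or malformed
#' numeric fields, are rejected with an error naming the row.
#'
#' @param path Path to a `predictions.csv` file
#'   (`scan_id,coord_x_mm,coord_y_mm,coord_z_mm,score`).
#' @param manifest Optional manifest data.frame for scan-id validation.
#' @return A data.frame of predictions. An empty file (header only) yields
#'   an empty data.frame, not an error.
#' @export
read_predictions <- function(path, manifest = NULL) {
  df <- read_csv_checked(path, c("scan_id", COORD_COLS, "score"), "predictions")
  df$scan_id <- as.character(df$scan_id)
  for (cc in c(COORD_COLS, "score")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- is.na(v) & !is.na(df[[cc]])
    if (any(bad)) {
      stop("predictions file ", path, ", row ", which(bad)[1],
           ": malformed value in column ", cc, call. = FALSE)
    }
    df[[cc]] <- v
  }
  out_of_range <- is.na(df$score) | df$score < 0 | df$score > 1
  if (any(out_of_range)) {
    stop("predictions file ", path, ", row ", which(out_of_range)[1],
         ": score outside [0, 1]", call. = FALSE)
  }
  check_scan_ids(df, manifest, "predictions")
  df[c("scan_id", COORD_COLS, "score")]
}

#' @rdname read_predictions
#' @param predictions Prediction data.frame.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions[c("scan_id", COORD_COLS, "score")]
  for (cc in c(COORD_COLS, "score")) out[[cc]] <- num_fmt(out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the malignancy registry
#'
#' Registry records localize histologically or clinically confirmed
#' malignancies (primary cancers and metastases); benign status is the
#' absence of a record.
#'
#' @param path Path to a `registry.csv` file
#'   (`scan_id,coord_x_mm,coord_y_mm,coord_z_mm,diameter_mm,status`).
#' @param manifest Optional manifest data.frame for scan-id validation.
#' @return A data.frame of registry records.
#' @export
read_registry <- function(path, manifest = NULL) {
  df <- read_csv_checked(path, c("scan_id", COORD_COLS, "diameter_mm",
                                 "status"), "registry")
  df$scan_id <- as.character(df$scan_id)
  for (cc in c(COORD_COLS, "diameter_mm")) df[[cc]] <- as.numeric(df[[cc]])
  bad <- !df$status %in% c("primary_cancer", "metastasis")
  if (any(bad)) {
    stop("registry row ", which(bad)[1], ": status must be primary_cancer ",
         "or metastasis, got '", df$status[which(bad)[1]], "'", call. = FALSE)
  }
  check_scan_ids(df, manifest, "registry")
  df[c("scan_id", COORD_COLS, "diameter_mm", "status")]
}

#' @rdname read_registry
#' @param registry Registry data.frame.
#' @export
write_registry <- function(registry, path) {
  out <- registry[c("scan_id", COORD_COLS, "diameter_mm", "status")]
  for (cc in c(COORD_COLS, "diameter_mm")) out[[cc]] <- num_fmt(out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
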