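#' Assemble a feature table
#'
#' A feature table bundles a peak-area matrix (one row per injection, one
#' column per aligned chromatographic feature) with per-injection sample
#' metadata and per-feature metadata. It is the object every preprocessing
#' stage consumes and returns.
#'
#' @param areas Numeric matrix of non-negative peak areas, injections in rows,
#'   features in columns. Column names are taken as feature ids (generated if
#'   absent).
#' @param sample_meta Data frame with one row per injection and columns
#'   `id` (character), `role` (one of `"sample"`, `"QC"`, `"blank"`),
#'   `class` (`"PCa"`, `"BPH"` or `NA` for non-sample rows),
#'   `injection_order` (unique positive integers) and `creatinine`
#'   (mg/dL; positive for `role == "sample"`, `NA` otherwise).
#' @param feature_meta Data frame with one row per feature and columns
#'   `id`, `molecular_weight` (Da) and `retention_time` (min). Generated with
#'   `NA` masses/times when omitted.
#'
#' @return An object of class `feature_table`: a list with elements `areas`,
#'   `sample_meta`, `feature_meta`.
#' @export
feature_table <- function(areas, sample_meta, feature_meta = NULL) {
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  if (is.null(feature_meta)) {
    ids <- colnames(areas)
    if (is.null(ids)) ids <- sprintf("F%04d", seq_len(ncol(areas)))
    feature_meta <- data.frame(id = ids, molecular_weight = NA_real_,
                               retention_time = NA_real_,
                               stringsAsFactors = FALSE)
  }
  if (is.null(colnames(areas))) colnames(areas) <- feature_meta$id
  if (nrow(areas) == nrow(sample_meta)) rownames(areas) <- sample_meta$id
  x <- structure(list(areas = areas,
                      sample_meta = as.data.frame(sample_meta),
                      feature_meta = as.data.frame(feature_meta)),
                 class = "feature_table")
  validate_feature_table(x)
  x
}

#' Validate feature-table invariants
#'
#' Checks row/column consistency between the area matrix and the metadata,
#' uniqueness of injection orders, admissible roles and classes, and positive
#' creatinine on sample rows. Called by the constructor and by
#' [read_feature_table()].
#'
#' @param x A `feature_table`.
#' @return `x`, invisibly, if all invariants hold; otherwise an error naming
#'   the offending record.
#' @export
validate_feature_table <- function(x) {
  sm <- x$sample_meta
  need <- c("id", "role", "class", "injection_order", "creatinine")
  miss <- setdiff(need, names(sm))
  if (length(miss))
    stop("sample_meta lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x$areas) != nrow(sm))
    stop("area matrix has ", nrow(x$areas), " rows but sample_meta has ",
         nrow(sm), " rows")
  if (ncol(x$areas) != nrow(x$feature_meta))
    stop("area matrix has ", ncol(x$areas), " columns but feature_meta has ",
         nrow(x$feature_meta), " rows")
  bad_role <- setdiff(unique(sm$role), c("sample", "QC", "blank"))
  if (length(bad_role))
    stop("unknown sample role(s): ", paste(bad_role, collapse = ", "))
  bad_class <- setdiff(unique(sm$class[!is.na(sm$class)]), c("PCa", "BPH"))
  if (length(bad_class))
    stop("unknown class label(s): ", paste(bad_class, collapse = ", "))
  if (anyDuplicated(sm$injection_order))
    stop("injection_order values are not unique")
  if (any(x$areas < 0, na.rm = TRUE))
    stop("peak areas must be non-negative")
  smp <- sm$role == "sample"
  bad_cre <- smp & (is.na(sm$creatinine) | sm$creatinine <= 0)
  if (any(bad_cre))
    stop("missing or non-positive creatinine for sample(s): ",
         paste(sm$id[bad_cre], collapse = ", "))
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  sm <- x$sample_meta
  cat("Feature table: ", nrow(x$areas), " injections x ", ncol(x$areas),
      " features\n", sep = "")
  cat("  roles:   ", paste(sprintf("%s=%d", names(table(sm$role)),
                                   table(sm$role)), collapse = ", "), "\n",
      sep = "")
  cl <- table(sm$class[sm$role == "sample"])
  if (length(cl))
    cat("  classes: ", paste(sprintf("%s=%d", names(cl), cl),
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Injection-order rows treated as pooled-QC monitors: QCs injected after the
# first real sample. Earlier QCs condition the chromatographic system and are
# excluded from drift regression and RSD statistics.
monitoring_qc_rows <- function(x) {
  sm <- x$sample_meta
  first_sample <- suppressWarnings(
    min(sm$injection_order[sm$role == "sample"]))
  which(sm$role == "QC" & sm$injection_order > first_sample)
}

subset_features <- function(x, keep) {
  x$areas <- x$areas[, keep, drop = FALSE]
  x$feature_meta <- x$feature_meta[keep, , drop = FALSE]
  rownames(x$feature_meta) <- NULL
  x
}

subset_rows <- function(x, keep) {
  x$areas <- x$areas[keep, , drop = FALSE]
  x$sample_meta <- x$sample_meta[keep, , drop = FALSE]
  rownames(x$sample_meta) <- NULL
  x
}

#' Read a feature table from delimited text files
#'
#' Reads the comma-separated interchange format written by
#' [write_feature_table()]: an area file (rows = injections, columns =
#' features, first column the injection id), a sample-metadata file and an
#' optional feature-metadata file.
#'
#' @param areas_file,samples_file,features_file Paths to the CSV files;
#'   `features_file` may be `NULL`.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(areas_file, samples_file, features_file = NULL) {
  a <- utils::read.csv(areas_file, check.names = FALSE,
                       stringsAsFactors = FALSE)
  sm <- utils::read.csv(samples_file, stringsAsFactors = FALSE)
  areas <- as.matrix(a[, -1, drop = FALSE])
  rownames(areas) <- a[[1]]
  if (nrow(areas) != nrow(sm))
    stop("area file has ", nrow(areas), " injection rows but sample file has ",
         nrow(sm), " rows")
  if (!identical(as.character(a[[1]]), as.character(sm$id)))
    stop("injection ids differ between area and sample files")
  fm <- if (!is.null(features_file))
    utils::read.csv(features_file, stringsAsFactors = FALSE) else NULL
  if (!is.null(fm) && !identical(as.character(fm$id), colnames(areas)))
    stop("feature ids differ between area and feature files")
  feature_table(areas, sm, fm)
}

#' Write a feature table to delimited text files
#'
#' @param x A `feature_table`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are
#'   `<prefix>_areas.csv`, `<prefix>_samples.csv`, `<prefix>_features.csv`.
#' @return Invisibly, the vector of paths written.
#' @export
write_feature_table <- function(x, dir, prefix = "table") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_areas.csv", "_samples.csv",
                                           "_features.csv")))
  a <- data.frame(id = x$sample_meta$id, x$areas, check.names = FALSE)
  utils::write.csv(a, paths[1], row.names = FALSE)
  utils::write.csv(x$sample_meta, paths[2], row.names = FALSE)
  utils::write.csv(x$feature_meta, paths[3], row.names = FALSE)
  invisible(paths)
}
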