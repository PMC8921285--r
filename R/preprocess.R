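#' Remove blank-contaminated and carry-over features
#'
#' Features whose mean blank area exceeds `threshold` times their mean QC area
#' are attributed to contaminants or carry-over and dropped. Blank injections
#' are removed from the returned table once the filter has used them.
#'
#' @param x A [feature_table()] containing at least one blank and one QC row.
#' @param threshold Carry-over fraction (default 0.10).
#' @return List with elements `table` (filtered, blanks dropped) and
#'   `removed` (character vector of dropped feature ids).
#' @export
filter_blank_carryover <- function(x, threshold = 0.10) {
  validate_feature_table(x)
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)")
  blk <- x$sample_meta$role == "blank"
  qc <- x$sample_meta$role == "QC"
  if (!any(blk))
    stop("no blank rows: the blank/carry-over filter cannot be applied")
  if (!any(qc))
    stop("no QC rows: the blank/carry-over filter cannot be applied")
  blank_mean <- colMeans(x$areas[blk, , drop = FALSE])
  qc_mean <- colMeans(x$areas[qc, , drop = FALSE])
  drop <- blank_mean > threshold * qc_mean
  out <- subset_features(x, !drop)
  out <- subset_rows(out, !blk)
  list(table = out, removed = x$feature_meta$id[drop])
}

#' QC-anchored signal drift correction
#'
#' For each feature an ordinary least-squares line of QC peak area on
#' injection order is fitted over the monitoring QCs (conditioning QCs, those
#' injected before the first sample, only equilibrate the system and are
#' excluded). Every row is then detrended so the refit QC slope is zero:
#' additively by default (`area - b * (order - mean QC order)`, floored at 0),
#' or multiplicatively (division by the fitted line normalized at the mean QC
#' order) with `method = "multiplicative"`. Zero areas denote non-detected
#' peaks and are left at zero by either method.
#'
#' @param x A [feature_table()] with at least 3 monitoring QC rows.
#' @param method `"additive"` (default) or `"multiplicative"`.
#' @return The corrected `feature_table`.
#' @export
qc_drift_correct <- function(x, method = c("additive", "multiplicative")) {
  method <- match.arg(method)
  validate_feature_table(x)
  qc <- monitoring_qc_rows(x)
  if (length(qc) < 3)
    stop("drift correction needs at least 3 monitoring QC rows, found ",
         length(qc))
  ord_qc <- x$sample_meta$injection_order[qc]
  if (stats::var(ord_qc) == 0)
    stop("QC injection orders have zero variance")
  o_bar <- mean(ord_qc)
  d <- ord_qc - o_bar
  # per-feature OLS slope of QC area on injection order
  slope <- crossprod(d, x$areas[qc, , drop = FALSE])[1, ] / sum(d^2)
  ord_all <- x$sample_meta$injection_order
  undetected <- x$areas == 0   # a non-detected peak stays non-detected
  if (method == "additive") {
    corr <- outer(ord_all - o_bar, slope)
    x$areas <- pmax(x$areas - corr, 0)
    x$areas[undetected] <- 0
  } else {
    icept <- colMeans(x$areas[qc, , drop = FALSE])
    fac <- 1 + outer(ord_all - o_bar, slope / icept)
    fac[fac <= 0] <- NA
    x$areas <- x$areas / fac
    x$areas[is.na(x$areas)] <- 0
  }
  x
}

#' Filter features on QC presence and QC relative standard deviation
#'
#' Drops features that are absent (zero area) from any monitoring QC
#' injection, and features whose QC relative standard deviation (sd/mean)
#' exceeds `rsd_threshold`. The sample (n-1) standard deviation is used.
#' A feature with QC mean 0 is dropped by the presence rule, never a division
#' error.
#'
#' @param x A [feature_table()] with at least 2 monitoring QC rows.
#' @param rsd_threshold RSD cut-off (default 0.25).
#' @return List with elements `table` and `removed` (list with components
#'   `qc_missing` and `qc_rsd`, character ids).
#' @export
filter_qc_presence_rsd <- function(x, rsd_threshold = 0.25) {
  validate_feature_table(x)
  if (rsd_threshold <= 0) stop("'rsd_threshold' must be positive")
  qc <- monitoring_qc_rows(x)
  if (length(qc) < 2)
    stop("QC filtering needs at least 2 monitoring QC rows, found ",
         length(qc))
  qa <- x$areas[qc, , drop = FALSE]
  missing <- apply(qa <= 0, 2, any)
  m <- colMeans(qa)
  s <- apply(qa, 2, stats::sd)
  rsd <- ifelse(m > 0, s / m, Inf)
  unstable <- !missing & rsd > rsd_threshold
  keep <- !missing & !unstable
  list(table = subset_features(x, keep),
       removed = list(qc_missing = x$feature_meta$id[missing],
                      qc_rsd = x$feature_meta$id[unstable]))
}

#' Creatinine normalization of sample rows
#'
#' Divides each sample row's areas by that sample's urinary creatinine
#' concentration, correcting for urine dilution. QC rows are pooled material
#' without a creatinine value and pass through unchanged.
#'
#' @param x A [feature_table()].
#' @return The normalized `feature_table`.
#' @export
normalize_creatinine <- function(x) {
  validate_feature_table(x)
  smp <- which(x$sample_meta$role == "sample")
  cre <- x$sample_meta$creatinine[smp]
  x$areas[smp, ] <- x$areas[smp, , drop = FALSE] / cre
  x
}

#' Fit autoscaling parameters
#'
#' Learns per-column means and sample standard deviations from the given rows
#' only. Inside any cross-validation loop the fit must use calibration rows
#' exclusively; validation rows are transformed with [autoscale_apply()] using
#' those same parameters.
#'
#' @param x Numeric matrix (>= 2 rows).
#' @return Object of class `scaling_params` with fields `mean` and `sd`.
#' @export
autoscale_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("autoscaling needs at least 2 rows")
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  zero <- s <= 0 | !is.finite(s)
  if (any(zero)) {
    nm <- colnames(x)
    if (is.null(nm)) nm <- as.character(seq_len(ncol(x)))
    stop("zero-variance column(s): ", paste(nm[zero], collapse = ", "))
  }
  structure(list(mean = m, sd = s), class = "scaling_params")
}

#' Apply autoscaling parameters
#'
#' @param x Numeric matrix with the same columns as the training rows.
#' @param params A `scaling_params` object from [autoscale_fit()].
#' @return The matrix `(x - mean) / sd`, column-wise.
#' @export
autoscale_apply <- function(x, params) {
  x <- as.matrix(x)
  if (ncol(x) != length(params$mean))
    stop("matrix has ", ncol(x), " columns but scaling parameters have ",
         length(params$mean))
  sweep(sweep(x, 2, params$mean), 2, params$sd, "/")
}

#' Scale data blocks to unit Frobenius norm and concatenate
#'
#' Each (already autoscaled) block is divided by its Frobenius norm so no
#' block dominates the fused model, then the blocks are joined column-wise.
#' When used inside cross-validation the norms must come from calibration
#' rows; pass them via `norms` to scale validation rows consistently.
#'
#' @param blocks List of numeric matrices sharing row count and order.
#' @param norms Optional numeric vector of pre-computed Frobenius norms (one
#'   per block); defaults to the norms of `blocks` themselves.
#' @return Concatenated matrix, with attribute `"block_norms"` holding the
#'   norms used.
#' @export
block_scale_concat <- function(blocks, norms = NULL) {
  if (!length(blocks)) stop("'blocks' must be a non-empty list")
  nr <- vapply(blocks, nrow, 0L)
  if (length(unique(nr)) != 1)
    stop("blocks disagree on row count: ", paste(nr, collapse = ", "))
  if (is.null(norms))
    norms <- vapply(blocks, function(b) sqrt(sum(b^2)), 0)
  if (any(norms <= 0)) stop("zero-norm block")
  out <- do.call(cbind, Map(function(b, f) b / f, blocks, norms))
  attr(out, "block_norms") <- norms
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in the fixed order the workflow prescribes:
#' blank/carry-over filtering, QC-anchored drift correction, QC presence and
#' RSD filtering, and creatinine normalization. Autoscaling is deliberately
#' not part of this chain: it is refit on calibration rows inside every
#' cross-validation split.
#'
#' @param x A raw [feature_table()].
#' @param carryover_threshold Blank/carry-over fraction (default 0.10).
#' @param rsd_threshold QC RSD cut-off (default 0.25).
#' @param drift_method Passed to [qc_drift_correct()].
#' @return List with elements `table` (the processed `feature_table`) and
#'   `removed` (list of dropped feature ids by reason: `blank`, `qc_missing`,
#'   `qc_rsd`).
#' @export
preprocess <- function(x, carryover_threshold = 0.10, rsd_threshold = 0.25,
                       drift_method = "additive") {
  st1 <- filter_blank_carryover(x, carryover_threshold)
  st2 <- qc_drift_correct(st1$table, method = drift_method)
  st3 <- filter_qc_presence_rsd(st2, rsd_threshold)
  out <- normalize_creatinine(st3$table)
  list(table = out,
       removed = c(list(blank = st1$removed), st3$removed))
}

#' Extract the model-ready sample matrix and class labels
#'
#' Drops QC rows and returns the area matrix of study samples together with
#' their class factor (levels `BPH`, `PCa`; `BPH` is the negative class).
#'
#' @param x A processed [feature_table()].
#' @return List with `x` (samples-by-features matrix) and `y` (factor).
#' @export
sample_matrix <- function(x) {
  smp <- x$sample_meta$role == "sample"
  list(x = x$areas[smp, , drop = FALSE],
       y = factor(x$sample_meta$class[smp], levels = c("BPH", "PCa")))
}
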