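#' Rank variables within each sub-model by coefficient magnitude
#'
#' Per sub-model, variables are ranked by descending absolute PLS regression
#' coefficient: the most contributing predictor gets rank 1. Ties receive the
#' average of the tied rank positions.
#'
#' @param coefficients Matrix (sub-models x variables) of regression
#'   coefficient vectors, or a list of equal-length vectors.
#' @return Matrix of ranks, same shape.
#' @export
rank_coefficients <- function(coefficients) {
  if (is.list(coefficients)) {
    if (!length(coefficients)) stop("empty coefficient list")
    coefficients <- do.call(rbind, coefficients)
  }
  coefficients <- as.matrix(coefficients)
  if (!nrow(coefficients)) stop("empty coefficient matrix")
  t(apply(coefficients, 1,
          function(b) rank(-abs(b), ties.method = "average")))
}

#' Rank product across sub-models
#'
#' The geometric mean of each variable's ranks over the sub-models, computed
#' as `exp(mean(log(rank)))` for overflow safety.
#'
#' @param rank_matrix Matrix (sub-models x variables) of positive ranks.
#' @return Numeric vector of rank products, one per variable.
#' @export
rank_product <- function(rank_matrix) {
  rank_matrix <- as.matrix(rank_matrix)
  if (any(rank_matrix <= 0)) stop("ranks must be positive")
  exp(colMeans(log(rank_matrix)))
}

#' Select variables below the geometric-mean rank-product threshold
#'
#' Variables whose rank product is strictly lower than the geometric mean of
#' all rank products are flagged as significant contributors.
#'
#' @param rp Numeric vector of rank products.
#' @return List with `selected` (integer indices) and `threshold` (the
#'   geometric mean).
#' @export
select_by_rp <- function(rp) {
  if (any(rp <= 0)) stop("rank products must be positive")
  thr <- exp(mean(log(rp)))
  list(selected = which(rp < thr), threshold = thr)
}

#' Retain rank-product selections confirmed by VIP
#'
#' Cross-check of the rank-product selection against variable importance in
#' projection: only variables whose mean VIP exceeds `vip_threshold`
#' (conventionally 1) are kept.
#'
#' @param selected_rp Integer indices selected by rank product.
#' @param vip_mean Per-variable mean VIP over the sub-models.
#' @param vip_threshold Relevance cut-off (default 1).
#' @return Integer indices of the final selection; warns when the
#'   intersection is empty.
#' @export
vip_crosscheck <- function(selected_rp, vip_mean, vip_threshold = 1) {
  keep <- intersect(selected_rp, which(vip_mean > vip_threshold))
  if (!length(keep))
    warning("rank-product and VIP selections do not overlap", call. = FALSE)
  keep
}

#' Rank-product + VIP biomarker selection from an r-dCV fit
#'
#' Runs the full filter-selection chain on the sub-models harvested by
#' [rdcv_plsda()]: rank variables by absolute coefficient within each
#' sub-model, aggregate by rank product, select below the geometric-mean
#' threshold, and retain only variables whose mean VIP over the sub-models
#' exceeds `vip_threshold`.
#'
#' @param object An `rdcv_plsda` fit.
#' @param vip_threshold VIP relevance cut-off (default 1).
#' @return Object of class `biomarker_selection`: list with `rank_product`,
#'   `rp_threshold`, `vip_mean`, `coef_mean` (signed; positive = higher in
#'   the positive class), `selected` (indices), `selected_ids`,
#'   `selected_rp_only`, `selected_vip_only`, `n_sub_models`.
#' @export
select_biomarkers <- function(object, vip_threshold = 1) {
  if (!inherits(object, "rdcv_plsda"))
    stop("'object' must be an rdcv_plsda fit")
  rm <- rank_coefficients(object$coef_harvest)
  rp <- rank_product(rm)
  sel_rp <- select_by_rp(rp)
  vip_mean <- colMeans(object$vip_harvest)
  sel_vip <- which(vip_mean > vip_threshold)
  final <- vip_crosscheck(sel_rp$selected, vip_mean, vip_threshold)
  ids <- colnames(object$coef_harvest)
  structure(list(rank_product = rp, rp_threshold = sel_rp$threshold,
                 vip_mean = vip_mean, coef_mean = colMeans(object$coef_harvest),
                 selected = final, selected_ids = ids[final],
                 selected_rp_only = sel_rp$selected,
                 selected_vip_only = sel_vip,
                 n_sub_models = nrow(object$coef_harvest),
                 vip_threshold = vip_threshold),
            class = "biomarker_selection")
}

#' @export
print.biomarker_selection <- function(x, ...) {
  cat("Rank-product + VIP biomarker selection\n")
  cat("  sub-models aggregated: ", x$n_sub_models, "\n", sep = "")
  cat(sprintf("  rank-product threshold (geometric mean): %.2f\n",
              x$rp_threshold))
  cat("  selected by rank product: ", length(x$selected_rp_only),
      "; with VIP > ", x$vip_threshold, ": ", length(x$selected),
      " of ", length(x$rank_product), " variables\n", sep = "")
  invisible(x)
}

#' Write a selection report as delimited text
#'
#' One row per variable: id, rank product, mean VIP, mean coefficient sign
#' (over- or under-expressed in the positive class), and the selected flag.
#'
#' @param x A `biomarker_selection`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_selection_report <- function(x, path) {
  df <- data.frame(
    variable = names(x$rank_product),
    rank_product = x$rank_product,
    vip_mean = x$vip_mean,
    direction = ifelse(x$coef_mean > 0, "over", "under"),
    selected = seq_along(x$rank_product) %in% x$selected,
    row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
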