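#' Principal component analysis with sample diagnostics
#'
#' Singular-value decomposition of an autoscaled (or at least column-centered)
#' matrix, returning scores, loadings, explained variances, and the two
#' classical per-sample diagnostics: Hotelling's T2 (leverage inside the
#' model plane) and Q (squared orthogonal residual norm). Component signs are
#' fixed by forcing the largest-magnitude loading of each component to be
#' positive, so results are reproducible across platforms.
#'
#' @param x Numeric matrix, samples in rows. Expected to be autoscaled; the
#'   function does not center or scale.
#' @param n_components Number of components to retain; at most
#'   `min(nrow(x) - 1, ncol(x))` and at most the rank of `x`.
#' @return Object of class `pca_qc`: list with `scores` (n x A), `loadings`
#'   (p x A, orthonormal columns), `explained_variance` (squared singular
#'   values / (n - 1)), `t2`, `q` (per sample), and `n_components`.
#' @export
pca_qc <- function(x, n_components = 2) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_components < 1) stop("'n_components' must be at least 1")
  if (n_components > min(n - 1, ncol(x)))
    stop("'n_components' exceeds min(rows - 1, columns) = ",
         min(n - 1, ncol(x)))
  sv <- svd(x)
  pos <- sv$d > max(sv$d[1], 0) * 1e-10
  if (n_components > sum(pos))
    stop("'n_components' exceeds the rank of the matrix (", sum(pos), ")")
  A <- n_components
  P <- sv$v[, seq_len(A), drop = FALSE]
  flip <- vapply(seq_len(A),
                 function(a) sign(P[which.max(abs(P[, a])), a]), 0)
  P <- sweep(P, 2, flip, "*")
  Tm <- x %*% P
  ev <- sv$d[seq_len(A)]^2 / (n - 1)
  t2 <- rowSums(sweep(Tm^2, 2, ev, "/"))
  resid <- x - tcrossprod(Tm, P)
  q <- rowSums(resid^2)
  rn <- rownames(x)
  if (!is.null(rn)) {
    rownames(Tm) <- rn; names(t2) <- rn; names(q) <- rn
  }
  structure(list(scores = Tm, loadings = P, explained_variance = ev,
                 t2 = t2, q = q, n_components = A,
                 total_variance = sum(sv$d^2) / (n - 1)),
            class = "pca_qc")
}

#' @export
print.pca_qc <- function(x, ...) {
  cat("PCA diagnostics model:", nrow(x$scores), "samples,",
      nrow(x$loadings), "features,", x$n_components, "components\n")
  pct <- 100 * x$explained_variance / x$total_variance
  cat("  explained variance: ",
      paste(sprintf("PC%d %.1f%%", seq_along(pct), pct), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-feature contributions to a sample's T2 and Q
#'
#' Decomposes one sample's Hotelling T2 and Q residual into per-feature
#' contributions: for T2 the score-weighted loading decomposition
#' `x_ij * (P diag(1/ev) t_i)_j`, which sums to the sample's T2; for Q the
#' squared residuals, which sum to the sample's Q.
#'
#' @param object A `pca_qc` model.
#' @param x The matrix the model was fitted on.
#' @param sample_index Row index of the sample of interest.
#' @return List with numeric vectors `t2` and `q` (one element per feature).
#' @export
contributions <- function(object, x, sample_index) {
  if (!inherits(object, "pca_qc")) stop("'object' must be a pca_qc model")
  x <- as.matrix(x)
  if (sample_index < 1 || sample_index > nrow(x))
    stop("'sample_index' out of range 1..", nrow(x))
  xi <- x[sample_index, ]
  ti <- object$scores[sample_index, ]
  w <- drop(object$loadings %*% (ti / object$explained_variance))
  t2_contrib <- xi * w
  ei <- xi - drop(object$loadings %*% ti)
  list(t2 = t2_contrib, q = ei^2)
}

#' Correlation of PCA scores with injection order
#'
#' A sequence-effect screen: reports, per component, the Pearson correlation
#' between sample scores and injection order. No acceptance rule is attached;
#' large absolute values flag residual drift worth inspecting.
#'
#' @param object A `pca_qc` model.
#' @param injection_order Numeric vector, one value per scored sample row.
#' @return Named numeric vector of correlations, one per component.
#' @export
score_order_correlation <- function(object, injection_order) {
  if (length(injection_order) != nrow(object$scores))
    stop("'injection_order' length must match the number of scored samples")
  r <- apply(object$scores, 2, stats::cor, y = injection_order)
  stats::setNames(r, paste0("PC", seq_along(r)))
}
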