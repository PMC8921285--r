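# NIPALS PLS1 on a pre-scaled matrix and a +/-1 response.
# Sequential extraction: w = X'y normalized, t = Xw, p = X't/t't, q = y't/t't,
# deflate X (y is left undeflated, standard for a single response).
# Returns nested coefficient vectors B[, a] for every component count a <= A,
# so one fit serves all candidate latent-variable counts.
pls_nipals <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  A <- min(ncomp, n - 1L, p)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  qv <- numeric(A); ssy <- numeric(A)
  Xd <- X
  a <- 0L
  tol <- 1e-12 * max(abs(X), 1)
  while (a < A) {
    w <- crossprod(Xd, y)
    wn <- sqrt(sum(w^2))
    if (wn < tol) break
    w <- w / wn
    tv <- Xd %*% w
    tt <- sum(tv^2)
    if (tt < tol^2) break
    a <- a + 1L
    pv <- crossprod(Xd, tv) / tt
    qa <- sum(y * tv) / tt
    Xd <- Xd - tcrossprod(tv, pv)
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- tv
    qv[a] <- qa; ssy[a] <- qa^2 * tt
  }
  if (a == 0L) stop("no PLS component could be extracted (X'y is zero)")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]
  qv <- qv[seq_len(a)]; ssy <- ssy[seq_len(a)]
  B <- matrix(0, p, a)
  for (k in seq_len(a))
    B[, k] <- W[, seq_len(k), drop = FALSE] %*%
      solve(crossprod(P[, seq_len(k), drop = FALSE],
                      W[, seq_len(k), drop = FALSE]), qv[seq_len(k)])
  list(W = W, P = P, q = qv, scores = Tm, B = B, ssy = ssy, ncomp = a)
}

#' Fit a two-class PLS-DA model
#'
#' Partial least squares discriminant analysis for two classes: the class
#' factor is coded -1 (first level, the negative class) / +1 (second level)
#' and regressed on the autoscaled predictors by NIPALS PLS1. The model
#' carries the training scaling so prediction applies identical parameters.
#'
#' @param x Numeric matrix, samples in rows.
#' @param y Class labels: a two-level factor (first level = negative class),
#'   or a character/numeric vector coercible to one. For urinary prostate
#'   tables use levels `c("BPH", "PCa")` so PCa scores are positive.
#' @param ncomp Number of latent variables (>= 1, at most the rank of the
#'   autoscaled matrix).
#' @param scale Autoscale `x` internally (default `TRUE`). Set `FALSE` when
#'   `x` is already scaled, e.g. block-scaled fused matrices.
#'
#' @return Object of class `plsda` with elements `x_weights` (W),
#'   `x_loadings` (P), `y_loadings` (q), `coefficients` (regression vector b
#'   at `ncomp`), `coef_by_ncomp` (b for each component count), `scores`,
#'   `ssy` (response variance captured per component), `scaling`
#'   (a `scaling_params` or `NULL`), `levels`, `ncomp` and the fitted
#'   training `fitted` (data frame of score and class).
#' @export
plsda <- function(x, y, ncomp = 2, scale = TRUE) {
  x <- as.matrix(x)
  y <- as_class_factor(y)
  if (nlevels(y) != 2 || any(table(y) == 0))
    stop("PLS-DA needs both classes present in 'y'")
  if (length(y) != nrow(x)) stop("'y' length must equal nrow(x)")
  if (ncomp < 1) stop("'ncomp' must be at least 1")
  yv <- ifelse(y == levels(y)[2], 1, -1)
  scaling <- NULL
  Xs <- x
  if (scale) {
    scaling <- autoscale_fit(x)
    Xs <- autoscale_apply(x, scaling)
  }
  fit <- pls_nipals(Xs, yv, ncomp)
  if (fit$ncomp < ncomp)
    stop("'ncomp' = ", ncomp, " exceeds the rank of the (scaled) matrix (",
         fit$ncomp, ")")
  b <- fit$B[, ncomp]
  names(b) <- colnames(x)
  score <- drop(Xs %*% b)
  obj <- structure(list(
    x_weights = fit$W, x_loadings = fit$P, y_loadings = fit$q,
    coefficients = b, coef_by_ncomp = fit$B, scores = fit$scores,
    ssy = fit$ssy, scaling = scaling, levels = levels(y), ncomp = ncomp,
    y = y,
    fitted = data.frame(score = score,
                        class = score_to_class(score, levels(y)),
                        stringsAsFactors = FALSE),
    call = match.call()), class = "plsda")
  obj
}

as_class_factor <- function(y) {
  if (is.factor(y)) return(droplevels(y))
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (!all(u %in% c(-1, 1)))
      stop("numeric 'y' must be coded -1/+1")
    return(factor(y, levels = c(-1, 1)))
  }
  factor(y)
}

# decision rule: positive class iff score > 0; an exact 0 is the negative
# class (deterministic tie-break)
score_to_class <- function(score, levels) {
  factor(ifelse(score > 0, levels[2], levels[1]), levels = levels)
}

#' Predict classes and canonical scores from a PLS-DA model
#'
#' Applies the training scaling captured at fit time, computes the continuous
#' canonical score `x b`, and thresholds at zero (positive class for score
#' > 0; an exact zero is assigned to the negative class).
#'
#' @param object A `plsda` model.
#' @param newdata Matrix with the same columns as the training data.
#' @param ... Unused.
#' @return Data frame with columns `score` and `class`.
#' @export
predict.plsda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("'newdata' has ", ncol(newdata), " columns; model expects ",
         length(object$coefficients))
  Xs <- if (is.null(object$scaling)) newdata
        else autoscale_apply(newdata, object$scaling)
  score <- drop(Xs %*% object$coefficients)
  data.frame(score = score, class = score_to_class(score, object$levels),
             stringsAsFactors = FALSE)
}

#' @export
coef.plsda <- function(object, ...) object$coefficients

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA model: ", length(x$coefficients), " variables, ", x$ncomp,
      " latent variable(s)\n", sep = "")
  cat("  classes: ", x$levels[1], " (-1) vs ", x$levels[2], " (+1)\n",
      sep = "")
  cat(sprintf("  training misclassification: %.1f%%\n",
              100 * mean(x$fitted$class != x$y)))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' VIP for variable j over the A latent variables of a fitted model:
#' `sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with `SSY_a` the response
#' variance captured by component a and the weight vectors normalized to unit
#' length (as NIPALS produces them). The mean squared VIP over variables is 1
#' for every fitted model.
#'
#' @param object A `plsda` model.
#' @return Named numeric vector of VIP scores, one per variable.
#' @export
vip <- function(object) {
  if (!inherits(object, "plsda")) stop("'object' must be a plsda model")
  A <- object$ncomp
  W <- object$x_weights[, seq_len(A), drop = FALSE]
  ssy <- object$ssy[seq_len(A)]
  if (sum(ssy) <= 0) stop("model captures zero response variance")
  p <- nrow(W)
  v <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  stats::setNames(v, names(object$coefficients))
}

#' Export a PLS-DA model as JSON
#'
#' Serializes weights, loadings, coefficients and the training scaling for
#' audit or reuse outside R.
#'
#' @param object A `plsda` model.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_plsda_json <- function(object, path) {
  payload <- list(levels = object$levels, ncomp = object$ncomp,
                  x_weights = object$x_weights,
                  x_loadings = object$x_loadings,
                  y_loadings = object$y_loadings,
                  coefficients = object$coefficients,
                  scaling = if (!is.null(object$scaling))
                    list(mean = object$scaling$mean, sd = object$scaling$sd))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
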