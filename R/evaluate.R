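#' Receiver operating characteristic curve and AUROC
#'
#' Threshold sweep over the unique continuous scores: at each threshold the
#' true-positive rate (sensitivity) is plotted against the false-positive
#' rate (1 - specificity). The area under the curve is computed by the
#' trapezoid rule and equals the Mann-Whitney U statistic normalized by
#' `n1 * n2` (ties counted half).
#'
#' @param scores Continuous classifier scores; larger means more
#'   positive-class-like.
#' @param labels Class labels (two-level factor or coercible; second level =
#'   positive class).
#' @return Object of class `roc_curve`: list with `fpr`, `tpr`, `thresholds`
#'   (each starting at the (0, 0) corner) and `auroc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_class_factor(labels)
  if (nlevels(y) != 2 || any(table(y) == 0))
    stop("ROC needs both classes present")
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n2 <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores so the curve moves diagonally through ties
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n2)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[last]), auroc = auroc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUROC = %.3f\n", length(x$fpr),
              x$auroc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlab = "1 - specificity",
                 ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Mean ROC curve over r-dCV repetitions
#'
#' One ROC curve is computed from each run's outer-loop scores, then the
#' curves are vertically averaged on a common false-positive-rate grid
#' (101 points by default). The AUROC is summarized by its mean and
#' nonparametric percentile interval across runs.
#'
#' @param object An `rdcv_plsda` fit.
#' @param grid Common false-positive-rate grid in `[0, 1]`.
#' @param level Interval coverage; defaults to the fit's `ci_level`.
#' @return Object of class `mean_roc`: list with `grid`, `mean_tpr`,
#'   `tpr_matrix` (runs x grid), `auroc` (per run), `auroc_mean`,
#'   `auroc_ci`.
#' @export
mean_roc <- function(object, grid = seq(0, 1, length.out = 101),
                     level = object$config$ci_level) {
  if (!inherits(object, "rdcv_plsda"))
    stop("'object' must be an rdcv_plsda fit")
  runs <- nrow(object$scores)
  if (runs < 2) stop("mean ROC needs at least 2 runs")
  tprs <- matrix(NA_real_, runs, length(grid))
  aucs <- numeric(runs)
  for (r in seq_len(runs)) {
    rc <- roc_curve(object$scores[r, ], object$y)
    # step interpolation: the attained TPR at each grid FPR
    tprs[r, ] <- stats::approx(rc$fpr, rc$tpr, xout = grid,
                               method = "constant", f = 0, rule = 2,
                               ties = max)$y
    aucs[r] <- rc$auroc
  }
  ci <- nonparametric_ci(aucs, level)
  structure(list(grid = grid, mean_tpr = colMeans(tprs), tpr_matrix = tprs,
                 auroc = aucs, auroc_mean = unname(ci["mean"]),
                 auroc_ci = unname(ci[c("lower", "upper")])),
            class = "mean_roc")
}

#' @export
print.mean_roc <- function(x, ...) {
  cat(sprintf("Mean ROC over %d runs: AUROC = %.3f [%.3f, %.3f]\n",
              nrow(x$tpr_matrix), x$auroc_mean, x$auroc_ci[1],
              x$auroc_ci[2]))
  invisible(x)
}

#' @export
plot.mean_roc <- function(x, ...) {
  graphics::matplot(x$grid, t(x$tpr_matrix), type = "l", lty = 1,
                    col = grDevices_grey(), xlab = "1 - specificity",
                    ylab = "sensitivity", ...)
  graphics::lines(x$grid, x$mean_tpr, lwd = 2)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

grDevices_grey <- function() grDevices::grey(0.8)

#' Cross-validated performance of a single metabolite
#'
#' Runs the same repeated double cross-validation engine on one variable
#' (latent-variable count fixed at 1) and returns the figure-of-merit and
#' AUROC distributions, enabling the model-versus-single-marker comparison.
#'
#' @param x_j Numeric vector, the single variable's (preprocessed) values.
#' @param y Class labels.
#' @param ... Passed to [rdcv_plsda()] (e.g. `runs`, `outer_groups`, `seed`).
#' @return List with `fom` (data frame of mean/lower/upper per metric),
#'   `auroc` (named vector mean/lower/upper) and the underlying `rdcv` fit.
#' @export
univariate_performance <- function(x_j, y, ...) {
  x_j <- as.numeric(x_j)
  if (stats::sd(x_j) == 0) stop("constant column: no univariate model")
  fit <- rdcv_plsda(matrix(x_j, ncol = 1,
                           dimnames = list(NULL, "metabolite")),
                    y, max_lv = 1, ...)
  s <- summary(fit)
  roc <- mean_roc(fit)
  list(fom = s$fom,
       auroc = c(mean = roc$auroc_mean, lower = roc$auroc_ci[1],
                 upper = roc$auroc_ci[2]),
       rdcv = fit)
}

#' Two-sample t-test from raw data or summary statistics
#'
#' Pooled-variance Student's t with `n1 + n2 - 2` degrees of freedom (the
#' Welch unpooled variant is available with `welch = TRUE`). Either pass the
#' two raw vectors, or the per-group means, standard deviations and sizes.
#'
#' @param x,y Raw numeric vectors for the two groups, or `NULL` when using
#'   summaries.
#' @param means,sds,ns Length-2 numeric vectors of per-group summaries
#'   (ignored when `x` and `y` are given).
#' @param welch Use the Welch (unpooled) statistic.
#' @return List with `t`, `df`, `p.value` (two-sided).
#' @export
two_sample_t <- function(x = NULL, y = NULL, means = NULL, sds = NULL,
                         ns = NULL, welch = FALSE) {
  if (!is.null(x) && !is.null(y)) {
    means <- c(mean(x), mean(y))
    sds <- c(stats::sd(x), stats::sd(y))
    ns <- c(length(x), length(y))
  }
  if (is.null(means) || is.null(sds) || is.null(ns))
    stop("provide either two raw vectors or means/sds/ns summaries")
  if (any(ns < 2)) stop("each group needs at least 2 observations")
  if (welch) {
    se2 <- sds^2 / ns
    t <- (means[1] - means[2]) / sqrt(sum(se2))
    df <- sum(se2)^2 / sum(se2^2 / (ns - 1))
  } else {
    sp2 <- ((ns[1] - 1) * sds[1]^2 + (ns[2] - 1) * sds[2]^2) / (sum(ns) - 2)
    if (sp2 <= 0) stop("zero pooled variance: t statistic undefined")
    t <- (means[1] - means[2]) / sqrt(sp2 * sum(1 / ns))
    df <- sum(ns) - 2
  }
  list(t = t, df = df, p.value = 2 * stats::pt(-abs(t), df))
}

#' Per-class five-number summaries for each variable
#'
#' Tukey five-number summaries (minimum, lower hinge, median, upper hinge,
#' maximum) per class per variable — the numbers behind per-metabolite box
#' plots.
#'
#' @param x Numeric matrix, samples in rows.
#' @param y Class labels.
#' @return Data frame with columns `variable`, `class`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
class_fivenum <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as_class_factor(y)
  out <- expand.grid(variable = colnames(x), class = levels(y),
                     stringsAsFactors = FALSE)
  stats <- t(mapply(function(v, cl)
    stats::fivenum(x[y == cl, v]), out$variable, out$class))
  colnames(stats) <- c("min", "q1", "median", "q3", "max")
  cbind(out, as.data.frame(stats, row.names = FALSE))
}
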