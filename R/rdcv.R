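#' Partition samples into cross-validation deletion groups
#'
#' Splits sample indices into `k` near-equal groups. With `stratified = TRUE`
#' (the default, natural for the balanced 20 + 20 design) each group's
#' per-class counts differ from balance by at most one.
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param y Class labels (two-level factor or coercible).
#' @param k Number of deletion groups.
#' @param stratified Balance classes across groups (requires
#'   `k <= min(class counts)`).
#' @return List of `k` integer index vectors forming a partition of
#'   `seq_along(y)`.
#' @export
split_groups <- function(y, k, stratified = TRUE) {
  n <- length(y)
  if (k < 2 || k > n) stop("'k' must lie in 2..", n)
  y <- as_class_factor(y)
  if (stratified && k > min(table(y)))
    stop("stratified split infeasible: k = ", k,
         " exceeds the smallest class count (", min(table(y)), ")")
  groups <- integer(n)
  if (stratified) {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      idx <- idx[sample.int(length(idx))]
      groups[idx] <- rep_len(sample.int(k), length(idx))
    }
  } else {
    groups[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  unname(split(seq_len(n), groups))
}

# smallest latent-variable count minimizing the inner-CV error (ties go to
# the most parsimonious model)
choose_lv <- function(errors) which.min(errors)

# autoscale calibration rows, transform validation rows with the same
# parameters; optional per-block Frobenius scaling with norms learned on the
# calibration rows only (the training/validation separation contract)
scale_cal_val <- function(xcal, xval = NULL, blocks = NULL) {
  sp <- autoscale_fit(xcal)
  Xc <- autoscale_apply(xcal, sp)
  Xv <- if (!is.null(xval)) autoscale_apply(xval, sp)
  if (!is.null(blocks)) {
    for (j in blocks) {
      f <- sqrt(sum(Xc[, j]^2))
      if (f <= 0) stop("zero-norm block in calibration rows")
      Xc[, j] <- Xc[, j] / f
      if (!is.null(Xv)) Xv[, j] <- Xv[, j] / f
    }
  }
  list(cal = Xc, val = Xv)
}

# inner cross-validation over latent-variable counts 1..max_lv; autoscaling
# (and block scaling) refit per inner fold. Returns the chosen count, the
# per-count error curve, and the per-fold sub-models at the chosen count
# (coefficient and VIP vectors) for rank-product harvesting.
inner_cv <- function(x, y, inner_groups, max_lv, stratified = TRUE,
                     blocks = NULL, quiet = FALSE) {
  y <- as_class_factor(y)
  yv <- ifelse(y == levels(y)[2], 1, -1)
  folds <- split_groups(y, inner_groups, stratified)
  n <- length(y)
  fits <- vector("list", length(folds))
  mis <- matrix(0, length(folds), max_lv)
  eff <- max_lv
  for (i in seq_along(folds)) {
    val <- folds[[i]]
    cal <- setdiff(seq_len(n), val)
    sc <- scale_cal_val(x[cal, , drop = FALSE], x[val, , drop = FALSE],
                        blocks)
    fit <- pls_nipals(sc$cal, yv[cal], max_lv)
    pred <- sc$val %*% fit$B                      # n_val x ncomp_i
    wrong <- (pred > 0) != rep(yv[val] > 0, ncol(pred))
    mis[i, seq_len(fit$ncomp)] <- colSums(wrong)
    eff <- min(eff, fit$ncomp)
    fits[[i]] <- fit
  }
  if (eff < max_lv && !quiet)
    warning("latent-variable search truncated at ", eff,
            " (inner-fold rank limit)", call. = FALSE)
  err <- colSums(mis[, seq_len(eff), drop = FALSE]) / n
  lv <- choose_lv(err)
  p <- ncol(x)
  coefs <- matrix(0, length(folds), p)
  vips <- matrix(0, length(folds), p)
  for (i in seq_along(folds)) {
    fit <- fits[[i]]
    a <- min(lv, fit$ncomp)
    coefs[i, ] <- fit$B[, a]
    W <- fit$W[, seq_len(a), drop = FALSE]
    ssy <- fit$ssy[seq_len(a)]
    vips[i, ] <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  }
  list(n_lv = lv, errors = err, coefs = coefs, vips = vips)
}

#' Select the latent-variable count by inner cross-validation
#'
#' For each candidate count 1..`max_lv`, computes the misclassification error
#' of PLS-DA under `inner_groups`-fold cross-validation (autoscaling refit
#' per fold) and returns the count minimizing it; ties break to the smallest
#' count. If an inner fold's rank falls short of `max_lv` the candidate list
#' is truncated with a warning.
#'
#' @param x Calibration matrix (raw areas; scaling is refit per fold).
#' @param y Class labels.
#' @param inner_groups Number of inner deletion groups (default 8).
#' @param max_lv Largest candidate latent-variable count.
#' @param stratified Stratify the inner split.
#' @param blocks Optional list of column-index vectors for multi-block
#'   Frobenius scaling.
#' @return The chosen latent-variable count (integer), with the inner error
#'   curve attached as attribute `"errors"`.
#' @export
inner_select_lv <- function(x, y, inner_groups = 8, max_lv = 5,
                            stratified = TRUE, blocks = NULL) {
  ic <- inner_cv(as.matrix(x), y, inner_groups, max_lv, stratified, blocks)
  structure(ic$n_lv, errors = ic$errors)
}

#' Classification figures of merit
#'
#' Sensitivity (correct positive-class rate), specificity (correct
#' negative-class rate), misclassification error and accuracy, as fractions.
#' The positive class is the second factor level (PCa in the urinary
#' workflow).
#'
#' @param predicted,truth Class labels of equal length; `truth` must contain
#'   both classes.
#' @return Named numeric vector
#'   `c(sensitivity, specificity, error, accuracy)`.
#' @export
figures_of_merit <- function(predicted, truth) {
  truth <- as_class_factor(truth)
  predicted <- factor(as.character(predicted), levels = levels(truth))
  if (nlevels(truth) < 2 || any(table(truth) == 0))
    stop("'truth' must contain both classes")
  pos <- truth == levels(truth)[2]
  ok <- predicted == truth
  c(sensitivity = mean(ok[pos]), specificity = mean(ok[!pos]),
    error = mean(!ok), accuracy = mean(ok))
}

#' Nonparametric percentile confidence interval
#'
#' Mean plus a nearest-rank percentile interval at level `level`: the
#' endpoints are the order statistics at ranks `ceiling(q * n)` for
#' `q = (1 - level) / 2` and `1 - (1 - level) / 2`.
#'
#' @param values Numeric vector (>= 2 values), e.g. one figure of merit per
#'   r-dCV run.
#' @param level Coverage level in (0, 1), default 0.95.
#' @return Named numeric vector `c(mean, lower, upper)`.
#' @export
nonparametric_ci <- function(values, level = 0.95) {
  if (length(values) < 2)
    stop("need at least 2 values for a nonparametric interval")
  if (level <= 0 || level >= 1) stop("'level' must lie in (0, 1)")
  s <- sort(values)
  n <- length(s)
  alpha <- (1 - level) / 2
  lo <- s[max(1L, ceiling(alpha * n))]
  hi <- s[min(n, ceiling((1 - alpha) * n))]
  c(mean = mean(values), lower = lo, upper = hi)
}

# one double-cross-validation pass over a fixed outer partition.
# fold_seeds make the inner split of each outer fold reproducible and
# independent of the data, so validation rows cannot influence calibration
# models even through RNG consumption.
dcv_pass <- function(x, y, folds, fold_seeds, inner_groups, max_lv,
                     stratified = TRUE, blocks = NULL, fixed_lv = NULL,
                     harvest_folds = 1L) {
  y <- as_class_factor(y)
  yv <- ifelse(y == levels(y)[2], 1, -1)
  n <- length(y)
  scores <- numeric(n)
  chosen <- integer(length(folds))
  coef_h <- NULL; vip_h <- NULL
  models <- vector("list", length(folds))
  for (g in seq_along(folds)) {
    val <- folds[[g]]
    cal <- setdiff(seq_len(n), val)
    if (is.null(fixed_lv)) {
      set.seed(fold_seeds[g])
      ic <- inner_cv(x[cal, , drop = FALSE], y[cal], inner_groups, max_lv,
                     stratified, blocks, quiet = TRUE)
      lv <- ic$n_lv
      if (g %in% harvest_folds) {
        coef_h <- rbind(coef_h, ic$coefs)
        vip_h <- rbind(vip_h, ic$vips)
      }
    } else {
      lv <- fixed_lv
    }
    sc <- scale_cal_val(x[cal, , drop = FALSE], x[val, , drop = FALSE],
                        blocks)
    fit <- pls_nipals(sc$cal, yv[cal], lv)
    b <- fit$B[, min(lv, fit$ncomp)]
    scores[val] <- drop(sc$val %*% b)
    chosen[g] <- lv
    models[[g]] <- b
  }
  list(scores = scores, labels = score_to_class(scores, levels(y)),
       chosen_lv = chosen, coef_harvest = coef_h, vip_harvest = vip_h,
       models = models)
}

#' Repeated double cross-validation of a PLS-DA classifier
#'
#' The central fitting function of the package. The samples are repeatedly
#' partitioned into `outer_groups` deletion groups; each outer group in turn
#' is held out while the latent-variable count is selected by
#' `inner_groups`-fold cross-validation on the remaining calibration samples,
#' a PLS-DA model is fitted on them (autoscaling and any block scaling refit
#' on calibration rows only), and the held-out group is predicted. Every
#' sample is thus predicted exactly once per run by a model it never
#' influenced. Repetition over `runs` reshuffled partitions yields empirical
#' distributions of every figure of merit, sample score and model
#' coefficient, from which nonparametric confidence intervals are taken.
#'
#' During each run the calibration sub-models of one inner cross-validation
#' are harvested (coefficient and VIP vectors at the selected
#' latent-variable count), giving `runs * inner_groups` sub-models — 240 at
#' the default 30 runs and 8 inner groups — for rank-product variable
#' selection via [select_biomarkers()]. `harvest = "nested"` harvests every
#' outer fold's inner models instead (`runs * outer_groups * inner_groups`).
#'
#' @param x Numeric matrix of preprocessed (e.g. creatinine-normalized) peak
#'   areas, samples in rows. Autoscaling is performed internally per split.
#' @param y Two-level class factor (first level = negative class).
#' @param runs Number of repetitions (default 30).
#' @param outer_groups,inner_groups Outer and inner deletion-group counts
#'   (defaults 10 and 8).
#' @param max_lv Latent-variable search ceiling (default 5).
#' @param stratified Stratify the splits by class (default `TRUE`).
#' @param blocks Optional list of column-index vectors; each block is scaled
#'   to unit Frobenius norm on calibration rows (multi-block fusion).
#' @param ci_level Coverage of the nonparametric intervals (default 0.95).
#' @param harvest Sub-model harvesting scheme, `"inner"` (default) or
#'   `"nested"`; see Details.
#' @param seed Integer seed making the whole procedure reproducible; `NULL`
#'   uses the current RNG state.
#'
#' @return Object of class `rdcv_plsda` with elements `fom` (runs x 4 matrix
#'   of sensitivity/specificity/error/accuracy), `scores` (runs x n outer
#'   test-set scores), `predicted` (runs x n labels), `chosen_lv`
#'   (runs x outer_groups), `coef_harvest` and `vip_harvest` (sub-models x
#'   variables), `y`, `levels`, and `config`.
#' @seealso [summary.rdcv_plsda()], [select_biomarkers()],
#'   [permutation_test()], [mean_roc()]
#' @export
rdcv_plsda <- function(x, y, runs = 30, outer_groups = 10, inner_groups = 8,
                       max_lv = 5, stratified = TRUE, blocks = NULL,
                       ci_level = 0.95, harvest = c("inner", "nested"),
                       seed = NULL) {
  harvest <- match.arg(harvest)
  x <- as.matrix(x)
  y <- as_class_factor(y)
  n <- length(y)
  if (nrow(x) != n) stop("'y' length must equal nrow(x)")
  if (nlevels(y) != 2 || any(table(y) == 0))
    stop("both classes must be present")
  if (runs < 2) stop("'runs' must be at least 2 (intervals need a spread)")
  if (outer_groups > min(table(y)) && stratified)
    stop("outer split infeasible: ", outer_groups,
         " groups exceed the smallest class count")
  n_inner_cal <- n - ceiling(n / outer_groups)
  if (inner_groups > n_inner_cal)
    stop("inner split infeasible for ", inner_groups, " groups")
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, runs)
  hfolds <- if (harvest == "inner") 1L else seq_len(outer_groups)

  fom <- matrix(NA_real_, runs, 4,
                dimnames = list(NULL, c("sensitivity", "specificity",
                                        "error", "accuracy")))
  scores <- matrix(NA_real_, runs, n)
  predicted <- matrix(NA_character_, runs, n)
  chosen_lv <- matrix(NA_integer_, runs, outer_groups)
  coef_h <- vector("list", runs)
  vip_h <- vector("list", runs)
  for (r in seq_len(runs)) {
    set.seed(run_seeds[r])
    folds <- split_groups(y, outer_groups, stratified)
    fold_seeds <- sample.int(.Machine$integer.max - 1L, outer_groups)
    pass <- dcv_pass(x, y, folds, fold_seeds, inner_groups, max_lv,
                     stratified, blocks, harvest_folds = hfolds)
    fom[r, ] <- figures_of_merit(pass$labels, y)
    scores[r, ] <- pass$scores
    predicted[r, ] <- as.character(pass$labels)
    chosen_lv[r, ] <- pass$chosen_lv
    coef_h[[r]] <- pass$coef_harvest
    vip_h[[r]] <- pass$vip_harvest
  }
  coef_h <- do.call(rbind, coef_h)
  vip_h <- do.call(rbind, vip_h)
  vn <- colnames(x)
  if (is.null(vn)) vn <- paste0("V", seq_len(ncol(x)))
  colnames(coef_h) <- vn
  colnames(vip_h) <- vn
  sn <- rownames(x)
  if (is.null(sn)) sn <- sprintf("S%02d", seq_len(n))
  colnames(scores) <- sn
  structure(list(fom = fom, scores = scores, predicted = predicted,
                 chosen_lv = chosen_lv, coef_harvest = coef_h,
                 vip_harvest = vip_h, y = y, levels = levels(y),
                 config = list(runs = runs, outer_groups = outer_groups,
                               inner_groups = inner_groups, max_lv = max_lv,
                               stratified = stratified, blocks = blocks,
                               ci_level = ci_level, harvest = harvest,
                               seed = seed),
                 call = match.call()),
            class = "rdcv_plsda")
}

#' @export
print.rdcv_plsda <- function(x, ...) {
  cfg <- x$config
  cat("Repeated double cross-validation of PLS-DA\n")
  cat("  ", cfg$runs, " runs, ", cfg$outer_groups, " outer / ",
      cfg$inner_groups, " inner deletion groups, ",
      length(x$y), " samples, ", ncol(x$coef_harvest), " variables\n",
      sep = "")
  fm <- apply(x$fom, 2, nonparametric_ci, level = cfg$ci_level)
  for (k in colnames(x$fom))
    cat(sprintf("  %-12s %5.1f%%  [%.1f, %.1f]\n", k, 100 * fm["mean", k],
                100 * fm["lower", k], 100 * fm["upper", k]))
  cat("  modal latent variables:", modal_lv(x), "\n")
  invisible(x)
}

#' Modal latent-variable count of an r-dCV fit
#'
#' @param object An `rdcv_plsda` object.
#' @return The most frequently selected latent-variable count across all
#'   outer folds and runs (smallest on ties).
#' @export
modal_lv <- function(object) {
  tb <- table(object$chosen_lv)
  as.integer(names(tb)[which.max(tb)])
}

#' Summarize an r-dCV fit
#'
#' Figures of merit, per-sample outer-loop score distributions and
#' per-variable coefficient distributions, each as mean plus nonparametric
#' percentile interval over the r-dCV repetitions.
#'
#' @param object An `rdcv_plsda` object.
#' @param level Interval coverage; defaults to the fit's `ci_level`.
#' @param ... Unused.
#' @return Object of class `summary.rdcv_plsda`: list with data frames
#'   `fom`, `sample_scores`, `coefficients`, and `modal_lv`.
#' @export
summary.rdcv_plsda <- function(object, level = object$config$ci_level, ...) {
  fm <- t(apply(object$fom, 2, nonparametric_ci, level = level))
  sc <- t(apply(object$scores, 2, nonparametric_ci, level = level))
  cf <- t(apply(object$coef_harvest, 2, nonparametric_ci, level = level))
  res <- list(
    fom = data.frame(metric = rownames(fm), fm, row.names = NULL),
    sample_scores = data.frame(sample = colnames(object$scores),
                               class = as.character(object$y), sc,
                               row.names = NULL),
    coefficients = data.frame(variable = colnames(object$coef_harvest), cf,
                              row.names = NULL),
    modal_lv = modal_lv(object), level = level,
    config = object$config)
  class(res) <- "summary.rdcv_plsda"
  res
}

#' @export
print.summary.rdcv_plsda <- function(x, ...) {
  cat("r-dCV summary (", x$config$runs, " runs, ",
      round(100 * x$level), "% nonparametric intervals)\n", sep = "")
  f <- x$fom
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-12s %5.1f%%  [%.1f, %.1f]\n", f$metric[i],
                100 * f$mean[i], 100 * f$lower[i], 100 * f$upper[i]))
  cat("  modal latent variables:", x$modal_lv, "\n")
  cat("  per-sample scores and per-variable coefficients in",
      "$sample_scores and $coefficients\n")
  invisible(x)
}

#' @export
coef.rdcv_plsda <- function(object, ...) colMeans(object$coef_harvest)

#' Plot per-sample canonical scores from an r-dCV fit
#'
#' Bars show each sample's mean outer-loop score over the repetitions;
#' whiskers show the nonparametric interval. Negative scores indicate the
#' negative class (BPH), positive the positive class (PCa).
#'
#' @param x An `rdcv_plsda` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.rdcv_plsda <- function(x, ...) {
  s <- summary(x)$sample_scores
  col <- ifelse(s$class == x$levels[2], "firebrick", "steelblue")
  bp <- graphics::barplot(s$mean, col = col, border = NA,
                          names.arg = s$sample, las = 2,
                          cex.names = 0.6,
                          ylab = "canonical score (outer loop mean)", ...)
  graphics::arrows(bp, s$lower, bp, s$upper, angle = 90, code = 3,
                   length = 0.02, col = "grey30")
  graphics::abline(h = 0, lty = 2)
  graphics::legend("topleft", fill = c("steelblue", "firebrick"),
                   legend = x$levels, bty = "n")
  invisible(x)
}

#' Permutation test of the classification figures of merit
#'
#' Re-evaluates the double-cross-validated PLS-DA classifier under `B` random
#' permutations of the class labels, building the null distribution of
#' sensitivity, specificity, error and accuracy. A sound model on permuted
#' labels classifies at chance (about 50% accuracy); p-values are
#' `(1 + #{null >= observed}) / (B + 1)` (for error, `<=`).
#'
#' By default each permutation is evaluated with a single double-CV pass
#' whose latent-variable count is fixed at the unpermuted model's modal
#' count, which makes 1000 randomizations feasible at the desk;
#' `scheme = "full"` reruns the entire r-dCV (inner selection included) per
#' permutation.
#'
#' @param x Predictor matrix (as passed to [rdcv_plsda()]).
#' @param y Class labels.
#' @param B Number of label randomizations (default 1000).
#' @param observed Optional `rdcv_plsda` fit of the unpermuted data; supplies
#'   the fixed latent-variable count and the observed figures of merit for
#'   p-values.
#' @param n_lv Latent-variable count for the reduced scheme; defaults to
#'   `modal_lv(observed)` or, failing that, inner selection on the full data.
#' @param runs Repetitions per permutation under `scheme = "full"`.
#' @param outer_groups,inner_groups,max_lv,stratified,blocks As in
#'   [rdcv_plsda()].
#' @param scheme `"reduced"` (default) or `"full"`; see Details.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Object of class `permutation_test`: list with `null` (B x 4
#'   matrix), `observed` (named vector or `NULL`), `p_values`, `B`, `n_lv`,
#'   `scheme`.
#' @export
permutation_test <- function(x, y, B = 1000, observed = NULL, n_lv = NULL,
                             runs = 2, outer_groups = 10, inner_groups = 8,
                             max_lv = 5, stratified = TRUE, blocks = NULL,
                             scheme = c("reduced", "full"), seed = NULL) {
  scheme <- match.arg(scheme)
  if (B < 1) stop("'B' must be at least 1")
  x <- as.matrix(x)
  y <- as_class_factor(y)
  obs_fom <- NULL
  if (!is.null(observed)) {
    if (!inherits(observed, "rdcv_plsda"))
      stop("'observed' must be an rdcv_plsda fit")
    obs_fom <- colMeans(observed$fom)
    if (is.null(n_lv)) n_lv <- modal_lv(observed)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_lv) && scheme == "reduced")
    n_lv <- as.integer(inner_select_lv(x, y, inner_groups, max_lv,
                                       stratified, blocks))
  null <- matrix(NA_real_, B, 4,
                 dimnames = list(NULL, c("sensitivity", "specificity",
                                         "error", "accuracy")))
  for (b in seq_len(B)) {
    yp <- y[sample.int(length(y))]
    if (scheme == "reduced") {
      folds <- split_groups(yp, outer_groups, stratified)
      pass <- dcv_pass(x, yp, folds, fold_seeds = NULL, inner_groups,
                       max_lv, stratified, blocks, fixed_lv = n_lv)
      null[b, ] <- figures_of_merit(pass$labels, yp)
    } else {
      fit <- rdcv_plsda(x, yp, runs = runs, outer_groups = outer_groups,
                        inner_groups = inner_groups, max_lv = max_lv,
                        stratified = stratified, blocks = blocks)
      null[b, ] <- colMeans(fit$fom)
    }
  }
  p_values <- NULL
  if (!is.null(obs_fom)) {
    p_values <- vapply(colnames(null), function(k) {
      extreme <- if (k == "error") null[, k] <= obs_fom[k]
                 else null[, k] >= obs_fom[k]
      (1 + sum(extreme)) / (B + 1)
    }, 0)
  }
  structure(list(null = null, observed = obs_fom, p_values = p_values,
                 B = B, n_lv = n_lv, scheme = scheme),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("Permutation test (", x$B, " randomizations, ", x$scheme,
      " scheme, ", x$n_lv, " latent variable(s))\n", sep = "")
  cat(sprintf("  null accuracy: mean %.1f%%, sd %.1f%%\n",
              100 * mean(x$null[, "accuracy"]),
              100 * stats::sd(x$null[, "accuracy"])))
  if (!is.null(x$p_values)) {
    for (k in names(x$p_values))
      cat(sprintf("  %-12s observed %5.1f%%  p = %.4g\n", k,
                  100 * x$observed[k], x$p_values[k]))
  }
  invisible(x)
}
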