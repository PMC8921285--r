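test_that("stratified splits balance classes across deletion groups", {
  withr::local_seed(1)
  y <- factor(rep(c("BPH", "PCa"), each = 20), levels = c("BPH", "PCa"))
  g <- split_groups(y, 10)
  expect_length(g, 10)
  # partition: disjoint, exhaustive
  expect_setequal(unlist(g), seq_along(y))
  expect_equal(sum(lengths(g)), 40)
  # 20 per class over 10 groups -> exactly 2 + 2 in each
  for (gr in g) expect_equal(as.integer(table(y[gr])), c(2L, 2L))
  # leave-one-out partition
  loo <- split_groups(y, 40, stratified = FALSE)
  expect_equal(sort(lengths(loo)), rep(1L, 40))
  expect_error(split_groups(y, 21), "infeasible")
  expect_error(split_groups(y, 41, stratified = FALSE), "k")
})

test_that("latent-variable choice minimizes error with parsimony ties", {
  # constructed error profiles exercise the selection rule directly
  expect_equal(plsrdcv:::choose_lv(c(0.4, 0.3, 0.1, 0.1, 0.1)), 3)
  expect_equal(plsrdcv:::choose_lv(c(0.5, 0.5, 0.5)), 1)   # pure-noise tie
  expect_equal(plsrdcv:::choose_lv(c(0.2, 0.1, 0.3)), 2)
})

test_that("inner selection finds one latent variable in rank-1 structure", {
  # signal living entirely in a single direction (rank-1 class structure):
  # n_lv = 1 chosen in >= 90% of seeds
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    t <- rep(c(-1, 1), each = 10) + 0.15 * rnorm(20)
    x <- outer(t, runif(6, 0.5, 2)) + matrix(rnorm(120, 0, 0.05), 20)
    y <- factor(rep(c("BPH", "PCa"), each = 10), levels = c("BPH", "PCa"))
    as.integer(inner_select_lv(x, y, inner_groups = 5, max_lv = 3)) == 1L
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("figures of merit follow the counting definitions", {
  y <- factor(rep(c("BPH", "PCa"), each = 20), levels = c("BPH", "PCa"))
  expect_equal(unname(figures_of_merit(y, y)), c(1, 1, 0, 1))
  # 19/20 PCa and 18/20 BPH correct
  pred <- y
  pred[which(y == "PCa")[1]] <- "BPH"
  pred[which(y == "BPH")[1:2]] <- "PCa"
  fm <- figures_of_merit(pred, y)
  expect_equal(unname(fm), c(0.95, 0.90, 0.075, 0.925))
  # total flip zeroes both rates
  flip <- factor(ifelse(y == "PCa", "BPH", "PCa"), levels = levels(y))
  expect_equal(unname(figures_of_merit(flip, y)[1:2]), c(0, 0))
  expect_error(figures_of_merit(y, factor(rep("PCa", 40))), "both classes")
})

test_that("nearest-rank percentile intervals behave", {
  expect_equal(unname(nonparametric_ci(rep(3, 10))), c(3, 3, 3))
  ci <- nonparametric_ci(1:100, 0.95)
  expect_equal(unname(ci), c(50.5, 3, 98))
  expect_error(nonparametric_ci(1), "at least 2")
  # widening noise widens the interval
  withr::local_seed(2)
  base <- rnorm(200)
  w1 <- diff(nonparametric_ci(base)[c("lower", "upper")])
  w2 <- diff(nonparametric_ci(3 * base)[c("lower", "upper")])
  expect_gt(w2, w1)
})

test_that("every sample is predicted exactly once per run", {
  withr::local_seed(3)
  tc <- two_class_matrix(n_per_class = 10, p = 8, delta = 3)
  fit <- rdcv_plsda(tc$x, tc$y, runs = 3, outer_groups = 5,
                    inner_groups = 4, max_lv = 2, seed = 5)
  expect_equal(dim(fit$scores), c(3, 20))
  expect_false(anyNA(fit$scores))
  expect_equal(dim(fit$fom), c(3, 4))
  # harvested sub-models: runs x inner_groups under the default scheme
  expect_equal(nrow(fit$coef_harvest), 3 * 4)
})

test_that("the engine hits its separable limit", {
  # a strongly separated simulated study (effect 4 SD): zero error in
  # every run
  st <- simulated_study(seed = 31, effect_size = 4)
  fit <- rdcv_plsda(st$x, st$y, runs = 5, seed = 32)
  expect_equal(unname(fit$fom[, "error"]), rep(0, 5))
  expect_equal(unname(fit$fom[, "sensitivity"]), rep(1, 5))
  expect_equal(unname(fit$fom[, "specificity"]), rep(1, 5))
})

test_that("a fixed seed reproduces the result bit-identically", {
  withr::local_seed(5)
  tc <- two_class_matrix(n_per_class = 8, p = 6, delta = 2)
  f1 <- rdcv_plsda(tc$x, tc$y, runs = 3, outer_groups = 4,
                   inner_groups = 3, max_lv = 2, seed = 123)
  f2 <- rdcv_plsda(tc$x, tc$y, runs = 3, outer_groups = 4,
                   inner_groups = 3, max_lv = 2, seed = 123)
  expect_identical(f1$fom, f2$fom)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$coef_harvest, f2$coef_harvest)
})

test_that("validation rows never influence the fitted sub-models", {
  # leakage guard: corrupting an outer validation fold must leave that
  # fold's calibration model exactly unchanged
  withr::local_seed(6)
  tc <- two_class_matrix(n_per_class = 10, p = 8, delta = 2)
  set.seed(11)
  folds <- split_groups(tc$y, 5)
  fold_seeds <- sample.int(1e6, 5)
  p1 <- plsrdcv:::dcv_pass(tc$x, tc$y, folds, fold_seeds, inner_groups = 4,
                           max_lv = 3)
  x_corrupt <- tc$x
  x_corrupt[folds[[2]], ] <- 1e6 * matrix(runif(length(folds[[2]]) * 8),
                                          ncol = 8)
  p2 <- plsrdcv:::dcv_pass(x_corrupt, tc$y, folds, fold_seeds,
                           inner_groups = 4, max_lv = 3)
  expect_identical(p1$models[[2]], p2$models[[2]])
  expect_identical(p1$chosen_lv[2], p2$chosen_lv[2])
})

test_that("permutation p-values respect their bounds and formula", {
  withr::local_seed(7)
  tc <- two_class_matrix(n_per_class = 8, p = 6, delta = 5)
  fit <- rdcv_plsda(tc$x, tc$y, runs = 2, outer_groups = 4,
                    inner_groups = 3, max_lv = 2, seed = 2)
  pm <- permutation_test(tc$x, tc$y, B = 19, observed = fit,
                         outer_groups = 4, seed = 3)
  expect_true(all(pm$p_values >= 1 / 20 & pm$p_values <= 1))
  # separable data beats every null: p = 1/(B+1)
  expect_equal(unname(pm$p_values["accuracy"]), 1 / 20)
  expect_error(permutation_test(tc$x, tc$y, B = 0), "at least 1")
})

test_that("summary and coef expose the r-dCV distributions", {
  withr::local_seed(8)
  tc <- two_class_matrix(n_per_class = 8, p = 6, delta = 3)
  fit <- rdcv_plsda(tc$x, tc$y, runs = 4, outer_groups = 4,
                    inner_groups = 3, max_lv = 2, seed = 4)
  s <- summary(fit)
  expect_equal(nrow(s$fom), 4)
  expect_equal(nrow(s$sample_scores), 16)
  expect_equal(nrow(s$coefficients), 6)
  expect_true(all(s$fom$lower <= s$fom$mean & s$fom$mean <= s$fom$upper))
  expect_length(coef(fit), 6)
  expect_true(modal_lv(fit) %in% 1:2)
})
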