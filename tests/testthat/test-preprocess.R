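test_that("blank/carry-over filter drops features above 10% of the QC mean", {
  # feature 1 clean (blank 0), feature 2 at 20% of QC mean, feature 3 at 5%
  areas <- rbind(c(0, 20, 5),     # blank
                 c(100, 100, 100), c(100, 100, 100), c(100, 100, 100),
                 matrix(100, 4, 3))
  roles <- c("blank", "QC", "QC", "QC", rep("sample", 4))
  tab <- tiny_table(areas, roles)
  res <- filter_blank_carryover(tab, threshold = 0.10)
  expect_equal(colnames(res$table$areas), c("F0001", "F0003"))
  expect_equal(res$removed, "F0002")
  # blanks are consumed by the filter
  expect_false(any(res$table$sample_meta$role == "blank"))
  expect_error(filter_blank_carryover(res$table), "blank")
})

test_that("drift correction flattens an exactly linear QC trend", {
  # QC areas linear in injection order with slope 5: after correction every
  # QC equals the value at the mean QC order and the refit slope is 0
  orders <- 1:9
  qc_rows <- c(2, 4, 6, 8)
  areas <- matrix(100, 9, 2)
  areas[, 2] <- 50 + 5 * orders
  roles <- rep("sample", 9); roles[qc_rows] <- "QC"
  roles[1] <- "sample"
  tab <- tiny_table(areas, roles, orders = orders)
  out <- qc_drift_correct(tab)
  o_bar <- mean(orders[qc_rows])
  expect_equal(unname(out$areas[qc_rows, 2]), rep(50 + 5 * o_bar, 4))
  # refit slope on corrected QCs is 0 to numerical tolerance
  refit <- lm(out$areas[qc_rows, 2] ~ orders[qc_rows])
  expect_lt(abs(coef(refit)[2]), 1e-10)
  # a feature with no trend is untouched
  expect_equal(unname(out$areas[, 1]), rep(100, 9))
})

test_that("drift correction is idempotent and reduces QC dispersion", {
  withr::local_seed(7)
  cfg <- sim_config(seed = 7, drift_fraction = 1, drift_magnitude = 0.01,
                    n_blank_contaminated = 0, n_unstable_qc = 0,
                    n_qc_missing = 0)
  sim <- simulate_feature_table(cfg)
  once <- qc_drift_correct(sim$table)
  twice <- qc_drift_correct(once)
  expect_equal(twice$areas, once$areas, tolerance = 1e-10)
  qc <- monitoring_qc_rows_for_test(sim$table)
  rsd <- function(tab) mean(apply(tab$areas[qc, ], 2,
                                  function(v) sd(v) / mean(v)))
  expect_lt(rsd(once), rsd(sim$table))
})

test_that("QC presence and RSD filters apply the 25% rule", {
  # {80, 100, 120}: population sd 16.33 -> sample (n-1) sd 20, RSD 0.20,
  # retained; alternating 40/160 exceeds the threshold; a zero QC is a
  # presence failure, not a division error
  roles <- c("sample", rep("QC", 3), rep("sample", 4))
  areas2 <- rbind(c(100, 100, 100, 100),
                  c(100, 80, 40, 0),
                  c(100, 100, 160, 100),
                  c(100, 120, 40, 100),
                  matrix(100, 4, 4))
  tab <- tiny_table(areas2, roles)
  res <- filter_qc_presence_rsd(tab, rsd_threshold = 0.25)
  expect_equal(colnames(res$table$areas), c("F0001", "F0002"))
  expect_equal(res$removed$qc_missing, "F0004")
  expect_equal(res$removed$qc_rsd, "F0003")
  # re-running removes nothing further (filter chain no-op on its output)
  again <- filter_qc_presence_rsd(res$table)
  expect_length(unlist(again$removed), 0)
})

test_that("creatinine normalization divides sample rows only", {
  areas <- rbind(c(10, 100), c(20, 100), c(30, 300))
  roles <- c("sample", "sample", "QC")
  tab <- tiny_table(areas, roles, creatinine = c(5, 10, NA))
  out <- normalize_creatinine(tab)
  expect_equal(unname(out$areas[1:2, 1]), c(2, 2))
  expect_equal(unname(out$areas[3, ]), c(30, 300))  # QC untouched
  # a 20x lower creatinine inflates the normalized profile 20x
  expect_equal(out$areas[1, 2] / out$areas[2, 2], 2)
  tab$sample_meta$creatinine[2] <- -1
  expect_error(validate_feature_table(tab), "R02")
})

test_that("autoscaling obeys the fit/apply contract", {
  withr::local_seed(1)
  x <- matrix(rnorm(60, 10, 3), 10, 6)
  sp <- autoscale_fit(x)
  z <- autoscale_apply(x, sp)
  expect_equal(unname(colMeans(z)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, var)), rep(1, 6), tolerance = 1e-12)
  # a validation row at the training mean maps to the zero vector
  expect_equal(unname(drop(autoscale_apply(rbind(sp$mean), sp))), rep(0, 6),
               tolerance = 1e-12)
  xc <- x; xc[, 3] <- 7; colnames(xc) <- paste0("V", 1:6)
  expect_error(autoscale_fit(xc), "V3")
})

test_that("block scaling yields unit Frobenius norms before concatenation", {
  withr::local_seed(2)
  a <- matrix(rnorm(40), 10, 4)
  one <- block_scale_concat(list(a))
  expect_equal(sqrt(sum(one^2)), 1)
  expect_equal(one, a / sqrt(sum(a^2)), ignore_attr = TRUE)
  # two identical blocks: same factor each, concatenated norm sqrt(2)
  two <- block_scale_concat(list(a, a))
  expect_equal(sqrt(sum(two^2)), sqrt(2))
  expect_equal(ncol(two), 8)
  # the study's reduced sets: 22 + 47 columns concatenate to 69
  b22 <- matrix(rnorm(40 * 22), 40); b47 <- matrix(rnorm(40 * 47), 40)
  expect_equal(ncol(block_scale_concat(list(b22, b47))), 69)
  expect_error(block_scale_concat(list(a, matrix(0, 9, 2))), "row count")
  expect_error(block_scale_concat(list(matrix(0, 10, 2))), "zero-norm")
})

test_that("a common creatinine factor cancels under autoscaling", {
  withr::local_seed(3)
  sim <- simulate_feature_table(sim_config(seed = 3, n_features = 20,
                                           n_discriminant = 3,
                                           n_blank_contaminated = 0,
                                           n_unstable_qc = 0, n_qc_missing = 0))
  tab <- sim$table
  tab$sample_meta$creatinine[tab$sample_meta$role == "sample"] <- 100
  norm <- normalize_creatinine(tab)
  smp <- tab$sample_meta$role == "sample"
  z_raw <- autoscale_apply(tab$areas[smp, ],
                           autoscale_fit(tab$areas[smp, ]))
  z_norm <- autoscale_apply(norm$areas[smp, ],
                            autoscale_fit(norm$areas[smp, ]))
  expect_equal(z_norm, z_raw, tolerance = 1e-12)
})
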