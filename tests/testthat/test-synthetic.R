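test_that("injection sequence interleaves QCs after sample blocks", {
  # the study layout: 10 conditioning QCs, 8 blocks of 5 samples + 1 QC
  seq40 <- injection_sequence(40, n_conditioning_qc = 10, group_size = 5)
  expect_equal(nrow(seq40), 58)
  expect_equal(sum(seq40$role == "QC"), 18)
  expect_equal(seq40$role[1:10], rep("QC", 10))
  expect_equal(seq40$injection_order, 1:58)
  # every block of 5 samples is followed by one QC
  post <- seq40$role[-(1:10)]
  expect_equal(post, rep(c(rep("sample", 5), "QC"), 8))

  seq5 <- injection_sequence(5, n_conditioning_qc = 0, group_size = 5)
  expect_equal(seq5$role, c(rep("sample", 5), "QC"))
  expect_equal(seq5$injection_order, 1:6)

  # a final partial block still gets its QC: 7 samples -> ceiling(7/5) QCs
  seq7 <- injection_sequence(7, n_conditioning_qc = 0, group_size = 5)
  expect_equal(nrow(seq7), 7 + ceiling(7 / 5))
  expect_equal(seq7$role[nrow(seq7)], "QC")

  expect_error(injection_sequence(0), "positive")
  expect_error(injection_sequence(5, group_size = 0), "positive")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(effect_size = -1), "effect_size")
  expect_error(sim_config(qc_rsd = -0.1), "qc_rsd")
  expect_error(sim_config(n_features = 20, n_discriminant = 10,
                          n_blank_contaminated = 6, n_unstable_qc = 3,
                          n_qc_missing = 3), "exceed")
  expect_error(sim_config(n_per_class = 0), "n_per_class")
})

test_that("noise-free null generator gives identical QCs and equal classes", {
  cfg <- sim_config(effect_size = 0, drift_fraction = 0, qc_rsd = 0,
                    n_unstable_qc = 0, n_qc_missing = 0,
                    n_blank_contaminated = 0, seed = 1)
  sim <- simulate_feature_table(cfg)
  qc <- sim$table$sample_meta$role == "QC"
  expect_true(all(apply(sim$table$areas[qc, ], 2,
                        function(v) diff(range(v)) == 0)))
  # zero effect size: classes exchangeable in expectation
  expect_true(all(sim$truth$signed_effects == 0))
  smp <- sim$table$sample_meta$role == "sample"
  cls <- sim$table$sample_meta$class[smp]
  x1 <- sim$table$areas[smp, sim$truth$discriminant_indices[1]]
  expect_gt(t.test(x1[cls == "PCa"], x1[cls == "BPH"])$p.value, 0.01)
})

test_that("simulated tables honour structure and ground truth", {
  sim <- simulate_feature_table(sim_config(seed = 9))
  tab <- sim$table
  expect_s3_class(tab, "feature_table")
  expect_equal(sum(tab$sample_meta$role == "sample"), 40)
  expect_equal(as.integer(table(tab$sample_meta$class)[c("BPH", "PCa")]),
               c(20L, 20L))
  tr <- sim$truth
  expect_length(tr$discriminant_indices, 22)
  expect_length(intersect(tr$discriminant_indices,
                          unlist(tr$filtered_indices)), 0)
  # signed effects split per direction_mix
  expect_equal(sum(tr$signed_effects > 0), 11)
})

test_that("low-creatinine outlier is planted exactly once", {
  sim <- simulate_feature_table(sim_config(seed = 3,
                                           low_creatinine_outlier = TRUE))
  cre <- sim$table$sample_meta$creatinine
  cre <- cre[sim$table$sample_meta$role == "sample"]
  expect_equal(sum(cre < 10), 1)
  expect_equal(cre[1], 5)
})

test_that("QC technical noise matches the configured RSD", {
  # across the stable, undrifted features the empirical QC RSD should sit
  # within 20% (relative) of the configured value; >1000 QC draws in total
  cfg <- sim_config(seed = 21, drift_fraction = 0, n_unstable_qc = 0,
                    n_qc_missing = 0, qc_rsd = 0.10)
  sim <- simulate_feature_table(cfg)
  qc <- monitoring_qc_rows_for_test(sim$table)
  qa <- sim$table$areas[qc, -unlist(sim$truth$filtered_indices)]
  expect_gt(length(qa), 1000)
  rsd <- apply(qa, 2, function(v) sd(v) / mean(v))
  expect_lt(abs(mean(rsd) - 0.10) / 0.10, 0.20)
})

test_that("power at the planted effect size is high", {
  # Monte-Carlo: the two-sample t-test on a planted feature at effect 1.5
  # (n = 20 + 20) rejects at alpha = 0.05 in >= 90% of seeds
  hits <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = s, n_features = 5, n_discriminant = 1,
                      n_blank_contaminated = 0, n_unstable_qc = 0,
                      n_qc_missing = 0, drift_fraction = 0)
    sim <- simulate_feature_table(cfg)
    norm <- normalize_creatinine(sim$table)   # remove dilution spread
    smp <- norm$sample_meta$role == "sample"
    x <- norm$areas[smp, sim$truth$discriminant_indices]
    cl <- norm$sample_meta$class[smp]
    stats::t.test(x[cl == "PCa"], x[cl == "BPH"])$p.value < 0.05
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("filters remove exactly the planted indices in noise-free settings", {
  cfg <- sim_config(seed = 5, qc_rsd = 0, drift_fraction = 0)
  sim <- simulate_feature_table(cfg)
  pp <- preprocess(sim$table)
  ids <- sim$table$feature_meta$id
  expect_setequal(pp$removed$blank, ids[sim$truth$filtered_indices$blank])
  expect_setequal(pp$removed$qc_rsd, ids[sim$truth$filtered_indices$qc_rsd])
  expect_setequal(pp$removed$qc_missing,
                  ids[sim$truth$filtered_indices$qc_missing])
  expect_equal(ncol(pp$table$areas),
               cfg$n_features - length(unlist(sim$truth$filtered_indices)))
})

test_that("truth file round-trips through JSON", {
  sim <- simulate_feature_table(sim_config(seed = 2, n_features = 30,
                                           n_discriminant = 4,
                                           n_blank_contaminated = 2,
                                           n_unstable_qc = 1,
                                           n_qc_missing = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_truth(sim$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$discriminant_indices, sim$truth$discriminant_indices)
  expect_equal(back$filtered_indices$blank,
               sim$truth$filtered_indices$blank)
})
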