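# small fixtures built in code

# a hand-sized feature table: n_smp samples split over two classes, plus
# monitoring QCs and blanks, with directly controllable areas
tiny_table <- function(areas, roles, classes = NULL, orders = NULL,
                       creatinine = NULL) {
  n <- nrow(areas)
  if (is.null(orders)) orders <- seq_len(n)
  if (is.null(classes)) {
    classes <- rep(NA_character_, n)
    smp <- which(roles == "sample")
    classes[smp] <- rep_len(c("BPH", "PCa"), length(smp))
  }
  if (is.null(creatinine)) {
    creatinine <- rep(NA_real_, n)
    creatinine[roles == "sample"] <- 100
  }
  feature_table(areas,
                data.frame(id = sprintf("R%02d", seq_len(n)), role = roles,
                           class = classes, injection_order = orders,
                           creatinine = creatinine,
                           stringsAsFactors = FALSE))
}

# two spherical Gaussian classes with signal on the first `informative`
# columns; separation `delta` in SD units
two_class_matrix <- function(n_per_class = 10, p = 10, informative = 2,
                             delta = 4) {
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * p), n, p)
  y <- factor(rep(c("BPH", "PCa"), each = n_per_class),
              levels = c("BPH", "PCa"))
  sgn <- ifelse(y == "PCa", 1, -1)
  x[, seq_len(informative)] <- x[, seq_len(informative)] +
    outer(sgn, rep(delta / 2, informative))
  colnames(x) <- paste0("V", seq_len(p))
  list(x = x, y = y)
}

monitoring_qc_rows_for_test <- function(x) plsrdcv:::monitoring_qc_rows(x)

# default simulated study, preprocessed down to the model-ready matrix
simulated_study <- function(seed = 42, ...) {
  sim <- simulate_feature_table(sim_config(seed = seed, ...))
  pp <- preprocess(sim$table)
  c(sample_matrix(pp$table), list(truth = sim$truth, removed = pp$removed,
                                  table = pp$table))
}
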