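#' Simulation configuration for synthetic feature tables
#'
#' Describes a two-class untargeted metabolomics acquisition: a balanced
#' PCa/BPH cohort profiled in one injection sequence with pooled-QC monitors
#' every few samples, blank injections, injection-order signal drift, and a
#' planted subset of class-discriminant features with known signed effects.
#'
#' Peak areas are log-normal: feature baselines (log means) spread around
#' `base_log_mean`, biological between-sample variation has standard deviation
#' `base_log_sd` on the log scale, and planted features differ between classes
#' by `effect_size * base_log_sd` on the log scale (so `effect_size` is the
#' class separation in within-class standard-deviation units).
#'
#' @param n_per_class Samples per class (default 20, the study design).
#' @param n_features Total number of features (default 200; scalable to the
#'   thousands found in real peak tables).
#' @param n_discriminant Number of planted class-dependent features.
#' @param effect_size Mean class separation of planted features in
#'   within-class SD units on the log scale (>= 0).
#' @param direction_mix Fraction of planted features overexpressed in PCa.
#' @param base_log_mean,base_log_sd Log-normal baseline: mean log area and
#'   biological log-scale SD.
#' @param drift_fraction,drift_magnitude Share of features subject to linear
#'   injection-order drift and the relative slope per injection (a drifted
#'   area is multiplied by `1 + drift_magnitude * (order - 1)`).
#' @param qc_rsd Technical relative standard deviation of stable features in
#'   QC injections.
#' @param n_blank_contaminated Features also present in blank injections (at
#'   20% of the QC mean, above the 10% carry-over rule).
#' @param n_unstable_qc Features whose QC areas alternate +/-50% around their
#'   mean, guaranteeing QC RSD above the 25% stability filter.
#' @param n_qc_missing Features absent (zero) from at least one monitoring QC.
#' @param creatinine_log_mean,creatinine_log_sd Log-normal urinary creatinine
#'   distribution (mg/dL).
#' @param low_creatinine_outlier Plant one sample with creatinine 5 mg/dL,
#'   emulating an anomalously dilute urine.
#' @param n_conditioning_qc Conditioning QC injections preceding the sample
#'   sequence (default 10); excluded from drift and RSD statistics downstream.
#' @param qc_group_size Samples per block between monitoring QC injections.
#' @param n_blank_rows Blank injections preceding the sequence.
#' @param seed RNG seed used by [simulate_feature_table()]; `NULL` leaves the
#'   RNG state untouched.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_per_class = 20,
                       n_features = 200,
                       n_discriminant = 22,
                       effect_size = 1.5,
                       direction_mix = 0.5,
                       base_log_mean = log(1e6),
                       base_log_sd = 0.5,
                       drift_fraction = 0.3,
                       drift_magnitude = 0.005,
                       qc_rsd = 0.10,
                       n_blank_contaminated = 10,
                       n_unstable_qc = 5,
                       n_qc_missing = 5,
                       creatinine_log_mean = log(100),
                       creatinine_log_sd = 0.4,
                       low_creatinine_outlier = FALSE,
                       n_conditioning_qc = 10,
                       qc_group_size = 5,
                       n_blank_rows = 3,
                       seed = NULL) {
  cfg <- as.list(environment())
  counts <- c("n_per_class", "n_features", "n_discriminant",
              "n_blank_contaminated", "n_unstable_qc", "n_qc_missing",
              "n_conditioning_qc", "qc_group_size", "n_blank_rows")
  for (nm in counts)
    if (cfg[[nm]] < 0 || cfg[[nm]] != round(cfg[[nm]]))
      stop("'", nm, "' must be a non-negative integer")
  if (cfg$n_per_class < 1) stop("'n_per_class' must be at least 1")
  if (cfg$qc_group_size < 1) stop("'qc_group_size' must be at least 1")
  if (cfg$effect_size < 0) stop("'effect_size' must be >= 0")
  if (cfg$qc_rsd < 0) stop("'qc_rsd' must be >= 0")
  if (cfg$direction_mix < 0 || cfg$direction_mix > 1)
    stop("'direction_mix' must lie in [0, 1]")
  planted <- cfg$n_discriminant + cfg$n_blank_contaminated +
    cfg$n_unstable_qc + cfg$n_qc_missing
  if (planted > cfg$n_features)
    stop("planted feature counts (", planted, ") exceed n_features (",
         cfg$n_features, ")")
  structure(cfg, class = "sim_config")
}

#' Build an injection sequence
#'
#' Conditioning QC injections first, then the randomized samples in blocks of
#' `group_size`, each block (including a final partial one) followed by one
#' monitoring QC injection. Injection orders run from 1.
#'
#' @param n_samples Number of study samples.
#' @param n_conditioning_qc Leading QC injections (system conditioning).
#' @param group_size Samples per block between monitoring QCs.
#' @return Data frame with columns `injection_order` and `role`
#'   (`"QC"` or `"sample"`).
#' @export
injection_sequence <- function(n_samples, n_conditioning_qc = 10,
                               group_size = 5) {
  if (n_samples < 1) stop("'n_samples' must be positive")
  if (group_size < 1) stop("'group_size' must be positive")
  if (n_conditioning_qc < 0) stop("'n_conditioning_qc' must be non-negative")
  roles <- rep("QC", n_conditioning_qc)
  left <- n_samples
  while (left > 0) {
    k <- min(group_size, left)
    roles <- c(roles, rep("sample", k), "QC")
    left <- left - k
  }
  data.frame(injection_order = seq_along(roles), role = roles,
             stringsAsFactors = FALSE)
}

#' Simulate a feature table with planted ground truth
#'
#' Generates peak areas for a balanced two-class cohort following the
#' acquisition layout in `config`: blank injections, conditioning QCs, then
#' randomized samples interleaved with monitoring QCs. Each sample's areas
#' scale with its urine concentration, indexed by the drawn creatinine value,
#' so downstream creatinine normalization removes the dilution spread (up to
#' a constant absorbed by autoscaling). QC areas are the
#' per-feature mean of the sample areas (pooled-QC semantics) plus
#' multiplicative technical noise with relative SD `qc_rsd`. Drifted features
#' are multiplied by a linear function of injection order across all rows.
#' Planted discriminant features shift the class log-means by their signed
#' effects; contaminated, unstable and QC-missing features are planted so the
#' preprocessing filters remove exactly the recorded `filtered_indices`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `table` (a [feature_table()]) and `truth`, an
#'   object of class `sim_truth` with fields `discriminant_indices`,
#'   `signed_effects` (log-scale, + means overexpressed in PCa),
#'   `filtered_indices` (list by reason: `blank`, `qc_rsd`, `qc_missing`)
#'   and `drift_indices`.
#' @export
simulate_feature_table <- function(config = sim_config()) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config object")
  if (!is.null(config$seed)) set.seed(config$seed)
  n_smp <- 2L * config$n_per_class
  p <- config$n_features

  # planted index sets, disjoint by construction
  idx <- seq_len(p)
  disc <- idx[seq_len(config$n_discriminant)]
  rest <- setdiff(idx, disc)
  blank_idx <- rest[seq_len(config$n_blank_contaminated)]
  rest <- setdiff(rest, blank_idx)
  unstable_idx <- rest[seq_len(config$n_unstable_qc)]
  rest <- setdiff(rest, unstable_idx)
  missing_idx <- rest[seq_len(config$n_qc_missing)]

  n_up <- round(config$direction_mix * config$n_discriminant)
  signs <- rep(c(1, -1), c(n_up, config$n_discriminant - n_up))
  signed_effects <- signs * config$effect_size

  seq_df <- injection_sequence(n_smp, config$n_conditioning_qc,
                               config$qc_group_size)
  seq_df$injection_order <- seq_df$injection_order + config$n_blank_rows
  if (config$n_blank_rows > 0)
    seq_df <- rbind(data.frame(injection_order = seq_len(config$n_blank_rows),
                               role = "blank", stringsAsFactors = FALSE),
                    seq_df)

  classes <- sample(rep(c("PCa", "BPH"), each = config$n_per_class))
  y_sign <- ifelse(classes == "PCa", 1, -1)

  # urinary creatinine indexes each sample's dilution; peak areas scale
  # with urine concentration the same way, which is what creatinine
  # normalization later removes
  creat <- stats::rlnorm(n_smp, config$creatinine_log_mean,
                         config$creatinine_log_sd)
  creat <- pmax(creat, 10.01)
  if (config$low_creatinine_outlier) creat[1] <- 5
  dilution <- log(creat) - config$creatinine_log_mean

  # sample log-areas: feature baseline + class effect + dilution +
  # biological noise
  mu <- stats::rnorm(p, config$base_log_mean, 1)
  logA <- matrix(stats::rnorm(n_smp * p, 0, config$base_log_sd), n_smp, p)
  logA <- sweep(logA, 2, mu, "+") + dilution
  if (config$n_discriminant > 0)
    logA[, disc] <- logA[, disc] +
      outer(y_sign, signed_effects * config$base_log_sd / 2)
  sample_areas <- exp(logA)

  pooled <- colMeans(sample_areas)
  n_qc <- sum(seq_df$role == "QC")
  sig <- sqrt(log1p(config$qc_rsd^2))
  qc_noise <- matrix(exp(stats::rnorm(n_qc * p, -sig^2 / 2, sig)), n_qc, p)
  qc_areas <- sweep(qc_noise, 2, pooled, "*")
  # unstable features: deterministic +/-50% alternation on top of the noise,
  # keeping their QC RSD above the stability filter even at qc_rsd = 0
  if (length(unstable_idx)) {
    alt <- 1 + 0.5 * rep_len(c(1, -1), n_qc)
    qc_areas[, unstable_idx] <- qc_areas[, unstable_idx] * alt
  }

  blank_areas <- matrix(0, config$n_blank_rows, p)
  if (config$n_blank_rows > 0 && length(blank_idx))
    blank_areas[, blank_idx] <- rep(0.2 * pooled[blank_idx],
                                    each = config$n_blank_rows)

  # assemble rows in injection order
  areas <- matrix(0, nrow(seq_df), p)
  is_qc <- seq_df$role == "QC"
  is_smp <- seq_df$role == "sample"
  is_blk <- seq_df$role == "blank"
  areas[is_qc, ] <- qc_areas
  areas[is_smp, ] <- sample_areas
  if (any(is_blk)) areas[is_blk, ] <- blank_areas

  # zero out QC-missing features in the first monitoring QC
  mon_qc <- which(is_qc & seq_df$injection_order >
                    min(seq_df$injection_order[is_smp]))
  if (length(missing_idx) && length(mon_qc))
    areas[mon_qc[1], missing_idx] <- 0

  n_drift <- round(config$drift_fraction * p)
  drift_idx <- if (n_drift > 0) sort(sample(idx, n_drift)) else integer(0)
  if (length(drift_idx)) {
    fac <- 1 + config$drift_magnitude * (seq_df$injection_order - 1)
    areas[, drift_idx] <- areas[, drift_idx] * fac
  }

  ids <- character(nrow(seq_df))
  ids[is_blk] <- sprintf("Blank%02d", seq_len(sum(is_blk)))
  ids[is_qc] <- sprintf("QC%02d", seq_len(sum(is_qc)))
  ids[is_smp] <- sprintf("S%02d", seq_len(n_smp))
  cls <- rep(NA_character_, nrow(seq_df))
  cls[is_smp] <- classes
  cre_col <- rep(NA_real_, nrow(seq_df))
  cre_col[is_smp] <- creat
  sm <- data.frame(id = ids, role = seq_df$role, class = cls,
                   injection_order = seq_df$injection_order,
                   creatinine = cre_col, stringsAsFactors = FALSE)
  fm <- data.frame(id = sprintf("F%04d", idx),
                   molecular_weight = round(stats::runif(p, 70, 1000), 4),
                   retention_time = round(stats::runif(p, 0.5, 22), 3),
                   stringsAsFactors = FALSE)
  colnames(areas) <- fm$id

  truth <- structure(list(
    discriminant_indices = disc,
    signed_effects = stats::setNames(signed_effects, fm$id[disc]),
    filtered_indices = list(blank = blank_idx, qc_rsd = unstable_idx,
                            qc_missing = missing_idx),
    drift_indices = drift_idx), class = "sim_truth")

  list(table = feature_table(areas, sm, fm), truth = truth)
}

#' Write planted ground truth as JSON
#'
#' @param truth A `sim_truth` object from [simulate_feature_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
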