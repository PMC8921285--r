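#' Run the end-to-end discovery pipeline
#'
#' Orchestrates the whole workflow on one or two data blocks (the two
#' electrospray-ionization modes of an untargeted acquisition): simulate (or
#' read) feature tables, preprocess, PCA diagnostics, full-variable repeated
#' double cross-validation, rank-product + VIP biomarker selection, reduced
#' re-modeling, optional two-block fusion with unit-Frobenius block scaling,
#' and a permutation test of the final model. All reports are written under
#' `out_dir` and a top-level `summary.json` collects the figures of merit
#' (with nonparametric intervals), selected variable counts and permutation
#' p-values. The run is deterministic given `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config_a Simulation configuration for block A ([sim_config()]), or
#'   a ready [feature_table()].
#' @param config_b Optional second block (simulation config or table);
#'   `NULL` for a single-block analysis.
#' @param runs,outer_groups,inner_groups,max_lv As in [rdcv_plsda()].
#' @param permutations Label randomizations for the permutation test
#'   (reduced scheme); 0 skips the test.
#' @param seed Integer master seed; every stage derives its seed from it.
#' @param simulate_only Stop after writing tables and truth files.
#' @param verbose Log stage progress via [message()].
#' @return Invisibly, a list with per-block results (`table`, `removed`,
#'   `pca`, `rdcv`, `selection`, `reduced`), `fused` (when two blocks),
#'   `permutation`, and `summary` (the list written to `summary.json`).
#' @export
run_pipeline <- function(out_dir,
                         config_a = sim_config(),
                         config_b = NULL,
                         runs = 30, outer_groups = 10, inner_groups = 8,
                         max_lv = 5, permutations = 200, seed = 1,
                         simulate_only = FALSE, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  stage <- function(nm) say("[%s] %.1fs", nm, proc.time()[3] - t0)

  blocks_in <- Filter(Negate(is.null), list(A = config_a, B = config_b))
  tables <- list()
  truths <- list()
  for (i in seq_along(blocks_in)) {
    nm <- names(blocks_in)[i]
    cfg <- blocks_in[[i]]
    if (inherits(cfg, "feature_table")) {
      tables[[nm]] <- cfg
    } else {
      if (is.null(cfg$seed)) cfg$seed <- (seed * 13L + i) %% 2147483647L
      sim <- simulate_feature_table(cfg)
      tables[[nm]] <- sim$table
      truths[[nm]] <- sim$truth
      write_feature_table(sim$table, out_dir, paste0("block", nm, "_raw"))
      write_sim_truth(sim$truth,
                      file.path(out_dir, paste0("block", nm, "_truth.json")))
    }
  }
  stage("simulate")
  if (simulate_only)
    return(invisible(list(tables = tables, truths = truths)))

  results <- list()
  summary_out <- list(seed = seed, models = list())
  reduced_mats <- list()
  y_ref <- NULL
  for (nm in names(tables)) {
    pp <- preprocess(tables[[nm]])
    jsonlite::write_json(pp$removed,
                         file.path(out_dir,
                                   paste0("block", nm, "_filter_report.json")),
                         auto_unbox = FALSE, pretty = TRUE)
    sm <- sample_matrix(pp$table)
    y_ref <- sm$y
    xs <- autoscale_apply(sm$x, autoscale_fit(sm$x))
    pca <- pca_qc(xs, n_components = min(3, nrow(xs) - 1))
    jsonlite::write_json(list(t2 = pca$t2, q = pca$q,
                              explained_variance = pca$explained_variance,
                              score_order_correlation = NULL),
                         file.path(out_dir,
                                   paste0("block", nm, "_pca.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage(paste0("preprocess+pca ", nm))

    fit <- rdcv_plsda(sm$x, sm$y, runs = runs, outer_groups = outer_groups,
                      inner_groups = inner_groups, max_lv = max_lv,
                      seed = (seed * 101L + match(nm, names(tables))) %%
                        2147483647L)
    sel <- select_biomarkers(fit)
    write_selection_report(sel,
                           file.path(out_dir,
                                     paste0("block", nm, "_selection.csv")))
    stage(paste0("rdcv+selection ", nm))

    x_red <- sm$x[, sel$selected, drop = FALSE]
    red <- rdcv_plsda(x_red, sm$y, runs = runs,
                      outer_groups = outer_groups,
                      inner_groups = inner_groups, max_lv = max_lv,
                      seed = (seed * 211L + match(nm, names(tables))) %%
                        2147483647L)
    roc <- mean_roc(red)
    summary_out$models[[paste0("block_", nm)]] <-
      model_summary(red, roc, n_selected = length(sel$selected))
    results[[nm]] <- list(table = pp$table, removed = pp$removed, pca = pca,
                          rdcv = fit, selection = sel, reduced = red,
                          roc = roc)
    reduced_mats[[nm]] <- x_red
    stage(paste0("reduced model ", nm))
  }

  fused <- NULL
  if (length(reduced_mats) == 2) {
    x_fused <- cbind(reduced_mats[[1]], reduced_mats[[2]])
    blocks <- list(seq_len(ncol(reduced_mats[[1]])),
                   ncol(reduced_mats[[1]]) + seq_len(ncol(reduced_mats[[2]])))
    fused <- rdcv_plsda(x_fused, y_ref, runs = runs,
                        outer_groups = outer_groups,
                        inner_groups = inner_groups, max_lv = max_lv,
                        blocks = blocks,
                        seed = (seed * 307L) %% 2147483647L)
    roc_f <- mean_roc(fused)
    summary_out$models$fused <-
      model_summary(fused, roc_f, n_selected = ncol(x_fused))
    stage("fused model")
  }

  perm <- NULL
  if (permutations > 0) {
    final <- if (!is.null(fused)) fused else results[[1]]$reduced
    x_final <- if (!is.null(fused)) {
      cbind(reduced_mats[[1]], reduced_mats[[2]])
    } else reduced_mats[[1]]
    perm <- permutation_test(x_final, y_ref, B = permutations,
                             observed = final,
                             outer_groups = outer_groups,
                             blocks = final$config$blocks,
                             seed = (seed * 401L) %% 2147483647L)
    summary_out$permutation <- list(
      B = perm$B,
      null_accuracy_mean = mean(perm$null[, "accuracy"]),
      p_values = as.list(perm$p_values))
    stage("permutation test")
  }

  path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("summary written to %s", path)
  invisible(list(blocks = results, fused = fused, permutation = perm,
                 summary = summary_out))
}

model_summary <- function(fit, roc, n_selected) {
  fm <- apply(fit$fom, 2, nonparametric_ci, level = fit$config$ci_level)
  list(n_variables = n_selected,
       figures_of_merit = apply(fm, 2, as.list),
       auroc = list(mean = roc$auroc_mean, lower = roc$auroc_ci[1],
                    upper = roc$auroc_ci[2]),
       modal_lv = modal_lv(fit))
}
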