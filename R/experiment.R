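#' Experiment configuration
#'
#' Bundles everything needed for a reproducible end-to-end run: the
#' synthetic-data (or on-disk) inputs, the MCMC schedule, the fold seed and
#' the list of model configurations to compare.  All randomness derives
#' from the seeds recorded here, so a configuration re-run yields an
#' identical report.
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param model a [model_config()] used for all fits.
#' @param k_folds number of cross-validation folds.
#' @param fold_seed seed for the family-to-fold assignment (shared across
#'   all configurations so the paired t-test pairs like with like).
#' @param configurations list of configurations, each a list with `name`,
#'   `blocks` (subset of `c("S", "G")`), `priors`, `selection`, `k_genes`.
#' @param maf_min,call_rate_min genotype QC thresholds.
#' @param output_dir optional directory for the report bundle.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              model = model_config(),
                              k_folds = 5,
                              fold_seed = 1,
                              configurations = list(
                                list(name = "S_lasso", blocks = "S",
                                     priors = "lasso", selection = "all",
                                     k_genes = 3000),
                                list(name = "G_lasso", blocks = "G",
                                     priors = "lasso", selection = "all",
                                     k_genes = 3000),
                                list(name = "S+G_lasso", blocks = c("S", "G"),
                                     priors = "lasso", selection = "all",
                                     k_genes = 3000)),
                              maf_min = 0.05, call_rate_min = 0.90,
                              output_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"), inherits(model, "model_config"),
            length(configurations) >= 1)
  for (cc in configurations)
    stopifnot(!is.null(cc$name), all(cc$blocks %in% c("S", "G")))
  structure(list(sim = sim, model = model, k_folds = as.integer(k_folds),
                 fold_seed = as.integer(fold_seed),
                 configurations = configurations,
                 maf_min = maf_min, call_rate_min = call_rate_min,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Run a full experiment
#'
#' Orchestrates the pipeline: simulate the dataset, apply genotype QC and
#' imputation, standardize expression, build the shared fold plan, and for
#' every configuration fit the full-data model (DIC + variance partition)
#' and run family-grouped cross-validation; finally compute the pairwise
#' paired-t matrix between configurations.  When `output_dir` is set the
#' report (JSON), the accuracy/DIC summary (TSV) and the config echo (YAML)
#' are written there.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress to stderr.
#' @return An object of class `experiment_report`: list with `data`
#'   (genotypes, expression, atlas, phenotype, truth), `fold_plan`,
#'   per-configuration `fits` (dic, variance partition, cv), `accuracy`
#'   summary data.frame, and the `pairwise` paired-t matrices.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("simulating data (seed %d)", config$sim$seed)
  geno <- simulate_population(config$sim)
  expr <- simulate_expression(geno, config$sim)
  atlas <- simulate_tissue_atlas(config$sim)
  sim_ph <- simulate_phenotype(geno, expr, config$sim)

  say("preprocessing")
  geno_qc <- filter_snps(geno, config$maf_min, config$call_rate_min)
  geno_imp <- impute_missing(geno_qc)
  expr_std <- standardize_expression(expr)

  phen <- sim_ph$phenotype
  fold_plan <- make_family_folds(setNames(phen$family, phen$sample),
                                 k = config$k_folds, seed = config$fold_seed)

  results <- list()
  for (cc in config$configurations) {
    say("configuration %s", cc$name)
    blocks <- cc$blocks
    selection <- cc$selection %||% "all"
    k_genes <- cc$k_genes %||% 3000

    # full-data fit for DIC and variance partition
    design <- list()
    if ("S" %in% blocks) design$S <- geno_imp$dosage[phen$sample, , drop = FALSE]
    if ("G" %in% blocks) {
      genes <- switch(selection,
        all = colnames(expr_std$std),
        SL_higher = ,
        SL_lower = select_sl(
          anova_family_pvalues(expr_std, setNames(phen$family, phen$sample)),
          k_genes, if (selection == "SL_higher") "higher" else "lower")$genes,
        TS_higher = intersect(
          select_ts(tissue_specificity_scores(
            atlas, attr(atlas, "target_tissue")), k_genes)$genes,
          colnames(expr_std$std)),
        SD_higher = select_sd(expr_std, k_genes)$genes)
      design$G <- expr_std$std[phen$sample, sort(genes), drop = FALSE]
    }
    y <- setNames(phen$value, phen$sample)
    fit <- gibbs_fit(y, design[blocks], priors = cc$priors,
                     config = config$model)
    dic <- compute_dic(fit, y, design[blocks])
    vp <- variance_partition(fit, design[blocks])

    cv <- cross_validate(phen,
                         genotypes = if ("S" %in% blocks) geno_imp else NULL,
                         expression = if ("G" %in% blocks) expr_std else NULL,
                         fold_plan = fold_plan, blocks = blocks,
                         priors = cc$priors, selection = selection,
                         k_genes = k_genes, atlas = atlas,
                         config = config$model, label = cc$name)
    results[[cc$name]] <- list(dic = dic, variance_partition = vp, cv = cv)
  }

  labels <- names(results)
  nL <- length(labels)
  t_mat <- p_mat <- matrix(NA_real_, nL, nL, dimnames = list(labels, labels))
  for (i in seq_len(nL)) for (j in seq_len(nL)) if (i != j) {
    tt <- paired_t_test(results[[i]]$cv$fold_cor, results[[j]]$cv$fold_cor)
    t_mat[i, j] <- tt$t
    p_mat[i, j] <- tt$p
  }

  accuracy <- data.frame(
    configuration = labels,
    mean_accuracy = vapply(results, function(r) r$cv$mean_accuracy, 0),
    dic = vapply(results, function(r) r$dic$dic, 0),
    pD = vapply(results, function(r) r$dic$pD, 0),
    row.names = NULL, stringsAsFactors = FALSE)

  report <- structure(list(
    data = list(genotypes = geno_imp, expression = expr_std, atlas = atlas,
                phenotype = phen, truth = sim_ph$truth),
    fold_plan = fold_plan,
    fits = results,
    accuracy = accuracy,
    pairwise = list(t = t_mat, p = p_mat),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "experiment_report")

  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(list(sim = unclass(config$sim),
                          model = unclass(config$model),
                          k_folds = config$k_folds,
                          fold_seed = config$fold_seed,
                          configurations = config$configurations),
                     file.path(dir, "experiment_config.yaml"))
    write.table(accuracy, file.path(dir, "accuracy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(accuracy = accuracy,
           pairwise_p = as.data.frame(p_mat),
           variance_partition = lapply(results, function(r)
             as.data.frame(r$variance_partition)),
           dic = lapply(results, function(r) r$dic),
           fold_cor = lapply(results, function(r) r$cv$fold_cor)),
      file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
    say("report written to %s", dir)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report\n")
  print(x$accuracy)
  invisible(x)
}
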