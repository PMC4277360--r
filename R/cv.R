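#' Family-grouped fold assignment
#'
#' Assigns whole full-sib families to k folds so that no family straddles a
#' fold boundary: families are visited in a seeded random order and each is
#' placed on the currently smallest fold (by animal count, ties toward the
#' lowest fold index).  With equal family sizes this yields exactly
#' balanced folds.
#'
#' @param family named character vector mapping sample IDs to families.
#' @param k number of folds.
#' @param seed optional integer seed for the family order.
#' @return An object of class `fold_plan`: list with `k`, `family_fold`
#'   (named integer vector), `sample_fold`, and `seed`.
#' @export
make_family_folds <- function(family, k = 5, seed = NULL) {
  stopifnot(!is.null(names(family)), k >= 2)
  fams <- unique(family)
  if (length(fams) < k) stop("fewer families than folds")
  if (!is.null(seed)) set.seed(seed)
  fam_sizes <- table(family)[fams]
  ord <- sample(fams)
  fold_of <- setNames(integer(length(fams)), fams)
  load <- numeric(k)
  for (f in ord) {
    i <- which.min(load)          # ties -> lowest index
    fold_of[f] <- i
    load[i] <- load[i] + fam_sizes[[f]]
  }
  structure(list(k = as.integer(k),
                 family_fold = fold_of,
                 sample_fold = setNames(fold_of[family], names(family)),
                 seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %d folds, %d families, %d samples\n",
              x$k, length(x$family_fold), length(x$sample_fold)))
  print(table(fold = x$sample_fold))
  invisible(x)
}

#' Family-grouped cross-validated prediction accuracy
#'
#' For each fold the model is trained on the remaining folds and accuracy
#' is the Pearson correlation between predicted and observed phenotypes on
#' the held-out fold; the reported accuracy is the mean over folds.  Gene
#' selection by the SL and SD criteria is recomputed on the training rows
#' of every fold (test data never influence the selection); the TS
#' criterion uses the external atlas and is fold-invariant.
#'
#' @param phenotype data.frame with columns `sample`, `family`, `value` (as
#'   produced by [simulate_phenotype()]).
#' @param genotypes imputed [geno_matrix()], or `NULL` when no SNP block is
#'   used.
#' @param expression standardized [expr_matrix()], or `NULL` when no
#'   expression block is used.
#' @param fold_plan a [make_family_folds()] plan covering all samples.
#' @param blocks character subset of `c("S", "G")` naming the explanatory
#'   blocks.
#' @param priors prior per block (`"ridge"`/`"lasso"`, recycled).
#' @param selection gene-selection criterion applied to the expression
#'   block: `"all"`, `"SL_higher"`, `"SL_lower"`, `"TS_higher"` or
#'   `"SD_higher"`.
#' @param k_genes number of genes kept by the selection criterion.
#' @param atlas a [tissue_atlas()]; required for `"TS_higher"`.
#' @param target_tissue atlas tissue used by `"TS_higher"` (defaults to the
#'   atlas's recorded target).
#' @param config a [model_config()] for the per-fold fits.
#' @param label configuration label carried into the result.
#' @return An object of class `cv_result`: list with `label`, `fold_cor`,
#'   `mean_accuracy`, `fold_sizes`.
#' @export
cross_validate <- function(phenotype, genotypes = NULL, expression = NULL,
                           fold_plan, blocks = c("S", "G"),
                           priors = "lasso",
                           selection = c("all", "SL_higher", "SL_lower",
                                         "TS_higher", "SD_higher"),
                           k_genes = 3000, atlas = NULL, target_tissue = NULL,
                           config = model_config(), label = NULL) {
  selection <- match.arg(selection)
  blocks <- match.arg(blocks, c("S", "G"), several.ok = TRUE)
  stopifnot(inherits(fold_plan, "fold_plan"))
  if ("S" %in% blocks && is.null(genotypes)) stop("S block requested but no genotypes")
  if ("G" %in% blocks && is.null(expression)) stop("G block requested but no expression")
  if (selection == "TS_higher" && "G" %in% blocks && is.null(atlas))
    stop("TS selection needs a tissue atlas")

  samples <- phenotype$sample
  fold_of <- fold_plan$sample_fold[samples]
  if (anyNA(fold_of)) stop("fold plan does not cover all phenotyped samples")
  y <- setNames(phenotype$value, samples)

  Xs <- if ("S" %in% blocks) genotypes$dosage[samples, , drop = FALSE] else NULL
  if (!is.null(Xs) && anyNA(Xs))
    stop("genotypes must be imputed before cross-validation")
  Eg <- if ("G" %in% blocks) {
    if (is.null(expression$std)) expression <- standardize_expression(expression)
    expression
  } else NULL

  ts_sel <- NULL
  if (!is.null(Eg) && selection == "TS_higher") {
    if (is.null(target_tissue)) target_tissue <- attr(atlas, "target_tissue")
    ts_sel <- select_ts(tissue_specificity_scores(atlas, target_tissue), k_genes)
  }

  priors <- rep_len(priors, length(blocks))
  fold_cor <- rep(NA_real_, fold_plan$k)
  fold_sizes <- matrix(0L, fold_plan$k, 2,
                       dimnames = list(NULL, c("train", "test")))
  for (fold in seq_len(fold_plan$k)) {
    test <- samples[fold_of == fold]
    train <- samples[fold_of != fold]
    fold_sizes[fold, ] <- c(length(train), length(test))
    if (length(test) == 0) next

    design <- list(); design_new <- list()
    if (!is.null(Xs)) {
      design$S <- Xs[train, , drop = FALSE]
      design_new$S <- Xs[test, , drop = FALSE]
    }
    if (!is.null(Eg)) {
      genes <- switch(selection,
        all = colnames(Eg$std),
        SL_higher = ,
        SL_lower = {
          p <- anova_family_pvalues(Eg, setNames(phenotype$family, samples),
                                    samples = train)
          select_sl(p, k_genes,
                    if (selection == "SL_higher") "higher" else "lower")$genes
        },
        TS_higher = intersect(ts_sel$genes, colnames(Eg$std)),
        SD_higher = select_sd(Eg, k_genes, samples = train)$genes)
      genes <- sort(genes)
      design$G <- Eg$std[train, genes, drop = FALSE]
      design_new$G <- Eg$std[test, genes, drop = FALSE]
    }
    fit <- gibbs_fit(y[train], design[blocks], priors = priors, config = config)
    yhat <- predict(fit, design_new[blocks])
    if (sd(y[test]) == 0) {
      warning("fold ", fold, " test phenotypes have zero variance; ",
              "correlation undefined, fold excluded from the mean")
    } else {
      fold_cor[fold] <- cor(yhat, y[test])
    }
  }
  structure(list(label = label %||%
                   paste0(paste(blocks, collapse = "+"), "/",
                          paste(priors, collapse = "+"), "/", selection),
                 fold_cor = fold_cor,
                 mean_accuracy = mean(fold_cor, na.rm = TRUE),
                 fold_sizes = fold_sizes),
            class = "cv_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: mean accuracy %.3f over %d folds (%s)\n",
              x$label, x$mean_accuracy, length(x$fold_cor),
              paste(sprintf("%.3f", x$fold_cor), collapse = ", ")))
  invisible(x)
}

#' Paired t-test between fold-wise accuracies
#'
#' Classical paired t-test on the fold-wise differences of two accuracy
#' vectors paired by fold: `t = mean(d) / (sd(d)/sqrt(k))` with k - 1
#' degrees of freedom, two-sided p-value.  Degenerate cases follow the
#' natural limits: all differences zero gives t = 0, p = 1; identical
#' nonzero differences give t = +/-Inf, p = 0.
#'
#' @param acc_a,acc_b numeric vectors of per-fold accuracies, equal length
#'   k >= 2, paired by fold.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t_test <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 2)
  d <- acc_a - acc_b
  k <- length(d)
  sd_d <- sd(d)
  if (sd_d == 0) {
    if (all(d == 0)) return(list(t = 0, df = k - 1, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = k - 1, p = 0))
  }
  t <- mean(d) / (sd_d / sqrt(k))
  list(t = t, df = k - 1, p = 2 * pt(-abs(t), df = k - 1))
}
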