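#' Simulation configuration
#'
#' Defines the conditions under which synthetic genotype, expression, atlas
#' and phenotype data are generated.  The defaults emulate the structure of a
#' heterogeneous-stock mouse study: around 250 animals phenotyped in full-sib
#' families, a genome-wide SNP panel of minor-allele counts, and a
#' transcriptome with an among-family variance component and heteroscedastic
#' raw-scale dispersion.
#'
#' @param n_families number of full-sib families.
#' @param sibs_per_family number of sibs per family; either a single count or
#'   a length-2 range from which each family's size is drawn uniformly.
#' @param n_snps number of SNPs on the panel (before any QC).
#' @param founder_maf_range interval in (0, 0.5] from which per-SNP founder
#'   allele frequencies are drawn.
#' @param n_genes number of genes on the expression array.
#' @param family_var_fraction_expr fraction in [0, 1) of each gene's
#'   (unit-scale) expression variance attributable to the full-sib family
#'   random effect.
#' @param n_eqtl_genes number of genes receiving a cis-eQTL effect from the
#'   SNP with the same index.
#' @param n_tissues number of tissues in the reference expression atlas.
#' @param n_tissue_specific number of genes boosted in the atlas target
#'   tissue.
#' @param tissue_boost additive boost (atlas log-scale units) applied to
#'   tissue-specific genes in the target tissue.
#' @param architecture `"dense"` (every marker has a Gaussian effect) or
#'   `"sparse"` (only `n_causal_*` markers have nonzero effects).
#' @param n_causal_snps,n_causal_genes number of causal markers per block
#'   under the sparse architecture.
#' @param var_frac_snp,var_frac_expr fractions of phenotypic variance
#'   explained by the SNP and expression blocks; their sum must be < 1.
#' @param missing_rate fraction of genotype entries set to missing,
#'   uniformly at random.
#' @param seed integer seed; all `simulate_*()` functions are deterministic
#'   given the configuration (each stage uses `seed` plus a small fixed
#'   offset so stages are independently reproducible).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_families = 10, sibs_per_family = 4,
#'                   n_snps = 100, n_genes = 50, seed = 1)
sim_config <- function(n_families = 50,
                       sibs_per_family = 5,
                       n_snps = 10000,
                       founder_maf_range = c(0.05, 0.5),
                       n_genes = 5000,
                       family_var_fraction_expr = 0.3,
                       n_eqtl_genes = 0,
                       n_tissues = 8,
                       n_tissue_specific = max(1, round(0.1 * n_genes)),
                       tissue_boost = 3,
                       architecture = c("dense", "sparse"),
                       n_causal_snps = 10,
                       n_causal_genes = 10,
                       var_frac_snp = 0.45,
                       var_frac_expr = 0.35,
                       missing_rate = 0,
                       seed = 1) {
  architecture <- match.arg(architecture)
  stopifnot(
    n_families >= 1, n_snps >= 1, n_genes >= 1, n_tissues >= 1,
    length(founder_maf_range) == 2,
    founder_maf_range[1] > 0, founder_maf_range[2] <= 0.5,
    founder_maf_range[1] <= founder_maf_range[2],
    family_var_fraction_expr >= 0, family_var_fraction_expr < 1,
    n_eqtl_genes >= 0, n_eqtl_genes <= min(n_genes, n_snps),
    n_tissue_specific >= 0, n_tissue_specific <= n_genes,
    var_frac_snp >= 0, var_frac_expr >= 0,
    var_frac_snp + var_frac_expr < 1,
    missing_rate >= 0, missing_rate < 1,
    n_causal_snps >= 1, n_causal_genes >= 1
  )
  if (length(sibs_per_family) == 1) sibs_per_family <- rep(sibs_per_family, 2)
  stopifnot(length(sibs_per_family) == 2, sibs_per_family[1] >= 1,
            sibs_per_family[1] <= sibs_per_family[2])
  structure(
    list(n_families = as.integer(n_families),
         sibs_per_family = as.integer(sibs_per_family),
         n_snps = as.integer(n_snps),
         founder_maf_range = founder_maf_range,
         n_genes = as.integer(n_genes),
         family_var_fraction_expr = family_var_fraction_expr,
         n_eqtl_genes = as.integer(n_eqtl_genes),
         n_tissues = as.integer(n_tissues),
         n_tissue_specific = as.integer(n_tissue_specific),
         tissue_boost = tissue_boost,
         architecture = architecture,
         n_causal_snps = as.integer(n_causal_snps),
         n_causal_genes = as.integer(n_causal_genes),
         var_frac_snp = var_frac_snp,
         var_frac_expr = var_frac_expr,
         missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "sim_config")
}

pad_id <- function(prefix, i, n) {
  sprintf(paste0(prefix, "%0", nchar(as.character(n)), "d"), i)
}

#' Simulate full-sib family genotypes
#'
#' For every family two unrelated parents are drawn per SNP under
#' Hardy-Weinberg proportions at a founder allele frequency (uniform on
#' `founder_maf_range`), and offspring genotypes are produced by Mendelian
#' transmission (gene dropping).  Entries are minor-allele counts 0/1/2;
#' missingness is injected uniformly at random at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return A [geno_matrix()] with family labels; parental genotypes are kept
#'   in the `"parents"` attribute so Mendelian consistency can be audited.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$n_snps
  freq <- runif(p, config$founder_maf_range[1], config$founder_maf_range[2])

  sizes <- if (config$sibs_per_family[1] == config$sibs_per_family[2]) {
    rep(config$sibs_per_family[1], config$n_families)
  } else {
    sample(seq(config$sibs_per_family[1], config$sibs_per_family[2]),
           config$n_families, replace = TRUE)
  }
  n <- sum(sizes)
  fam_ids <- pad_id("F", seq_len(config$n_families), config$n_families)

  geno <- matrix(NA_real_, n, p)
  mother <- matrix(0L, config$n_families, p)
  father <- matrix(0L, config$n_families, p)
  sample_ids <- character(n)
  family <- character(n)
  row <- 0L
  for (f in seq_len(config$n_families)) {
    # parental allele pairs under HWE at freq
    m1 <- rbinom(p, 1, freq); m2 <- rbinom(p, 1, freq)
    f1 <- rbinom(p, 1, freq); f2 <- rbinom(p, 1, freq)
    mother[f, ] <- m1 + m2
    father[f, ] <- f1 + f2
    for (s in seq_len(sizes[f])) {
      row <- row + 1L
      pick_m <- rbinom(p, 1, 0.5)  # which maternal allele is transmitted
      pick_f <- rbinom(p, 1, 0.5)
      geno[row, ] <- ifelse(pick_m == 1, m1, m2) + ifelse(pick_f == 1, f1, f2)
      sample_ids[row] <- paste0(fam_ids[f], "_S", s)
      family[row] <- fam_ids[f]
    }
  }
  rownames(geno) <- sample_ids
  colnames(geno) <- pad_id("SNP", seq_len(p), p)
  rownames(mother) <- rownames(father) <- fam_ids
  colnames(mother) <- colnames(father) <- colnames(geno)

  if (config$missing_rate > 0) {
    drop <- runif(length(geno)) < config$missing_rate
    geno[drop] <- NA_real_
  }
  g <- geno_matrix(geno, setNames(family, sample_ids))
  attr(g, "parents") <- list(mother = mother, father = father,
                             founder_freq = freq)
  g
}

#' Simulate gene expression with a family variance component
#'
#' Each gene's unit-scale signal is the sum of a full-sib family random
#' effect (variance `family_var_fraction_expr`), an optional cis-eQTL
#' contribution for the first `n_eqtl_genes` genes (driven by the SNP with
#' the same index), and Gaussian noise; the raw-scale value is
#' `baseline + scale * signal`, with per-gene log-normal scale factors so
#' that raw-scale standard deviations differ across genes.
#'
#' @param genotypes a [geno_matrix()] carrying family labels.
#' @param config a [sim_config()].
#' @return An [expr_matrix()] (raw view only; standardize with
#'   [standardize_expression()]).  The eQTL truth set is stored in the
#'   `"eqtl_genes"` attribute.
#' @export
simulate_expression <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "geno_matrix"))
  family <- genotypes$family
  if (is.null(family) || any(is.na(family)))
    stop("genotypes must carry a complete sample -> family map")
  set.seed(config$seed + 1L)

  n <- nrow(genotypes$dosage)
  g <- config$n_genes
  fams <- unique(family)
  f2i <- match(family, fams)
  fv <- config$family_var_fraction_expr

  baseline <- rnorm(g, mean = 7, sd = 1)
  scale_f <- exp(rnorm(g, 0, 0.5))
  u <- matrix(rnorm(length(fams) * g, 0, sqrt(fv)), length(fams), g)
  eps <- matrix(rnorm(n * g, 0, sqrt(1 - fv)), n, g)
  z <- u[f2i, , drop = FALSE] + eps

  eqtl_genes <- integer(0)
  if (config$n_eqtl_genes > 0) {
    eqtl_genes <- seq_len(config$n_eqtl_genes)
    x <- genotypes$dosage[, eqtl_genes, drop = FALSE]
    # mean-impute so effects apply to every sample
    for (j in seq_along(eqtl_genes)) {
      xj <- x[, j]
      xj[is.na(xj)] <- mean(xj, na.rm = TRUE)
      sdx <- sd(xj)
      if (sdx > 0) z[, eqtl_genes[j]] <- z[, eqtl_genes[j]] +
          sqrt(0.3) * (xj - mean(xj)) / sdx
    }
  }

  raw <- sweep(sweep(z, 2, scale_f, `*`), 2, baseline, `+`)
  rownames(raw) <- rownames(genotypes$dosage)
  gene_ids <- pad_id("G", seq_len(g), g)
  colnames(raw) <- gene_ids
  e <- expr_matrix(raw)
  attr(e, "eqtl_genes") <- gene_ids[eqtl_genes]
  attr(e, "scale_factors") <- setNames(scale_f, gene_ids)
  e
}

#' Simulate a multi-tissue reference expression atlas
#'
#' Generates a genes x tissues matrix of reference (log-scale) expression:
#' per-gene baselines plus tissue-level noise, with `n_tissue_specific`
#' designated genes receiving an additive `tissue_boost` in the first
#' (target) tissue.  The boosted truth set is recorded for recovery tests.
#'
#' @param config a [sim_config()]; requires `n_tissues >= 2` (the
#'   tissue-specificity score needs a median over several tissues).
#' @return A [tissue_atlas()] whose `"boosted"` attribute holds the truth
#'   set and `"target_tissue"` the boosted tissue.
#' @export
simulate_tissue_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tissues < 2)
    stop("atlas needs at least 2 tissues (across-tissue median undefined)")
  set.seed(config$seed + 2L)
  g <- config$n_genes
  gene_ids <- pad_id("G", seq_len(g), g)
  tissues <- paste0("T", seq_len(config$n_tissues))
  vals <- matrix(rnorm(g * config$n_tissues, 0, 0.5), g, config$n_tissues,
                 dimnames = list(gene_ids, tissues))
  vals <- vals + rnorm(g, mean = 6, sd = 1)  # per-gene baseline, recycled by column
  boosted <- sort(sample(gene_ids, config$n_tissue_specific))
  vals[boosted, 1L] <- vals[boosted, 1L] + config$tissue_boost
  a <- tissue_atlas(vals)
  attr(a, "boosted") <- boosted
  attr(a, "target_tissue") <- tissues[1L]
  a
}

#' Simulate phenotypes from the linear model
#'
#' Phenotypes follow `y = mu + X_s beta_s + X_g beta_g + e` with Gaussian
#' residuals.  Under the dense architecture every marker effect is Gaussian;
#' under the sparse architecture only `n_causal_*` markers have (large)
#' nonzero effects.  Effects are rescaled so the realized variance of each
#' block contribution equals the configured fraction of a unit total
#' variance; the residual variance is `1 - var_frac_snp - var_frac_expr`.
#'
#' @param genotypes a [geno_matrix()] (missing entries are mean-imputed for
#'   the purpose of computing breeding values).
#' @param expression an [expr_matrix()] sharing the genotype samples;
#'   standardized internally if no standardized view is present.
#' @param config a [sim_config()].
#' @return A list with `phenotype` (data.frame: sample, family, trait,
#'   value) and `truth` (true effect vectors, causal index sets, realized
#'   variance fractions).
#' @export
simulate_phenotype <- function(genotypes, expression, config) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "geno_matrix"),
            inherits(expression, "expr_matrix"))
  if (!identical(rownames(genotypes$dosage), rownames(expression$raw)))
    stop("genotype and expression matrices must share sample IDs (same order)")
  set.seed(config$seed + 3L)

  Xs <- genotypes$dosage
  if (anyNA(Xs)) {
    cm <- colMeans(Xs, na.rm = TRUE)
    idx <- which(is.na(Xs), arr.ind = TRUE)
    Xs[idx] <- cm[idx[, 2]]
  }
  Xg <- if (is.null(expression$std)) {
    standardize_expression(expression)$std
  } else {
    expression$std
  }
  n <- nrow(Xs)

  draw_effects <- function(p, frac, n_causal) {
    if (frac == 0) return(list(beta = numeric(p), causal = integer(0)))
    if (config$architecture == "dense") {
      beta <- rnorm(p)
      causal <- seq_len(p)
    } else {
      causal <- sort(sample.int(p, min(n_causal, p)))
      beta <- numeric(p)
      beta[causal] <- rnorm(length(causal))
    }
    list(beta = beta, causal = causal)
  }

  es <- draw_effects(ncol(Xs), config$var_frac_snp, config$n_causal_snps)
  eg <- draw_effects(ncol(Xg), config$var_frac_expr, config$n_causal_genes)

  scale_to <- function(X, beta, frac) {
    g <- as.numeric(X %*% beta)
    v <- var(g)
    if (frac > 0 && v > 0) {
      beta <- beta * sqrt(frac / v)
      g <- g * sqrt(frac / v)
    }
    list(beta = beta, g = g)
  }
  ss <- scale_to(Xs, es$beta, config$var_frac_snp)
  sg <- scale_to(Xg, eg$beta, config$var_frac_expr)

  resid_var <- 1 - config$var_frac_snp - config$var_frac_expr
  e <- rnorm(n, 0, sqrt(resid_var))
  y <- ss$g + sg$g + e

  truth <- list(
    beta_snp = setNames(ss$beta, colnames(Xs)),
    beta_expr = setNames(sg$beta, colnames(Xg)),
    causal_snps = colnames(Xs)[es$causal],
    causal_genes = colnames(Xg)[eg$causal],
    realized_frac_snp = var(ss$g) / var(y),
    realized_frac_expr = var(sg$g) / var(y)
  )
  phen <- data.frame(sample = rownames(Xs),
                     family = unname(genotypes$family[rownames(Xs)]),
                     trait = "sim_trait",
                     value = y,
                     stringsAsFactors = FALSE)
  list(phenotype = phen, truth = truth)
}
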