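test_that("population simulation is deterministic and respects missingness", {
  cfg <- sim_config(n_families = 8, sibs_per_family = 3, n_snps = 30, seed = 5,
                    n_genes = 10, missing_rate = 0)
  g1 <- simulate_population(cfg)
  g2 <- simulate_population(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$family, g2$family)
  expect_true(all(snp_call_rate(g1) == 1))

  cfg2 <- sim_config(n_families = 20, sibs_per_family = 5, n_snps = 200,
                     n_genes = 10, missing_rate = 0.1, seed = 5)
  g3 <- simulate_population(cfg2)
  miss <- mean(is.na(g3$dosage))
  expect_gt(miss, 0.07)
  expect_lt(miss, 0.13)
})

test_that("genotypes follow binomial sampling at the founder frequency", {
  # at founder frequency ~0.5 and n = 10,000 the per-SNP mean genotype must
  # match 2 * freq within binomial error
  cfg <- sim_config(n_families = 2000, sibs_per_family = 5, n_snps = 40,
                    founder_maf_range = c(0.5, 0.5), n_genes = 5, seed = 2)
  g <- simulate_population(cfg)
  n <- nrow(g$dosage)
  means <- colMeans(g$dosage)
  # sibs are correlated; bound the SE by the family-level binomial error
  se <- sqrt(2 * 0.5 * 0.5 / cfg$n_families)
  expect_true(all(abs(means - 1) < 4 * se))
  expect_true(all(abs(snp_maf(g) - 0.5) < 4 * se))
})

test_that("offspring are Mendel-consistent with their sampled parents", {
  cfg <- sim_config(n_families = 10, sibs_per_family = 4, n_snps = 50,
                    n_genes = 5, seed = 3, missing_rate = 0)
  g <- simulate_population(cfg)
  par <- attr(g, "parents")
  allowed <- function(gp) if (gp == 0) 0 else if (gp == 2) 1 else c(0, 1)
  for (s in rownames(g$dosage)) {
    f <- g$family[[s]]
    for (j in seq_len(ncol(g$dosage))) {
      sums <- outer(allowed(par$mother[f, j]), allowed(par$father[f, j]), `+`)
      expect_true(g$dosage[s, j] %in% sums)
    }
  }
})

test_that("expression carries the configured family variance component", {
  # no family component: ANOVA p-values are uniform
  cfg0 <- sim_config(n_families = 30, sibs_per_family = 4, n_snps = 10,
                     n_genes = 2000, family_var_fraction_expr = 0, seed = 7)
  g <- simulate_population(cfg0)
  e <- simulate_expression(g, cfg0)
  p0 <- anova_family_pvalues(e, g$family)
  expect_gt(stats::ks.test(p0, "punif")$p.value, 0.01)

  # strong family component: p-values pile up near 0
  cfg5 <- sim_config(n_families = 30, sibs_per_family = 4, n_snps = 10,
                     n_genes = 500, family_var_fraction_expr = 0.5, seed = 7)
  e5 <- simulate_expression(g, cfg5)
  p5 <- anova_family_pvalues(e5, g$family)
  expect_lt(median(p5), 0.01)
})

test_that("per-gene raw-scale dispersion comes from the scale factors", {
  s <- small_sim(seed = 9)
  sf <- attr(s$expr, "scale_factors")
  sds <- apply(s$expr$raw, 2, sd)
  expect_gt(cor(sds, sf), 0.95)
  # undoing the scale factors recovers the homoscedastic limit: unit-scale
  # SDs are approximately equal across genes
  unit_sds <- sds / sf
  expect_lt(sd(unit_sds) / mean(unit_sds), 0.25)
})

test_that("tissue atlas boosts the designated truth set", {
  cfg <- sim_config(n_families = 5, sibs_per_family = 2, n_snps = 5,
                    n_genes = 2000, n_tissues = 8, n_tissue_specific = 100,
                    tissue_boost = 6, seed = 4)
  a <- simulate_tissue_atlas(cfg)
  sc <- tissue_specificity_scores(a, attr(a, "target_tissue"))
  top <- select_ts(sc, 100)$genes
  expect_setequal(top, attr(a, "boosted"))

  cfg0 <- sim_config(n_families = 5, sibs_per_family = 2, n_snps = 5,
                     n_genes = 1000, n_tissues = 8, tissue_boost = 0, seed = 4)
  a0 <- simulate_tissue_atlas(cfg0)
  sc0 <- tissue_specificity_scores(a0, "T1")
  expect_lt(abs(mean(sc0)), 0.1)  # no systematic specificity without a boost

  expect_error(simulate_tissue_atlas(
    sim_config(n_tissues = 1, n_genes = 10, n_snps = 5, n_tissue_specific = 1)),
    "2 tissues")
})

test_that("phenotypes realize the configured variance fractions", {
  # pure-noise phenotype
  s <- small_sim(seed = 11, var_frac_snp = 0, var_frac_expr = 0)
  ph0 <- simulate_phenotype(s$geno, s$expr, s$cfg)
  expect_true(all(ph0$truth$beta_snp == 0))
  expect_true(all(ph0$truth$beta_expr == 0))
  expect_equal(ph0$truth$realized_frac_snp, 0)

  # large-sample check of the realized fraction
  cfg <- sim_config(n_families = 2000, sibs_per_family = 5, n_snps = 150,
                    n_genes = 60, var_frac_snp = 0.5, var_frac_expr = 0,
                    seed = 13)
  g <- simulate_population(cfg)
  e <- simulate_expression(g, cfg)
  ph <- simulate_phenotype(g, e, cfg)
  expect_lt(abs(ph$truth$realized_frac_snp - 0.5), 0.02)

  # sparse architecture: exactly n_causal nonzero SNP effects
  s2 <- small_sim(seed = 15, architecture = "sparse", n_causal_snps = 10,
                  n_causal_genes = 3)
  ph2 <- simulate_phenotype(s2$geno, s2$expr, s2$cfg)
  expect_identical(sum(ph2$truth$beta_snp != 0), 10L)
  expect_identical(length(ph2$truth$causal_snps), 10L)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_families = 0))
  expect_error(sim_config(n_snps = 0))
  expect_error(sim_config(var_frac_snp = 0.6, var_frac_expr = 0.5))
  expect_error(sim_config(founder_maf_range = c(0, 0.5)))
})

test_that("datasets round-trip through the TSV/JSON formats", {
  s <- small_sim(seed = 17)
  ph <- simulate_phenotype(s$geno, s$expr, s$cfg)
  dir <- withr::local_tempdir()
  write_dataset(dir, s$geno, s$expr, atlas = simulate_tissue_atlas(s$cfg),
                phenotype = ph$phenotype, truth = ph$truth, config = s$cfg)
  m <- read_matrix_tsv(file.path(dir, "genotypes.tsv"))
  expect_equal(m, s$geno$dosage)
  fam <- read_family_tsv(file.path(dir, "families.tsv"))
  expect_identical(fam, s$geno$family)
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_true(file.exists(file.path(dir, "sim_config.yaml")))
})
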