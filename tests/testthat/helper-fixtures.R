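# In-code fixtures shared across test files.

# tiny genotype matrix with explicit entries and a trivial family map
toy_geno <- function(dosage, families = NULL) {
  n <- nrow(dosage)
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("s", seq_len(n))
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("snp", seq_len(ncol(dosage)))
  if (is.null(families)) families <- rep(c("famA", "famB"), length.out = n)
  geno_matrix(dosage, setNames(families, rownames(dosage)))
}

toy_expr <- function(values) {
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("g", seq_len(ncol(values)))
  expr_matrix(values)
}

# a small simulated dataset used by several files
small_sim <- function(seed = 1, ...) {
  args <- utils::modifyList(list(n_families = 12, sibs_per_family = 4,
                                 n_snps = 60, n_genes = 40, seed = seed),
                            list(...))
  cfg <- do.call(sim_config, args)
  g <- simulate_population(cfg)
  e <- simulate_expression(g, cfg)
  list(cfg = cfg, geno = g, expr = e)
}

# effective sample size from the initial positive sequence of autocorrelations;
# used to put Monte-Carlo standard errors on posterior means
ess <- function(x) {
  m <- length(x)
  if (sd(x) == 0) return(m)
  rho <- acf(x, lag.max = min(100, m - 1), plot = FALSE)$acf[-1]
  pos <- which(rho < 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1)]
  max(1, m / (1 + 2 * sum(rho)))
}

mc_se <- function(x) sd(x) / sqrt(ess(x))
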