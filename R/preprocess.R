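#' SNP quality control
#'
#' Retains exactly the SNPs whose minor allele frequency (computed on
#' non-missing entries) is at least `maf_min` AND whose call rate is at
#' least `call_rate_min`; column order is preserved.  The defaults are the
#' conventional thresholds for outbred-population panels (MAF >= 0.05,
#' call rate >= 0.90).
#'
#' @param genotypes a [geno_matrix()].
#' @param maf_min minimum minor allele frequency.
#' @param call_rate_min minimum call rate.
#' @return A filtered [geno_matrix()] with a `"qc"` attribute recording the
#'   number of SNPs dropped by each predicate.
#' @export
filter_snps <- function(genotypes, maf_min = 0.05, call_rate_min = 0.90) {
  stopifnot(inherits(genotypes, "geno_matrix"),
            maf_min >= 0, maf_min <= 0.5, call_rate_min >= 0, call_rate_min <= 1)
  maf <- snp_maf(genotypes)
  cr <- snp_call_rate(genotypes)
  maf_ok <- !is.na(maf) & maf >= maf_min
  cr_ok <- cr >= call_rate_min
  keep <- maf_ok & cr_ok
  if (!any(keep)) warning("no SNP passed QC")
  out <- geno_matrix(genotypes$dosage[, keep, drop = FALSE],
                     genotypes$family, imputed = genotypes$imputed)
  attr(out, "qc") <- list(n_input = length(keep),
                          n_kept = sum(keep),
                          n_failed_maf = sum(!maf_ok),
                          n_failed_call_rate = sum(!cr_ok),
                          maf_min = maf_min, call_rate_min = call_rate_min)
  out
}

#' Mean-dosage imputation of missing genotypes
#'
#' Replaces every missing call by the per-SNP mean of the non-missing
#' entries (a real-valued dosage), the standard choice in whole-genome
#' regression because it is unbiased for the column mean.
#'
#' @param genotypes a [geno_matrix()]; SNPs with all entries missing cannot
#'   be imputed and raise an error (run [filter_snps()] first).
#' @return A [geno_matrix()] with `imputed = TRUE`.
#' @export
impute_missing <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosage
  if (!anyNA(d)) return(geno_matrix(d, genotypes$family, imputed = TRUE))
  n_miss <- colSums(is.na(d))
  if (any(n_miss == nrow(d)))
    stop("cannot impute SNPs with all entries missing: ",
         paste(head(colnames(d)[n_miss == nrow(d)]), collapse = ", "))
  cm <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- cm[idx[, 2]]
  geno_matrix(d, genotypes$family, imputed = TRUE)
}

#' Collapse multiple probes per gene (highest-minimal rule)
#'
#' Microarray chips often carry several probes for the same gene.  For each
#' gene the single probe whose minimum expression across samples is largest
#' is retained (the probe least affected by floor-level signal); ties are
#' broken toward the lexicographically smallest probe ID.  Probes with no
#' gene mapping are dropped with a message.
#'
#' @param expression an [expr_matrix()] whose columns are probes.
#' @param probe_to_gene_map data.frame with columns `probe`, `gene`; every
#'   probe maps to at most one gene.
#' @return An [expr_matrix()] with one column per mapped gene (columns named
#'   by gene, ordered by gene ID); any standardized view is discarded since
#'   standardization should follow deduplication.
#' @export
deduplicate_probes <- function(expression, probe_to_gene_map) {
  stopifnot(inherits(expression, "expr_matrix"),
            is.data.frame(probe_to_gene_map),
            all(c("probe", "gene") %in% names(probe_to_gene_map)))
  map <- probe_to_gene_map
  if (anyDuplicated(map$probe))
    stop("every probe must map to at most one gene")
  probes <- colnames(expression$raw)
  unmapped <- setdiff(probes, map$probe)
  if (length(unmapped))
    message(length(unmapped), " unmapped probe(s) dropped")
  map <- map[map$probe %in% probes, , drop = FALSE]
  if (!nrow(map)) stop("no probe in the expression matrix is mapped")

  col_min <- apply(expression$raw[, map$probe, drop = FALSE], 2, min)
  # order so that within each gene the best probe (largest minimum, then
  # smallest probe ID) comes first, then take the first per gene
  ord <- order(map$gene, -col_min, map$probe)
  map <- map[ord, , drop = FALSE]
  chosen <- map[!duplicated(map$gene), , drop = FALSE]
  chosen <- chosen[order(chosen$gene), , drop = FALSE]

  raw <- expression$raw[, chosen$probe, drop = FALSE]
  colnames(raw) <- chosen$gene
  out <- expr_matrix(raw, probe_map = chosen[, c("probe", "gene")])
  out
}

#' Standardize expression to mean 0, variance 1
#'
#' Centers and scales each gene by its sample standard deviation (n - 1
#' denominator).  The raw view is preserved alongside the standardized view;
#' constant genes are set to all-zero and flagged rather than dropped so
#' matrix shapes stay stable across cross-validation folds.
#'
#' @param expression an [expr_matrix()] with at least 2 samples.
#' @return The [expr_matrix()] with its `std` view filled in; names of
#'   constant genes are recorded in the `"constant_genes"` attribute.
#' @export
standardize_expression <- function(expression) {
  stopifnot(inherits(expression, "expr_matrix"), nrow(expression$raw) >= 2)
  raw <- expression$raw
  mu <- colMeans(raw)
  s <- apply(raw, 2, sd)
  constant <- s == 0 | !is.finite(s)
  s[constant] <- 1  # avoid 0/0; those columns become all-zero anyway
  std <- sweep(sweep(raw, 2, mu, `-`), 2, s, `/`)
  std[, constant] <- 0
  out <- expr_matrix(raw, std = std, probe_map = expression$probe_map)
  attr(out, "constant_genes") <- colnames(raw)[constant]
  out
}
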