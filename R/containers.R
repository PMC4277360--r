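#' Genotype matrix container
#'
#' Samples x SNPs minor-allele counts (0/1/2; `NA` = missing call) together
#' with the sample -> full-sib-family map.  Per-SNP minor allele frequency
#' and call rate are computed on demand from the non-missing entries.
#'
#' @param dosage numeric matrix, samples in rows (rownames = sample IDs),
#'   SNPs in columns (colnames = SNP IDs); entries in \{0, 1, 2, NA\} unless
#'   the matrix has been imputed (then real-valued dosages are allowed).
#' @param family named character vector mapping every sample ID to a family.
#' @param imputed logical; `TRUE` once missing entries have been replaced by
#'   mean dosages.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, family, imputed = FALSE) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)))
  if (!all(rownames(dosage) %in% names(family)))
    stop("family map must cover all samples")
  ok <- is.na(dosage) | (dosage >= 0 & dosage <= 2)
  if (!all(ok)) stop("genotype entries must lie in [0, 2] or be missing")
  if (!imputed && !all(is.na(dosage) | dosage %in% c(0, 1, 2)))
    stop("non-imputed genotype entries must be 0, 1, 2 or missing")
  structure(list(dosage = dosage,
                 family = family[rownames(dosage)],
                 imputed = imputed),
            class = "geno_matrix")
}

#' @describeIn geno_matrix per-SNP minor allele frequency (non-missing
#'   entries only; an all-missing SNP gives `NA`).
#' @param x a `geno_matrix`.
#' @export
snp_maf <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  p_hat <- colMeans(x$dosage, na.rm = TRUE) / 2
  pmin(p_hat, 1 - p_hat)
}

#' @describeIn geno_matrix per-SNP call rate (fraction of non-missing
#'   entries).
#' @export
snp_call_rate <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  colMeans(!is.na(x$dosage))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d SNPs, %d families%s\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$family)),
              if (x$imputed) " (imputed)" else ""))
  invisible(x)
}

#' Expression matrix container
#'
#' Samples x genes (or probes) expression values, carrying the raw-scale
#' view and, after [standardize_expression()], a standardized view in which
#' every gene has mean 0 and variance 1.
#'
#' @param raw numeric matrix, samples in rows, genes/probes in columns, with
#'   dimnames.
#' @param std optional standardized matrix of the same shape.
#' @param probe_map optional data.frame with columns `probe`, `gene`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(raw, std = NULL, probe_map = NULL) {
  stopifnot(is.matrix(raw), !is.null(rownames(raw)), !is.null(colnames(raw)))
  if (!is.null(std)) stopifnot(identical(dim(std), dim(raw)))
  if (!is.null(probe_map))
    stopifnot(is.data.frame(probe_map), all(c("probe", "gene") %in% names(probe_map)))
  structure(list(raw = raw, std = std, probe_map = probe_map),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d samples x %d genes%s\n",
              nrow(x$raw), ncol(x$raw),
              if (is.null(x$std)) " (raw only)" else " (raw + standardized)"))
  invisible(x)
}

#' Tissue atlas container
#'
#' Genes x tissues reference expression (log scale) used only by the
#' tissue-specificity gene-selection criterion.
#'
#' @param values numeric matrix, genes in rows, tissues in columns, with
#'   dimnames; at least two tissues are required and every gene must have a
#'   value in every tissue.
#' @return An object of class `tissue_atlas`.
#' @export
tissue_atlas <- function(values) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (ncol(values) < 2)
    stop("a tissue atlas needs at least 2 tissues")
  if (anyNA(values))
    stop("every gene must have a value in every tissue")
  structure(list(values = values), class = "tissue_atlas")
}

#' @export
print.tissue_atlas <- function(x, ...) {
  cat(sprintf("tissue_atlas: %d genes x %d tissues\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
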