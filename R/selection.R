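#' Among-family one-way ANOVA p-values per gene
#'
#' For every gene, a one-way analysis of variance of (standardized)
#' expression on the full-sib family factor: F = MS(between families) /
#' MS(within families) with (G - 1, n - G) degrees of freedom for G
#' families, upper-tail p-value.  A small p-value indicates a hereditary
#' component in that gene's expression.  Implemented with vectorized sums
#' of squares so thousands of genes are handled at once; per-gene F
#' statistics are scale-invariant, so raw or standardized input gives
#' identical p-values.
#'
#' @param expression an [expr_matrix()] (standardized view used when
#'   present, else raw) or a plain samples x genes matrix.
#' @param family named character vector mapping sample IDs to families.
#' @param samples optional character vector restricting the computation to
#'   a sample subset (used inside cross-validation so test data never
#'   influence the selection).
#' @return Named numeric vector of p-values, one per gene; a gene with zero
#'   total variance returns p = 1.
#' @export
anova_family_pvalues <- function(expression, family, samples = NULL) {
  m <- if (inherits(expression, "expr_matrix")) {
    if (is.null(expression$std)) expression$raw else expression$std
  } else {
    stopifnot(is.matrix(expression))
    expression
  }
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  fam <- family[rownames(m)]
  if (anyNA(fam)) stop("family map must cover all samples")
  fams <- unique(fam)
  G <- length(fams)
  n <- nrow(m)
  if (G < 2) stop("need at least 2 families")
  if (n <= G) stop("need more samples than families")

  f2i <- match(fam, fams)
  ng <- tabulate(f2i, G)
  # group sums via indicator cross-product
  group_sum <- rowsum(m, f2i)                   # G x genes
  group_mean <- group_sum / ng
  grand_mean <- colMeans(m)
  ss_between <- colSums(ng * (group_mean - rep(grand_mean, each = G))^2)
  ss_total <- colSums(sweep(m, 2, grand_mean, `-`)^2)
  ss_within <- pmax(ss_total - ss_between, 0)

  fstat <- (ss_between / (G - 1)) / (ss_within / (n - G))
  p <- pf(fstat, G - 1, n - G, lower.tail = FALSE)
  p[ss_total < .Machine$double.eps * n] <- 1   # constant gene: no evidence
  setNames(p, colnames(m))
}

new_selection_result <- function(criterion, ids, scores, k) {
  structure(list(criterion = criterion,
                 genes = ids,
                 scores = scores,
                 k = k),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: %d genes (k = %d)\n",
              x$criterion, length(x$genes), x$k))
  invisible(x)
}

take_top <- function(scores, k, decreasing, criterion) {
  n <- length(scores)
  if (k > n) warning("k exceeds the number of genes; returning all genes")
  kk <- min(k, n)
  ids <- names(scores)
  ord <- if (decreasing) order(-scores, ids) else order(scores, ids)
  sel <- ord[seq_len(kk)]
  new_selection_result(criterion, ids[sel], unname(scores[sel]), as.integer(k))
}

#' Select genes by significance level of the among-family variance
#'
#' Ranks genes by their one-way family-ANOVA p-value and returns the k most
#' significant (`direction = "higher"`, highest significance = smallest
#' p-values) or the k least significant (`direction = "lower"`).  Ties are
#' broken by gene ID for reproducibility.
#'
#' @param pvalues named p-value vector from [anova_family_pvalues()].
#' @param k number of genes to select.
#' @param direction `"higher"` or `"lower"` significance.
#' @return A `selection_result`.
#' @export
select_sl <- function(pvalues, k = 3000, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  stopifnot(all(pvalues >= 0 & pvalues <= 1), !is.null(names(pvalues)))
  take_top(pvalues, k, decreasing = (direction == "lower"),
           criterion = paste0("SL_", direction))
}

#' Tissue-specificity scores from a reference atlas
#'
#' For gene j the score is `e[target, j] - m_j`, where `m_j` is the median
#' of that gene's expression over all tissues in the atlas (target
#' included).  On the atlas's log scale this difference is a log-ratio of
#' target expression to the typical tissue; large positive scores mark
#' genes preferentially expressed in the target tissue.
#'
#' @param atlas a [tissue_atlas()].
#' @param target_tissue tissue (column) name.
#' @return Named numeric score vector, one per gene.
#' @export
tissue_specificity_scores <- function(atlas, target_tissue) {
  stopifnot(inherits(atlas, "tissue_atlas"))
  v <- atlas$values
  if (!target_tissue %in% colnames(v))
    stop("unknown tissue: ", target_tissue)
  m <- apply(v, 1, median)
  setNames(v[, target_tissue] - m, rownames(v))
}

#' Select genes by tissue specificity
#'
#' Returns the k genes with the largest tissue-specificity score (ties by
#' gene ID).  This criterion uses the external atlas only, so it does not
#' depend on the training/test split.
#'
#' @param scores named scores from [tissue_specificity_scores()].
#' @param k number of genes to select.
#' @return A `selection_result`.
#' @export
select_ts <- function(scores, k = 3000) {
  stopifnot(!is.null(names(scores)))
  if (k == 0)
    return(new_selection_result("TS_higher", character(0), numeric(0), 0L))
  take_top(scores, k, decreasing = TRUE, criterion = "TS_higher")
}

#' Select genes by raw-scale standard deviation
#'
#' Ranks genes by the sample standard deviation of their expression on the
#' original (pre-standardization) scale, descending, and returns the top k.
#' Standardized-only input is rejected: after standardization every SD is 1
#' and the ranking would be meaningless.
#'
#' @param expression an [expr_matrix()] with a raw view.
#' @param k number of genes to select.
#' @param samples optional sample subset (training rows only inside CV).
#' @return A `selection_result`.
#' @export
select_sd <- function(expression, k = 3000, samples = NULL) {
  stopifnot(inherits(expression, "expr_matrix"))
  if (is.null(expression$raw))
    stop("SD selection requires the raw-scale expression view")
  m <- expression$raw
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  sds <- apply(m, 2, sd)
  take_top(setNames(sds, colnames(m)), k, decreasing = TRUE,
           criterion = "SD_higher")
}
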