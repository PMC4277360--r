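#' Read and write the package's delimited-text formats
#'
#' Matrices travel as tab-separated files with samples (or genes, for the
#' atlas) in rows and a header row of marker/gene/tissue IDs; the sample ->
#' family map as a two-column TSV; truth records, QC reports and fit
#' summaries as JSON.
#'
#' @param x matrix to write.
#' @param path file path.
#' @name omicpred-io
NULL

#' @rdname omicpred-io
#' @export
write_matrix_tsv <- function(x, path) {
  stopifnot(is.matrix(x))
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname omicpred-io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname omicpred-io
#' @param family named character vector (sample -> family).
#' @export
write_family_tsv <- function(family, path) {
  write.table(data.frame(sample = names(family), family = unname(family)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname omicpred-io
#' @export
read_family_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  setNames(as.character(df$family), df$sample)
}

#' Write a simulated dataset to a directory
#'
#' Writes genotype/expression/atlas/phenotype matrices as TSV, the truth
#' record as JSON, and echoes the generating configuration as YAML.
#'
#' @param dir output directory (created if absent).
#' @param genotypes a [geno_matrix()].
#' @param expression an [expr_matrix()].
#' @param atlas a [tissue_atlas()] or `NULL`.
#' @param phenotype phenotype data.frame.
#' @param truth truth record list or `NULL`.
#' @param config the generating [sim_config()] or `NULL`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dir, genotypes, expression, atlas = NULL,
                          phenotype = NULL, truth = NULL, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(genotypes$dosage, file.path(dir, "genotypes.tsv"))
  write_family_tsv(genotypes$family, file.path(dir, "families.tsv"))
  write_matrix_tsv(expression$raw, file.path(dir, "expression_raw.tsv"))
  if (!is.null(expression$std))
    write_matrix_tsv(expression$std, file.path(dir, "expression_std.tsv"))
  if (!is.null(atlas))
    write_matrix_tsv(atlas$values, file.path(dir, "tissue_atlas.tsv"))
  if (!is.null(phenotype))
    write.table(phenotype, file.path(dir, "phenotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(config))
    yaml::write_yaml(unclass(config), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Write a selection result as TSV + JSON metadata
#'
#' @param sel a `selection_result`.
#' @param path TSV output path (metadata goes to `<path>.json`).
#' @export
write_selection_tsv <- function(sel, path) {
  stopifnot(inherits(sel, "selection_result"))
  write.table(data.frame(gene = sel$genes, score = sel$scores),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(criterion = sel$criterion, k = sel$k,
                            n_selected = length(sel$genes)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
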