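#' Construct an expression matrix container
#'
#' Holds a gene x sample FPKM abundance matrix, optionally with the raw count
#' matrix and gene lengths it was derived from. All values must be
#' non-negative; gene and sample identifiers must be unique.
#'
#' @param fpkm numeric matrix of FPKM values, genes in rows (rownames = gene
#'   ids), samples in columns (colnames = sample ids).
#' @param counts optional integer matrix of read counts on the same grid.
#' @param gene_lengths optional positive integer vector (bp), named by gene id.
#' @return An object of class `triad_expr`.
#' @export
expression_matrix <- function(fpkm, counts = NULL, gene_lengths = NULL) {
  fpkm <- as.matrix(fpkm)
  assert_that(is.numeric(fpkm), "fpkm must be numeric")
  assert_that(nrow(fpkm) == 0L ||
                (!is.null(rownames(fpkm)) && !anyDuplicated(rownames(fpkm))),
              "gene ids (rownames) must be present and unique")
  assert_that(!is.null(colnames(fpkm)) && !anyDuplicated(colnames(fpkm)),
              "sample ids (colnames) must be present and unique")
  if (anyNA(fpkm)) abort("fpkm contains missing values")
  if (any(fpkm < 0)) abort("negative FPKM value")
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    assert_that(identical(dim(counts), dim(fpkm)) &&
                  identical(rownames(counts), rownames(fpkm)) &&
                  identical(colnames(counts), colnames(fpkm)),
                "counts must align to the same gene x sample grid as fpkm")
    if (anyNA(counts) || any(counts < 0))
      abort("counts must be non-negative and complete")
    if (any(counts != round(counts))) abort("counts must be integers")
  }
  if (!is.null(gene_lengths)) {
    assert_that(!is.null(names(gene_lengths)) &&
                  all(rownames(fpkm) %in% names(gene_lengths)),
                "gene_lengths must be named and cover all genes")
    gene_lengths <- gene_lengths[rownames(fpkm)]
    if (any(gene_lengths <= 0)) abort("gene lengths must be positive")
  }
  structure(list(fpkm = fpkm, counts = counts, gene_lengths = gene_lengths),
            class = "triad_expr")
}

#' @export
print.triad_expr <- function(x, ...) {
  cat(sprintf("triad_expr: %d genes x %d samples (FPKM%s)\n",
              nrow(x$fpkm), ncol(x$fpkm),
              if (is.null(x$counts)) "" else " + counts"))
  invisible(x)
}

#' @export
dim.triad_expr <- function(x) dim(x$fpkm)

#' Gene identifiers of an expression matrix
#' @param x a `triad_expr`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$fpkm)

#' Subset an expression matrix by gene and/or sample
#' @param x a `triad_expr`.
#' @param genes gene ids or index vector (default all).
#' @param samples sample ids or index vector (default all).
#' @return A `triad_expr` restricted to the selection.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  genes <- genes %||% rownames(x$fpkm)
  samples <- samples %||% colnames(x$fpkm)
  expression_matrix(
    x$fpkm[genes, samples, drop = FALSE],
    counts = if (!is.null(x$counts)) x$counts[genes, samples, drop = FALSE],
    gene_lengths = if (!is.null(x$gene_lengths)) x$gene_lengths[genes])
}

#' Read an expression table from TSV
#'
#' The file must have a header row of sample ids and gene ids in the first
#' column. Cells are validated: a non-numeric cell raises a parse error naming
#' its row and column; a negative value or duplicated gene id is rejected.
#'
#' @param path path to the tab-separated expression file.
#' @return A validated [expression_matrix] (`triad_expr`).
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) abort("expression file needs a gene column plus samples")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    abort(sprintf("duplicated gene id: %s", ids[duplicated(ids)][1L]))
  vals <- vapply(names(tab)[-1L], function(cn) {
    parse_numeric_column(tab[[cn]], cn, what = "expression value")
  }, numeric(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(ids, names(tab)[-1L]))
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("negative expression value for gene '%s', sample '%s'",
                  rownames(vals)[bad[1L]], colnames(vals)[bad[2L]]))
  }
  expression_matrix(vals)
}

#' Replicate-mean expression per genotype
#'
#' Averages FPKM over the replicate samples of each genotype declared in the
#' design, yielding the gene x genotype matrix on which the FPKM filter, the
#' remodeling classifier's noise-free mode and the hub screen operate.
#'
#' @param expr a `triad_expr`.
#' @param design a [triad_design]; only genotypes with samples present in
#'   `expr` are used.
#' @return Numeric matrix, genes x genotypes.
#' @export
genotype_means <- function(expr, design) {
  assert_that(inherits(expr, "triad_expr"), "expr must be a triad_expr")
  assert_that(inherits(design, "triad_design"), "design must be a triad_design")
  genos <- design$genotypes$genotype
  keep <- vapply(genos, function(g) {
    all(design_samples(design, g) %in% colnames(expr$fpkm))
  }, logical(1L))
  genos <- genos[keep]
  if (!length(genos)) abort("no design genotype has samples in the matrix")
  out <- vapply(genos, function(g) {
    rowMeans(expr$fpkm[, design_samples(design, g), drop = FALSE])
  }, numeric(nrow(expr$fpkm)))
  matrix(out, nrow = nrow(expr$fpkm),
         dimnames = list(rownames(expr$fpkm), genos))
}
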