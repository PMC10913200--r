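# Readers and writers for the remaining pipeline tables. All tables are plain
# TSV; writers emit a "#triadex <version> <command>" provenance line which the
# readers skip. Coordinates are 1-based inclusive throughout.

#' Read a methylation site table
#'
#' BED-like TSV with columns `chrom`, `pos` (1-based), `context`, followed by
#' one reads-per-million (RPM) column per genotype. The cytosine context is
#' restricted to the two restriction-motif vocabularies assayed by
#' MethylRAD-style data, `CCGG` and `CCWGG`. Empty RPM cells are treated as 0
#' with a warning; negative RPM or an unknown context is rejected.
#'
#' @param path path to the tab-separated site file.
#' @param contexts allowed context strings.
#' @return A data.frame of class `meth_sites` with columns `site_id`, `chrom`,
#'   `pos`, `context` and one numeric RPM column per genotype; the genotype
#'   column names are stored in `attr(, "genotypes")` in file order.
#' @export
read_methylation_sites <- function(path, contexts = c("CCGG", "CCWGG")) {
  tab <- read_tsv_checked(path)
  need <- c("chrom", "pos", "context")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    abort(sprintf("methylation file lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  geno_cols <- setdiff(names(tab), c("site_id", need))
  if (!length(geno_cols)) abort("no genotype RPM columns found")
  bad_ctx <- setdiff(unique(tab$context), contexts)
  if (length(bad_ctx))
    abort(sprintf("unknown methylation context '%s' (allowed: %s)",
                  bad_ctx[1L], paste(contexts, collapse = ", ")))
  tab$pos <- parse_numeric_column(as.character(tab$pos), "pos", "position")
  if (any(tab$pos < 1 | tab$pos != round(tab$pos)))
    abort("site positions must be positive 1-based integers")
  n_empty <- 0L
  for (cn in geno_cols) {
    x <- as.character(tab[[cn]])
    empty <- is.na(x) | x == ""
    n_empty <- n_empty + sum(empty)
    x[empty] <- "0"
    v <- parse_numeric_column(x, cn, "RPM")
    if (any(v < 0))
      abort(sprintf("negative RPM in column '%s'", cn))
    tab[[cn]] <- v
  }
  if (n_empty > 0L)
    warning(sprintf("%d missing RPM cell(s) treated as 0", n_empty))
  if (!"site_id" %in% names(tab))
    tab$site_id <- paste(tab$chrom, tab$pos, sep = ":")
  if (anyDuplicated(tab$site_id))
    abort("duplicated site ids")
  out <- tab[, c("site_id", "chrom", "pos", "context", geno_cols)]
  attr(out, "genotypes") <- geno_cols
  class(out) <- c("meth_sites", "data.frame")
  out
}

#' Construct a validated methylation site table from in-memory data
#' @param tab data.frame with `site_id`, `chrom`, `pos`, `context` and genotype
#'   RPM columns.
#' @param genotypes names of the RPM columns.
#' @return A `meth_sites` data.frame.
#' @export
methylation_sites <- function(tab, genotypes) {
  assert_that(all(c("site_id", "chrom", "pos", "context") %in% names(tab)),
              "site table needs site_id, chrom, pos, context")
  assert_that(all(genotypes %in% names(tab)), "missing genotype RPM columns")
  assert_that(all(tab$context %in% c("CCGG", "CCWGG")),
              "context must be CCGG or CCWGG")
  for (g in genotypes) {
    if (any(tab[[g]] < 0)) abort("negative RPM")
  }
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  attr(out, "genotypes") <- genotypes
  class(out) <- c("meth_sites", "data.frame")
  out
}

#' Read gene models from a BED/GFF-lite TSV
#'
#' Columns `gene`, `chrom`, `start`, `end`, `strand` with 1-based inclusive
#' coordinates and strand `+`/`-`.
#'
#' @param path path to the tab-separated gene model file.
#' @return data.frame with the five validated columns.
#' @export
read_gene_models <- function(path) {
  tab <- read_tsv_checked(path)
  need <- c("gene", "chrom", "start", "end", "strand")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    abort(sprintf("gene model file lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  tab$start <- parse_numeric_column(as.character(tab$start), "start", "coordinate")
  tab$end <- parse_numeric_column(as.character(tab$end), "end", "coordinate")
  validate_gene_models(tab[, need])
}

#' @noRd
validate_gene_models <- function(tab) {
  assert_that(!anyDuplicated(tab$gene), "duplicated gene ids in gene models")
  if (any(tab$start < 1)) abort("gene start coordinates must be >= 1")
  if (any(tab$start > tab$end)) abort("gene start must be <= end")
  if (!all(tab$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  as.data.frame(tab, stringsAsFactors = FALSE)
}

#' Read a phenotype replicate table
#'
#' Long-format TSV with columns `genotype`, `trait`, `replicate`, `value`.
#' Every genotype x trait cell must carry at least three biological
#' replicates.
#'
#' @param path path to the tab-separated phenotype file.
#' @param min_replicates minimum replicates per genotype x trait (default 3).
#' @return data.frame with the four columns, `value` numeric.
#' @export
read_phenotypes <- function(path, min_replicates = 3L) {
  tab <- read_tsv_checked(path)
  need <- c("genotype", "trait", "replicate", "value")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    abort(sprintf("phenotype file lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  tab$value <- parse_numeric_column(as.character(tab$value), "value", "phenotype")
  counts <- stats::aggregate(value ~ genotype + trait, tab, length)
  few <- counts[counts$value < min_replicates, , drop = FALSE]
  if (nrow(few))
    abort(sprintf("fewer than %d replicates for %s / %s", min_replicates,
                  few$genotype[1L], few$trait[1L]))
  tab[, need]
}

#' Read a term-to-gene mapping
#'
#' Two-column TSV (`term`, `gene`); an optional `name` column carries a
#' human-readable term label. The mapping is taken as already propagated: no
#' ontology-graph traversal is performed.
#'
#' @param path path to the tab-separated mapping.
#' @return data.frame with columns `term`, `gene` (and `name` if present).
#' @export
read_term_map <- function(path) {
  tab <- read_tsv_checked(path)
  missing <- setdiff(c("term", "gene"), names(tab))
  if (length(missing))
    abort(sprintf("term map lacks column(s): %s", paste(missing, collapse = ", ")))
  tab
}

#' Write result tables as provenance-stamped TSV files
#'
#' Each table is written to `<out_dir>/<name>.tsv` with a provenance header
#' line, deterministic column order (as given) and rows sorted by the first
#' column whose name contains "gene" or "site" (stable sort; other tables keep
#' their row order). Writing then re-reading with [read_result_table] round
#' trips the content.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @param command provenance command string recorded in the header.
#' @param seed optional seed recorded in the header.
#' @return Invisibly, the named vector of written paths.
#' @export
write_results <- function(tables, out_dir, command = "write_results",
                          seed = NULL) {
  assert_that(is.list(tables) && !is.null(names(tables)) &&
                all(nzchar(names(tables))), "tables must be a named list")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  paths <- character(0L)
  for (name in names(tables)) {
    tab <- as.data.frame(tables[[name]], stringsAsFactors = FALSE)
    key <- grep("gene|site", names(tab), value = TRUE)
    if (length(key) && nrow(tab))
      tab <- tab[order(tab[[key[1L]]], method = "radix"), , drop = FALSE]
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, open = "wt")
    on.exit(close(con), add = TRUE)
    writeLines(provenance_line(command, seed), con)
    num <- vapply(tab, is.double, logical(1L))
    tab[num] <- lapply(tab[num], function(x) {
      ifelse(is.na(x), "NA", formatC(x, digits = 15, format = "g"))
    })
    suppressWarnings(utils::write.table(tab, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE, na = "NA"))
    close(con)
    on.exit()
    paths[name] <- path
  }
  invisible(paths)
}

#' Read back a table written by [write_results]
#' @param path path to the TSV file.
#' @return data.frame with the table content (provenance line skipped).
#' @export
read_result_table <- function(path) {
  read_tsv_checked(path)
}

#' Serialize a gene-set ledger to membership and overlap-statistic tables
#' @param ledger a [gene_set_ledger].
#' @return Named list with data.frames `membership` (columns set, gene) and
#'   `overlaps` (if any overlap statistics are recorded).
#' @export
ledger_tables <- function(ledger) {
  assert_that(inherits(ledger, "gene_set_ledger"), "not a gene_set_ledger")
  membership <- do.call(rbind, lapply(names(ledger$sets), function(nm) {
    genes <- ledger$sets[[nm]]
    if (!length(genes)) return(NULL)
    data.frame(set = nm, gene = genes, stringsAsFactors = FALSE)
  }))
  membership <- membership %||%
    data.frame(set = character(0L), gene = character(0L))
  out <- list(membership = membership)
  if (!is.null(ledger$overlaps) && nrow(ledger$overlaps))
    out$overlaps <- ledger$overlaps
  out
}
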