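# Decomposition of differential expression into inheritance gene sets:
#   PEGs    genes DE between the two parents of a combination
#   DEGs    hybrid vs single parent
#   copDEGs genes DE versus both parents of the hybrid (direction recorded)
#   HEGs    genes DE between two hybrids
#   H&P     HEGs intersect PEGs
#   DIGs    differentially inherited genes: the two hybrids differ from each
#           other while each matches (is ns versus) exactly one parent, and
#           those matched parents differ; the matched parent is the gene's
#           inheritance origin for that hybrid.

#' @noRd
sig_genes <- function(call) call$gene[call$direction != "ns"]

new_ledger <- function() {
  structure(list(sets = list(), provenance = character(0L),
                 directions = list(), digs = list(),
                 overlaps = NULL),
            class = "gene_set_ledger")
}

add_set <- function(ledger, name, genes, provenance) {
  ledger$sets[[name]] <- unique(genes)
  ledger$provenance[name] <- provenance
  ledger
}

#' @export
print.gene_set_ledger <- function(x, ...) {
  cat(sprintf("gene_set_ledger: %d sets\n", length(x$sets)))
  for (nm in names(x$sets))
    cat(sprintf("  %-20s %6d genes   [%s]\n", nm, length(x$sets[[nm]]),
                x$provenance[nm]))
  invisible(x)
}

#' Build the DEG inheritance-set ledger
#'
#' From pairwise DE calls, assembles per crossing combination: the parental
#' DEGs (PEGs), each hybrid's DEGs versus each parent, the common DEGs versus
#' both parents (copDEGs, with up/down/mixed direction), the DEGs between the
#' reciprocal hybrids (HEGs), their intersection with PEGs (H&P), and the
#' differentially inherited genes (DIGs) with per-hybrid parental origin.
#'
#' @param de_calls named list of `de_calls` tables (as from [de_all_pairs]);
#'   a missing required comparison raises an error naming it.
#' @param design a [triad_design].
#' @return A `gene_set_ledger`: list with `sets` (name -> gene vector),
#'   `provenance`, `directions` (copDEG direction tables) and `digs`
#'   (DIG origin tables per hybrid pair).
#' @export
build_deg_ledger <- function(de_calls, design) {
  ledger <- new_ledger()
  cb <- design$combinations
  for (key in unique(cb$combination)) {
    rows <- cb[cb$combination == key, ]
    pa <- rows$parent_a[1L]; pb <- rows$parent_b[1L]
    peg_call <- get_call(de_calls, pa, pb)
    peg_name <- paste0("PEG.", key)
    ledger <- add_set(ledger, peg_name, sig_genes(peg_call),
                      sprintf("%s vs %s", pa, pb))
    for (i in seq_len(nrow(rows))) {
      h <- rows$hybrid[i]
      ca <- get_call(de_calls, h, pa)
      cb2 <- get_call(de_calls, h, pb)
      ledger <- add_set(ledger, sprintf("DEG.%s.vs.%s", h, pa), sig_genes(ca),
                        sprintf("%s vs %s", h, pa))
      ledger <- add_set(ledger, sprintf("DEG.%s.vs.%s", h, pb), sig_genes(cb2),
                        sprintf("%s vs %s", h, pb))
      both <- intersect(sig_genes(ca), sig_genes(cb2))
      dir_a <- ca$direction[match(both, ca$gene)]
      dir_b <- cb2$direction[match(both, cb2$gene)]
      direction <- ifelse(dir_a == dir_b, dir_a, "mixed")
      ledger <- add_set(ledger, paste0("copDEG.", h), both,
                        sprintf("DE vs both %s and %s", pa, pb))
      ledger$directions[[paste0("copDEG.", h)]] <-
        data.frame(gene = both, direction = direction, stringsAsFactors = FALSE)
    }
    if (nrow(rows) == 2L) {
      hx <- rows$hybrid[1L]; hy <- rows$hybrid[2L]
      heg <- sig_genes(get_call(de_calls, hx, hy))
      heg_name <- sprintf("HEG.%s.%s", hx, hy)
      ledger <- add_set(ledger, heg_name, heg, sprintf("%s vs %s", hx, hy))
      ledger <- add_set(ledger, sprintf("HP.%s.%s", hx, hy),
                        intersect(heg, ledger$sets[[peg_name]]),
                        sprintf("HEG(%s,%s) intersect %s", hx, hy, peg_name))
      digs <- detect_digs(de_calls, design, hx, hy)
      ledger <- add_set(ledger, sprintf("DIG.%s.%s", hx, hy), digs$gene,
                        sprintf("differential inheritance %s vs %s", hx, hy))
      ledger$digs[[sprintf("DIG.%s.%s", hx, hy)]] <- digs
    }
  }
  ledger
}

#' Detect differentially inherited genes between two hybrids
#'
#' A gene is a DIG when (i) it is DE between the two hybrids, (ii) each hybrid
#' is non-significant versus exactly one of its own parents, and (iii) the two
#' matched parents differ. The matched parent is recorded as each hybrid's
#' inheritance origin.
#'
#' @param de_calls named list of `de_calls` tables; must contain the
#'   hybrid-hybrid comparison and each hybrid versus each of its parents.
#' @param design a [triad_design].
#' @param hybrid_x,hybrid_y hybrid genotype labels (reciprocal hybrids or
#'   hybrids of different combinations).
#' @return data.frame with columns `gene`, `origin_x`, `origin_y` (the parent
#'   genotype each hybrid inherited its expression level from).
#' @export
detect_digs <- function(de_calls, design, hybrid_x, hybrid_y) {
  hh <- get_call(de_calls, hybrid_x, hybrid_y)
  px <- canonical_parents(design, hybrid_x)
  py <- canonical_parents(design, hybrid_y)
  calls_x <- lapply(px, function(p) get_call(de_calls, hybrid_x, p))
  calls_y <- lapply(py, function(p) get_call(de_calls, hybrid_y, p))
  genes <- hh$gene
  for (cl in c(calls_x, calls_y)) {
    if (!setequal(cl$gene, genes))
      abort("DE call tables cover different gene universes")
  }
  ns_mat <- function(calls) {
    vapply(calls, function(cl) cl$direction[match(genes, cl$gene)] == "ns",
           logical(length(genes)))
  }
  ns_x <- ns_mat(calls_x)   # genes x 2 parents of hybrid_x
  ns_y <- ns_mat(calls_y)
  one_x <- rowSums(ns_x) == 1L
  one_y <- rowSums(ns_y) == 1L
  origin_x <- ifelse(ns_x[, 1L], px[[1L]], px[[2L]])
  origin_y <- ifelse(ns_y[, 1L], py[[1L]], py[[2L]])
  is_dig <- hh$direction != "ns" & one_x & one_y & origin_x != origin_y
  data.frame(gene = genes[is_dig],
             origin_x = origin_x[is_dig], origin_y = origin_y[is_dig],
             stringsAsFactors = FALSE)
}

#' Asymmetric overlap percentage between two ledger sets
#'
#' Reports 100 * |A intersect B| / |A| to two decimals; the first-named set is
#' the denominator. An empty first set yields `NA` with a warning rather
#' than 0.
#'
#' @param ledger a `gene_set_ledger`.
#' @param name_a,name_b set names in the ledger.
#' @return Percentage (numeric scalar), rounded to 2 decimals.
#' @export
overlap_fraction <- function(ledger, name_a, name_b) {
  for (nm in c(name_a, name_b)) {
    if (is.null(ledger$sets[[nm]]))
      abort(sprintf("set '%s' not in ledger", nm))
  }
  a <- ledger$sets[[name_a]]; b <- ledger$sets[[name_b]]
  if (!length(a)) {
    warning(sprintf("set '%s' is empty; overlap undefined", name_a))
    return(NA_real_)
  }
  round(100 * length(intersect(a, b)) / length(a), 2L)
}

#' Overlap statistics for a list of ordered set pairs
#' @param ledger a `gene_set_ledger`.
#' @param pairs list of length-2 character vectors of set names.
#' @return data.frame with columns `set_a`, `set_b`, `n_a`, `n_intersect`,
#'   `percent` (of `set_a`).
#' @export
overlap_stats <- function(ledger, pairs) {
  do.call(rbind, lapply(pairs, function(pr) {
    a <- ledger$sets[[pr[1L]]]; b <- ledger$sets[[pr[2L]]]
    data.frame(set_a = pr[1L], set_b = pr[2L],
               n_a = length(a), n_intersect = length(intersect(a, b)),
               percent = if (length(a))
                 round(100 * length(intersect(a, b)) / length(a), 2L)
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Maternal attribution of DIG origins
#'
#' For each hybrid of a DIG comparison, the fraction of DIGs whose inheritance
#' origin is that hybrid's maternal parent, plus a combined summary over both
#' hybrids.
#'
#' @param digs DIG origin table from [detect_digs] (columns `gene`,
#'   `origin_x`, `origin_y`).
#' @param design a [triad_design].
#' @param hybrid_x,hybrid_y the hybrids the origins refer to.
#' @return data.frame with columns `hybrid`, `n`, `maternal_fraction`
#'   (in \[0, 1\]; `NA` with a warning when there are no DIGs), ending with a
#'   `combined` row.
#' @export
maternal_attribution <- function(digs, design, hybrid_x, hybrid_y) {
  if (!all(c("origin_x", "origin_y") %in% names(digs)))
    abort("DIG table lacks origin labels")
  gh <- design$genotypes
  mat_of <- function(h) gh$maternal[gh$genotype == h]
  frac <- function(origins, h) {
    if (!length(origins)) return(NA_real_)
    mean(origins == mat_of(h))
  }
  n <- nrow(digs)
  if (n == 0L) warning("no DIGs; maternal attribution undefined")
  fx <- frac(digs$origin_x, hybrid_x)
  fy <- frac(digs$origin_y, hybrid_y)
  comb <- if (n == 0L) NA_real_ else
    mean(c(digs$origin_x == mat_of(hybrid_x),
           digs$origin_y == mat_of(hybrid_y)))
  data.frame(hybrid = c(hybrid_x, hybrid_y, "combined"),
             n = c(n, n, 2L * n),
             maternal_fraction = c(fx, fy, comb),
             stringsAsFactors = FALSE)
}
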