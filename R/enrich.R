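# Hypergeometric term enrichment with the study-wide significance filter
# (BH-adjusted p < 0.05 AND at least 5 study genes in the term), and the
# hub-gene screen over focal biological processes.

#' The four focal GO processes of the hub screen
#' @return Named character vector of GO ids.
#' @export
focal_terms_default <- function() {
  c(photosynthesis = "GO:0015979",
    pigment_biosynthesis = "GO:0046148",
    rhythmic_process = "GO:0048511",
    starch_metabolism = "GO:0005982")
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric p-value per term (probability of at least the
#' observed number of study genes in the term, given the background),
#' BH-adjusted over the tested terms. A term passes when padj < 0.05 and its
#' study gene count is at least `min_count`.
#'
#' @param study character vector of study genes; must be a subset of
#'   `background`.
#' @param background character vector of background (tested-universe) genes.
#' @param term_map data.frame with columns `term`, `gene` (and optionally
#'   `name`); genes outside the background are ignored.
#' @param padj_threshold BH-adjusted significance cutoff (default 0.05).
#' @param min_count minimum study gene count (default 5).
#' @return data.frame with columns `term`, `k` (study hits), `K` (term size in
#'   background), `n` (study size), `N` (background size), `p`, `padj`,
#'   `pass`, sorted by `p`.
#' @export
enrich_terms <- function(study, background, term_map,
                         padj_threshold = 0.05, min_count = 5L) {
  study <- unique(study); background <- unique(background)
  outside <- setdiff(study, background)
  if (length(outside))
    abort(sprintf("study gene(s) absent from background: %s%s",
                  paste(utils::head(outside, 5L), collapse = ", "),
                  if (length(outside) > 5L) ", ..." else ""))
  term_map <- term_map[term_map$gene %in% background, , drop = FALSE]
  N <- length(background); n <- length(study)
  terms <- unique(term_map$term)
  res <- do.call(rbind, lapply(terms, function(tm) {
    genes <- unique(term_map$gene[term_map$term == tm])
    K <- length(genes)
    k <- length(intersect(genes, study))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    return(data.frame(term = character(0L), k = integer(0L), K = integer(0L),
                      n = integer(0L), N = integer(0L), p = numeric(0L),
                      padj = numeric(0L), pass = logical(0L)))
  res$padj <- bh_adjust(res$p)
  res$pass <- res$padj < padj_threshold & res$k >= min_count
  res[order(res$p, res$term), , drop = FALSE]
}

#' Screen hub-gene candidates over the focal processes
#'
#' A gene is a hub candidate when it (a) belongs to at least one focal term,
#' (b) shows expression remodeling (subcategory other than 13) in at least one
#' hybrid, (c) is balanced between the reciprocal hybrids of the first
#' crossing combination (|log2 ratio of genotype-mean expression| strictly
#' below `ratio_threshold`), and (d) differs between the two crossing
#' combinations (|log2 ratio of the combination-mean expression| strictly
#' above `ratio_threshold`). The ratio criteria are interpreted on the log2
#' scale by default; `ratio_mode = "literal"` applies the thresholds to the
#' absolute raw ratios instead.
#'
#' @param classes `class_assignment` covering all hybrids (from
#'   [classify_all]).
#' @param expr a `triad_expr` (filtered).
#' @param design a [triad_design] with two crossing combinations.
#' @param term_map data.frame with columns `term`, `gene`.
#' @param focal_terms term ids to restrict to (default
#'   [focal_terms_default]).
#' @param ratio_threshold threshold for both ratio criteria (default 1, log2
#'   units).
#' @param ratio_mode `"log2"` (default) or `"literal"`.
#' @return data.frame with one row per candidate: `gene`, `terms`
#'   (semicolon-collapsed focal terms), `n_remodeled_hybrids`,
#'   `log2_reciprocal_ratio`, `log2_combination_ratio`.
#' @export
screen_hubs <- function(classes, expr, design, term_map,
                        focal_terms = focal_terms_default(),
                        ratio_threshold = 1,
                        ratio_mode = c("log2", "literal")) {
  ratio_mode <- match.arg(ratio_mode)
  cb <- design$combinations
  combos <- unique(cb$combination)
  assert_that(length(combos) == 2L,
              "hub screen needs exactly two crossing combinations")
  hyb1 <- cb$hybrid[cb$combination == combos[1L]]
  hyb2 <- cb$hybrid[cb$combination == combos[2L]]
  assert_that(length(hyb1) == 2L, "first combination needs reciprocal hybrids")

  means <- genotype_means(expr, design)
  genes <- rownames(means)
  m_h1 <- means[, hyb1[1L]]
  m_h2 <- means[, hyb1[2L]]
  m_c1 <- rowMeans(means[, hyb1, drop = FALSE])
  m_c2 <- rowMeans(means[, hyb2, drop = FALSE])
  rec_ratio <- log2(m_h1 / m_h2)
  comb_ratio <- log2(m_c1 / m_c2)

  crit_rec <- if (ratio_mode == "log2") abs(rec_ratio) < ratio_threshold
              else abs(m_h1 / m_h2) < ratio_threshold
  crit_comb <- if (ratio_mode == "log2") abs(comb_ratio) > ratio_threshold
               else abs(m_c1 / m_c2) > ratio_threshold
  crit_rec[!is.finite(rec_ratio) & ratio_mode == "log2"] <- FALSE
  crit_comb[is.na(comb_ratio)] <- FALSE

  remodeled <- stats::aggregate(subcategory ~ gene, classes,
                                function(s) sum(s != 13L))
  n_remod <- remodeled$subcategory[match(genes, remodeled$gene)]
  n_remod[is.na(n_remod)] <- 0L
  crit_class <- n_remod >= 1L

  focal_map <- term_map[term_map$term %in% focal_terms, , drop = FALSE]
  gene_terms <- tapply(focal_map$term, focal_map$gene, function(tm)
    paste(sort(unique(tm)), collapse = ";"))
  in_focal <- genes %in% names(gene_terms)

  keep <- in_focal & crit_class & crit_rec & crit_comb
  data.frame(gene = genes[keep],
             terms = unname(gene_terms[genes[keep]]),
             n_remodeled_hybrids = n_remod[keep],
             log2_reciprocal_ratio = rec_ratio[keep],
             log2_combination_ratio = comb_ratio[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}
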