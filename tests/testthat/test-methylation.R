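# Methylation link: strand-aware region assignment, aggregation, correlation,
# DMS classification and expression-methylation concordance.

toy_genes <- function(strand = c("+", "-")) {
  data.frame(gene = c("gA", "gB"), chrom = c("chr1", "chr1"),
             start = c(10000L, 50000L), end = c(12000L, 53000L),
             strand = strand, stringsAsFactors = FALSE)
}

toy_sites <- function(pos, context = "CCGG", rpm = NULL) {
  n <- length(pos)
  rpm <- rpm %||% matrix(1, n, 7, dimnames = list(NULL, sim_genotypes))
  methylation_sites(
    cbind(data.frame(site_id = sprintf("s%02d", seq_len(n)), chrom = "chr1",
                     pos = pos, context = rep(context, length.out = n),
                     stringsAsFactors = FALSE),
          as.data.frame(rpm)),
    sim_genotypes)
}

test_that("region assignment is strand-aware and clips at the origin", {
  genes <- toy_genes(c("+", "+"))
  sites <- toy_sites(c(9500, 10500, 12500, 30000))
  asn <- assign_regions(sites, genes)
  expect_equal(asn$region[asn$site_id == "s01"], "upstream2k")
  expect_equal(asn$region[asn$site_id == "s02"], "body")
  expect_equal(asn$region[asn$site_id == "s03"], "downstream2k")
  expect_equal(asn$region[asn$site_id == "s04"], "intergenic")
  expect_true(is.na(asn$gene[asn$site_id == "s04"]))

  # flipping the strand swaps the flanks and keeps the body
  genes_flip <- toy_genes(c("-", "-"))
  asn_flip <- assign_regions(sites, genes_flip)
  expect_equal(asn_flip$region[asn_flip$site_id == "s01"], "downstream2k")
  expect_equal(asn_flip$region[asn_flip$site_id == "s03"], "upstream2k")
  expect_equal(asn_flip$region[asn_flip$site_id == "s02"], "body")

  # a gene starting near the origin has its upstream window clipped, not
  # pushed below position 1
  near <- data.frame(gene = "gN", chrom = "chr2", start = 500L, end = 900L,
                     strand = "+", stringsAsFactors = FALSE)
  s <- toy_sites(100)
  s$chrom <- "chr2"
  asn_near <- assign_regions(s, near)
  expect_equal(asn_near$region[asn_near$site_id == "s01"], "upstream2k")
})

test_that("region levels sum site RPM and satisfy context additivity", {
  genes <- toy_genes(c("+", "+"))
  rpm <- matrix(rep(c(2, 3, 4), each = 7), nrow = 3, byrow = TRUE,
                dimnames = list(NULL, sim_genotypes))
  sites <- toy_sites(c(10100, 10200, 10300), context = c("CCGG", "CCGG", "CCWGG"),
                     rpm = rpm)
  asn <- assign_regions(sites, genes)
  lev <- region_level(sites, asn, gene_ids = genes$gene)
  pick <- function(region, context, gene = "gA")
    lev$P1[lev$gene == gene & lev$region == region & lev$context == context]
  expect_equal(pick("body", "CCGG"), 5)        # 2 + 3
  expect_equal(pick("body", "CCWGG"), 4)
  expect_equal(pick("body", "all"), 9)         # additivity
  expect_equal(pick("upstream2k", "CCGG"), 0)  # no sites -> level 0
  expect_equal(pick("body", "CCGG", "gB"), 0)
  # additivity holds over the whole grid
  wide <- reshape(lev[, c("gene", "region", "context", "P1")],
                  direction = "wide", idvar = c("gene", "region"),
                  timevar = "context")
  expect_equal(wide$P1.all, wide$P1.CCGG + wide$P1.CCWGG)
})

test_that("methylation-expression correlation recovers exact linear links", {
  design <- example_design(2L)
  n <- 30
  genes <- sprintf("g%02d", seq_len(n))
  set.seed(77)
  e <- runif(n, 5, 100)
  means <- matrix(rep(e, 7), n, dimnames = list(genes, sim_genotypes))
  expr <- expr_from_means(means, design)
  grid <- expand.grid(gene = genes,
                      region = c("upstream2k", "body", "downstream2k"),
                      context = c("CCGG", "CCWGG", "all"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lvl <- matrix(runif(nrow(grid) * 7, 1, 5), nrow(grid),
                dimnames = list(NULL, sim_genotypes))
  sel_pos <- grid$region == "body" & grid$context == "CCGG"
  sel_neg <- grid$region == "downstream2k" & grid$context == "CCGG"
  lvl[sel_pos, ] <- 2 * e[match(grid$gene[sel_pos], genes)]
  lvl[sel_neg, ] <- 100 - e[match(grid$gene[sel_neg], genes)]
  region_meth <- cbind(grid, as.data.frame(lvl))
  attr(region_meth, "genotypes") <- sim_genotypes
  res <- meth_expr_correlation(region_meth, expr, design)
  expect_equal(res$r[res$region == "body" & res$context == "CCGG"], 1,
               tolerance = 1e-12)
  expect_equal(res$r[res$region == "downstream2k" & res$context == "CCGG"],
               -1, tolerance = 1e-12)
  expect_true(all(res$n == n))
})

test_that("DMS classification mirrors the expression scheme with OMS/BMS/AMS majors", {
  design <- example_design(2L)
  rpm <- rbind(
    c(P1 = 4, P2 = 4, P3 = 4, F12 = 16, F21 = 16, F13 = 4, F31 = 4),   # 1
    c(P1 = 4, P2 = 4, P3 = 4, F12 = 4, F21 = 4, F13 = 4, F31 = 4),     # 13
    c(P1 = 16, P2 = 2, P3 = 4, F12 = 6, F21 = 6, F13 = 4, F31 = 4))    # 11
  sites <- toy_sites(c(10100, 10200, 10300), rpm = rpm)
  dms <- classify_dms(sites, design, "F12")
  expect_equal(dms$subcategory, c(1L, 13L, 11L))
  expect_equal(dms$major, c("OMS", "conserved", "AMS"))
  # externally supplied calls reuse the identical pattern map
  pats <- all_patterns()
  ids <- sprintf("p%02d", seq_len(nrow(pats)))
  inv_rel <- c(A_gt_B = "up", A_lt_B = "down", ns = "ns")
  inv_f1 <- c(gt = "up", lt = "down", ns = "ns")
  calls <- list(pp = make_call(ids, unname(inv_rel[pats$parent_rel]), "P1", "P2"),
                fa = make_call(ids, unname(inv_f1[pats$f1_vs_a]), "F12", "P1"),
                fb = make_call(ids, unname(inv_f1[pats$f1_vs_b]), "F12", "P2"))
  sites27 <- toy_sites(seq(10100, by = 10, length.out = 27))
  sites27$site_id <- ids
  dms27 <- classify_dms(sites27, design, "F12", calls = calls)
  expect_equal(dms27$subcategory, class_from_pattern(pats)$subcategory)
  expect_error(classify_dms(sites27, design, "F12", calls = calls[1:2]),
               "missing differential-methylation call")
})

test_that("concordance matching labels consistent, conflicting and unmatched genes", {
  expr_classes <- data.frame(
    gene = c("gA", "gB", "gC"), hybrid = "F12",
    parent_a = "P1", parent_b = "P2",
    subcategory = c(7L, 4L, 4L), stringsAsFactors = FALSE)
  dms_classes <- data.frame(
    site_id = c("s1", "s2", "s3", "s4"), context = "CCGG", hybrid = "F12",
    parent_a = "P1", parent_b = "P2",
    subcategory = c(2L, 4L, 13L, 5L), stringsAsFactors = FALSE)
  assignments <- data.frame(site_id = c("s1", "s2", "s3", "s4"),
                            gene = c("gA", "gB", "gC", NA),
                            region = c("body", "body", "body", "intergenic"),
                            stringsAsFactors = FALSE)
  expect_message(
    conc <- match_remodeling(expr_classes, dms_classes, assignments),
    "mapped to no gene")
  # methylation F1 > PA > PB (2) against expression PB > PA > F1 (7):
  # the documented contrasting pair
  expect_equal(conc$label[conc$gene == "gA"], "conflicting")
  expect_equal(conc$label[conc$gene == "gB"], "consistent")
  expect_equal(conc$label[conc$gene == "gC"], "unmatched")
})

test_that("feature distribution reports genic fractions per class group", {
  dms <- data.frame(site_id = c("s1", "s2", "s3"), context = "CCGG",
                    hybrid = "F12", parent_a = "P1", parent_b = "P2",
                    subcategory = c(2L, 7L, 13L), stringsAsFactors = FALSE)
  asn <- data.frame(site_id = c("s1", "s2", "s3"),
                    gene = c("gA", "gB", NA),
                    region = c("body", "upstream2k", "intergenic"),
                    stringsAsFactors = FALSE)
  expect_warning(fd <- feature_distribution(dms, asn), "no AMS sites")
  expect_equal(fd$genic_fraction[fd$group == "NMS"], 1)
  expect_true(is.na(fd$genic_fraction[fd$group == "AMS"]))
  expect_equal(fd$genic_fraction[fd$group == "conserved"], 0)
})
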