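# Links immature-seed DNA methylation (site-level RPM in the CCGG / CCWGG
# restriction contexts) to seedling expression: strand-aware assignment of
# sites to gene regions (2 kb upstream, gene body, 2 kb downstream),
# region-level RPM aggregation, methylation-expression correlation per
# region x context, remodeling classification of differentially methylated
# sites with the same 27-pattern scheme as expression (majors renamed
# OMS/BMS/AMS), and gene-level concordance matching of the two remodeling
# modes.

.regions <- c("upstream2k", "body", "downstream2k")

#' Strand-aware region ranges of gene models
#' @noRd
region_ranges <- function(genes, flank = 2000L) {
  body <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  names(body) <- genes$gene
  upstream <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::promoters(body, upstream = flank, downstream = 0L)))
  downstream <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::flank(body, width = flank, start = FALSE)))
  list(upstream2k = upstream, body = body, downstream2k = downstream)
}

#' Assign methylation sites to gene regions
#'
#' The gene body is `[start, end]`; the upstream region is the 2 kb 5' of the
#' transcription start and the downstream region the 2 kb 3' of the
#' transcription end, both respecting strand and clipped at position 1. A site
#' may fall in regions of several genes (one output row each); sites covered
#' by no region are labeled intergenic.
#'
#' @param sites a `meth_sites` table.
#' @param genes gene model data.frame (`gene`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param flank flank width in bp (default 2000).
#' @return data.frame with columns `site_id`, `gene` (`NA` for intergenic) and
#'   `region` (`upstream2k`, `body`, `downstream2k`, `intergenic`).
#' @export
assign_regions <- function(sites, genes, flank = 2000L) {
  genes <- validate_gene_models(genes)
  rr <- region_ranges(genes, flank)
  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos, width = 1L))
  out <- NULL
  for (region in .regions) {
    hits <- GenomicRanges::findOverlaps(site_gr, rr[[region]],
                                        ignore.strand = TRUE)
    if (length(hits)) {
      out <- rbind(out, data.frame(
        site_id = sites$site_id[S4Vectors_from(hits)],
        gene = names(rr[[region]])[S4Vectors_to(hits)],
        region = region, stringsAsFactors = FALSE))
    }
  }
  assigned <- if (is.null(out)) character(0L) else unique(out$site_id)
  inter <- setdiff(sites$site_id, assigned)
  if (length(inter)) {
    out <- rbind(out, data.frame(site_id = inter, gene = NA_character_,
                                 region = "intergenic",
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# queryHits/subjectHits without attaching S4Vectors
S4Vectors_from <- function(hits) methods::slot(hits, "from")
S4Vectors_to <- function(hits) methods::slot(hits, "to")

#' Aggregate site RPM into per-gene region methylation levels
#'
#' The methylation level of a gene region is the sum of the RPM of its sites
#' ("overall methylation amount"), per genotype and per context; the `all`
#' context is the sum of the CCGG and CCWGG levels. Regions without sites get
#' level 0. Set `aggregate = "mean"` for a mean-per-site level instead of the
#' sum (the `all` additivity then no longer holds).
#'
#' @param sites a `meth_sites` table.
#' @param assignments output of [assign_regions].
#' @param gene_ids gene universe for the output grid (default: genes
#'   appearing in `assignments`).
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @return data.frame with columns `gene`, `region`, `context` and one level
#'   column per genotype.
#' @export
region_level <- function(sites, assignments, gene_ids = NULL,
                         aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  genotypes <- attr(sites, "genotypes") %||%
    setdiff(names(sites), c("site_id", "chrom", "pos", "context"))
  gene_ids <- gene_ids %||% sort(unique(assignments$gene[!is.na(assignments$gene)]))
  contexts <- c("CCGG", "CCWGG")
  joined <- merge(assignments[!is.na(assignments$gene), ],
                  sites[, c("site_id", "context", genotypes)],
                  by = "site_id")
  grid <- expand.grid(gene = gene_ids, region = .regions, context = contexts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lev <- matrix(0, nrow(grid), length(genotypes),
                dimnames = list(NULL, genotypes))
  if (nrow(joined)) {
    key_grid <- paste(grid$gene, grid$region, grid$context)
    key_join <- paste(joined$gene, joined$region, joined$context)
    for (g in genotypes) {
      agg_fun <- if (aggregate == "sum") sum else mean
      agg <- tapply(joined[[g]], key_join, agg_fun)
      idx <- match(key_grid, names(agg))
      lev[, g] <- ifelse(is.na(idx), 0, agg[idx])
    }
  }
  per_ctx <- cbind(grid, as.data.frame(lev))
  # "all" = CCGG + CCWGG on the same gene x region (sum aggregation);
  # for mean aggregation, recompute from the joined sites
  if (aggregate == "sum") {
    key <- paste(per_ctx$gene, per_ctx$region)
    all_rows <- per_ctx[per_ctx$context == "CCGG", c("gene", "region")]
    all_lev <- lev[per_ctx$context == "CCGG", , drop = FALSE] +
      lev[per_ctx$context == "CCWGG", , drop = FALSE]
  } else {
    all_rows <- unique(per_ctx[, c("gene", "region")])
    all_lev <- matrix(0, nrow(all_rows), length(genotypes),
                      dimnames = list(NULL, genotypes))
    if (nrow(joined)) {
      key_all <- paste(all_rows$gene, all_rows$region)
      key_join2 <- paste(joined$gene, joined$region)
      for (g in genotypes) {
        agg <- tapply(joined[[g]], key_join2, mean)
        idx <- match(key_all, names(agg))
        all_lev[, g] <- ifelse(is.na(idx), 0, agg[idx])
      }
    }
  }
  all_ctx <- cbind(all_rows, context = "all", as.data.frame(all_lev))
  out <- rbind(per_ctx, all_ctx)
  out <- out[order(out$gene, out$region, out$context), ]
  rownames(out) <- NULL
  attr(out, "genotypes") <- genotypes
  out
}

#' Correlate region methylation with expression across genes
#'
#' For each of the nine region x context combinations, the Pearson
#' correlation across genes between the genotype-mean expression (FPKM) and
#' the genotype-mean region methylation level.
#'
#' @param region_meth output of [region_level].
#' @param expr a `triad_expr`.
#' @param design optional [triad_design]; when given, expression is averaged
#'   over genotype means, otherwise over samples.
#' @return data.frame with columns `region`, `context`, `n`, `r`, `p`
#'   (two-sided). Zero-variance combinations yield `NA` with a warning.
#' @export
meth_expr_correlation <- function(region_meth, expr, design = NULL) {
  genotypes <- attr(region_meth, "genotypes") %||%
    setdiff(names(region_meth), c("gene", "region", "context"))
  ex <- if (is.null(design)) rowMeans(expr$fpkm)
        else rowMeans(genotype_means(expr, design))
  meth_mean <- rowMeans(as.matrix(region_meth[, genotypes, drop = FALSE]))
  out <- NULL
  for (region in .regions) {
    for (context in c("CCGG", "CCWGG", "all")) {
      rows <- region_meth$region == region & region_meth$context == context
      genes <- intersect(region_meth$gene[rows], names(ex))
      if (length(genes) < 3L)
        abort("need >= 3 genes shared between methylation and expression")
      m <- meth_mean[rows][match(genes, region_meth$gene[rows])]
      e <- ex[genes]
      if (stats::sd(m) == 0 || stats::sd(e) == 0) {
        warning(sprintf("zero variance for %s/%s; correlation undefined",
                        region, context))
        r <- p <- NA_real_
      } else {
        ct <- stats::cor.test(e, m, method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out <- rbind(out, data.frame(region = region, context = context,
                                   n = length(genes), r = r, p = p,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Classify differentially methylated sites by remodeling pattern
#'
#' Applies the identical 27-pattern / 14-subcategory mapping used for
#' expression to site-level methylation, for one hybrid's triad. With
#' genotype-level RPM (one column per genotype) the calls are deterministic
#' fold-change calls; externally computed differential-methylation calls can
#' be supplied instead via `calls`. Major categories are the methylation
#' counterparts: OMS (over-parent), BMS (parent-biased), AMS (additive),
#' conserved, other; subcategories 1-10 are the non-additive sites (NMS).
#'
#' @param sites a `meth_sites` table.
#' @param design a [triad_design].
#' @param hybrid hybrid genotype label.
#' @param lfc_threshold strict |log2 ratio| cutoff (default 1).
#' @param pseudocount added before ratios (default 0; site RPM is strictly
#'   positive in MethylRAD-style data — use a positive pseudocount when zeros
#'   occur).
#' @param calls optional list with elements `pp`, `fa`, `fb`: `de_calls`-style
#'   tables over sites (gene column = site_id) for parents A vs B, hybrid vs
#'   A, hybrid vs B; overrides the internal fold-change calls.
#' @return data.frame of class `dms_assignment` with columns `site_id`,
#'   `context`, `hybrid`, `parent_a`, `parent_b`, `subcategory`, `major`.
#' @export
classify_dms <- function(sites, design, hybrid, lfc_threshold = 1,
                         pseudocount = 0, calls = NULL) {
  par <- canonical_parents(design, hybrid)
  if (!is.null(calls)) {
    missing <- setdiff(c("pp", "fa", "fb"), names(calls))
    if (length(missing))
      abort(sprintf("missing differential-methylation call(s): %s",
                    paste(missing, collapse = ", ")))
    pattern <- pattern_from_calls(calls$pp, calls$fa, calls$fb)
    context <- sites$context[match(pattern$gene, sites$site_id)]
    ids <- pattern$gene
  } else {
    genotypes <- attr(sites, "genotypes")
    need <- c(par, hybrid)
    assert_that(all(need %in% genotypes),
                "triad genotypes missing from site table")
    lev <- as.matrix(sites[, need, drop = FALSE])
    ratio_rel <- function(a, b) {
      num <- lev[, a] + pseudocount
      den <- lev[, b] + pseudocount
      lfc <- log2(num / den)
      lfc[num == 0 & den == 0] <- 0
      ifelse(lfc > lfc_threshold, "gt",
             ifelse(lfc < -lfc_threshold, "lt", "ns"))
    }
    pr <- ratio_rel(par[["parent_a"]], par[["parent_b"]])
    pattern <- data.frame(
      gene = sites$site_id,
      parent_rel = ifelse(pr == "gt", "A_gt_B",
                          ifelse(pr == "lt", "A_lt_B", "ns")),
      f1_vs_a = ratio_rel(hybrid, par[["parent_a"]]),
      f1_vs_b = ratio_rel(hybrid, par[["parent_b"]]),
      stringsAsFactors = FALSE)
    context <- sites$context
    ids <- sites$site_id
  }
  cls <- class_from_pattern(pattern)
  meth_major <- c(OPG = "OMS", BPG = "BMS", AEG = "AMS",
                  conserved = "conserved", other = "other")
  out <- data.frame(site_id = ids, context = context, hybrid = hybrid,
                    parent_a = par[["parent_a"]], parent_b = par[["parent_b"]],
                    subcategory = cls$subcategory,
                    major = unname(meth_major[cls$major]),
                    stringsAsFactors = FALSE)
  class(out) <- c("dms_assignment", "data.frame")
  out
}

#' Match methylation remodeling against expression remodeling
#'
#' For every gene x hybrid x context with at least one gene-linked methylation
#' site, records whether any site's remodeling subcategory equals the gene's
#' expression subcategory ("consistent") and whether any site's subcategory is
#' the hyper/hypo dual of it (pairs 1-6, 2-7, 3-8, 4-9, 5-10; "conflicting").
#' A gene with several sites may carry both labels. Sites mapped to no gene
#' are skipped (count reported via message).
#'
#' @param expr_classes `class_assignment` (expression) covering the hybrids
#'   of interest.
#' @param dms_classes `dms_assignment` (methylation) for the same hybrids.
#' @param assignments site-to-gene assignments from [assign_regions].
#' @return data.frame with columns `gene`, `hybrid`, `context`, `n_sites`,
#'   `consistent`, `conflicting`, `label` (`consistent`, `conflicting`,
#'   `both`, `unmatched`).
#' @export
match_remodeling <- function(expr_classes, dms_classes, assignments) {
  linked <- assignments[!is.na(assignments$gene), c("site_id", "gene")]
  linked <- unique(linked)
  n_skip <- length(setdiff(dms_classes$site_id, linked$site_id))
  if (n_skip)
    message(sprintf("%d site(s) mapped to no gene; skipped", n_skip))
  dm <- merge(dms_classes, linked, by = "site_id")
  dm <- merge(dm, expr_classes[, c("gene", "hybrid", "subcategory")],
              by = c("gene", "hybrid"), suffixes = c("_meth", "_expr"))
  if (!nrow(dm))
    return(data.frame(gene = character(0L), hybrid = character(0L),
                      context = character(0L), n_sites = integer(0L),
                      consistent = logical(0L), conflicting = logical(0L),
                      label = character(0L)))
  dm$is_consistent <- dm$subcategory_meth == dm$subcategory_expr
  dm$is_conflicting <- dm$subcategory_expr <= 10L &
    dm$subcategory_meth == class_dual(dm$subcategory_expr)
  key <- interaction(dm$gene, dm$hybrid, dm$context, drop = TRUE)
  agg <- data.frame(
    gene = tapply(dm$gene, key, `[`, 1L),
    hybrid = tapply(dm$hybrid, key, `[`, 1L),
    context = tapply(dm$context, key, `[`, 1L),
    n_sites = as.integer(tapply(dm$site_id, key, function(x) length(unique(x)))),
    consistent = as.logical(tapply(dm$is_consistent, key, any)),
    conflicting = as.logical(tapply(dm$is_conflicting, key, any)),
    stringsAsFactors = FALSE, row.names = NULL)
  agg$label <- ifelse(agg$consistent & agg$conflicting, "both",
                      ifelse(agg$consistent, "consistent",
                             ifelse(agg$conflicting, "conflicting",
                                    "unmatched")))
  agg <- agg[order(agg$gene, agg$hybrid, agg$context), ]
  rownames(agg) <- NULL
  agg
}

#' Genomic-feature distribution of remodeled methylation sites
#'
#' For each remodeling class group — NMS (subcategories 1-10), AMS (11-12)
#' and conserved (13) — the fraction of sites lying in gene regions (body or
#' flanks) versus intergenic space, per hybrid.
#'
#' @param dms_classes a `dms_assignment`.
#' @param assignments site-to-gene assignments from [assign_regions].
#' @return data.frame with columns `hybrid`, `group`, `n_sites`,
#'   `genic_fraction` (`NA` with a warning for empty groups).
#' @export
feature_distribution <- function(dms_classes, assignments) {
  genic_sites <- unique(assignments$site_id[!is.na(assignments$gene)])
  groups <- list(NMS = 1:10, AMS = 11:12, conserved = 13L)
  out <- NULL
  for (h in unique(dms_classes$hybrid)) {
    sub <- dms_classes[dms_classes$hybrid == h, ]
    for (gname in names(groups)) {
      ids <- unique(sub$site_id[sub$subcategory %in% groups[[gname]]])
      if (!length(ids)) {
        warning(sprintf("no %s sites for %s; fraction undefined", gname, h))
        frac <- NA_real_
      } else frac <- mean(ids %in% genic_sites)
      out <- rbind(out, data.frame(hybrid = h, group = gname,
                                   n_sites = length(ids),
                                   genic_fraction = frac,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
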