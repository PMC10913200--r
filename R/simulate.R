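# Synthetic triad study generator. Emulates the 7-genotype design (parents
# P1, P2, P3; reciprocal hybrids F12/F21 and F13/F31) x 3 replicates with
# planted ground truth: per-gene remodeling subcategories realized exactly in
# the noise-free genotype means, negative-binomial count noise on top,
# methylation sites whose region-aggregate levels are coupled to expression
# at configured correlation signs, and phenotypes with exact planted
# mid-parent heterosis.

.sim_genotypes <- c("P1", "P2", "P3", "F12", "F21", "F13", "F31")
.sim_hybrids <- c("F12", "F21", "F13", "F31")

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic generators.
#' Defaults emulate the study conditions: 7 genotypes x 3 replicates,
#' planted |log2 fold change| of 2 for "different" triad relations,
#' negative-binomial dispersion 0.05, most genes conserved (subcategory 13).
#'
#' @param n_genes number of genes (default 2000).
#' @param replicates replicates per genotype (default 3).
#' @param seed integer RNG seed.
#' @param class_proportions named probabilities over subcategories "1".."14";
#'   must sum to 1. Default: 0.55 conserved, 0.03 per subcategory 1-12, 0.09
#'   other.
#' @param effect_size planted |log2 fold change| between "different" triad
#'   levels (default 2); must strictly exceed `lfc_threshold` when any
#'   non-conserved class has positive probability.
#' @param lfc_threshold,pseudocount thresholds the downstream classifier will
#'   use; the generator checks that planted patterns survive the pseudocount
#'   shrinkage at the configured base-mean floor.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2; default 0.05).
#' @param base_mean_range log-uniform FPKM range of each gene's lowest triad
#'   level before library normalization (default c(32, 512)). Because FPKM is
#'   tied to the library definition (sum of FPKM x length_kb is 1e6), the
#'   whole matrix is rescaled once after construction; the generator verifies
#'   that the post-normalization floor still clears the classifier's
#'   pseudocount shrinkage.
#' @param depth nominal per-sample library size in reads (default 5e6).
#' @param gene_length_range log-uniform gene length range in bp.
#' @param recip_match probability that a reciprocal hybrid repeats its
#'   partner's planted level (hence subcategory); otherwise a feasible
#'   alternative class is drawn (default 0.5).
#' @param flank flank width for gene-model regions (bp, default 2000).
#' @param genes_per_chrom gene models per chromosome.
#' @param sites_lambda named Poisson means of extra methylation sites per
#'   gene x region x context beyond the guaranteed one.
#' @param meth_effect_size planted |log2 ratio| for differential methylation
#'   levels (default 2).
#' @param dms_class_proportions subcategory probabilities for methylation
#'   sites (default: 0.40 conserved, 0.04 each for 1-12, 0.12 other).
#' @param meth_recip_match reciprocal-repeat probability for site patterns.
#' @param coupling data.frame (`region`, `context`, `rho`) of target Pearson
#'   correlations between gene-level region methylation and expression;
#'   magnitudes must be < 1. Defaults follow the gene-body positive /
#'   upstream-inverted / downstream-negative structure, CCGG dominant.
#' @param meth_scale per-context base level and latent slope of the region
#'   aggregate RPM.
#' @param intergenic_fraction intergenic sites as a fraction of genic sites.
#' @param traits data.frame of parent trait means (`trait`, `P1`, `P2`, `P3`),
#'   all positive.
#' @param planted_mph named planted mid-parent heterosis (percent) per hybrid.
#' @param pheno_cv replicate coefficient of variation for phenotypes.
#' @param pheno_replicates phenotype replicates per genotype (>= 3).
#' @param n_terms,term_size_range,focal_size,focal_bias synthetic term-map
#'   shape (number of background terms, their size range, the size of the
#'   four focal terms, and the fraction of focal-term genes drawn from
#'   remodeled genes).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, replicates = 3L, seed = 1L,
                       class_proportions = NULL,
                       effect_size = 2, lfc_threshold = 1, pseudocount = 1,
                       dispersion = 0.05, base_mean_range = c(32, 512),
                       depth = 5e6, gene_length_range = c(500, 5000),
                       recip_match = 0.5,
                       flank = 2000L, genes_per_chrom = 100L,
                       sites_lambda = c(body = 2, upstream2k = 1,
                                        downstream2k = 1),
                       meth_effect_size = 2,
                       dms_class_proportions = NULL,
                       meth_recip_match = 0.5,
                       coupling = NULL, meth_scale = NULL,
                       intergenic_fraction = 0.3,
                       traits = NULL, planted_mph = NULL,
                       pheno_cv = 0.05, pheno_replicates = 3L,
                       n_terms = 20L, term_size_range = c(10L, 80L),
                       focal_size = 60L, focal_bias = 0.7) {
  class_proportions <- class_proportions %||%
    stats::setNames(c(rep(0.03, 12L), 0.55, 0.09), as.character(1:14))
  dms_class_proportions <- dms_class_proportions %||%
    stats::setNames(c(rep(0.04, 12L), 0.40, 0.12), as.character(1:14))
  coupling <- coupling %||% data.frame(
    region = rep(c("body", "upstream2k", "downstream2k"), each = 2L),
    context = rep(c("CCGG", "CCWGG"), 3L),
    rho = c(0.5, -0.3, -0.5, 0.3, -0.5, -0.3),
    stringsAsFactors = FALSE)
  meth_scale <- meth_scale %||% list(CCGG = c(base = 20, slope = 6),
                                     CCWGG = c(base = 6, slope = 1.5))
  traits <- traits %||% data.frame(
    trait = c("leaf_length", "leaf_width", "stem_diameter", "plant_height",
              "fresh_weight", "root_fresh_weight"),
    P1 = c(6.0, 3.0, 2.2, 18, 2.5, 0.8),
    P2 = c(5.0, 2.6, 1.8, 15, 1.9, 0.6),
    P3 = c(7.0, 3.4, 2.6, 21, 3.1, 1.0),
    stringsAsFactors = FALSE)
  planted_mph <- planted_mph %||% c(F12 = 30, F21 = 25, F13 = 8, F31 = 5)

  cfg <- list(n_genes = as.integer(n_genes), replicates = as.integer(replicates),
              seed = as.integer(seed), class_proportions = class_proportions,
              effect_size = effect_size, lfc_threshold = lfc_threshold,
              pseudocount = pseudocount, dispersion = dispersion,
              base_mean_range = base_mean_range, depth = depth,
              gene_length_range = gene_length_range,
              recip_match = recip_match, flank = as.integer(flank),
              genes_per_chrom = as.integer(genes_per_chrom),
              sites_lambda = sites_lambda,
              meth_effect_size = meth_effect_size,
              dms_class_proportions = dms_class_proportions,
              meth_recip_match = meth_recip_match,
              coupling = coupling, meth_scale = meth_scale,
              intergenic_fraction = intergenic_fraction,
              traits = traits, planted_mph = planted_mph,
              pheno_cv = pheno_cv,
              pheno_replicates = as.integer(pheno_replicates),
              n_terms = as.integer(n_terms),
              term_size_range = term_size_range,
              focal_size = as.integer(focal_size), focal_bias = focal_bias)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @noRd
validate_sim_config <- function(cfg) {
  for (nm in c("class_proportions", "dms_class_proportions")) {
    p <- cfg[[nm]]
    assert_that(length(p) == 14L && !is.null(names(p)) &&
                  identical(names(p), as.character(1:14)),
                sprintf("%s must be named over subcategories 1..14", nm))
    assert_that(all(p >= 0) && abs(sum(p) - 1) < 1e-9,
                sprintf("%s must be non-negative and sum to 1", nm))
  }
  assert_that(cfg$n_genes >= 1L, "n_genes must be positive")
  assert_that(cfg$replicates >= 2L, "need >= 2 replicates per genotype")
  assert_that(cfg$dispersion > 0, "dispersion must be > 0")
  assert_that(cfg$effect_size > 0, "effect_size must be > 0")
  non_cons <- sum(cfg$class_proportions[as.character(c(1:12, 14))])
  if (non_cons > 0 && cfg$effect_size <= cfg$lfc_threshold)
    abort("infeasible configuration: effect_size must exceed lfc_threshold to realize non-conserved classes")
  assert_that(length(cfg$base_mean_range) == 2L &&
                cfg$base_mean_range[1L] > 0 &&
                diff(cfg$base_mean_range) >= 0,
              "base_mean_range must be a positive increasing interval")
  assert_that(all(abs(cfg$coupling$rho) < 1),
              "coupling magnitudes must be < 1 (noise is nonzero)")
  assert_that(all(cfg$coupling$region %in% .regions) &&
                all(cfg$coupling$context %in% c("CCGG", "CCWGG")),
              "coupling must cover regions upstream2k/body/downstream2k and contexts CCGG/CCWGG")
  assert_that(all(unlist(cfg$traits[, c("P1", "P2", "P3")]) > 0),
              "parent trait means must be positive for ratio-based heterosis")
  assert_that(all(.sim_hybrids %in% names(cfg$planted_mph)),
              "planted_mph must name all four hybrids")
  assert_that(cfg$pheno_replicates >= 3L,
              "phenotypes need >= 3 replicates per genotype")
  cfg
}

# ---- planted level machinery ------------------------------------------------

#' Canonical (A, B, F1) log2 levels realizing each subcategory, in units of
#' the effect size e; subcategory 14 uses threshold-relative offsets that
#' force the contradictory pattern (ns parents, F1 above A only).
#' @noRd
canonical_levels <- function(cls, e, thr) {
  tab <- list(c(0, 0, e), c(e, 0, 2 * e), c(0, e, 2 * e), c(e, 0, e),
              c(0, e, e), c(e, e, 0), c(2 * e, e, 0), c(e, 2 * e, 0),
              c(e, 0, 0), c(0, e, 0), c(2 * e, 0, e), c(0, 2 * e, e),
              c(0, 0, 0), c(0, 0.9 * thr, 1.45 * thr))
  tab[[cls]]
}

#' F1 level realizing subcategory `cls` against given parent levels.
#' @noRd
hybrid_level <- function(cls, la, lb, e, thr) {
  switch(cls,
         max(la, lb) + e,          # 1
         la + e,                   # 2
         lb + e,                   # 3
         la,                       # 4
         lb,                       # 5
         min(la, lb) - e,          # 6
         lb - e,                   # 7
         la - e,                   # 8
         lb,                       # 9
         la,                       # 10
         (la + lb) / 2,            # 11
         (la + lb) / 2,            # 12
         (la + lb) / 2,            # 13
         min(la, lb) + thr + abs(la - lb) / 2)  # 14
}

#' Subcategories realizable as an alternative F1 level given fixed parents.
#' @noRd
feasible_classes <- function(la, lb, e, thr) {
  d <- la - lb
  if (d > thr) {
    f <- c(2L, 4L, 7L, 9L)
    if (d >= 2 * e) f <- c(f, 11L)
  } else if (d < -thr) {
    f <- c(3L, 5L, 8L, 10L)
    if (-d >= 2 * e) f <- c(f, 12L)
  } else if (abs(d) >= 0.5 * thr) {
    f <- c(1L, 6L, 13L, 14L)
  } else {
    f <- c(1L, 6L, 13L)
  }
  f
}

#' @noRd
draw_reciprocal <- function(cls_focal, la, lb, lh, e, thr, recip_match, probs) {
  if (stats::runif(1L) < recip_match)
    return(list(level = lh, class = cls_focal))
  feas <- feasible_classes(la, lb, e, thr)
  w <- probs[as.character(feas)]
  if (sum(w) <= 0) w <- rep(1, length(feas))
  alt <- feas[sample.int(length(feas), 1L, prob = w)]
  list(level = hybrid_level(alt, la, lb, e, thr), class = alt)
}

#' Plant genotype-level log2 offsets and per-hybrid subcategories for n units
#' (genes or methylation sites) over the 7-genotype design.
#' @noRd
plant_patterns <- function(n, probs, e, thr, recip_match) {
  focal1 <- sample(1:14, n, replace = TRUE, prob = probs)
  focal2 <- sample(1:14, n, replace = TRUE, prob = probs)
  lev <- matrix(0, n, 7L, dimnames = list(NULL, .sim_genotypes))
  cls <- matrix(13L, n, 4L, dimnames = list(NULL, .sim_hybrids))
  for (i in seq_len(n)) {
    l1 <- canonical_levels(focal1[i], e, thr)
    l_p1 <- l1[1L]; l_p2 <- l1[2L]; l_f12 <- l1[3L]
    l2 <- canonical_levels(focal2[i], e, thr)
    sh <- l_p1 - l2[1L]
    l_p3 <- l2[2L] + sh; l_f13 <- l2[3L] + sh
    r1 <- draw_reciprocal(focal1[i], l_p1, l_p2, l_f12, e, thr,
                          recip_match, probs)
    r2 <- draw_reciprocal(focal2[i], l_p1, l_p3, l_f13, e, thr,
                          recip_match, probs)
    lev[i, ] <- c(l_p1, l_p2, l_p3, l_f12, r1$level, l_f13, r2$level)
    cls[i, ] <- c(focal1[i], r1$class, focal2[i], r2$class)
  }
  list(levels = lev, classes = cls)
}

# ---- expression -------------------------------------------------------------

#' Generate a synthetic triad expression dataset with planted classes
#'
#' Draws per-gene remodeling subcategories from `class_proportions`, realizes
#' them as genotype-mean FPKM levels (each "different" relation separated by
#' `effect_size` log2 units), normalizes the FPKM scale to be self-consistent
#' with the gene lengths and library definition, and simulates
#' negative-binomial counts per replicate. Realized FPKM is
#' counts / (length_kb x effective-library-millions), with the effective
#' library size a median-of-ratios size factor times the nominal depth —
#' robust to the compositional asymmetry of the planted differential tail.
#' Classifying the noise-free mean matrix recovers 100% of the planted
#' subcategories; this is checked at generation time.
#'
#' @param config a [sim_config].
#' @return list with elements `expr` (a `triad_expr` with counts and
#'   lengths), `design` (a [triad_design]) and `truth` (list with
#'   `classes` — data.frame gene/hybrid/subcategory/major —, `mean_fpkm` —
#'   the noise-free gene x genotype matrix —, and `levels`).
#' @export
generate_triad_dataset <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  design <- example_design(config$replicates)
  genes <- sprintf("g%05d", seq_len(n))

  lengths <- round(exp(stats::runif(n, log(config$gene_length_range[1L]),
                                    log(config$gene_length_range[2L]))))
  names(lengths) <- genes
  mu <- exp(stats::runif(n, log(config$base_mean_range[1L]),
                         log(config$base_mean_range[2L])))
  planted <- plant_patterns(n, config$class_proportions, config$effect_size,
                            config$lfc_threshold, config$recip_match)
  lev <- planted$levels - apply(planted$levels, 1L, min)
  raw <- mu * 2^lev
  dimnames(raw) <- list(genes, .sim_genotypes)
  len_kb <- lengths / 1000
  # one global factor so that sum(FPKM * length_kb) ~ 1e6, making the planted
  # FPKM consistent with the count-based library definition
  norm <- mean(colSums(raw * len_kb)) / 1e6
  mean_fpkm <- raw / norm
  # the planted margins must survive the classifier's pseudocount shrinkage
  # at the post-normalization FPKM floor; the tightest planted margin is
  # min(effect_size, 1.45 * lfc_threshold) at a gene's lowest level
  non_cons <- sum(config$class_proportions[as.character(c(1:12, 14))])
  if (non_cons > 0) {
    floor_fpkm <- min(mu) / norm
    margin <- min(config$effect_size, 1.45 * config$lfc_threshold)
    shrunk <- log2((floor_fpkm * 2^margin + config$pseudocount) /
                     (floor_fpkm + config$pseudocount))
    if (shrunk <= config$lfc_threshold)
      abort(paste0(
        "infeasible configuration: after library normalization the lowest ",
        "planted FPKM is ", signif(floor_fpkm, 3L), " and the pseudocount ",
        "shrinks planted margins below lfc_threshold; raise base_mean_range[1] ",
        "relative to base_mean_range[2]"))
  }

  samples <- design$samples
  mu_counts <- mean_fpkm[, samples$genotype, drop = FALSE] * len_kb *
    (config$depth / 1e6)
  counts <- matrix(stats::rnbinom(length(mu_counts), mu = mu_counts,
                                  size = 1 / config$dispersion),
                   nrow = n, dimnames = list(genes, samples$sample))
  # effective library size via median-of-ratios size factors: total-count
  # scaling is dominated by the planted differential tail (hybrids with
  # transgressive-up patterns inflate their own libraries), whereas the
  # median gene is conserved, so size factors keep cross-genotype ratios of
  # the realized FPKM aligned with the planted means
  ref <- exp(rowMeans(log(counts + 0.5)))
  sf <- apply(counts, 2L, function(x) stats::median(x / ref))
  sf <- sf / exp(mean(log(sf)))
  lib <- sf * config$depth / 1e6
  fpkm <- sweep(counts / len_kb, 2L, lib, "/")
  expr <- expression_matrix(fpkm, counts = counts, gene_lengths = lengths)

  class_table <- data.frame(
    gene = rep(genes, times = 4L),
    hybrid = rep(.sim_hybrids, each = n),
    subcategory = as.integer(planted$classes),
    stringsAsFactors = FALSE)
  class_table$major <- .major_of(class_table$subcategory)

  for (h in .sim_hybrids) {
    par <- canonical_parents(design, h)
    got <- classify_means(mean_fpkm, par[["parent_a"]], par[["parent_b"]], h,
                          lfc_threshold = config$lfc_threshold,
                          pseudocount = config$pseudocount)
    want <- class_table$subcategory[class_table$hybrid == h]
    if (!identical(got$subcategory, want))
      abort(sprintf(
        "internal error: planted subcategories not realized for %s", h))
  }

  list(expr = expr, design = design,
       truth = list(classes = class_table, mean_fpkm = mean_fpkm,
                    levels = lev))
}

#' Generate gene models matching simulated gene lengths
#'
#' Genes are laid out consecutively on chromosomes with intergenic gaps wide
#' enough to keep the 2 kb flank regions of neighbouring genes disjoint;
#' strands are random.
#'
#' @param config a [sim_config].
#' @param gene_lengths named vector of gene lengths (bp), e.g. from the
#'   `expr` element of [generate_triad_dataset].
#' @return Gene model data.frame (`gene`, `chrom`, `start`, `end`, `strand`).
#' @export
generate_gene_models <- function(config, gene_lengths) {
  set.seed(config$seed + 1L)
  n <- length(gene_lengths)
  chrom_idx <- (seq_len(n) - 1L) %/% config$genes_per_chrom + 1L
  chrom <- sprintf("chr%02d", chrom_idx)
  gaps <- round(stats::runif(n, 2000, 8000)) + 2L * config$flank
  start <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    if (i > 1L && chrom_idx[i] != chrom_idx[i - 1L]) pos <- 1L
    start[i] <- pos + gaps[i]
    pos <- start[i] + as.integer(gene_lengths[i])
  }
  data.frame(gene = names(gene_lengths), chrom = chrom, start = start,
             end = start + as.integer(gene_lengths) - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# ---- methylation ------------------------------------------------------------

#' Generate methylation sites coupled to expression
#'
#' Every gene receives at least one site per region x context (plus a Poisson
#' number of extras) whose summed RPM — the region aggregate — is constructed
#' so that, across genes, its genotype mean correlates with genotype-mean
#' expression at the configured Pearson rho per (region, context): a latent
#' score rho * z + sqrt(1 - rho^2) * noise (z = standardized expression) is
#' mapped linearly to the aggregate level. The aggregate is split over sites
#' by symmetric Dirichlet weights, and each site carries a planted remodeling
#' pattern across the 7 genotypes (per-genotype multipliers normalized to
#' preserve the aggregate's genotype mean). Intergenic sites are placed on a
#' separate unannotated chromosome. Because per-site genotype ratios are
#' exact, classifying the site table with a zero pseudocount recovers the
#' planted DMS subcategories exactly.
#'
#' @param config a [sim_config].
#' @param genes gene models from [generate_gene_models].
#' @param mean_fpkm noise-free gene x genotype mean matrix (the coupling
#'   anchor), from the truth of [generate_triad_dataset].
#' @return list with `sites` (a `meth_sites` table) and `truth` (list with
#'   `dms_classes` — site/hybrid/subcategory/major —, and `coupling` — the
#'   planted rho and expected correlation sign per region x context,
#'   including the induced "all" context).
#' @export
generate_methylation <- function(config, genes, mean_fpkm) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- nrow(genes)
  assert_that(identical(genes$gene, rownames(mean_fpkm)),
              "gene models and expression truth must cover the same genes in order")
  x <- rowMeans(mean_fpkm)
  zx <- (x - mean(x)) / stats::sd(x)
  rr <- region_ranges(genes, config$flank)
  contexts <- c("CCGG", "CCWGG")

  site_rows <- list()
  coupling <- config$coupling
  for (region in .regions) {
    rstart <- GenomicRanges::start(rr[[region]])
    rend <- GenomicRanges::end(rr[[region]])
    for (context in contexts) {
      rho <- coupling$rho[coupling$region == region &
                            coupling$context == context]
      sc <- config$meth_scale[[context]]
      y <- rho * zx + sqrt(1 - rho^2) * stats::rnorm(n)
      target <- pmax(0.05 * sc[["base"]], sc[["base"]] + sc[["slope"]] * y)
      lambda <- config$sites_lambda[[region]]
      if (lambda <= 0) next
      n_sites <- 1L + stats::rpois(n, max(0, lambda - 1))
      gi <- rep(seq_len(n), n_sites)
      w <- stats::rgamma(length(gi), 1)
      w <- w / stats::ave(w, gi, FUN = sum)
      pos <- floor(stats::runif(length(gi), rstart[gi], rend[gi] + 1))
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        chrom = genes$chrom[gi], pos = as.integer(pos), context = context,
        base = target[gi] * w, stringsAsFactors = FALSE)
    }
  }
  genic <- do.call(rbind, site_rows) %||%
    data.frame(chrom = character(0L), pos = integer(0L),
               context = character(0L), base = numeric(0L))
  n_genic <- nrow(genic)
  n_inter <- round(config$intergenic_fraction * n_genic)
  inter <- data.frame(
    chrom = rep("chrU", n_inter),
    pos = as.integer(seq(1e6, by = 5000, length.out = n_inter)),
    context = sample(contexts, n_inter, replace = TRUE, prob = c(0.6, 0.4)),
    base = stats::rlnorm(n_inter, log(5), 0.5),
    stringsAsFactors = FALSE)
  all_sites <- rbind(genic, inter)
  m <- nrow(all_sites)

  planted <- plant_patterns(m, config$dms_class_proportions,
                            config$meth_effect_size, 1,
                            config$meth_recip_match)
  fold <- 2^planted$levels
  rpm <- all_sites$base * fold / rowMeans(fold)
  colnames(rpm) <- .sim_genotypes

  site_id <- sprintf("s%06d", seq_len(m))
  sites <- cbind(data.frame(site_id = site_id, chrom = all_sites$chrom,
                            pos = all_sites$pos, context = all_sites$context,
                            stringsAsFactors = FALSE),
                 as.data.frame(rpm))
  sites <- methylation_sites(sites, .sim_genotypes)

  dms_classes <- data.frame(
    site_id = rep(site_id, times = 4L),
    hybrid = rep(.sim_hybrids, each = m),
    subcategory = as.integer(planted$classes),
    stringsAsFactors = FALSE)

  slopes <- vapply(config$meth_scale, `[[`, numeric(1L), "slope")
  rho_of <- function(region, context)
    coupling$rho[coupling$region == region & coupling$context == context]
  coup_truth <- do.call(rbind, lapply(.regions, function(region) {
    rc <- rho_of(region, "CCGG"); rw <- rho_of(region, "CCWGG")
    data.frame(region = region,
               context = c("CCGG", "CCWGG", "all"),
               rho = c(rc, rw, NA_real_),
               expected_sign = sign(c(rc, rw,
                                      slopes[["CCGG"]] * rc +
                                        slopes[["CCWGG"]] * rw)),
               stringsAsFactors = FALSE)
  }))

  list(sites = sites,
       truth = list(dms_classes = dms_classes, coupling = coup_truth))
}

# ---- phenotypes -------------------------------------------------------------

#' Generate phenotype replicates with planted heterosis
#'
#' Parent genotype means come from `config$traits`; each hybrid's mean is set
#' to mid-parent x (1 + MPH/100) so that the population mid-parent heterosis
#' equals the planted value exactly. Replicates add Gaussian noise with the
#' configured coefficient of variation (CV 0 reproduces the means exactly).
#'
#' @param config a [sim_config].
#' @param design a [triad_design].
#' @return list with `pheno` (long data.frame genotype/trait/replicate/value)
#'   and `truth` (data.frame hybrid/trait/mph_planted/bph_planted).
#' @export
generate_phenotypes <- function(config, design) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 3L)
  gh <- design$genotypes
  traits <- config$traits
  nrep <- config$pheno_replicates
  rows <- list(); truth <- list()
  for (t in seq_len(nrow(traits))) {
    tr <- traits$trait[t]
    pm <- c(P1 = traits$P1[t], P2 = traits$P2[t], P3 = traits$P3[t])
    means <- pm
    for (h in .sim_hybrids) {
      mat <- gh$maternal[gh$genotype == h]
      pat <- gh$paternal[gh$genotype == h]
      mid <- (pm[[mat]] + pm[[pat]]) / 2
      hm <- mid * (1 + config$planted_mph[[h]] / 100)
      means[[h]] <- hm
      best <- max(pm[[mat]], pm[[pat]])
      truth[[length(truth) + 1L]] <- data.frame(
        hybrid = h, trait = tr, mph_planted = config$planted_mph[[h]],
        bph_planted = 100 * (hm - best) / best, stringsAsFactors = FALSE)
    }
    for (g in names(means)) {
      vals <- stats::rnorm(nrep, means[[g]], config$pheno_cv * means[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, trait = tr, replicate = seq_len(nrep), value = vals,
        stringsAsFactors = FALSE)
    }
  }
  list(pheno = do.call(rbind, rows), truth = do.call(rbind, truth))
}

# ---- term map ---------------------------------------------------------------

#' Generate a synthetic term-to-gene mapping
#'
#' Builds the four focal processes plus `n_terms` background terms. Focal
#' terms draw a configurable fraction of their genes from a supplied
#' "interesting" gene pool (e.g. planted remodeled genes), the rest at
#' random.
#'
#' @param config a [sim_config].
#' @param gene_ids universe of gene ids.
#' @param enriched_in optional gene pool the focal terms are biased toward.
#' @return data.frame with columns `term`, `gene`.
#' @export
generate_term_map <- function(config, gene_ids, enriched_in = NULL) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 4L)
  out <- list()
  for (tm in unname(focal_terms_default())) {
    k <- min(config$focal_size, length(gene_ids))
    n_bias <- if (is.null(enriched_in)) 0L else
      min(round(config$focal_bias * k), length(enriched_in))
    picked <- unique(c(sample(enriched_in, n_bias),
                       sample(gene_ids, k - n_bias)))
    out[[length(out) + 1L]] <- data.frame(term = tm, gene = picked,
                                          stringsAsFactors = FALSE)
  }
  for (j in seq_len(config$n_terms)) {
    k <- sample(seq(config$term_size_range[1L], config$term_size_range[2L]),
                1L)
    k <- min(k, length(gene_ids))
    out[[length(out) + 1L]] <- data.frame(
      term = sprintf("T%04d", j), gene = sample(gene_ids, k),
      stringsAsFactors = FALSE)
  }
  unique(do.call(rbind, out))
}

# ---- full study -------------------------------------------------------------

#' Simulate a complete triad study
#'
#' Runs all generators with one seed: expression with planted remodeling
#' classes, gene models, methylation sites coupled to expression, phenotypes
#' with planted heterosis, and a synthetic term map biased toward the planted
#' remodeled genes. Identical config (including seed) gives identical output.
#'
#' @param config a [sim_config].
#' @return list of class `triad_sim` with elements `expr`, `design`, `genes`,
#'   `sites`, `pheno`, `terms` and `truth` (classes, mean_fpkm, dms_classes,
#'   coupling, phenotype).
#' @export
simulate_triad_study <- function(config = sim_config()) {
  ds <- generate_triad_dataset(config)
  genes <- generate_gene_models(config, ds$expr$gene_lengths)
  meth <- generate_methylation(config, genes, ds$truth$mean_fpkm)
  ph <- generate_phenotypes(config, ds$design)
  remodeled <- unique(ds$truth$classes$gene[ds$truth$classes$subcategory != 13L])
  terms <- generate_term_map(config, gene_ids(ds$expr), enriched_in = remodeled)
  structure(list(expr = ds$expr, design = ds$design, genes = genes,
                 sites = meth$sites, pheno = ph$pheno, terms = terms,
                 config = config,
                 truth = list(classes = ds$truth$classes,
                              mean_fpkm = ds$truth$mean_fpkm,
                              dms_classes = meth$truth$dms_classes,
                              coupling = meth$truth$coupling,
                              phenotype = ph$truth)),
            class = "triad_sim")
}

#' @export
print.triad_sim <- function(x, ...) {
  cat(sprintf(paste0("triad_sim: %d genes x %d samples, %d methylation sites,",
                     " %d traits (seed %d)\n"),
              nrow(x$expr$fpkm), ncol(x$expr$fpkm), nrow(x$sites),
              length(unique(x$pheno$trait)), x$config$seed))
  invisible(x)
}
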