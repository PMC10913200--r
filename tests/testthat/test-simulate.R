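# Generator contracts: determinism, planted structure realized exactly in the
# noise-free means, count moments, phenotype heterosis, config validation.

test_that("identical seed and config reproduce identical outputs", {
  cfg <- sim_config(n_genes = 80, seed = 5)
  a <- simulate_triad_study(cfg)
  b <- simulate_triad_study(cfg)
  expect_identical(a$expr$fpkm, b$expr$fpkm)
  expect_identical(a$expr$counts, b$expr$counts)
  expect_identical(a$sites, b$sites)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$terms, b$terms)
  expect_identical(a$truth, b$truth)
})

test_that("planted conserved genes have equal means; planted dominance is exact", {
  all13 <- setNames(rep(0, 14), as.character(1:14)); all13["13"] <- 1
  cfg <- sim_config(n_genes = 20, seed = 2, class_proportions = all13)
  ds <- generate_triad_dataset(cfg)
  spread <- apply(ds$truth$mean_fpkm, 1, function(x) diff(range(x)))
  expect_true(all(spread == 0))

  all4 <- setNames(rep(0, 14), as.character(1:14)); all4["4"] <- 1
  cfg4 <- sim_config(n_genes = 20, seed = 2, class_proportions = all4,
                     recip_match = 1, effect_size = 2)
  ds4 <- generate_triad_dataset(cfg4)
  m <- ds4$truth$mean_fpkm
  # subcategory 4: F1 = parent A = 2^effect_size * parent B
  expect_equal(m[, "F12"], m[, "P1"], tolerance = 1e-12)
  expect_equal(m[, "P1"], 4 * m[, "P2"], tolerance = 1e-12)
  expect_true(all(ds4$truth$classes$subcategory[
    ds4$truth$classes$hybrid == "F12"] == 4L))
})

test_that("planted subcategory distribution follows the configured proportions", {
  cfg <- sim_config(n_genes = 4000, seed = 9)
  ds <- generate_triad_dataset(cfg)
  # the focal hybrid of each combination draws straight from the config
  f12 <- ds$truth$classes$subcategory[ds$truth$classes$hybrid == "F12"]
  frac13 <- mean(f12 == 13L)
  expect_gt(frac13, 0.50)
  expect_lt(frac13, 0.60)
})

test_that("simulated counts match the negative-binomial moments", {
  cfg <- sim_config(n_genes = 5000, seed = 13)
  ds <- generate_triad_dataset(cfg)
  counts <- ds$expr$counts
  len_kb <- ds$expr$gene_lengths / 1000
  mu <- ds$truth$mean_fpkm[, ds$design$samples$genotype] * len_kb *
    (5e6 / 1e6)
  expect_equal(mean(counts) / mean(mu), 1, tolerance = 0.01)
  # per-gene unbiased moment estimator of the dispersion (deterministic
  # denominator), averaged over genes to keep the tail from dominating
  dev2 <- (counts - mu)^2 - mu
  disp_gene <- rowSums(dev2) / rowSums(mu^2)
  expect_equal(mean(disp_gene), 0.05, tolerance = 0.1)
})

test_that("phenotype generator plants MPH exactly", {
  design <- example_design(3L)
  traits <- data.frame(trait = "mass", P1 = 10, P2 = 20, P3 = 30)
  cfg <- sim_config(n_genes = 10, seed = 4, traits = traits,
                    planted_mph = c(F12 = 30, F21 = 0, F13 = 10, F31 = 5),
                    pheno_cv = 0)
  ph <- generate_phenotypes(cfg, design)
  means <- aggregate(value ~ genotype, ph$pheno, mean)
  get <- function(g) means$value[means$genotype == g]
  # MPH 30% on parents 10 and 20: 15 * 1.3
  expect_equal(get("F12"), 19.5)
  # MPH 0: hybrid equals mid-parent
  expect_equal(get("F21"), 15)
  # with zero CV the sample heterosis equals the planted value exactly
  het <- heterosis_indices(ph$pheno, design)
  expect_equal(het$mph[het$hybrid == "F12"], 30)
  expect_equal(het$mph[het$hybrid == "F13"], 10)
  expect_equal(ph$truth$bph_planted[ph$truth$hybrid == "F12"],
               100 * (19.5 - 20) / 20)
})

test_that("methylation generator honors zero-site requests and couples signs", {
  cfg0 <- sim_config(n_genes = 30, seed = 6,
                     sites_lambda = c(body = 0, upstream2k = 0,
                                      downstream2k = 0),
                     intergenic_fraction = 0)
  ds <- generate_triad_dataset(cfg0)
  genes <- generate_gene_models(cfg0, ds$expr$gene_lengths)
  meth <- generate_methylation(cfg0, genes, ds$truth$mean_fpkm)
  expect_equal(nrow(meth$sites), 0L)
  expect_equal(nrow(meth$truth$dms_classes), 0L)

  cfg <- sim_config(n_genes = 400, seed = 6)
  ds <- generate_triad_dataset(cfg)
  genes <- generate_gene_models(cfg, ds$expr$gene_lengths)
  meth <- generate_methylation(cfg, genes, ds$truth$mean_fpkm)
  # body CCGG aggregate correlates positively, downstream CCGG negatively
  x <- rowMeans(ds$truth$mean_fpkm)
  asn <- assign_regions(meth$sites, genes)
  lv <- region_level(meth$sites, asn, gene_ids = genes$gene)
  agg <- function(region, context) {
    sub <- lv[lv$region == region & lv$context == context, ]
    rowMeans(as.matrix(sub[match(genes$gene, sub$gene), sim_genotypes]))
  }
  expect_gt(cor(x, agg("body", "CCGG")), 0.3)
  expect_lt(cor(x, agg("downstream2k", "CCGG")), -0.3)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(effect_size = 0.5, lfc_threshold = 1),
               "effect_size must exceed")
  bad <- setNames(rep(1 / 13, 14), as.character(1:14))
  expect_error(sim_config(class_proportions = bad), "sum to 1")
  coup <- data.frame(region = rep(c("body", "upstream2k", "downstream2k"),
                                  each = 2),
                     context = rep(c("CCGG", "CCWGG"), 3),
                     rho = c(1.0, 0.3, -0.5, 0.3, -0.5, -0.3))
  expect_error(sim_config(coupling = coup), "magnitudes must be < 1")
  traits <- data.frame(trait = "t", P1 = -1, P2 = 2, P3 = 3)
  expect_error(sim_config(traits = traits), "must be positive")
  # base-mean floor too low for the pseudocount once normalized
  expect_error(
    generate_triad_dataset(sim_config(n_genes = 4000, seed = 1,
                                      base_mean_range = c(0.5, 512))),
    "infeasible configuration")
})
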