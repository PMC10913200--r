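# Heterosis indices, one-way ANOVA (with degenerate inputs) and trait
# correlations.

pheno_from_means <- function(means, trait = "height", reps = 3L) {
  do.call(rbind, lapply(names(means), function(g) {
    data.frame(genotype = g, trait = trait, replicate = seq_len(reps),
               value = rep(means[[g]], reps), stringsAsFactors = FALSE)
  }))
}

het_design <- function() {
  d <- example_design(2L)
  d
}

test_that("MPH and BPH follow the percent-deviation formulas", {
  design <- het_design()
  ph <- pheno_from_means(c(P1 = 10, P2 = 20, P3 = 5, F12 = 18, F21 = 15,
                           F13 = 7.5, F31 = 20))
  het <- heterosis_indices(ph, design)
  f12 <- het[het$hybrid == "F12", ]
  expect_equal(f12$mph, 20)          # (18 - 15) / 15 * 100
  expect_equal(f12$bph, -10)         # (18 - 20) / 20 * 100
  # hybrid at the mid-parent: MPH = 0
  expect_equal(het$mph[het$hybrid == "F21"], 0)
  # hybrid at the best parent: BPH = 0 (F13: parents 10, 5 -> best 10? no:
  # parents of F13 are P1=10 and P3=5, best 10, hybrid 7.5 = mid-parent)
  expect_equal(het$mph[het$hybrid == "F13"], 0)
  f31 <- het[het$hybrid == "F31", ]
  expect_equal(f31$bph, 100)
  # scale invariance: multiplying all values by c > 0 changes nothing
  ph2 <- ph; ph2$value <- ph2$value * 3.7
  expect_equal(heterosis_indices(ph2, design)$mph, het$mph)
  expect_equal(heterosis_indices(ph2, design)$bph, het$bph)
})

test_that("BPH never exceeds MPH for positive traits with distinct parents", {
  design <- het_design()
  set.seed(14)
  for (i in 1:20) {
    means <- runif(7, 1, 50)
    names(means) <- c("P1", "P2", "P3", "F12", "F21", "F13", "F31")
    het <- heterosis_indices(pheno_from_means(means), design)
    expect_true(all(het$bph <= het$mph + 1e-12))
  }
})

test_that("a zero mid-parent mean is flagged undefined", {
  design <- het_design()
  ph <- pheno_from_means(c(P1 = 10, P2 = -10, P3 = 5, F12 = 3, F21 = 3,
                           F13 = 7.5, F31 = 7.5))
  # both F12 and F21 share the degenerate parent pair, hence two warnings
  expect_warning(expect_warning(het <- heterosis_indices(ph, design),
                                "MPH undefined"))
  expect_true(is.na(het$mph[het$hybrid == "F12"]))
})

test_that("one-way ANOVA matches the mean-squares ratio and handles degeneracy", {
  ph <- data.frame(
    genotype = rep(c("a", "b", "c"), each = 4),
    trait = "t", replicate = rep(1:4, 3),
    value = c(5.1, 4.9, 5.3, 4.7, 6.2, 6.0, 6.4, 5.8, 4.0, 4.2, 3.9, 4.3))
  res <- one_way_anova(ph, "t")
  # brute-force mean squares
  gm <- tapply(ph$value, ph$genotype, mean)
  grand <- mean(ph$value)
  msb <- sum(4 * (gm - grand)^2) / 2
  msw <- sum((ph$value - gm[ph$genotype])^2) / 9
  expect_equal(res$F, msb / msw, tolerance = 1e-12)
  expect_equal(res$p, pf(msb / msw, 2, 9, lower.tail = FALSE),
               tolerance = 1e-12)

  # two identical constant groups: p = 1
  const <- data.frame(genotype = rep(c("a", "b"), each = 3), trait = "t",
                      replicate = rep(1:3, 2), value = rep(7, 6))
  expect_equal(one_way_anova(const, "t")$p, 1)

  # separated groups with epsilon jitter: overwhelming evidence
  jit <- data.frame(genotype = rep(c("a", "b"), each = 3), trait = "t",
                    replicate = rep(1:3, 2),
                    value = c(0.001, -0.002, 0.0015, 10.001, 9.998, 10.0005))
  expect_lt(one_way_anova(jit, "t")$p, 1e-6)

  # constant but different groups: degenerate p -> 0, flagged
  sep <- data.frame(genotype = rep(c("a", "b"), each = 3), trait = "t",
                    replicate = rep(1:3, 2), value = rep(c(0, 10), each = 3))
  expect_warning(res_sep <- one_way_anova(sep, "t"), "degenerate")
  expect_equal(res_sep$p, 0)
  expect_true(res_sep$degenerate)

  # a null draw from one normal population is not significant at 0.001
  set.seed(31)
  null_ph <- data.frame(genotype = rep(letters[1:7], each = 3), trait = "t",
                        replicate = rep(1:3, 7), value = rnorm(21, 10, 1))
  expect_gt(one_way_anova(null_ph, "t")$p, 0.001)
})

test_that("trait correlations recover planted structure", {
  set.seed(42)
  x <- rnorm(100)
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(100)
  ph <- rbind(
    data.frame(genotype = rep("g", 100), trait = "x", replicate = 1:100,
               value = x),
    data.frame(genotype = rep("g", 100), trait = "x_copy", replicate = 1:100,
               value = x),
    data.frame(genotype = rep("g", 100), trait = "neg_x", replicate = 1:100,
               value = -x),
    data.frame(genotype = rep("g", 100), trait = "y", replicate = 1:100,
               value = y))
  res <- trait_correlation(ph)
  expect_equal(res$r["x", "x_copy"], 1, tolerance = 1e-12)
  expect_equal(res$r["x", "neg_x"], -1, tolerance = 1e-12)
  # seeded bivariate normal with rho = 0.8 lands inside the oracle band
  expect_gt(res$r["x", "y"], 0.7)
  expect_lt(res$r["x", "y"], 0.88)
  expect_true(isSymmetric(res$r))
  expect_equal(unname(diag(res$r)), rep(1, 4))

  flat <- rbind(ph[ph$trait == "x", ],
                data.frame(genotype = "g", trait = "const", replicate = 1:100,
                           value = 5))
  expect_warning(resf <- trait_correlation(flat), "zero-variance")
  expect_true(is.na(resf$r["x", "const"]))
})
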