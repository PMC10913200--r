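# Triad remodeling classification: the pattern map, its symmetries, hybrid
# classification on matrices, and reciprocal-consistent gene sets.

test_that("anchor patterns map to their documented subcategories", {
  cases <- data.frame(
    parent_rel = c("ns", "ns", "A_gt_B", "A_gt_B", "A_lt_B", "A_gt_B",
                   "A_lt_B", "ns", "A_gt_B", "A_lt_B", "A_gt_B", "A_lt_B",
                   "A_gt_B", "A_lt_B", "ns"),
    f1_vs_a    = c("gt", "ns", "ns", "gt", "gt", "lt",
                   "gt", "lt", "lt", "lt", "lt", "ns",
                   "lt", "gt", "gt"),
    f1_vs_b    = c("gt", "ns", "gt", "gt", "gt", "ns",
                   "ns", "lt", "lt", "lt", "ns", "lt",
                   "gt", "lt", "ns"),
    expected   = c(1L, 13L, 4L, 2L, 3L, 9L,
                   5L, 6L, 7L, 8L, 9L, 10L,
                   11L, 12L, 14L),
    stringsAsFactors = FALSE)
  got <- class_from_pattern(cases)
  expect_equal(got$subcategory, cases$expected)
  expect_equal(got$major, oracle_major(cases$expected))
  # biased-parent bookkeeping: 4/10 toward A, 5/9 toward B
  expect_equal(got$biased_parent[got$subcategory == 4L], "A")
  expect_equal(got$biased_parent[got$subcategory == 5L], "B")
  expect_equal(unique(got$biased_parent[got$subcategory == 9L]), "B")
  expect_equal(got$biased_parent[got$subcategory == 10L], "A")
})

test_that("the pattern map is total over all 27 patterns", {
  pats <- all_patterns()
  got <- class_from_pattern(pats)
  expect_equal(nrow(got), 27L)
  expect_true(all(got$subcategory %in% 1:14))
  expect_true(all(sort(unique(got$subcategory)) == 1:14))
  # each of subcategories 1..13 is hit exactly once
  expect_equal(unname(table(got$subcategory)[as.character(1:13)]),
               rep(1L, 13L), ignore_attr = TRUE)
})

test_that("parent relabeling and mid-parent mirroring act as the documented permutations", {
  pats <- all_patterns()
  base <- class_from_pattern(pats)$subcategory
  flip_rel <- function(x) c(A_gt_B = "A_lt_B", A_lt_B = "A_gt_B", ns = "ns")[x]
  flip_f1 <- function(x) c(gt = "lt", lt = "gt", ns = "ns")[x]
  # swap parent labels A <-> B
  swapped <- data.frame(parent_rel = unname(flip_rel(pats$parent_rel)),
                        f1_vs_a = pats$f1_vs_b, f1_vs_b = pats$f1_vs_a,
                        stringsAsFactors = FALSE)
  expect_equal(class_from_pattern(swapped)$subcategory,
               class_swap_parents(base))
  # major category is invariant under relabeling
  expect_equal(oracle_major(class_swap_parents(base)), oracle_major(base))
  # mirror about the mid-parent: negate all three relations, then relabel
  # parents so the original orientation is restored
  mirrored <- data.frame(
    parent_rel = unname(flip_rel(flip_rel(pats$parent_rel))),
    f1_vs_a = unname(flip_f1(pats$f1_vs_b)),
    f1_vs_b = unname(flip_f1(pats$f1_vs_a)),
    stringsAsFactors = FALSE)
  mirrored$parent_rel <- pats$parent_rel  # double flip restores it
  expect_equal(class_from_pattern(mirrored)$subcategory, class_dual(base))
})

test_that("pattern assembly copies directions and rejects mismatched genes", {
  pp <- make_call(c("g1", "g2"), c("ns", "up"), "P1", "P2")
  fa <- make_call(c("g1", "g2"), c("up", "ns"), "F12", "P1")
  fb <- make_call(c("g1", "g2"), c("up", "up"), "F12", "P2")
  pat <- pattern_from_calls(pp, fa, fb)
  expect_equal(pat$parent_rel, c("ns", "A_gt_B"))
  expect_equal(pat$f1_vs_a, c("gt", "ns"))
  expect_equal(pat$f1_vs_b, c("gt", "gt"))
  fb_bad <- make_call(c("g1", "gX"), c("up", "up"), "F12", "P2")
  expect_error(pattern_from_calls(pp, fa, fb_bad), "identical genes")
})

test_that("a constant matrix classifies every gene as conserved", {
  design <- example_design(3L)
  means <- matrix(10, nrow = 5, ncol = 7,
                  dimnames = list(sprintf("g%d", 1:5), sim_genotypes))
  expr <- expr_from_means(means, design, replicates = 3L)
  for (h in sim_hybrids) {
    cls <- classify_hybrid(expr, design, h)
    expect_equal(unique(cls$subcategory), 13L)
  }
  expect_error(classify_hybrid(expr, design, "F99"), "not a declared hybrid")
})

test_that("a strong planted transgressive class is recovered from noisy data", {
  # subcategory-2 genes planted inside the default balanced mixture (FPKM is
  # a relative measure, so planted classes are only recoverable when the
  # overall composition stays balanced across genotypes); at |log2FC| = 3
  # with 6 replicates a pre-build simulation oracle fixed >= 95% recovery
  cfg <- sim_config(n_genes = 1500, replicates = 6L, effect_size = 3,
                    base_mean_range = c(96, 512), seed = 21)
  ds <- generate_triad_dataset(cfg)
  cls <- classify_hybrid(filter_low_expression(ds$expr, ds$design),
                         ds$design, "F12")
  truth <- ds$truth$classes[ds$truth$classes$hybrid == "F12", ]
  planted2 <- truth$gene[truth$subcategory == 2L]
  expect_gte(length(planted2), 20)
  got <- cls$subcategory[match(planted2, cls$gene)]
  expect_gte(mean(got == 2L), 0.95)
})

test_that("reciprocal consistency keeps shared non-conserved subcategories", {
  a <- structure(data.frame(gene = c("g1", "g2", "g3"), hybrid = "F12",
                            parent_a = "P1", parent_b = "P2",
                            subcategory = c(4L, 4L, 13L),
                            stringsAsFactors = FALSE),
                 class = c("class_assignment", "data.frame"))
  b <- a; b$hybrid <- "F21"; b$subcategory <- c(4L, 13L, 13L)
  recg <- reciprocal_consistent(a, b)
  expect_equal(recg$gene, "g1")
  expect_equal(recg$subcategory, 4L)
  b_bad <- b[b$gene != "g3", ]
  expect_error(reciprocal_consistent(a, b_bad), "different gene universes")
})
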