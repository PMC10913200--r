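# Inheritance gene sets: ledger assembly, copDEG direction, the DIG rule,
# overlap percentages and maternal attribution, on hand-made call tables.

toy_design <- function() {
  d <- example_design(2L)
  d$combinations <- d$combinations[d$combinations$combination == "P1xP2", ]
  d$genotypes <- d$genotypes[d$genotypes$genotype %in%
                               c("P1", "P2", "F12", "F21"), ]
  d$samples <- d$samples[d$samples$genotype %in% d$genotypes$genotype, ]
  d
}

toy_calls <- function() {
  g <- c("g1", "g2", "g3", "g4")
  list(
    # parents differ on g1, g2, g4
    P1_vs_P2   = make_call(g, c("up", "down", "ns", "up"), "P1", "P2"),
    # F12 matches P1 (ns) on g1, DE vs P2
    F12_vs_P1  = make_call(g, c("ns", "up", "up", "ns"), "F12", "P1"),
    F12_vs_P2  = make_call(g, c("up", "up", "up", "ns"), "F12", "P2"),
    # F21 matches P2 (ns) on g1, DE vs P1
    F21_vs_P1  = make_call(g, c("down", "ns", "ns", "ns"), "F21", "P1"),
    F21_vs_P2  = make_call(g, c("ns", "ns", "ns", "down"), "F21", "P2"),
    F12_vs_F21 = make_call(g, c("up", "up", "ns", "ns"), "F12", "F21"))
}

test_that("ledger contains PEGs, copDEGs with direction, HEGs and H&P", {
  ledger <- build_deg_ledger(toy_calls(), toy_design())
  expect_setequal(ledger$sets[["PEG.P1xP2"]], c("g1", "g2", "g4"))
  # copDEG: DE versus both parents with recorded direction
  expect_setequal(ledger$sets[["copDEG.F12"]], c("g2", "g3"))
  dirs <- ledger$directions[["copDEG.F12"]]
  expect_equal(dirs$direction[dirs$gene == "g2"], "up")
  # g1 is DE only vs P2, hence not a copDEG
  expect_false("g1" %in% ledger$sets[["copDEG.F12"]])
  expect_setequal(ledger$sets[["HEG.F12.F21"]], c("g1", "g2"))
  expect_setequal(ledger$sets[["HP.F12.F21"]],
                  intersect(ledger$sets[["HEG.F12.F21"]],
                            ledger$sets[["PEG.P1xP2"]]))
  expect_error(build_deg_ledger(toy_calls()[-1], toy_design()),
               "missing differential-expression comparison")
})

test_that("the DIG rule requires hybrid DE plus distinct matched parents", {
  calls <- toy_calls()
  digs <- detect_digs(calls, toy_design(), "F12", "F21")
  # g1: F12 ns-vs-P1 & DE-vs-P2, F21 ns-vs-P2 & DE-vs-P1, hybrids DE -> DIG
  expect_equal(digs$gene, "g1")
  expect_equal(digs$origin_x, "P1")
  expect_equal(digs$origin_y, "P2")
  # g2: F21 is ns vs both parents -> not exactly one -> excluded
  # g3: hybrids not DE from each other -> excluded
  # g4: both hybrids would match, but F12 is ns vs both -> excluded
  expect_false(any(c("g2", "g3", "g4") %in% digs$gene))
})

test_that("DIGs are a subset of HEGs and H&P obeys its identities", {
  ledger <- build_deg_ledger(toy_calls(), toy_design())
  expect_true(all(ledger$sets[["DIG.F12.F21"]] %in%
                    ledger$sets[["HEG.F12.F21"]]))
  expect_true(all(ledger$sets[["HP.F12.F21"]] %in%
                    ledger$sets[["HEG.F12.F21"]]))
  expect_true(all(ledger$sets[["HP.F12.F21"]] %in%
                    ledger$sets[["PEG.P1xP2"]]))
  expect_equal(overlap_fraction(ledger, "HP.F12.F21", "HEG.F12.F21"), 100)
})

test_that("overlap percentages are asymmetric with the first set as denominator", {
  ledger <- triadex:::new_ledger()
  ledger <- triadex:::add_set(ledger, "A", paste0("g", 1:4), "toy")
  ledger <- triadex:::add_set(ledger, "B", c("g1", "g2"), "toy")
  ledger <- triadex:::add_set(ledger, "C", c("g9"), "toy")
  ledger <- triadex:::add_set(ledger, "empty", character(0), "toy")
  expect_equal(overlap_fraction(ledger, "A", "B"), 50)
  expect_equal(overlap_fraction(ledger, "B", "A"), 100)
  expect_equal(overlap_fraction(ledger, "A", "C"), 0)
  expect_warning(res <- overlap_fraction(ledger, "empty", "A"), "empty")
  expect_true(is.na(res))
  expect_error(overlap_fraction(ledger, "A", "missing"), "not in ledger")
})

test_that("maternal attribution reports per-hybrid and combined fractions", {
  design <- toy_design()
  digs <- data.frame(gene = paste0("g", 1:4),
                     origin_x = c("P1", "P1", "P1", "P2"),
                     origin_y = c("P2", "P2", "P2", "P2"),
                     stringsAsFactors = FALSE)
  res <- maternal_attribution(digs, design, "F12", "F21")
  # F12's maternal parent is P1: 3 of 4 origins
  expect_equal(res$maternal_fraction[res$hybrid == "F12"], 0.75)
  # F21's maternal parent is P2: all 4
  expect_equal(res$maternal_fraction[res$hybrid == "F21"], 1)
  expect_equal(res$maternal_fraction[res$hybrid == "combined"], 7 / 8)

  all_pat <- data.frame(gene = "g1", origin_x = "P2", origin_y = "P1",
                        stringsAsFactors = FALSE)
  res0 <- maternal_attribution(all_pat, design, "F12", "F21")
  expect_equal(res0$maternal_fraction[res0$hybrid == "F12"], 0)

  none <- digs[0, ]
  expect_warning(resna <- maternal_attribution(none, design, "F12", "F21"),
                 "no DIGs")
  expect_true(all(is.na(resna$maternal_fraction)))
  expect_error(maternal_attribution(data.frame(gene = "g1"), design,
                                    "F12", "F21"), "origin labels")
})
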