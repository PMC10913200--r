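# Triad remodeling classification. Each gene's three pairwise DE relations
# (parent A vs parent B, F1 vs A, F1 vs B) form one of 27 patterns, mapped to
# 14 subcategories in 5 major categories:
#   OPG (over-parent / transgressive)      1, 2, 3, 6, 7, 8
#   BPG (parent-biased / dominance)        4, 5, 9, 10
#   AEG (additive, strictly intermediate)  11, 12
#   conserved                              13
#   other (contradictory patterns)         14
# Subcategories 1-5 are the hyper side (F1 at or above the higher parent),
# 6-10 the hypo side; 1/6 arise from parents that do not differ, 2,3/7,8 are
# transgressive beyond differing parents, 4,5/9,10 are high-/low-parent
# dominance, split by which labeled parent is the higher one.

.pattern_grid <- function() {
  expand.grid(parent_rel = c("A_gt_B", "A_lt_B", "ns"),
              f1_vs_a = c("gt", "lt", "ns"),
              f1_vs_b = c("gt", "lt", "ns"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# The full 27-pattern mapping. Rows not listed are contradictory or
# unresolvable and fall into subcategory 14.
.class_rules <- data.frame(
  parent_rel = c("ns", "A_gt_B", "A_lt_B", "A_gt_B", "A_lt_B",
                 "ns", "A_gt_B", "A_lt_B", "A_gt_B", "A_lt_B",
                 "A_gt_B", "A_lt_B", "ns"),
  f1_vs_a    = c("gt", "gt", "gt", "ns", "gt",
                 "lt", "lt", "lt", "lt", "ns",
                 "lt", "gt", "ns"),
  f1_vs_b    = c("gt", "gt", "gt", "gt", "ns",
                 "lt", "lt", "lt", "ns", "lt",
                 "gt", "lt", "ns"),
  subcategory = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L),
  stringsAsFactors = FALSE)

.major_of <- function(subcategory) {
  m <- c("OPG", "OPG", "OPG", "BPG", "BPG", "OPG", "OPG", "OPG", "BPG", "BPG",
         "AEG", "AEG", "conserved", "other")
  m[subcategory]
}

.biased_of <- function(subcategory) {
  b <- rep("none", 14L)
  b[c(4L, 10L)] <- "A"
  b[c(5L, 9L)] <- "B"
  b[subcategory]
}

#' Parent-relabeling permutation of subcategories
#'
#' Swapping the two parent labels (A <-> B) maps 2<->3, 4<->5, 7<->8, 9<->10,
#' 11<->12 and fixes 1, 6, 13, 14; the major category is invariant.
#'
#' @param subcategory integer vector in 1..14.
#' @return Permuted subcategory vector.
#' @export
class_swap_parents <- function(subcategory) {
  perm <- c(1L, 3L, 2L, 5L, 4L, 6L, 8L, 7L, 10L, 9L, 12L, 11L, 13L, 14L)
  perm[subcategory]
}

#' Hyper/hypo dual of a subcategory
#'
#' Mirroring expression about the mid-parent (with parent labels fixed) maps
#' the hyper subcategories to their hypo counterparts: 1<->6, 2<->7, 3<->8,
#' 4<->9, 5<->10; 11, 12, 13 and 14 are fixed. These five pairs are exactly
#' the "contrasting pattern" pairs used when matching methylation remodeling
#' against expression remodeling (e.g. F1 > PA > PB in methylation versus
#' PB > PA > F1 in expression).
#'
#' @param subcategory integer vector in 1..14.
#' @return Dual subcategory vector.
#' @export
class_dual <- function(subcategory) {
  perm <- c(6L, 7L, 8L, 9L, 10L, 1L, 2L, 3L, 4L, 5L, 11L, 12L, 13L, 14L)
  perm[subcategory]
}

#' Assemble a triad pattern from three DE call tables
#'
#' Copies the call directions into a pattern code; no thresholds are
#' re-applied. The three tables must cover the same genes in the same order of
#' a coherent triad: parents A vs B, hybrid vs A, hybrid vs B.
#'
#' @param call_pp `de_calls` for parent A vs parent B (`up` means A > B).
#' @param call_fa `de_calls` for hybrid vs parent A.
#' @param call_fb `de_calls` for hybrid vs parent B.
#' @return data.frame with columns `gene`, `parent_rel` (`A_gt_B`, `A_lt_B`,
#'   `ns`), `f1_vs_a`, `f1_vs_b` (`gt`, `lt`, `ns`).
#' @export
pattern_from_calls <- function(call_pp, call_fa, call_fb) {
  if (!identical(call_pp$gene, call_fa$gene) ||
      !identical(call_pp$gene, call_fb$gene))
    abort("the three call tables must cover identical genes in the same order")
  rel <- c(up = "A_gt_B", down = "A_lt_B", ns = "ns")
  f1 <- c(up = "gt", down = "lt", ns = "ns")
  data.frame(gene = call_pp$gene,
             parent_rel = unname(rel[call_pp$direction]),
             f1_vs_a = unname(f1[call_fa$direction]),
             f1_vs_b = unname(f1[call_fb$direction]),
             stringsAsFactors = FALSE)
}

#' Map triad patterns to remodeling subcategories
#'
#' A total, deterministic function over all 27 patterns. Patterns not covered
#' by the 13 coherent rules (e.g. F1 above one parent and below the other
#' while the parents do not differ) fall into subcategory 14 ("other").
#'
#' @param pattern data.frame with columns `parent_rel`, `f1_vs_a`, `f1_vs_b`
#'   (as produced by [pattern_from_calls]); extra columns are carried through.
#' @return The input with columns `subcategory` (1..14), `major` (`OPG`,
#'   `BPG`, `AEG`, `conserved`, `other`) and `biased_parent` (`A`, `B`,
#'   `none`) appended.
#' @export
class_from_pattern <- function(pattern) {
  need <- c("parent_rel", "f1_vs_a", "f1_vs_b")
  assert_that(all(need %in% names(pattern)), "pattern lacks relation columns")
  assert_that(all(pattern$parent_rel %in% c("A_gt_B", "A_lt_B", "ns")) &&
                all(pattern$f1_vs_a %in% c("gt", "lt", "ns")) &&
                all(pattern$f1_vs_b %in% c("gt", "lt", "ns")),
              "invalid relation code in pattern")
  key <- function(df) paste(df$parent_rel, df$f1_vs_a, df$f1_vs_b)
  idx <- match(key(pattern), key(.class_rules))
  subcategory <- ifelse(is.na(idx), 14L, .class_rules$subcategory[idx])
  out <- pattern
  out$subcategory <- as.integer(subcategory)
  out$major <- .major_of(out$subcategory)
  out$biased_parent <- .biased_of(out$subcategory)
  out
}

#' Classify every gene of one hybrid's triad
#'
#' Runs the three pairwise DE comparisons for the hybrid against its crossing
#' combination's canonical parent pair and maps each gene's pattern to a
#' remodeling subcategory. With `method = "lfc"` the calls are deterministic
#' fold-change calls on genotype means, appropriate for noise-free matrices.
#'
#' @param expr a `triad_expr` (typically after [filter_low_expression]).
#' @param design a [triad_design].
#' @param hybrid hybrid genotype label.
#' @param ... passed to [test_pair] (`method`, thresholds, pseudocount).
#' @return data.frame of class `class_assignment`: one row per gene with
#'   columns `gene`, `hybrid`, `parent_a`, `parent_b`, `subcategory`, `major`,
#'   `biased_parent`.
#' @export
classify_hybrid <- function(expr, design, hybrid, ...) {
  par <- canonical_parents(design, hybrid)
  call_pp <- test_pair(expr, design, par[["parent_a"]], par[["parent_b"]], ...)
  call_fa <- test_pair(expr, design, hybrid, par[["parent_a"]], ...)
  call_fb <- test_pair(expr, design, hybrid, par[["parent_b"]], ...)
  pattern <- pattern_from_calls(call_pp, call_fa, call_fb)
  cls <- class_from_pattern(pattern)
  out <- data.frame(gene = cls$gene, hybrid = hybrid,
                    parent_a = par[["parent_a"]], parent_b = par[["parent_b"]],
                    subcategory = cls$subcategory, major = cls$major,
                    biased_parent = cls$biased_parent,
                    stringsAsFactors = FALSE)
  class(out) <- c("class_assignment", "data.frame")
  out
}

#' Classify a genotype-mean matrix directly
#'
#' Deterministic fold-change classification of a gene x genotype mean matrix
#' (one column per genotype, no replicates), used to verify planted
#' subcategories on noise-free simulated means.
#'
#' @param means numeric gene x genotype matrix.
#' @param parent_a,parent_b,hybrid genotype column names of the triad.
#' @param lfc_threshold strict |log2 fold change| cutoff (default 1).
#' @param pseudocount added before the ratio (default 1).
#' @return `class_assignment` data.frame as in [classify_hybrid].
#' @export
classify_means <- function(means, parent_a, parent_b, hybrid,
                           lfc_threshold = 1, pseudocount = 1) {
  assert_that(all(c(parent_a, parent_b, hybrid) %in% colnames(means)),
              "triad genotypes missing from mean matrix")
  rel <- function(a, b) {
    lfc <- log2((means[, a] + pseudocount) / (means[, b] + pseudocount))
    ifelse(lfc > lfc_threshold, "gt", ifelse(lfc < -lfc_threshold, "lt", "ns"))
  }
  pr <- rel(parent_a, parent_b)
  pattern <- data.frame(
    gene = rownames(means),
    parent_rel = ifelse(pr == "gt", "A_gt_B", ifelse(pr == "lt", "A_lt_B", "ns")),
    f1_vs_a = rel(hybrid, parent_a),
    f1_vs_b = rel(hybrid, parent_b),
    stringsAsFactors = FALSE)
  cls <- class_from_pattern(pattern)
  out <- data.frame(gene = cls$gene, hybrid = hybrid,
                    parent_a = parent_a, parent_b = parent_b,
                    subcategory = cls$subcategory, major = cls$major,
                    biased_parent = cls$biased_parent,
                    stringsAsFactors = FALSE)
  class(out) <- c("class_assignment", "data.frame")
  out
}

#' Classify all hybrids of a design
#' @param expr a `triad_expr`.
#' @param design a [triad_design].
#' @param ... passed to [classify_hybrid].
#' @return One `class_assignment` data.frame covering every hybrid.
#' @export
classify_all <- function(expr, design, ...) {
  out <- do.call(rbind, lapply(design_hybrids(design), function(h) {
    classify_hybrid(expr, design, h, ...)
  }))
  class(out) <- c("class_assignment", "data.frame")
  out
}

#' Subcategory counts of a class assignment
#' @param assign a `class_assignment`.
#' @return data.frame with columns `hybrid`, `subcategory`, `major`, `n`.
#' @export
class_summary <- function(assign) {
  tab <- as.data.frame(table(hybrid = assign$hybrid,
                             subcategory = assign$subcategory),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L | TRUE, ]
  tab$subcategory <- as.integer(tab$subcategory)
  tab$major <- .major_of(tab$subcategory)
  names(tab)[names(tab) == "Freq"] <- "n"
  tab[order(tab$hybrid, tab$subcategory), c("hybrid", "subcategory", "major", "n")]
}

#' Reciprocal-consistent remodeling genes (ReCGs)
#'
#' Genes assigned the identical remodeling subcategory in both reciprocal
#' hybrids of a crossing combination, excluding the doubly conserved
#' (subcategory 13) genes, which show no remodeling to be consistent about.
#' Both assignments must be classified against the same canonical parent
#' orientation (guaranteed when both come from [classify_hybrid] on one
#' design).
#'
#' @param assign_x,assign_y `class_assignment` tables for the two reciprocal
#'   hybrids, covering the same gene universe.
#' @return data.frame with columns `gene` and `subcategory` of the shared
#'   remodeling class.
#' @export
reciprocal_consistent <- function(assign_x, assign_y) {
  if (!setequal(assign_x$gene, assign_y$gene))
    abort("assignments cover different gene universes")
  if (!identical(unique(assign_x$parent_a), unique(assign_y$parent_a)) ||
      !identical(unique(assign_x$parent_b), unique(assign_y$parent_b)))
    abort("assignments use different parent orientations")
  y <- assign_y[match(assign_x$gene, assign_y$gene), ]
  same <- assign_x$subcategory == y$subcategory & assign_x$subcategory != 13L
  data.frame(gene = assign_x$gene[same],
             subcategory = assign_x$subcategory[same],
             stringsAsFactors = FALSE)
}
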