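# Shared in-code fixtures: tiny designs, expression matrices built from
# genotype means, and hand-made DE call tables.

sim_genotypes <- c("P1", "P2", "P3", "F12", "F21", "F13", "F31")
sim_hybrids <- c("F12", "F21", "F13", "F31")

# expression matrix whose replicates are exact copies of given genotype means
expr_from_means <- function(means, design, replicates = 2L) {
  samples <- design$samples
  fpkm <- means[, samples$genotype, drop = FALSE]
  colnames(fpkm) <- samples$sample
  expression_matrix(fpkm)
}

# two-genotype design for simple pairwise tests
pair_design <- function(replicates = 3L, genotypes = c("A", "B")) {
  triad_design(
    samples = data.frame(
      sample = paste(rep(genotypes, each = replicates),
                     seq_len(replicates), sep = "_"),
      genotype = rep(genotypes, each = replicates)),
    genotypes = data.frame(genotype = genotypes, role = "parent",
                           maternal = NA_character_,
                           paternal = NA_character_))
}

# expression matrix with explicit replicate values per genotype
expr_from_values <- function(values, design) {
  # values: named list genotype -> numeric replicate vector, same gene count
  samples <- design$samples
  cols <- lapply(seq_len(nrow(samples)), function(i) {
    g <- samples$genotype[i]
    rep_idx <- samples$replicate[i]
    vapply(values, function(v) v[[g]][rep_idx], numeric(1L))
  })
  fpkm <- do.call(cbind, cols)
  dimnames(fpkm) <- list(names(values), samples$sample)
  expression_matrix(fpkm)
}

# hand-made DE call table
make_call <- function(genes, directions, group_a, group_b) {
  lfc <- ifelse(directions == "up", 2, ifelse(directions == "down", -2, 0))
  structure(
    data.frame(gene = genes, group_a = group_a, group_b = group_b,
               log2fc = lfc, p = ifelse(directions == "ns", 1, 0.001),
               direction = directions, stringsAsFactors = FALSE),
    class = c("de_calls", "data.frame"))
}

# all 27 triad patterns
all_patterns <- function() {
  expand.grid(parent_rel = c("A_gt_B", "A_lt_B", "ns"),
              f1_vs_a = c("gt", "lt", "ns"),
              f1_vs_b = c("gt", "lt", "ns"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# independent brute-force classifier: decides the subcategory of one pattern
# from the verbal definitions (transgressive / dominant / additive /
# conserved), written without reference to the package's rule table
oracle_class <- function(pr, fa, fb) {
  if (pr == "ns" && fa == "ns" && fb == "ns") return(13L)
  if (fa == "gt" && fb == "gt")               # above both parents
    return(switch(pr, ns = 1L, A_gt_B = 2L, A_lt_B = 3L))
  if (fa == "lt" && fb == "lt")               # below both parents
    return(switch(pr, ns = 6L, A_gt_B = 7L, A_lt_B = 8L))
  if (pr == "A_gt_B" && fa == "ns" && fb == "gt") return(4L)  # = high parent A
  if (pr == "A_lt_B" && fb == "ns" && fa == "gt") return(5L)  # = high parent B
  if (pr == "A_gt_B" && fb == "ns" && fa == "lt") return(9L)  # = low parent B
  if (pr == "A_lt_B" && fa == "ns" && fb == "lt") return(10L) # = low parent A
  if (pr == "A_gt_B" && fa == "lt" && fb == "gt") return(11L) # A > F1 > B
  if (pr == "A_lt_B" && fa == "gt" && fb == "lt") return(12L) # B > F1 > A
  14L
}

oracle_major <- function(k) {
  c("OPG", "OPG", "OPG", "BPG", "BPG", "OPG", "OPG", "OPG", "BPG", "BPG",
    "AEG", "AEG", "conserved", "other")[k]
}
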