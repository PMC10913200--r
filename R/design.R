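#' Construct a parent/hybrid crossing design
#'
#' A triad design declares the genotypes of a crossing experiment (parents and
#' F1 hybrids), maps every sequencing sample to its genotype and replicate, and
#' groups reciprocal hybrids into crossing combinations. All downstream triad
#' operations (differential expression, remodeling classification, inheritance
#' sets) consult this object rather than re-deriving structure from labels.
#'
#' Each crossing combination carries one canonical ordered parent pair
#' `(parent_a, parent_b)`, taken from the maternal/paternal order of the
#' first-declared hybrid of that combination. Both reciprocal hybrids are
#' classified against this shared orientation, so that subcategory labels are
#' directly comparable between them.
#'
#' @param samples data.frame with columns `sample` and `genotype`; one row per
#'   sequenced sample. A `replicate` column is added (order of appearance) if
#'   absent.
#' @param genotypes data.frame with columns `genotype`, `role` (one of
#'   `"parent"`, `"hybrid"`), `maternal`, `paternal` (parent genotype labels
#'   for hybrids, `NA` for parents).
#' @return An object of class `triad_design`: a list with elements `samples`,
#'   `genotypes`, and `combinations` (one row per hybrid with its combination
#'   id and canonical parent orientation).
#' @examples
#' design <- example_design(replicates = 3)
#' design$combinations
#' @export
triad_design <- function(samples, genotypes) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  genotypes <- as.data.frame(genotypes, stringsAsFactors = FALSE)
  assert_that(all(c("sample", "genotype") %in% names(samples)),
              "samples needs columns 'sample' and 'genotype'")
  assert_that(all(c("genotype", "role", "maternal", "paternal") %in% names(genotypes)),
              "genotypes needs columns 'genotype', 'role', 'maternal', 'paternal'")
  assert_that(!anyDuplicated(samples$sample), "duplicated sample ids")
  assert_that(!anyDuplicated(genotypes$genotype), "duplicated genotype labels")
  assert_that(all(genotypes$role %in% c("parent", "hybrid")),
              "role must be 'parent' or 'hybrid'")
  assert_that(all(samples$genotype %in% genotypes$genotype),
              "samples reference undeclared genotypes")

  parents <- genotypes$genotype[genotypes$role == "parent"]
  hybrids <- genotypes[genotypes$role == "hybrid", , drop = FALSE]
  for (i in seq_len(nrow(hybrids))) {
    h <- hybrids[i, ]
    if (is.na(h$maternal) || is.na(h$paternal))
      abort(sprintf("hybrid '%s' lacks declared parents", h$genotype))
    if (h$maternal == h$paternal)
      abort(sprintf("hybrid '%s' has identical maternal and paternal parents",
                    h$genotype))
    missing <- setdiff(c(h$maternal, h$paternal), parents)
    if (length(missing))
      abort(sprintf("hybrid '%s' references undeclared parent(s): %s",
                    h$genotype, paste(missing, collapse = ", ")))
  }

  n_rep <- table(samples$genotype)
  few <- names(n_rep)[n_rep < 2L]
  if (length(few))
    abort(sprintf("genotype(s) with fewer than 2 replicate samples: %s",
                  paste(few, collapse = ", ")))
  if (!"replicate" %in% names(samples)) {
    samples$replicate <- stats::ave(seq_len(nrow(samples)), samples$genotype,
                                    FUN = seq_along)
  }

  # combination id = unordered parent pair; canonical orientation = the
  # (maternal, paternal) order of the first hybrid declared for that pair
  comb_key <- vapply(seq_len(nrow(hybrids)), function(i) {
    paste(sort(c(hybrids$maternal[i], hybrids$paternal[i])), collapse = "x")
  }, character(1L))
  combos <- NULL
  for (key in unique(comb_key)) {
    idx <- which(comb_key == key)
    pa <- hybrids$maternal[idx[1L]]
    pb <- hybrids$paternal[idx[1L]]
    combos <- rbind(combos, data.frame(
      combination = key,
      hybrid = hybrids$genotype[idx],
      parent_a = pa, parent_b = pb,
      maternal = hybrids$maternal[idx],
      paternal = hybrids$paternal[idx],
      stringsAsFactors = FALSE))
  }

  structure(list(samples = samples, genotypes = genotypes,
                 combinations = combos %||% data.frame()),
            class = "triad_design")
}

#' @export
print.triad_design <- function(x, ...) {
  n_par <- sum(x$genotypes$role == "parent")
  n_hyb <- sum(x$genotypes$role == "hybrid")
  cat(sprintf("triad_design: %d parents, %d hybrids, %d samples\n",
              n_par, n_hyb, nrow(x$samples)))
  if (nrow(x$combinations)) {
    for (key in unique(x$combinations$combination)) {
      rows <- x$combinations[x$combinations$combination == key, ]
      cat(sprintf("  %s: %s (orientation %s, %s)\n", key,
                  paste(rows$hybrid, collapse = ", "),
                  rows$parent_a[1L], rows$parent_b[1L]))
    }
  }
  invisible(x)
}

#' Read a crossing design from a TSV file
#'
#' Expects columns `sample`, `genotype`, `role`, `maternal`, `paternal`
#' (empty maternal/paternal cells for parents). Lines starting with `#` are
#' ignored.
#'
#' @param path path to a tab-separated design file.
#' @return A validated [triad_design] object.
#' @export
read_design <- function(path) {
  tab <- read_tsv_checked(path)
  need <- c("sample", "genotype", "role", "maternal", "paternal")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    abort(sprintf("design file lacks column(s): %s", paste(missing, collapse = ", ")))
  tab$maternal[tab$maternal == ""] <- NA_character_
  tab$paternal[tab$paternal == ""] <- NA_character_
  genotypes <- unique(tab[, c("genotype", "role", "maternal", "paternal")])
  triad_design(samples = tab[, c("sample", "genotype")], genotypes = genotypes)
}

#' Sample ids belonging to one genotype
#' @param design a [triad_design].
#' @param genotype genotype label.
#' @return Character vector of sample ids.
#' @export
design_samples <- function(design, genotype) {
  assert_that(inherits(design, "triad_design"), "not a triad_design")
  if (!genotype %in% design$genotypes$genotype)
    abort(sprintf("genotype '%s' not declared in design", genotype))
  design$samples$sample[design$samples$genotype == genotype]
}

#' Canonical ordered parents of a hybrid
#'
#' Returns the crossing combination's canonical `(parent_a, parent_b)` pair for
#' the given hybrid (shared by both reciprocal hybrids of the combination).
#'
#' @param design a [triad_design].
#' @param hybrid hybrid genotype label.
#' @return Named character vector with elements `parent_a` and `parent_b`.
#' @export
canonical_parents <- function(design, hybrid) {
  cb <- design$combinations
  row <- cb[cb$hybrid == hybrid, , drop = FALSE]
  if (!nrow(row)) abort(sprintf("'%s' is not a declared hybrid", hybrid))
  c(parent_a = row$parent_a[1L], parent_b = row$parent_b[1L])
}

#' Hybrid genotypes declared in a design
#' @param design a [triad_design].
#' @return Character vector of hybrid labels.
#' @export
design_hybrids <- function(design) {
  design$genotypes$genotype[design$genotypes$role == "hybrid"]
}

#' The standard 7-genotype example design
#'
#' Three parents (P1, P2, P3) and four F1 hybrids in two reciprocal crossing
#' combinations: F12/F21 (P1 x P2) and F13/F31 (P1 x P3). The first index of a
#' hybrid label names its maternal parent.
#'
#' @param replicates replicate samples per genotype (default 3).
#' @return A [triad_design].
#' @export
example_design <- function(replicates = 3L) {
  genotypes <- data.frame(
    genotype = c("P1", "P2", "P3", "F12", "F21", "F13", "F31"),
    role = c(rep("parent", 3L), rep("hybrid", 4L)),
    maternal = c(NA, NA, NA, "P1", "P2", "P1", "P3"),
    paternal = c(NA, NA, NA, "P2", "P1", "P3", "P1"),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = paste(rep(genotypes$genotype, each = replicates),
                   seq_len(replicates), sep = "_"),
    genotype = rep(genotypes$genotype, each = replicates),
    stringsAsFactors = FALSE)
  triad_design(samples, genotypes)
}
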