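# Pairwise differential-expression calling on FPKM triads. The DE rule is the
# study-wide threshold pair: a gene is called up/down only when p < p_threshold
# AND |log2 fold change| strictly exceeds lfc_threshold. Fold changes are
# computed on replicate-mean FPKM with a pseudocount, so a true 2-fold change
# sits exactly on the boundary and is non-significant.

#' Discard genes weakly expressed in every genotype
#'
#' A gene is discarded only when its replicate-mean FPKM is below `threshold`
#' in all genotypes; one genotype at or above the threshold retains the gene.
#'
#' @param expr a `triad_expr`.
#' @param design a [triad_design].
#' @param threshold FPKM cutoff (default 1).
#' @return The filtered `triad_expr`.
#' @export
filter_low_expression <- function(expr, design, threshold = 1.0) {
  if (nrow(expr$fpkm) == 0L) abort("empty expression matrix")
  means <- genotype_means(expr, design)
  keep <- rowSums(means >= threshold) > 0L
  subset_expression(expr, genes = rownames(means)[keep])
}

#' Two-group differential-expression test for one genotype pair
#'
#' The default method is a two-sided Welch t-test on log2(FPKM + pseudocount)
#' replicate values; the reported fold change is
#' log2((mean_A + pseudocount) / (mean_B + pseudocount)) on replicate-mean
#' FPKM. When both groups have zero variance the test degenerates: equal
#' means give p = 1; unequal constant groups fall back to an exact label
#' permutation p-value. Method `"nb_wald"` fits a per-gene negative-binomial
#' GLM on raw counts (requires counts in `expr`); method `"lfc"` makes
#' deterministic calls from genotype means alone (p is 0 when the fold change
#' clears the threshold, 1 otherwise) and is intended for noise-free matrices.
#'
#' @param expr a `triad_expr`.
#' @param design a [triad_design].
#' @param group_a,group_b genotype labels; `group_a` is the fold-change
#'   numerator, so swapping the groups negates `log2fc` and preserves `p`.
#' @param method `"welch_log"` (default), `"nb_wald"` or `"lfc"`.
#' @param pseudocount added to FPKM before log/fold change (default 1).
#' @param p_threshold,lfc_threshold significance thresholds (defaults 0.05
#'   and 1; the fold-change comparison is strict).
#' @return data.frame of class `de_calls` with columns `gene`, `group_a`,
#'   `group_b`, `log2fc`, `p`, `direction` (`up`/`down`/`ns`).
#' @export
test_pair <- function(expr, design, group_a, group_b,
                      method = c("welch_log", "nb_wald", "lfc"),
                      pseudocount = 1, p_threshold = 0.05, lfc_threshold = 1) {
  method <- match.arg(method)
  assert_that(inherits(expr, "triad_expr"), "expr must be a triad_expr")
  sa <- design_samples(design, group_a)
  sb <- design_samples(design, group_b)
  fa <- expr$fpkm[, sa, drop = FALSE]
  fb <- expr$fpkm[, sb, drop = FALSE]
  lfc <- log2((rowMeans(fa) + pseudocount) / (rowMeans(fb) + pseudocount))

  if (method == "lfc") {
    p <- ifelse(abs(lfc) > lfc_threshold, 0, 1)
  } else if (method == "welch_log") {
    if (length(sa) < 2L || length(sb) < 2L)
      abort("welch_log requires >= 2 replicates per group")
    p <- welch_log_p(fa, fb, pseudocount)
  } else {
    if (is.null(expr$counts)) abort("nb_wald requires raw counts")
    if (length(sa) < 2L || length(sb) < 2L)
      abort("nb_wald requires >= 2 replicates per group")
    p <- nb_wald_p(expr$counts[, sa, drop = FALSE],
                   expr$counts[, sb, drop = FALSE])
  }

  sig <- p < p_threshold & abs(lfc) > lfc_threshold
  direction <- ifelse(sig & lfc > 0, "up", ifelse(sig & lfc < 0, "down", "ns"))
  out <- data.frame(gene = rownames(expr$fpkm), group_a = group_a,
                    group_b = group_b, log2fc = lfc, p = p,
                    direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "method") <- method
  class(out) <- c("de_calls", "data.frame")
  out
}

#' Vectorised Welch test on log2(FPKM + pseudocount); degenerate genes (zero
#' variance in both groups) get p = 1 when means agree, else an exact
#' permutation p over replicate labels.
#' @noRd
welch_log_p <- function(fa, fb, pseudocount) {
  xa <- log2(fa + pseudocount)
  xb <- log2(fb + pseudocount)
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- row_vars(xa); vb <- row_vars(xb)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- !is.finite(p)
  if (any(degen)) {
    for (i in which(degen)) {
      p[i] <- if (isTRUE(all.equal(ma[i], mb[i]))) 1
              else perm_p_two_group(c(xa[i, ], xb[i, ]), na)
    }
  }
  p
}

#' Per-gene NB Wald p via glm.nb on counts ~ group with a library-size offset;
#' falls back to quasi-Poisson when the NB fit fails (e.g. all-zero genes).
#' @noRd
nb_wald_p <- function(ca, cb) {
  group <- factor(rep(c("a", "b"), c(ncol(ca), ncol(cb))), levels = c("b", "a"))
  offs <- log(colSums(cbind(ca, cb)) + 1)
  vapply(seq_len(nrow(ca)), function(i) {
    y <- c(ca[i, ], cb[i, ])
    if (all(y == y[1L])) return(1)
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ group + offset(offs))),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- suppressWarnings(stats::glm(y ~ group + offset(offs),
                                         family = stats::quasipoisson()))
    }
    cf <- summary(fit)$coefficients
    if (nrow(cf) < 2L || is.na(cf[2L, 4L])) 1 else cf[2L, 4L]
  }, numeric(1L))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated interface over `stats::p.adjust(method = "BH")`, used for
#' the enrichment-stage significance filter.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  assert_that(is.numeric(p), "p must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression calls for a list of genotype pairs
#'
#' @param expr a `triad_expr` (already filtered).
#' @param design a [triad_design].
#' @param pairs list of length-2 character vectors `(group_a, group_b)`; by
#'   default every parent-parent pair within a combination, every hybrid
#'   versus each of its parents, and the reciprocal hybrid pair of each
#'   combination.
#' @param ... passed to [test_pair].
#' @return Named list of `de_calls` tables, keyed `"A_vs_B"`.
#' @export
de_all_pairs <- function(expr, design, pairs = NULL, ...) {
  pairs <- pairs %||% default_pairs(design)
  out <- lapply(pairs, function(pr) test_pair(expr, design, pr[1L], pr[2L], ...))
  names(out) <- vapply(pairs, function(pr) paste(pr, collapse = "_vs_"),
                       character(1L))
  out
}

#' @noRd
default_pairs <- function(design) {
  cb <- design$combinations
  pairs <- list()
  for (key in unique(cb$combination)) {
    rows <- cb[cb$combination == key, ]
    pairs <- c(pairs, list(c(rows$parent_a[1L], rows$parent_b[1L])))
    for (i in seq_len(nrow(rows))) {
      pairs <- c(pairs, list(c(rows$hybrid[i], rows$parent_a[i])),
                 list(c(rows$hybrid[i], rows$parent_b[i])))
    }
    if (nrow(rows) == 2L)
      pairs <- c(pairs, list(c(rows$hybrid[1L], rows$hybrid[2L])))
  }
  unique(pairs)
}

#' Look up the DE call table for an ordered pair, flipping a stored reverse
#' orientation (negated log2fc, swapped up/down) when needed.
#' @noRd
get_call <- function(de_calls, a, b) {
  key <- paste(a, b, sep = "_vs_")
  if (!is.null(de_calls[[key]])) return(de_calls[[key]])
  rev_key <- paste(b, a, sep = "_vs_")
  if (!is.null(de_calls[[rev_key]])) {
    call <- de_calls[[rev_key]]
    call$log2fc <- -call$log2fc
    call$direction <- c(up = "down", down = "up", ns = "ns")[call$direction]
    call$group_a <- a
    call$group_b <- b
    return(call)
  }
  abort(sprintf("missing differential-expression comparison: %s vs %s", a, b))
}
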