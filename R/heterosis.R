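# Phenotype analytics: mid-parent and better-parent heterosis, one-way ANOVA
# across genotypes, and Pearson trait-trait correlations. Heterosis is
# computed on genotype means over replicates:
#   MPH = 100 * (hybrid mean - mid-parent mean) / mid-parent mean
#   BPH = 100 * (hybrid mean - optimal-parent mean) / optimal-parent mean
# with the optimal parent taken as the larger-mean parent unless a trait is
# flagged smaller-is-better.

#' Mid-parent and better-parent heterosis indices
#'
#' @param pheno phenotype table (columns `genotype`, `trait`, `replicate`,
#'   `value`), e.g. from [read_phenotypes] or [generate_phenotypes].
#' @param design a [triad_design]; indices are computed for every hybrid and
#'   trait with both parents measured.
#' @param larger_is_better named logical vector per trait (default `TRUE` for
#'   every trait): direction used to pick the optimal parent for BPH.
#' @return data.frame with columns `hybrid`, `trait`, `maternal_mean`,
#'   `paternal_mean`, `midparent`, `hybrid_mean`, `mph`, `bph` (percent).
#'   A zero mid-parent mean yields `NA` MPH with a warning.
#' @export
heterosis_indices <- function(pheno, design, larger_is_better = NULL) {
  gm <- stats::aggregate(value ~ genotype + trait, pheno, mean)
  gh <- design$genotypes
  hybrids <- gh[gh$role == "hybrid", , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(hybrids))) {
    h <- hybrids$genotype[i]
    for (tr in unique(gm$trait)) {
      pick <- function(g) gm$value[gm$genotype == g & gm$trait == tr]
      hm <- pick(h); m1 <- pick(hybrids$maternal[i]); m2 <- pick(hybrids$paternal[i])
      if (!length(hm) || !length(m1) || !length(m2)) next
      mid <- (m1 + m2) / 2
      lib <- if (is.null(larger_is_better)) TRUE else
        isTRUE(larger_is_better[[tr]] %||% TRUE)
      best <- if (lib) max(m1, m2) else min(m1, m2)
      if (mid == 0) {
        warning(sprintf("mid-parent mean is 0 for %s/%s; MPH undefined", h, tr))
        mph <- NA_real_
      } else mph <- 100 * (hm - mid) / mid
      bph <- if (best == 0) NA_real_ else 100 * (hm - best) / best
      out <- rbind(out, data.frame(
        hybrid = h, trait = tr, maternal_mean = m1, paternal_mean = m2,
        midparent = mid, hybrid_mean = hm, mph = mph, bph = bph,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' One-way ANOVA of a trait across genotypes
#'
#' Classical fixed-effects one-way F test via `lm`/`anova`, with explicit
#' handling of degenerate inputs: if every group is constant with equal means
#' the result is p = 1; constant groups with unequal means give p = 0 flagged
#' as degenerate.
#'
#' @param pheno phenotype table (long format).
#' @param trait trait name.
#' @return list with `F`, `p`, `df` (between, within), `n_groups`,
#'   `degenerate` flag.
#' @export
one_way_anova <- function(pheno, trait) {
  dat <- pheno[pheno$trait == trait, , drop = FALSE]
  if (!nrow(dat)) abort(sprintf("trait '%s' not in phenotype table", trait))
  dat$genotype <- factor(dat$genotype)
  k <- nlevels(dat$genotype)
  reps <- table(dat$genotype)
  assert_that(k >= 2L && all(reps >= 2L),
              "need >= 2 genotypes with >= 2 replicates each")
  grand <- mean(dat$value)
  gmeans <- tapply(dat$value, dat$genotype, mean)
  ssw <- sum((dat$value - gmeans[dat$genotype])^2)
  ssb <- sum(reps * (gmeans - grand)^2)
  if (ssw == 0) {
    if (ssb == 0)
      return(list(F = NA_real_, p = 1, df = c(k - 1L, nrow(dat) - k),
                  n_groups = k, degenerate = TRUE))
    warning("zero within-group variance with unequal means; p degenerates to 0")
    return(list(F = Inf, p = 0, df = c(k - 1L, nrow(dat) - k),
                n_groups = k, degenerate = TRUE))
  }
  fit <- stats::anova(stats::lm(value ~ genotype, data = dat))
  list(F = fit$`F value`[1L], p = fit$`Pr(>F)`[1L],
       df = fit$Df, n_groups = k, degenerate = FALSE)
}

#' Pearson correlation matrix across traits
#'
#' Observations are genotype x replicate units, paired across traits. A trait
#' with zero variance yields `NA` correlations with a warning.
#'
#' @param pheno phenotype table (long format).
#' @return list with symmetric matrices `r`, `p` (diagonal 1 and 0) and the
#'   observation count `n` per pair.
#' @export
trait_correlation <- function(pheno) {
  wide <- stats::reshape(pheno, direction = "wide",
                         idvar = c("genotype", "replicate"),
                         timevar = "trait")
  traits <- sub("^value\\.", "", grep("^value\\.", names(wide), value = TRUE))
  vals <- as.matrix(wide[, paste0("value.", traits), drop = FALSE])
  colnames(vals) <- traits
  k <- length(traits)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0; diag(n) <- colSums(!is.na(vals))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      x <- vals[, i]; y <- vals[, j]
      ok <- !is.na(x) & !is.na(y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3L) abort("need >= 3 paired observations per trait pair")
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning(sprintf("zero-variance trait in pair %s/%s; r undefined",
                        traits[i], traits[j]))
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, n = n)
}
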