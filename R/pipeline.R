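# End-to-end orchestration: simulate (or read) -> filter -> DE -> classify ->
# inheritance sets -> heterosis -> enrichment/hubs -> methylation link, with a
# machine-readable summary and provenance-stamped TSV outputs. A run is fully
# determined by its configuration (including the seed).

#' Default run configuration
#'
#' @param seed RNG seed for the simulation (default 1).
#' @param n_genes simulated gene count (default 2000).
#' @return Nested configuration list understood by [run_pipeline].
#' @export
default_run_config <- function(seed = 1L, n_genes = 2000L) {
  list(
    simulation = list(n_genes = n_genes, seed = seed),
    thresholds = list(p = 0.05, lfc = 1, fpkm_filter = 1,
                      padj = 0.05, min_count = 5L),
    de_method = "welch_log",
    ratio_mode = "log2",
    meth_aggregate = "sum")
}

#' @noRd
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML path")
  if (is.null(config$input) && is.null(config$simulation))
    abort("config error: need either input paths or a simulation block")
  base <- default_run_config()
  for (nm in setdiff(names(base), "simulation")) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- base[[nm]]
    } else if (is.list(base[[nm]])) {
      for (sub in names(base[[nm]]))
        config[[nm]][[sub]] <- config[[nm]][[sub]] %||% base[[nm]][[sub]]
    }
  }
  if (!is.null(config$seed) && !is.null(config$simulation))
    config$simulation$seed <- config$seed
  config
}

#' @noRd
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' @noRd
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full triad analysis pipeline
#'
#' Executes every stage on simulated data (or on input tables named in
#' `config$input`): low-expression filtering, pairwise DE calling,
#' remodeling classification of every hybrid, reciprocal-consistent genes,
#' the inheritance-set ledger with DIG maternal attribution and overlap
#' statistics, heterosis indices with per-trait ANOVA and trait correlations,
#' term enrichment of the remodeled genes, the hub screen, and the
#' methylation-expression concordance analysis. Identical configuration
#' (including seed) reproduces the result bundle byte-for-byte.
#'
#' @param config nested list or YAML file path; see [default_run_config] for
#'   the recognized fields. `config$input` may name paths `expr`, `design`,
#'   `genes`, `sites`, `pheno`, `terms` to analyse existing tables instead of
#'   simulating.
#' @param out_dir optional directory; when given, all result tables are
#'   written as provenance-stamped TSVs.
#' @return list of class `triadex_run` with the stage outputs and a `summary`
#'   block of key counts.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  config <- load_run_config(config)
  th <- config$thresholds
  seed <- config$simulation$seed %||% 1L
  hash <- config_hash(config)

  if (!is.null(config$input)) {
    inp <- config$input
    dat <- run_stage("input", {
      list(expr = read_expression(inp$expr), design = read_design(inp$design),
           genes = if (!is.null(inp$genes)) read_gene_models(inp$genes),
           sites = if (!is.null(inp$sites)) read_methylation_sites(inp$sites),
           pheno = if (!is.null(inp$pheno)) read_phenotypes(inp$pheno),
           terms = if (!is.null(inp$terms)) read_term_map(inp$terms),
           truth = NULL)
    })
  } else {
    sim_args <- config$simulation
    dat <- run_stage("simulate",
                     simulate_triad_study(do.call(sim_config, sim_args)))
  }
  design <- dat$design

  filtered <- run_stage("filter",
                        filter_low_expression(dat$expr, design,
                                              threshold = th$fpkm_filter))
  de <- run_stage("de", de_all_pairs(filtered, design,
                                     method = config$de_method,
                                     p_threshold = th$p,
                                     lfc_threshold = th$lfc))
  classes <- run_stage("classify", {
    do.call(rbind, lapply(design_hybrids(design), function(h) {
      par <- canonical_parents(design, h)
      pattern <- pattern_from_calls(
        get_call(de, par[["parent_a"]], par[["parent_b"]]),
        get_call(de, h, par[["parent_a"]]),
        get_call(de, h, par[["parent_b"]]))
      cls <- class_from_pattern(pattern)
      data.frame(gene = cls$gene, hybrid = h,
                 parent_a = par[["parent_a"]], parent_b = par[["parent_b"]],
                 subcategory = cls$subcategory, major = cls$major,
                 biased_parent = cls$biased_parent, stringsAsFactors = FALSE)
    }))
  })
  class(classes) <- c("class_assignment", "data.frame")

  recg <- run_stage("recg", {
    out <- list()
    cb <- design$combinations
    for (key in unique(cb$combination)) {
      hy <- cb$hybrid[cb$combination == key]
      if (length(hy) == 2L) {
        out[[key]] <- reciprocal_consistent(
          classes[classes$hybrid == hy[1L], ],
          classes[classes$hybrid == hy[2L], ])
      }
    }
    out
  })

  ledger <- run_stage("sets", build_deg_ledger(de, design))
  maternal <- run_stage("sets", {
    out <- NULL
    cb <- design$combinations
    for (key in unique(cb$combination)) {
      hy <- cb$hybrid[cb$combination == key]
      if (length(hy) == 2L) {
        dig <- ledger$digs[[sprintf("DIG.%s.%s", hy[1L], hy[2L])]]
        if (!is.null(dig) && nrow(dig))
          out <- rbind(out, cbind(combination = key,
                                  maternal_attribution(dig, design,
                                                       hy[1L], hy[2L])))
      }
    }
    out
  })
  overlaps <- run_stage("sets", {
    pairs <- list()
    cb <- design$combinations
    for (key in unique(cb$combination)) {
      hy <- cb$hybrid[cb$combination == key]
      if (length(hy) != 2L) next
      heg <- sprintf("HEG.%s.%s", hy[1L], hy[2L])
      hp <- sprintf("HP.%s.%s", hy[1L], hy[2L])
      dig <- sprintf("DIG.%s.%s", hy[1L], hy[2L])
      peg <- paste0("PEG.", key)
      pairs <- c(pairs, list(c(heg, peg), c(dig, peg), c(dig, hp),
                             c(hp, heg)))
    }
    ledger$overlaps <- overlap_stats(ledger, pairs)
    ledger$overlaps
  })
  ledger$overlaps <- overlaps

  het <- anova_tab <- cors <- NULL
  if (!is.null(dat$pheno)) {
    het <- run_stage("heterosis", heterosis_indices(dat$pheno, design))
    anova_tab <- run_stage("heterosis", {
      do.call(rbind, lapply(unique(dat$pheno$trait), function(tr) {
        a <- one_way_anova(dat$pheno, tr)
        data.frame(trait = tr, F = a$F, p = a$p, stringsAsFactors = FALSE)
      }))
    })
    cors <- run_stage("heterosis", trait_correlation(dat$pheno))
  }

  enr <- hubs <- NULL
  if (!is.null(dat$terms)) {
    background <- gene_ids(filtered)
    study <- intersect(unique(classes$gene[classes$subcategory != 13L]),
                       background)
    enr <- run_stage("enrich",
                     enrich_terms(study, background,
                                  dat$terms[dat$terms$gene %in% background, ],
                                  padj_threshold = th$padj,
                                  min_count = th$min_count))
    hubs <- run_stage("hubs",
                      screen_hubs(classes, filtered, design, dat$terms,
                                  ratio_mode = config$ratio_mode))
  }

  meth <- NULL
  if (!is.null(dat$sites) && !is.null(dat$genes)) {
    meth <- run_stage("methylation", {
      assignments <- assign_regions(dat$sites, dat$genes)
      levels <- region_level(dat$sites, assignments,
                             gene_ids = dat$genes$gene,
                             aggregate = config$meth_aggregate)
      corr <- meth_expr_correlation(levels, filtered, design)
      dms <- do.call(rbind, lapply(design_hybrids(design), function(h)
        classify_dms(dat$sites, design, h)))
      concord <- match_remodeling(classes, dms, assignments)
      feat <- feature_distribution(dms, assignments)
      list(assignments = assignments, levels = levels, correlation = corr,
           dms = dms, concordance = concord, features = feat)
    })
  }

  summary_kv <- run_stage("summary", {
    kv <- data.frame(key = "n_genes_filtered",
                     value = length(gene_ids(filtered)),
                     stringsAsFactors = FALSE)
    cs <- class_summary(classes)
    for (h in unique(cs$hybrid)) {
      for (mj in unique(cs$major)) {
        kv <- rbind(kv, data.frame(
          key = sprintf("n_%s_%s", mj, h),
          value = sum(cs$n[cs$hybrid == h & cs$major == mj])))
      }
    }
    for (key in names(recg))
      kv <- rbind(kv, data.frame(key = sprintf("n_ReCG_%s", key),
                                 value = nrow(recg[[key]])))
    for (nm in names(ledger$sets))
      kv <- rbind(kv, data.frame(key = sprintf("n_%s", nm),
                                 value = length(ledger$sets[[nm]])))
    if (!is.null(meth)) {
      for (lab in c("consistent", "conflicting", "both", "unmatched"))
        kv <- rbind(kv, data.frame(
          key = sprintf("n_concordance_%s", lab),
          value = sum(meth$concordance$label == lab)))
    }
    kv
  })

  bundle <- structure(
    list(config = config, config_hash = hash, seed = seed,
         data = dat, filtered = filtered, de = de, classes = classes,
         recg = recg, ledger = ledger, maternal = maternal,
         heterosis = het, anova = anova_tab, trait_cor = cors,
         enrichment = enr, hubs = hubs, meth = meth, summary = summary_kv),
    class = "triadex_run")

  if (!is.null(out_dir)) {
    tables <- list(classes = classes,
                   class_summary = class_summary(classes),
                   ledger_membership = ledger_tables(ledger)$membership,
                   overlap_stats = overlaps,
                   summary = summary_kv)
    if (!is.null(maternal)) tables$maternal_attribution <- maternal
    if (!is.null(het)) {
      tables$heterosis <- het
      tables$anova <- anova_tab
      tables$trait_correlation <- data.frame(
        trait_a = rep(rownames(cors$r), times = ncol(cors$r)),
        trait_b = rep(colnames(cors$r), each = nrow(cors$r)),
        r = as.vector(cors$r), p = as.vector(cors$p),
        stringsAsFactors = FALSE)
    }
    if (!is.null(enr)) tables$enrichment <- enr
    if (!is.null(hubs)) tables$hubs <- hubs
    if (!is.null(meth)) {
      tables$meth_correlation <- meth$correlation
      tables$dms_classes <- meth$dms
      tables$concordance <- meth$concordance
      tables$feature_distribution <- meth$features
    }
    write_results(tables, out_dir,
                  command = sprintf("run_pipeline config=%s", hash),
                  seed = seed)
  }
  bundle
}

#' @export
print.triadex_run <- function(x, ...) {
  cat(sprintf("triadex_run (seed %s, config %s)\n", x$seed, x$config_hash))
  cat(sprintf("  %d genes after filtering; %d DE comparisons\n",
              length(gene_ids(x$filtered)), length(x$de)))
  cat(sprintf("  %d class assignments over %d hybrids\n",
              nrow(x$classes), length(unique(x$classes$hybrid))))
  if (!is.null(x$meth))
    cat(sprintf("  methylation: %d sites, %d concordance rows\n",
                nrow(x$data$sites), nrow(x$meth$concordance)))
  invisible(x)
}
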