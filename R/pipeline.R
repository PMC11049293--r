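#' Run the full analysis pipeline on a synthetic experiment
#'
#' End-to-end orchestration of the package on simulated data:
#' spectrum-level processing (impurity mixing and correction when a
#' purity matrix is given, iterative normalization, log transform with
#' pruning and weighting, weighted-median rollup), the missing-value
#' filter, per-protein factorial ANOVA with interaction selection and
#' contrasts, PCA with design-association testing and randomization
#' FDR, preranked GSEA on a simulated gene-set collection with one
#' planted set, and interaction-heatmap clustering. Every stage is
#' seeded from the master seed in `config` and records row counts, so
#' identical configurations give identical bundles.
#'
#' @param config A [simulation_config()].
#' @param purity Optional [purity_matrix()]; when given, spectra are
#'   forward-mixed and corrected (exercising the impurity model).
#' @param n_components Principal components to retain.
#' @param n_rand Randomizations for the PC FDR.
#' @param n_perm_gsea Permutations for GSEA.
#' @param n_sets Simulated gene sets (one of them planted on
#'   interaction-true proteins).
#' @param use_spectra Quantify from the spectrum layer (default) or
#'   use the simulated protein matrix directly.
#' @return List of class `tmt_report`: `provenance`, `quant`, `stats`,
#'   `selected`, `contrasts` (TF vs TW and TW vs EW), `pc_model`,
#'   `pc_tests`, `pc_fdr`, `gsea`, `clusters`, `markers`, `truth`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         purity = NULL,
                         n_components = 7,
                         n_rand = 50,
                         n_perm_gsea = 500,
                         n_sets = 30,
                         use_spectra = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  prov <- list(seed = config$seed, stages = list())
  note <- function(stage, ...) {
    prov$stages[[stage]] <<- list(...)
  }

  sim <- simulate_experiment(config)
  note("simulate", n_proteins = config$n_proteins,
       n_spectra = nrow(sim$spectra))

  if (use_spectra) {
    spectra <- sim$spectra
    if (!is.null(purity)) {
      spectra <- impurity_correct(mix_impurities(spectra, purity), purity)
    }
    spectra <- iterative_normalize(spectra)
    spectra <- preprocess_spectra(spectra)
    qm <- rollup_proteins(spectra, sim$design)
    if (config$missing_rate > 0) {
      qm <- inject_missingness(qm, config$missing_rate,
                               seed = config$seed + 1000L)
    }
    note("quantify", n_spectra_used = nrow(spectra),
         n_pruned_shared = attr(spectra, "n_pruned_shared"))
  } else {
    qm <- sim$quant
    note("quantify", source = "simulated matrix")
  }

  qf <- filter_missing(qm, max_missing = 1)
  note("filter", n_retained = attr(qf, "n_retained"),
       n_dropped = attr(qf, "n_dropped"))

  stats <- fit_factorial_anova(qf)
  selected <- select_interaction(stats, alpha = 0.05)
  tf_tw <- contrast_all(stats, "TW", "TF")
  tw_ew <- contrast_all(stats, "EW", "TW")
  note("model", n_fitted = sum(stats$flag == "ok"),
       n_selected = attr(selected, "n_selected"))

  complete_qm <- filter_missing(qf, max_missing = 0)
  pc <- fit_pca(complete_qm, n_components)
  pc_tests <- test_pc_design(pc)
  pc_fdr <- randomization_fdr(complete_qm, n_components, n_rand = n_rand,
                              seed = config$seed + 2000L)
  note("pca", r2x = pc$r2x_cum[pc$n_components],
       n_significant_pairs = pc_fdr$n_observed)

  spec_enr <- c(set001 = "interaction_down_true")
  gene_sets <- simulate_gene_sets(sim$truth, n_sets = n_sets,
                                  enrichment_spec = spec_enr,
                                  seed = config$seed + 3000L)
  ranked <- rank_proteins(tf_tw, source = "signed_logp")
  enr <- run_gsea(ranked, gene_sets, n_perm = n_perm_gsea,
                  seed = config$seed + 4000L)
  note("gsea", n_sets_tested = nrow(enr))

  clusters <- NULL
  if (nrow(selected) >= 2) {
    sel_qm <- qf
    sel_qm$mat <- qf$mat[selected$protein_id, , drop = FALSE]
    scaled <- standard_scale(sel_qm)
    tree <- correlation_ward_tree(scaled)
    clusters <- cut_first_branch(tree, scaled)
    note("cluster", n_cut1 = sum(clusters$cluster == "cut1"),
         n_cut2 = sum(clusters$cluster == "cut2"))
  }

  markers <- marker_presence(qf, intersect(ds_risk_markers(), rownames(qf$mat)))

  structure(list(provenance = prov, quant = qf, stats = stats,
                 selected = selected,
                 contrasts = list(tf_vs_tw = tf_tw, tw_vs_ew = tw_ew),
                 pc_model = pc, pc_tests = pc_tests, pc_fdr = pc_fdr,
                 gsea = enr, clusters = clusters, markers = markers,
                 truth = sim$truth),
            class = "tmt_report")
}

#' @export
print.tmt_report <- function(x, ...) {
  cat("<tmt_report>\n")
  cat("  proteins analysed: ", nrow(x$stats), "\n", sep = "")
  cat("  interaction-selected (p < 0.05): ", nrow(x$selected), "\n", sep = "")
  cat("  PC pairs significant: ", x$pc_fdr$n_observed,
      " (est. FDR ", signif(x$pc_fdr$fdr, 3), ")\n", sep = "")
  cat("  gene sets at q < 0.05: ", sum(x$gsea$q < 0.05), "\n", sep = "")
  invisible(x)
}
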