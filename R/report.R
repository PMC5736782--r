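## End-to-end driver: run every fixture-based analysis stage and bundle the
## results into a machine-readable report.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full fixture-based analysis
#'
#' Executes the whole published-table analysis chain: group summaries and
#' t-tests on the membrane-affinity table, the three headline correlations,
#' KO:WT ratio arithmetic and per-group fold-change summaries on the
#' permeability table, rank-order impact tables, and the OPLS-DA fit on the
#' descriptor table.  Deterministic given the configuration.
#'
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, a JSON report
#'   (`report.json`) plus CSVs of the intermediate tables (scores, loadings,
#'   rank tables, recomputed ratios) are written there.
#' @return The report, an invisible nested list.
#' @export
#' @examples
#' rep <- run_full_analysis()
#' rep$oplsda$misclassified
run_full_analysis <- function(config = analysis_config(), out_dir = NULL) {
  validate_analysis_config(config)
  tab1 <- stage("load_table1", load_descriptor_table("table1"))
  tab2 <- stage("load_table2", load_assay_table("table2", "iam_mlv"))
  tab3 <- stage("load_table3", load_assay_table("table3", "ussing_papp"))

  affinity <- stage("membrane_affinity_summary", {
    by_grp <- function(col) {
      sapply(split(tab2[[col]], tab2$group), mean)
    }
    list(logk_iam_mean = as.list(by_grp("logk_iam")),
         mlv_mean = as.list(by_grp("mlv_partitioning")),
         logk_iam_ttest_p = unpaired_t(tab2$logk_iam[tab2$group == "A"],
                                       tab2$logk_iam[tab2$group == "B"])$p,
         mlv_ttest_p = unpaired_t(
           tab2$mlv_partitioning[tab2$group == "A"],
           tab2$mlv_partitioning[tab2$group == "B"])$p)
  })

  correlations <- stage("correlations", {
    pr <- pearson_cor(tab2$logk_iam, tab2$mlv_partitioning)
    sp1 <- spearman_cor(tab2$logk_iam, tab3$ratio)
    sp2 <- spearman_cor(tab3$papp_wt_e6, tab3$ratio)
    list(pearson_logk_mlv = list(r = pr$coefficient, p = pr$p),
         spearman_logk_ratio = list(rho = sp1$coefficient, p = sp1$p),
         spearman_wtpapp_ratio = list(rho = sp2$coefficient, p = sp2$p))
  })

  ratios <- stage("ratio_summary", {
    recomputed <- unclass(ko_wt_ratio(tab3$papp_ko_e6, tab3$papp_wt_e6))
    fc_all <- group_fold_change(tab3$ratio, tab3$group)
    fc_excl <- group_fold_change(tab3$ratio, tab3$group,
                                 names = tab3$name, exclude = "saquinavir")
    list(recomputed = data.frame(name = tab3$name, group = tab3$group,
                                 printed = tab3$ratio,
                                 recomputed = recomputed,
                                 stringsAsFactors = FALSE),
         group_mean = lapply(fc_all, function(g)
           list(n = g$n, mean = g$mean, sd = g$sd, ci = g$ci)),
         group_mean_excl_saquinavir = lapply(fc_excl, function(g)
           list(n = g$n, mean = g$mean, sd = g$sd, ci = g$ci)))
  })

  rank_tables <- stage("rank_impact", {
    sig <- tab3$p_value < 0.05
    list(logk_vs_intestinal_impact =
           rank_impact_table(tab3$name, tab2$logk_iam, tab3$ratio,
                             significant = sig),
         wtpapp_vs_intestinal_impact =
           rank_impact_table(tab3$name, tab3$papp_wt_e6, tab3$ratio,
                             significant = sig))
  })

  model <- stage("oplsda", {
    fit_oplsda(tab1, tab1$group, n_orth = config$n_orth,
               folds = config$folds, y_codes = config$y_codes,
               threshold = config$threshold)
  })
  exported <- stage("oplsda_export", export_scores_loadings(model))

  report <- list(
    config = list(n_orth_requested = config$n_orth,
                  n_orth_fitted = model$n_orth,
                  folds = config$folds, rng_seed = config$rng_seed),
    membrane_affinity = affinity,
    correlations = correlations,
    ussing_ratios = ratios[c("group_mean", "group_mean_excl_saquinavir")],
    oplsda = list(r2y = model$r2y, q2 = model$q2,
                  n_orth = model$n_orth,
                  misclassified = as.list(model$misclassified)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(ratios$recomputed, file.path(out_dir, "ratios_recomputed.csv"),
              row.names = FALSE)
    write.csv(exported$scores, file.path(out_dir, "oplsda_scores.csv"),
              row.names = FALSE)
    write.csv(exported$loadings, file.path(out_dir, "oplsda_loadings.csv"),
              row.names = FALSE)
    write.csv(rank_tables$logk_vs_intestinal_impact,
              file.path(out_dir, "rank_logk_vs_impact.csv"),
              row.names = FALSE)
    write.csv(rank_tables$wtpapp_vs_intestinal_impact,
              file.path(out_dir, "rank_wtpapp_vs_impact.csv"),
              row.names = FALSE)
  }

  out <- c(report,
           list(ratios_recomputed = ratios$recomputed,
                rank_tables = rank_tables,
                scores = exported$scores, loadings = exported$loadings,
                model = model))
  invisible(out)
}
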