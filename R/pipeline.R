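#' Run the full proteogenomic subtype analysis
#'
#' Chains the pipeline stages on a protein matrix (RNA optional):
#' complete-case filter, the three pairwise protein differential contrasts,
#' arm localization (on RNA contrasts when RNA is supplied, since dosage
#' signals are strongest there; otherwise on the protein contrasts),
#' combined 1p/19q z-scores with group comparisons, the per-arm RNA-protein
#' regression (RNA only), concordance marker selection, cross-validated
#' multinomial classification on the panel, and MAD-based hierarchical
#' clustering. Stage outputs are written as TSV under `out_dir` along with a
#' `report.json`; the run is deterministic given `config$rng_seed`.
#'
#' The classifier stage needs at least two panel features and three tumour
#' classes; with an insufficient panel (e.g. a null cohort) it is skipped
#' with a notice in the report rather than failing the run.
#'
#' @param config an [analysis_config()].
#' @param protein linear or log2 [expr_matrix()] of protein abundance
#'   (linear input is log2-transformed with pseudocount 1).
#' @param samples a [sample_sheet()].
#' @param arms an [arm_annotation()].
#' @param rna optional log2 [expr_matrix()] of RNA expression.
#' @param out_dir output directory, created if needed; `NULL` to skip
#'   writing files.
#' @return the report as a list (also serialized to `report.json`).
#' @export
run_all <- function(config, protein, samples, arms, rna = NULL,
                    out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  check_samples(protein, samples)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  report <- list(config = unclass(config), seed = config$rng_seed,
                 stages = list())

  if (em_scale(protein) == "linear") protein <- log2_transform(protein, 1)
  n_before <- nrow(protein)
  protein <- filter_complete_features(protein)
  report$stages$filter <- list(n_features_in = n_before,
                               n_features_complete = nrow(protein))

  pairs <- list(c("TYPE_I", "TYPE_II"), c("TYPE_I", "TYPE_III"),
                c("TYPE_II", "TYPE_III"))
  de_prot <- lapply(pairs, function(pr) {
    de_test(protein, samples, pr[1], pr[2],
            fc_threshold = config$fc_threshold,
            padj_cutoff = config$padj_protein)
  })
  names(de_prot) <- vapply(de_prot, contrast_name, character(1))
  report$stages$dpa <- lapply(de_prot, function(r) {
    list(n_significant = sum(r$table$significant),
         n_up = sum(r$table$direction == "UP", na.rm = TRUE),
         n_down = sum(r$table$direction == "DOWN", na.rm = TRUE))
  })

  de_for_arms <- de_prot
  if (!is.null(rna)) {
    check_samples(rna, samples)
    rna <- filter_complete_features(rna)
    de_for_arms <- lapply(pairs, function(pr) {
      de_test(rna, samples, pr[1], pr[2],
              fc_threshold = config$fc_threshold,
              padj_cutoff = config$padj_rna)
    })
    names(de_for_arms) <- vapply(de_for_arms, contrast_name, character(1))
  }
  arm_res <- lapply(de_for_arms, localize_de, arms = arms)
  report$stages$arm_localization <- lapply(arm_res, function(tb) {
    stats::setNames(as.list(tb$fisher_p), tb$arm_label)
  })

  scores <- combined_zscore(protein, samples, arms)
  score_tests <- compare_score_groups(scores, samples)
  report$stages$codeletion <- list(
    group_means = vapply(split(scores$z_combined,
                               samples$subtype[match(scores$sample_id,
                                                     samples$sample_id)]),
                         mean, numeric(1)),
    n_features_used = scores$n_features_used[1])

  if (!is.null(rna)) {
    armreg <- arm_rna_protein_regression(rna, protein, samples, arms,
                                         group = "TYPE_I")
    report$stages$rna_protein <- stats::setNames(as.list(armreg$r_squared),
                                                 armreg$arm_label)
  } else {
    armreg <- NULL
    report$stages$rna_protein <- "skipped: no RNA matrix supplied"
  }

  panel <- select_markers(de_prot[[1]], de_prot[[2]], de_prot[[3]])
  report$stages$panel <- list(size = nrow(panel),
                              rule = attr(panel, "rule"))

  tum <- samples[samples$subtype != "NORMAL", ]
  feats <- unique(panel$feature_id)
  if (length(feats) >= 2L &&
      length(unique(tum$subtype)) == 3L &&
      all(table(tum$subtype) >= 2L)) {
    X <- t(em_values(protein)[feats, tum$sample_id, drop = FALSE])
    cvrep <- cross_validate(X, tum$subtype, cv_folds = config$cv_folds,
                            ridge_lambda = config$ridge_lambda,
                            seed = config$rng_seed)
    report$stages$classifier <- list(
      auc_one_vs_rest = as.list(cvrep$auc_ovr),
      auc_pairwise = stats::setNames(
        as.list(cvrep$auc_pairwise$auc),
        paste(cvrep$auc_pairwise$class_a, cvrep$auc_pairwise$class_b,
              sep = "_vs_")))
  } else {
    cvrep <- NULL
    report$stages$classifier <- "skipped: insufficient markers"
  }

  sel <- top_mad_features(protein, config$top_n_mad)
  clus <- hierarchical_cluster(protein, sel, k = 2L)
  report$stages$clustering <- list(n_selected = length(sel),
                                   k2_sizes = as.list(table(clus$cut_labels)))

  if (!is.null(out_dir)) {
    for (nm in names(de_prot)) {
      write_tsv(de_prot[[nm]]$table, file.path(out_dir,
                                               paste0("dpa_", nm, ".tsv")))
    }
    for (nm in names(arm_res)) {
      write_tsv(arm_res[[nm]], file.path(out_dir, paste0("arms_", nm, ".tsv")))
    }
    write_tsv(scores, file.path(out_dir, "codeletion_scores.tsv"))
    write_tsv(score_tests, file.path(out_dir, "codeletion_group_tests.tsv"))
    if (!is.null(armreg)) write_tsv(armreg,
                                    file.path(out_dir, "rna_protein_arms.tsv"))
    write_tsv(tibble::as_tibble(panel), file.path(out_dir, "marker_panel.tsv"))
    if (!is.null(cvrep)) {
      write_tsv(cvrep$auc_pairwise, file.path(out_dir, "auc_pairwise.tsv"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
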