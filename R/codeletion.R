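#' Combined 1p/19q dosage z-score
#'
#' For every feature on the target arms, each sample's log2 value is
#' standardized against the normal-brain reference:
#' `z_fs = (x_fs - mean_f(NORMAL)) / sd_f(NORMAL)` (sd with n-1 denominator).
#' A sample's combined score is the mean (optionally median) of `z_fs` over
#' the target-arm features; strongly negative scores indicate dosage loss of
#' those arms, as expected under 1p/19q codeletion. NORMAL samples are scored
#' too, providing the reference distribution.
#'
#' Note the score is not invariant to per-sample global shifts: sample-level
#' normalization must precede scoring.
#'
#' @param m complete-case log2 [expr_matrix()].
#' @param samples a [sample_sheet()]; needs >= 2 NORMAL samples.
#' @param arms an [arm_annotation()].
#' @param target_arms arm labels to combine (default `c("1p", "19q")`).
#' @param method combine per-feature z by `"mean"` (default) or `"median"`.
#' @return tibble with `sample_id`, `z_combined`, `n_features_used`.
#' @export
combined_zscore <- function(m, samples, arms, target_arms = c("1p", "19q"),
                            method = c("mean", "median")) {
  stopifnot(inherits(m, "expr_matrix"))
  method <- match.arg(method)
  if (em_scale(m) != "log2") stop("expects a log2 matrix", call. = FALSE)
  v <- em_values(m)
  if (anyNA(v)) stop("matrix must be complete-case", call. = FALSE)
  check_samples(m, samples)
  normals <- intersect(samples$sample_id[samples$subtype == "NORMAL"],
                       colnames(v))
  if (length(normals) < 2L) stop(">= 2 NORMAL samples required", call. = FALSE)
  feats <- arms$feature_id[arms$arm_label %in% target_arms]
  feats <- intersect(rownames(v), feats)
  if (length(feats) == 0L) {
    stop("no features on target arms ", paste(target_arms, collapse = ", "),
         call. = FALSE)
  }
  x <- v[feats, , drop = FALSE]
  ref <- x[, normals, drop = FALSE]
  mu <- rowMeans(ref)
  sd <- sqrt(rowSums((ref - mu)^2) / (length(normals) - 1))
  keep <- sd >= 1e-8
  if (!all(keep)) {
    message(sum(!keep), " target-arm feature(s) with zero NORMAL variance excluded")
  }
  if (!any(keep)) stop("all target-arm features have zero NORMAL variance",
                       call. = FALSE)
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sd[keep]
  zc <- if (method == "mean") colMeans(z) else apply(z, 2L, stats::median)
  tibble::tibble(sample_id = colnames(v), z_combined = unname(zc),
                 n_features_used = sum(keep))
}

#' Pairwise group comparison of combined z-scores
#'
#' Welch two-sample tests of `z_combined` between every pair of subtype
#' groups with at least two scored samples, BH-adjusted across the pairs.
#'
#' @param scores output of [combined_zscore()].
#' @param samples a [sample_sheet()].
#' @return tibble with `group_a`, `group_b`, `mean_a`, `mean_b`, `p_value`,
#'   `padj`.
#' @export
compare_score_groups <- function(scores, samples) {
  df <- dplyr::inner_join(scores, samples, by = "sample_id")
  groups <- intersect(SUBTYPES, unique(df$subtype))
  groups <- groups[vapply(groups, function(g) sum(df$subtype == g) >= 2L,
                          logical(1))]
  if (length(groups) < 2L) stop(">= 2 groups with >= 2 samples required",
                                call. = FALSE)
  pairs <- utils::combn(groups, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    za <- df$z_combined[df$subtype == a]
    zb <- df$z_combined[df$subtype == b]
    tt <- stats::t.test(za, zb)
    tibble::tibble(group_a = a, group_b = b,
                   mean_a = mean(za), mean_b = mean(zb),
                   p_value = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$padj <- benjamini_hochberg(out$p_value)
  out
}

#' Per-arm RNA-protein regression
#'
#' Within one subtype group, computes each shared gene's mean RNA and mean
#' protein log2 expression over the group's samples and fits, per chromosome
#' arm, an ordinary least-squares regression of mean protein on mean RNA.
#' Low R^2 quantifies the attenuation of transcript-level dosage effects at
#' the protein level. Arms with fewer than 3 shared genes are skipped with a
#' warning; `"other"` features are not regressed.
#'
#' @param rna,protein log2 [expr_matrix()] objects sharing feature IDs.
#' @param samples a [sample_sheet()].
#' @param arms an [arm_annotation()].
#' @param group subtype whose samples define the means (default `TYPE_I`).
#' @return tibble with `arm_label`, `n_genes`, `slope`, `intercept`,
#'   `r_squared`.
#' @export
arm_rna_protein_regression <- function(rna, protein, samples, arms,
                                       group = "TYPE_I") {
  stopifnot(inherits(rna, "expr_matrix"), inherits(protein, "expr_matrix"))
  ids <- samples$sample_id[samples$subtype == group]
  ids <- intersect(intersect(ids, colnames(rna)), colnames(protein))
  if (length(ids) < 2L) stop("group ", group, " needs >= 2 samples present in both matrices",
                             call. = FALSE)
  shared <- intersect(rownames(rna), rownames(protein))
  lab <- arm_label_of(shared, arms)
  out <- list()
  for (a in setdiff(ARM_LABELS, "other")) {
    genes <- shared[lab == a]
    if (length(genes) < 3L) {
      warning("arm ", a, " skipped: fewer than 3 shared genes", call. = FALSE)
      next
    }
    mx <- rowMeans(em_values(rna)[genes, ids, drop = FALSE])
    my <- rowMeans(em_values(protein)[genes, ids, drop = FALSE])
    fit <- stats::lm(my ~ mx)
    out[[a]] <- tibble::tibble(arm_label = a, n_genes = length(genes),
                               slope = unname(stats::coef(fit)[2L]),
                               intercept = unname(stats::coef(fit)[1L]),
                               r_squared = summary(fit)$r.squared)
  }
  dplyr::bind_rows(out)
}
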