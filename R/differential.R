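#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control: order p ascending, multiply by m/rank,
#' enforce monotonicity from the largest p downwards, cap at 1. Ties are
#' handled by rank with stable ordering. This is the adjustment applied
#' across all features of every differential contrast in the pipeline.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1] with no NA", call. = FALSE)
  }
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Two-group differential test (Welch on log2 values)
#'
#' Per-feature Welch two-sample t-test of group A against group B on a
#' complete-case log2 matrix, BH adjustment across all tested features, and
#' the two study gates applied jointly: a feature is significant iff
#' `|log2fc| > log2(fc_threshold)` (strict) and `padj < padj_cutoff`.
#' `log2fc` is `mean_A - mean_B`, so swapping the groups negates fold changes
#' and leaves p-values unchanged. Degenerate features with zero variance in
#' both groups get p = 1 when the means are equal; with unequal means a
#' machine-epsilon variance floor is applied.
#'
#' This Welch-on-log2 statistic is used for protein abundance and, as a
#' declared surrogate for count-based RNA models, for RNA as well.
#'
#' @param m complete-case log2 [expr_matrix()].
#' @param samples a [sample_sheet()] covering the matrix samples.
#' @param group_a,group_b subtype labels to contrast (A vs B).
#' @param fc_threshold linear fold-change gate (> 1).
#' @param padj_cutoff BH-adjusted p gate.
#' @return a `de_result`: list with `contrast = c(group_a, group_b)`,
#'   the thresholds, and `table`, a tibble with columns `feature_id`,
#'   `log2fc`, `p_value`, `padj`, `significant`, `direction` (`UP`/`DOWN` for
#'   significant features, `NA` otherwise), in input feature order.
#' @export
de_test <- function(m, samples, group_a, group_b,
                    fc_threshold = 1.5, padj_cutoff = 0.05) {
  stopifnot(inherits(m, "expr_matrix"))
  if (em_scale(m) != "log2") stop("de_test expects a log2 matrix", call. = FALSE)
  v <- em_values(m)
  if (anyNA(v)) {
    stop("matrix has missing values; run filter_complete_features() first",
         call. = FALSE)
  }
  check_samples(m, samples)
  if (fc_threshold <= 1) stop("fc_threshold must be > 1", call. = FALSE)
  ids_a <- samples$sample_id[samples$subtype == group_a]
  ids_b <- samples$sample_id[samples$subtype == group_b]
  ids_a <- intersect(ids_a, colnames(v))
  ids_b <- intersect(ids_b, colnames(v))
  if (length(ids_a) < 2L || length(ids_b) < 2L) {
    stop("both groups need >= 2 samples in the matrix (",
         group_a, ": ", length(ids_a), ", ", group_b, ": ", length(ids_b), ")",
         call. = FALSE)
  }
  ws <- welch_stats(v[, ids_a, drop = FALSE], v[, ids_b, drop = FALSE])
  padj <- benjamini_hochberg(ws$p)
  significant <- abs(ws$diff) > log2(fc_threshold) & padj < padj_cutoff
  direction <- ifelse(significant, ifelse(ws$diff > 0, "UP", "DOWN"),
                      NA_character_)
  structure(list(contrast = c(group_a, group_b),
                 fc_threshold = fc_threshold, padj_cutoff = padj_cutoff,
                 table = tibble::tibble(feature_id = rownames(v),
                                        log2fc = unname(ws$diff),
                                        p_value = unname(ws$p),
                                        padj = unname(padj),
                                        significant = unname(significant),
                                        direction = unname(direction))),
            class = "de_result")
}

# vectorised Welch two-sample t-test; matches stats::t.test exactly
welch_stats <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  diff <- ma - mb
  se2 <- va / na + vb / nb
  degenerate_equal <- se2 == 0 & diff == 0
  se2[se2 == 0] <- .Machine$double.eps        # variance floor, unequal means
  tstat <- diff / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  df[!is.finite(df)] <- na + nb - 2           # both variances zero
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate_equal] <- 1
  list(diff = diff, t = tstat, df = df, p = p)
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %s vs %s, %d features, %d significant (|log2FC| > %.3f, padj < %g)\n",
              x$contrast[1], x$contrast[2], nrow(x$table),
              sum(x$table$significant), log2(x$fc_threshold), x$padj_cutoff))
  invisible(x)
}

significant_features <- function(r) {
  r$table[r$table$significant, c("feature_id", "direction")]
}

#' Overlap and directional concordance of two differential result lists
#'
#' A feature overlaps when significant in both results; it is concordant when
#' additionally its direction agrees. Used to ask whether two contrasts (e.g.
#' CIC loss-of-function vs CIC missense subgroup comparisons) carry the same
#' signature.
#'
#' @param r1,r2 `de_result` objects computed on overlapping feature universes.
#' @return list with `n_overlap`, `n_concordant`, `concordance_fraction`
#'   (`NA` when the overlap is empty) and `overlap`, a tibble of overlapping
#'   features with both directions.
#' @export
overlap_de_lists <- function(r1, r2) {
  s1 <- significant_features(r1)
  s2 <- significant_features(r2)
  common <- intersect(s1$feature_id, s2$feature_id)
  d1 <- s1$direction[match(common, s1$feature_id)]
  d2 <- s2$direction[match(common, s2$feature_id)]
  n_overlap <- length(common)
  n_concordant <- sum(d1 == d2)
  list(n_overlap = n_overlap, n_concordant = n_concordant,
       concordance_fraction = if (n_overlap > 0L) n_concordant / n_overlap
                              else NA_real_,
       overlap = tibble::tibble(feature_id = common, direction_1 = d1,
                                direction_2 = d2))
}

#' Classify a CIC variant for subgroup analysis
#'
#' CIC (chromosome 19q) is recurrently mutated in 1p/19q-codeleted
#' oligodendroglioma. Truncating frameshift and stop-gain variants are
#' loss-of-function regardless of position; missense variants count only when
#' they fall in the HMG DNA-binding domain (exon 5) or the C1 motif
#' (exon 20 by default; some annotations place the C1 motif in exon 19, hence
#' the `c1_exon` switch). Everything else is excluded from subgrouping.
#'
#' @param consequence one of `"frameshift"`, `"stop_gained"`, `"missense"`,
#'   `"other"` (vectorised).
#' @param exon exon number (>= 1), recycled against `consequence`.
#' @param c1_exon exon housing the C1 motif, 20 (default) or 19.
#' @return character vector over `{"LOF", "MISSENSE", "EXCLUDED"}`.
#' @export
classify_cic_mutation <- function(consequence, exon, c1_exon = 20L) {
  allowed <- c("frameshift", "stop_gained", "missense", "other")
  if (!all(consequence %in% allowed)) {
    stop("unknown consequence: ",
         paste(setdiff(consequence, allowed), collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  if (!c1_exon %in% c(19L, 20L)) stop("c1_exon must be 19 or 20", call. = FALSE)
  if (any(exon < 1)) stop("exon must be >= 1", call. = FALSE)
  out <- rep("EXCLUDED", length(consequence))
  out[consequence %in% c("frameshift", "stop_gained")] <- "LOF"
  out[consequence == "missense" &
        rep_len(exon, length(consequence)) %in% c(5L, c1_exon)] <- "MISSENSE"
  out
}
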