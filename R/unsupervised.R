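#' Top variable features by median absolute deviation
#'
#' Ranks features by MAD across samples, `median(|x - median(x)|)` (no
#' consistency constant), descending; ties are broken by feature ID in
#' lexicographic order so the selection is deterministic. MAD is invariant to
#' per-feature shifts and scales linearly, making it a robust dispersion
#' choice for heatmap-style structure assessment.
#'
#' @param m complete-case [expr_matrix()].
#' @param n number of features to keep (clamped to the feature count).
#' @return character vector of selected feature IDs, most variable first.
#' @export
top_mad_features <- function(m, n = 500L) {
  stopifnot(inherits(m, "expr_matrix"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  v <- em_values(m)
  if (anyNA(v)) stop("matrix must be complete-case", call. = FALSE)
  mads <- apply(v, 1L, stats::mad, constant = 1)
  ord <- order(-mads, rownames(v), method = "radix")
  rownames(v)[ord][seq_len(min(n, nrow(v)))]
}

#' Hierarchical clustering of samples on selected features
#'
#' Features are z-scored (per feature) on the selected submatrix, then
#' samples are clustered with the chosen distance (Euclidean, or correlation
#' distance `1 - cor`) and linkage. Euclidean distance on z-scored features
#' is the default (as in the common heatmap tools): it is sensitive to the
#' overall magnitude structure that separates tissue types, whereas
#' correlation distance keys on the strongest shared profile axis.
#' Zero-variance features cannot be z-scored and are excluded with a
#' warning. Deterministic; invariant to sample order up to dendrogram
#' relabeling.
#'
#' @param m complete-case [expr_matrix()] with >= 2 samples.
#' @param features feature IDs to cluster on (e.g. from
#'   [top_mad_features()]).
#' @param distance `"euclidean"` (default) or `"correlation"`.
#' @param linkage `"average"` (default), `"complete"` or `"ward"` (ward.D2).
#' @param k number of clusters for label extraction (default 2; the choice
#'   of k is the analyst's, dendrogram inspection is the primary readout).
#' @return a `cluster_result`: list with `selected_features`, `linkage`
#'   (an [stats::hclust] tree), `sample_order` (dendrogram order of sample
#'   IDs) and `cut_labels` (named cluster ids at `k`).
#' @export
hierarchical_cluster <- function(m, features,
                                 distance = c("euclidean", "correlation"),
                                 linkage = c("average", "complete", "ward"),
                                 k = 2L) {
  stopifnot(inherits(m, "expr_matrix"))
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (ncol(m) < 2L) stop(">= 2 samples required", call. = FALSE)
  v <- em_values(m)[features, , drop = FALSE]
  if (anyNA(v)) stop("matrix must be complete-case", call. = FALSE)
  sds <- apply(v, 1L, stats::sd)
  if (any(sds < 1e-8)) {
    warning(sum(sds < 1e-8), " zero-variance feature(s) excluded before z-scoring",
            call. = FALSE)
    v <- v[sds >= 1e-8, , drop = FALSE]
    sds <- sds[sds >= 1e-8]
  }
  if (nrow(v) < 1L) stop("no usable features left", call. = FALSE)
  z <- (v - rowMeans(v)) / sds
  d <- switch(distance,
              euclidean = stats::dist(t(z)),
              correlation = stats::as.dist(1 - stats::cor(z)))
  hc <- stats::hclust(d, method = switch(linkage, ward = "ward.D2", linkage))
  structure(list(selected_features = rownames(z), linkage = hc,
                 sample_order = hc$labels[hc$order],
                 cut_labels = stats::cutree(hc, k = min(k, ncol(z)))),
            class = "cluster_result")
}
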