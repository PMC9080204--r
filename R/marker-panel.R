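#' Select subtype marker proteins by directional concordance
#'
#' Works on the three pairwise differential contrasts between tumour
#' subtypes. Each pair of contrasts shares exactly one subtype, so "significant
#' and directionally concordant in at least two comparisons" resolves, per
#' subtype S, to: significant in BOTH contrasts involving S with the same
#' sign once directions are re-expressed relative to S (a fold change is
#' flipped when S is the second group of the contrast).
#'
#' Two rules are shipped:
#' * `any_two` (default): every subtype satisfying the condition yields an
#'   assignment, so a feature changing stepwise across subtypes (e.g.
#'   monotonically increasing from Type I to Type III) can receive two
#'   assignments such as TYPE_I-DOWN and TYPE_III-UP.
#' * `strict_both`: only features with a unique qualifying subtype are kept,
#'   so each feature appears at most once.
#'
#' `strict_both` output is always a subset of `any_two` output.
#'
#' @param r12 [de_test()] result for subtype 1 vs subtype 2.
#' @param r13 result for subtype 1 vs subtype 3.
#' @param r23 result for subtype 2 vs subtype 3. Contrast orientations are
#'   validated against each other; a mismatch is an error.
#' @param rule `"any_two"` or `"strict_both"`.
#' @return a `marker_panel` tibble with columns `feature_id`, `subtype`,
#'   `direction` (relative to the assigned subtype), `supporting_contrasts`;
#'   the rule is recorded in attribute `"rule"`.
#' @export
select_markers <- function(r12, r13, r23, rule = c("any_two", "strict_both")) {
  rule <- match.arg(rule)
  stopifnot(inherits(r12, "de_result"), inherits(r13, "de_result"),
            inherits(r23, "de_result"))
  s1 <- r12$contrast[1L]; s2 <- r12$contrast[2L]
  if (r13$contrast[1L] != s1 || r23$contrast[1L] != s2 ||
      r13$contrast[2L] != r23$contrast[2L]) {
    stop("contrast orientation mismatch: expected (A vs B), (A vs C), (B vs C)",
         call. = FALSE)
  }
  s3 <- r13$contrast[2L]
  contrasts <- list(r12 = r12, r13 = r13, r23 = r23)
  # contrasts involving each subtype, with the side S occupies
  involvement <- list()
  involvement[[s1]] <- list(c("r12", "A"), c("r13", "A"))
  involvement[[s2]] <- list(c("r12", "B"), c("r23", "A"))
  involvement[[s3]] <- list(c("r13", "B"), c("r23", "B"))

  rel_direction <- function(r, side) {
    # significant features of r with direction relative to the subtype on
    # `side`: +1 up in that subtype, -1 down
    tab <- r$table[r$table$significant, ]
    sgn <- ifelse(tab$direction == "UP", 1L, -1L)
    if (side == "B") sgn <- -sgn
    stats::setNames(sgn, tab$feature_id)
  }

  rows <- list()
  for (s in c(s1, s2, s3)) {
    inv <- involvement[[s]]
    d1 <- rel_direction(contrasts[[inv[[1L]][1L]]], inv[[1L]][2L])
    d2 <- rel_direction(contrasts[[inv[[2L]][1L]]], inv[[2L]][2L])
    common <- intersect(names(d1), names(d2))
    common <- common[d1[common] == d2[common]]
    if (length(common) > 0L) {
      support <- paste(contrast_name(contrasts[[inv[[1L]][1L]]]),
                       contrast_name(contrasts[[inv[[2L]][1L]]]), sep = ";")
      rows[[s]] <- tibble::tibble(
        feature_id = common, subtype = s,
        direction = unname(ifelse(d1[common] > 0L, "UP", "DOWN")),
        supporting_contrasts = support)
    }
  }
  panel <- dplyr::bind_rows(rows)
  if (nrow(panel) == 0L) {
    panel <- tibble::tibble(feature_id = character(), subtype = character(),
                            direction = character(),
                            supporting_contrasts = character())
  }
  if (rule == "strict_both" && nrow(panel) > 0L) {
    multi <- panel$feature_id[duplicated(panel$feature_id)]
    panel <- panel[!panel$feature_id %in% multi, , drop = FALSE]
  }
  panel <- panel[order(match(panel$subtype, c(s1, s2, s3)), panel$feature_id), ]
  attr(panel, "rule") <- rule
  class(panel) <- c("marker_panel", class(panel))
  panel
}

contrast_name <- function(r) paste(r$contrast, collapse = "_vs_")

#' Summarize a marker panel
#'
#' Counts of panel entries per (subtype, direction), plus the total panel
#' size as attribute `"total"`.
#'
#' @param panel a [select_markers()] panel.
#' @return tibble with `subtype`, `direction`, `n`.
#' @export
summarize_panel <- function(panel) {
  counts <- dplyr::count(tibble::as_tibble(panel), subtype, direction,
                         name = "n")
  attr(counts, "total") <- nrow(panel)
  counts
}

#' Precision and recall of a panel against planted truth
#'
#' Compares selected (feature, subtype, direction) assignments to the
#' planted-marker ground truth from [simulate_cohort()]. A selected entry is
#' a marker true positive when the feature was planted for that subtype with
#' the same direction; `recall` is the fraction of planted markers recovered.
#'
#' The generator plants a second subtype-specific effect besides the
#' markers: the 1p/19q dosage down-shift in TYPE_I. A 1p/19q feature
#' selected as TYPE_I-DOWN is therefore a correct detection of a planted
#' effect, not a selection error, and such entries are reported separately
#' as `n_dosage_explained`. `precision_markers` treats them as false
#' positives (planted markers are the only truth); `precision` counts any
#' planted effect — marker or dosage — as a true detection and is the
#' headline selection-accuracy metric.
#'
#' @param panel a [select_markers()] panel.
#' @param truth the `truth` list from [simulate_cohort()] (needs
#'   `planted_markers`; `arm_features` enables the dosage accounting).
#' @return list with `precision`, `precision_markers`, `recall`,
#'   `n_selected`, `n_planted`, `n_dosage_explained`.
#' @export
panel_recovery <- function(panel, truth) {
  if (!is.null(truth$planted_markers)) {
    planted_markers <- truth$planted_markers
  } else {
    planted_markers <- truth   # bare planted_markers list also accepted
    truth <- list(planted_markers = planted_markers)
  }
  truth_keys <- unlist(lapply(names(planted_markers), function(s) {
    pm <- planted_markers[[s]]
    paste(pm$feature_id, s, pm$direction)
  }), use.names = FALSE)
  sel_keys <- paste(panel$feature_id, panel$subtype, panel$direction)
  is_tp <- sel_keys %in% truth_keys
  del_feats <- unlist(truth$arm_features[c("1p", "19q")], use.names = FALSE)
  dosage_ok <- !is_tp & panel$feature_id %in% del_feats &
    panel$subtype == "TYPE_I" & panel$direction == "DOWN"
  n_sel <- length(sel_keys)
  list(precision = if (n_sel > 0L) sum(is_tp | dosage_ok) / n_sel else NA_real_,
       precision_markers = if (n_sel > 0L) sum(is_tp) / n_sel else NA_real_,
       recall = if (length(truth_keys) > 0L) sum(is_tp) / length(truth_keys)
                else NA_real_,
       n_selected = n_sel, n_planted = length(truth_keys),
       n_dosage_explained = sum(dosage_ok))
}
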