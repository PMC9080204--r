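#' Localize differential features to chromosome arms
#'
#' Counts significant up- and down-regulated features per arm label
#' (`1p`, `1q`, `19p`, `19q`, `other`) and, per arm, tests the 2x2 table
#' (on-arm vs off-arm) x (down vs up) with a two-sided Fisher exact test.
#' In a 1p/19q-codeleted subtype, genes on the lost arms are expected to be
#' enriched among down-regulated features when contrasted against a
#' 1p/19q-retained subtype; the Fisher test formalizes the up/down ratio
#' comparison, and the raw `down_fraction` is reported alongside.
#'
#' Significant features without an arm annotation are counted under
#' `"other"` and their number is reported via `message()`, never dropped
#' silently. With an empty significant set all counts are zero and p = 1 by
#' convention.
#'
#' @param r a [de_test()] result.
#' @param arms an [arm_annotation()].
#' @return tibble with one row per arm label: `n_up`, `n_down`,
#'   `down_fraction` (`NA` when the arm has no significant features),
#'   `fisher_odds_ratio`, `fisher_p`.
#' @export
localize_de <- function(r, arms) {
  stopifnot(inherits(r, "de_result"))
  sig <- significant_features(r)
  unmapped <- setdiff(sig$feature_id, arms$feature_id)
  if (length(unmapped) > 0L) {
    message(length(unmapped),
            " significant feature(s) lack an arm annotation; counted as 'other'")
  }
  lab <- arm_label_of(sig$feature_id, arms)
  out <- lapply(ARM_LABELS, function(a) {
    on_arm <- lab == a
    n_up <- sum(on_arm & sig$direction == "UP")
    n_down <- sum(on_arm & sig$direction == "DOWN")
    off_up <- sum(!on_arm & sig$direction == "UP")
    off_down <- sum(!on_arm & sig$direction == "DOWN")
    if (nrow(sig) == 0L) {
      or <- NA_real_; p <- 1
    } else {
      ft <- stats::fisher.test(matrix(c(n_down, n_up, off_down, off_up), 2L))
      or <- unname(ft$estimate); p <- ft$p.value
    }
    tibble::tibble(arm_label = a, n_up = n_up, n_down = n_down,
                   down_fraction = if (n_up + n_down > 0L)
                     n_down / (n_up + n_down) else NA_real_,
                   fisher_odds_ratio = or, fisher_p = p)
  })
  dplyr::bind_rows(out)
}
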