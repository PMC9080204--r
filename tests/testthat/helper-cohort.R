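# Shared fixtures, built in code at test time.

# small cohort for fast unit tests (defaults elsewhere exercise full scale)
small_params <- function(seed = 1L, ...) {
  simulation_params(n_features = 1000L, seed = seed, ...)
}

.cohort_cache <- new.env(parent = emptyenv())

# memoised default-scale cohort, reused across test files
default_cohort <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(simulation_params(seed = seed))
  }
  .cohort_cache[[key]]
}

# tiny hand-built expression matrix
toy_matrix <- function(values, scale_tag = "log2",
                       features = sprintf("F%d", seq_len(nrow(values))),
                       samples = sprintf("S%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(features, samples)
  expr_matrix(values, scale_tag)
}

# sheet with two groups of given sizes
two_group_sheet <- function(n_a, n_b, a = "TYPE_I", b = "TYPE_II") {
  sample_sheet(data.frame(
    sample_id = sprintf("S%d", seq_len(n_a + n_b)),
    subtype = rep(c(a, b), c(n_a, n_b))))
}

# fabricate a de_result with chosen significance/directions, for panel tests
fake_de <- function(contrast, feature_id, sig, direction) {
  structure(list(contrast = contrast, fc_threshold = 1.5, padj_cutoff = 0.05,
                 table = tibble::tibble(
                   feature_id = feature_id,
                   log2fc = ifelse(is.na(direction), 0,
                                   ifelse(direction == "UP", 1, -1)),
                   p_value = ifelse(sig, 1e-6, 0.9),
                   padj = ifelse(sig, 1e-5, 0.95),
                   significant = sig,
                   direction = ifelse(sig, direction, NA_character_))),
            class = "de_result")
}
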