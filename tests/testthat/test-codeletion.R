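zscore_fixture <- function() {
  # 4 normals with known per-feature mean/sd, 2 tumour samples
  set.seed(10)
  v <- matrix(rnorm(6 * 20, mean = 5), 20, 6,
              dimnames = list(sprintf("F%02d", 1:20), sprintf("S%d", 1:6)))
  sheet <- sample_sheet(data.frame(
    sample_id = sprintf("S%d", 1:6),
    subtype = c(rep("NORMAL", 4), "TYPE_I", "TYPE_II")))
  ann <- arm_annotation(sprintf("F%02d", 1:20),
                        arm_label = rep(c("1p", "19q", "other", "other"), 5))
  list(v = v, sheet = sheet, ann = ann)
}

test_that("combined z-score is exact on constructed shifts", {
  fx <- zscore_fixture()
  v <- fx$v
  target <- fx$ann$feature_id[fx$ann$arm_label %in% c("1p", "19q")]
  mu <- rowMeans(v[, 1:4]); sd <- apply(v[, 1:4], 1, sd)
  # sample equal to the normal mean on every target feature -> z = 0
  v[target, "S5"] <- mu[target]
  # sample at exactly -1 SD -> z = -1
  v[target, "S6"] <- mu[target] - sd[target]
  sc <- combined_zscore(toy_matrix(v, features = rownames(v),
                                   samples = colnames(v)),
                        fx$sheet, fx$ann)
  expect_equal(sc$z_combined[sc$sample_id == "S5"], 0, tolerance = 1e-12)
  expect_equal(sc$z_combined[sc$sample_id == "S6"], -1, tolerance = 1e-12)
  expect_equal(unique(sc$n_features_used), length(target))
})

test_that("NORMAL group mean z is zero by self-referential centering", {
  co <- simulate_cohort(small_params(seed = 14L))
  sc <- combined_zscore(co$protein, co$samples, co$arms)
  nm <- co$samples$sample_id[co$samples$subtype == "NORMAL"]
  expect_equal(mean(sc$z_combined[sc$sample_id %in% nm]), 0, tolerance = 1e-9)
})

test_that("z-score is sensitive to per-sample global shifts (normalization must precede)", {
  co <- simulate_cohort(small_params(seed = 15L))
  v <- unclass(co$protein)
  v[, 10] <- v[, 10] + 1            # global +1 shift of one tumour sample
  shifted <- expr_matrix(v, "log2")
  s0 <- combined_zscore(co$protein, co$samples, co$arms)
  s1 <- combined_zscore(shifted, co$samples, co$arms)
  id <- colnames(v)[10]
  expect_gt(s1$z_combined[s1$sample_id == id] -
              s0$z_combined[s0$sample_id == id], 0.5)
})

test_that("zero-variance reference features are excluded, all-excluded errors", {
  fx <- zscore_fixture()
  v <- fx$v
  target <- fx$ann$feature_id[fx$ann$arm_label %in% c("1p", "19q")]
  v[target[1], 1:4] <- 7
  expect_message(
    sc <- combined_zscore(toy_matrix(v, features = rownames(v),
                                     samples = colnames(v)), fx$sheet, fx$ann),
    "zero NORMAL variance")
  expect_equal(unique(sc$n_features_used), length(target) - 1L)
  v[target, 1:4] <- 7
  expect_error(suppressMessages(
    combined_zscore(toy_matrix(v, features = rownames(v),
                               samples = colnames(v)), fx$sheet, fx$ann)),
    "zero NORMAL variance")
})

test_that("Type I scores lowest and differs from the other subtypes at defaults", {
  co <- default_cohort(seed = 1L)
  sc <- combined_zscore(co$protein, co$samples, co$arms)
  sub <- co$samples$subtype[match(sc$sample_id, co$samples$sample_id)]
  gm <- tapply(sc$z_combined, sub, mean)
  expect_true(gm[["TYPE_I"]] < gm[["TYPE_II"]])
  expect_true(gm[["TYPE_I"]] < gm[["TYPE_III"]])
  cmp <- compare_score_groups(sc, co$samples)
  expect_lt(cmp$p_value[cmp$group_a == "TYPE_I" & cmp$group_b == "TYPE_II"],
            0.05)
  expect_lt(cmp$p_value[cmp$group_a == "TYPE_I" & cmp$group_b == "TYPE_III"],
            0.05)
})

test_that("all tumour groups shifted below normal are each flagged against NORMAL", {
  co <- simulate_cohort(small_params(seed = 20L))
  v <- unclass(co$protein)
  target <- co$arms$feature_id[co$arms$arm_label %in% c("1p", "19q")]
  tum <- co$samples$sample_id[co$samples$subtype != "NORMAL"]
  v[target, tum] <- v[target, tum] - 0.5
  sc <- combined_zscore(expr_matrix(v, "log2"), co$samples, co$arms)
  cmp <- compare_score_groups(sc, co$samples)
  vs_normal <- cmp[cmp$group_a == "NORMAL", ]
  expect_equal(nrow(vs_normal), 3L)
  expect_true(all(vs_normal$padj < 0.05))
  expect_true(all(vs_normal$mean_b < vs_normal$mean_a))
})

test_that("identical groups compare with p near 1", {
  sc <- tibble::tibble(sample_id = sprintf("S%d", 1:8),
                       z_combined = rep(c(-1, 1), 4),
                       n_features_used = 10L)
  sheet <- two_group_sheet(4, 4)
  cmp <- compare_score_groups(sc, sheet)
  expect_gt(cmp$p_value, 0.9)
})

test_that("arm regression: identity input gives R2 = slope = 1, intercept 0", {
  co <- simulate_cohort(small_params(seed = 16L))
  # lm warns about an essentially perfect fit here, which is the point
  reg <- suppressWarnings(
    arm_rna_protein_regression(co$rna, co$rna, co$samples, co$arms))
  expect_true(all(abs(reg$r_squared - 1) < 1e-12))
  expect_true(all(abs(reg$slope - 1) < 1e-12))
  expect_true(all(abs(reg$intercept) < 1e-9))
})

test_that("arm regression: shuffled protein decorrelates (R2 < 0.05 at 200+ genes)", {
  co <- simulate_cohort(simulation_params(seed = 17L))
  v <- unclass(co$protein)
  set.seed(1)
  shuf <- v[sample(nrow(v)), ]
  rownames(shuf) <- rownames(v)
  reg <- arm_rna_protein_regression(co$rna, expr_matrix(shuf, "log2"),
                                    co$samples, co$arms)
  big <- reg[reg$n_genes >= 200, ]
  expect_gt(nrow(big), 0)
  expect_true(all(big$r_squared < 0.05))
})

test_that("R2 equals squared Pearson correlation of the mean vectors", {
  co <- simulate_cohort(small_params(seed = 18L))
  reg <- arm_rna_protein_regression(co$rna, co$protein, co$samples, co$arms)
  ids <- co$samples$sample_id[co$samples$subtype == "TYPE_I"]
  for (a in reg$arm_label) {
    genes <- co$arms$feature_id[co$arms$arm_label == a]
    r <- cor(rowMeans(unclass(co$rna)[genes, ids]),
             rowMeans(unclass(co$protein)[genes, ids]))
    expect_equal(reg$r_squared[reg$arm_label == a], r^2, tolerance = 1e-12)
  }
})

test_that("arms with fewer than 3 shared genes are skipped with a warning", {
  co <- simulate_cohort(small_params(seed = 19L))
  keep <- co$arms$feature_id[co$arms$arm_label != "19q"]
  keep <- c(keep, co$arms$feature_id[co$arms$arm_label == "19q"][1:2])
  rna <- expr_matrix(unclass(co$rna)[keep, ], "log2")
  expect_warning(
    reg <- arm_rna_protein_regression(rna, co$protein, co$samples, co$arms),
    "19q")
  expect_false("19q" %in% reg$arm_label)
})
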