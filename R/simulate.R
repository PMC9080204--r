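#' Simulation parameters for the synthetic proteogenomic cohort
#'
#' Defaults emulate the study cohort: 6 normal brain, 21 Type I, 17 Type II
#' and 10 Type III samples; ~6000 complete-case proteins; a subset of
#' features on arms 1p and 19q whose protein abundance is attenuated (not
#' halved) in Type I, with a stronger dosage effect at the RNA level; 20
#' planted up-regulated markers per tumour subtype; Gaussian noise on the
#' log2 scale.
#'
#' Besides the subtype-specific effects, every feature carries a
#' tumour-shared shift (drawn once per feature from `N(0, tumor_shift_sd)`,
#' applied to all tumour samples in both omics). This emulates the broad
#' tumour-tissue-versus-normal-brain expression differences that dominate
#' unsupervised structure in real cohorts, without separating the tumour
#' subtypes from each other (it cancels exactly in tumour-vs-tumour
#' contrasts).
#'
#' The RNA-protein relationship is controlled by `rna_protein_decoupling_sd`,
#' a per-gene protein-level offset. Writing `S` for the gene-level variance
#' shared between the omics within a tumour group (`biological_sd^2 +
#' subtype_shift_sd^2 + tumor_shift_sd^2 = 0.26` at defaults) and `U` for
#' the variance of a group-mean noise term (`noise_sd^2 / n_group`), the
#' across-gene R^2 of mean protein on mean RNA within a group is
#' approximately `S^2 / ((S + U) (S + dec^2 + U))`. The default `dec = 1.0`
#' solves this for R^2 = 0.2, the regime observed for arms 1p/1q/19p/19q;
#' increasing it monotonically decreases R^2.
#'
#' @param n_per_group named integer vector of samples per subtype.
#' @param n_features total number of simulated features.
#' @param frac_1p,frac_19q fraction of features on the codeleted arms.
#' @param frac_1q,frac_19p fraction of features on the retained arms of
#'   chromosomes 1 and 19 (no dosage effect; exercises arm-ratio analyses).
#' @param dosage_effect_protein mean log2 shift of 1p/19q features in TYPE_I
#'   at the protein level.
#' @param dosage_effect_rna same at the RNA level.
#' @param n_markers_per_subtype planted markers per tumour subtype.
#' @param marker_effect log2 up-shift of a marker in its subtype.
#' @param noise_sd residual (measurement) log2 SD, independent per omic and
#'   per sample; the only within-group, across-sample noise source.
#' @param biological_sd SD of the per-feature baseline level, drawn once per
#'   feature and shared between RNA and protein.
#' @param subtype_shift_sd SD of per-feature background subtype shifts
#'   (non-separating structure; set 0 for a fully null cohort).
#' @param tumor_shift_sd SD of the per-feature shift shared by all tumour
#'   samples relative to normal brain (set 0 for a fully null cohort).
#' @param rna_protein_decoupling_sd per-gene protein offset SD (see above).
#' @param run_size samples per simulated mass-spectrometry run, used by
#'   [simulate_missingness()].
#' @param seed integer seed; the cohort is deterministic given the seed.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_per_group = c(NORMAL = 6L, TYPE_I = 21L,
                                              TYPE_II = 17L, TYPE_III = 10L),
                              n_features = 6000L,
                              frac_1p = 0.045, frac_19q = 0.035,
                              frac_1q = 0.055, frac_19p = 0.03,
                              dosage_effect_protein = -0.35,
                              dosage_effect_rna = -1.0,
                              n_markers_per_subtype = 20L,
                              marker_effect = 1.2,
                              noise_sd = 0.5, biological_sd = 0.3,
                              subtype_shift_sd = 0.1, tumor_shift_sd = 0.4,
                              rna_protein_decoupling_sd = 1.0,
                              run_size = 9L, seed = 1L) {
  if (!all(SUBTYPES %in% names(n_per_group))) {
    stop("n_per_group must name all of ", paste(SUBTYPES, collapse = ", "),
         call. = FALSE)
  }
  if (any(n_per_group < 2L)) {
    stop("every group needs >= 2 samples (variance estimates downstream)",
         call. = FALSE)
  }
  if (n_features < 1L) stop("n_features must be positive", call. = FALSE)
  fr <- c(frac_1p, frac_19q, frac_1q, frac_19p)
  if (any(fr <= 0) || any(fr >= 1) || sum(fr) >= 1) {
    stop("arm fractions must lie in (0, 1) and sum below 1", call. = FALSE)
  }
  sds <- c(noise_sd, biological_sd, subtype_shift_sd, tumor_shift_sd,
           rna_protein_decoupling_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (n_markers_per_subtype < 0) stop("marker count must be >= 0", call. = FALSE)
  structure(list(n_per_group = n_per_group[SUBTYPES], n_features = as.integer(n_features),
                 frac_1p = frac_1p, frac_19q = frac_19q, frac_1q = frac_1q,
                 frac_19p = frac_19p,
                 dosage_effect_protein = dosage_effect_protein,
                 dosage_effect_rna = dosage_effect_rna,
                 n_markers_per_subtype = as.integer(n_markers_per_subtype),
                 marker_effect = marker_effect, noise_sd = noise_sd,
                 biological_sd = biological_sd,
                 subtype_shift_sd = subtype_shift_sd,
                 tumor_shift_sd = tumor_shift_sd,
                 rna_protein_decoupling_sd = rna_protein_decoupling_sd,
                 run_size = as.integer(run_size), seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate a subtype-labelled proteogenomic cohort
#'
#' Generates matched protein and RNA log2 matrices with the structure the
#' downstream analyses assume. Per feature f and sample s,
#' `log2 abundance = baseline_f + subtype_shift + dosage (1p/19q features in
#' TYPE_I) + marker effect (planted markers in their subtype) +
#' N(0, noise_sd)`. The baseline and subtype shifts are shared between the
#' omics; the protein matrix additionally carries a per-gene decoupling
#' offset so that across-gene RNA-protein correlation is attenuated, and the
#' dosage effect is weaker at the protein level (codeletion is visible but
#' attenuated in the proteome).
#'
#' @param params a [simulation_params()] object.
#' @return list with elements `protein`, `rna` (log2 [expr_matrix()]),
#'   `samples` ([sample_sheet()]), `arms` ([arm_annotation()]) and `truth`
#'   (list: `planted_markers` per subtype, `arm_features` per arm label,
#'   `true_labels`).
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  set.seed(p$seed)

  subtype <- rep(names(p$n_per_group), p$n_per_group)
  sample_id <- unlist(lapply(names(p$n_per_group), function(g) {
    sprintf("%s_%02d", g, seq_len(p$n_per_group[[g]]))
  }), use.names = FALSE)
  ns <- length(sample_id)
  nf <- p$n_features
  feature_id <- sprintf("FEAT_%05d", seq_len(nf))

  # arm assignment: random disjoint blocks on 1p/19q/1q/19p, rest "other"
  n_arm <- round(nf * c(`1p` = p$frac_1p, `19q` = p$frac_19q,
                        `1q` = p$frac_1q, `19p` = p$frac_19p))
  perm <- sample.int(nf)
  arm_features <- list()
  at <- 0L
  for (a in names(n_arm)) {
    arm_features[[a]] <- sort(feature_id[perm[at + seq_len(n_arm[[a]])]])
    at <- at + n_arm[[a]]
  }
  arm_label <- rep("other", nf)
  for (a in names(arm_features)) {
    arm_label[match(arm_features[[a]], feature_id)] <- a
  }
  on_del <- arm_label %in% c("1p", "19q")

  # planted markers: disjoint, drawn from off-arm features
  other_idx <- perm[(at + 1L):nf]
  need <- 3L * p$n_markers_per_subtype
  if (need > length(other_idx)) stop("not enough off-arm features for markers",
                                     call. = FALSE)
  marker_idx <- other_idx[seq_len(need)]
  planted_markers <- list()
  is_marker <- matrix(FALSE, nf, 3L,
                      dimnames = list(feature_id, TUMOUR_SUBTYPES))
  for (i in seq_along(TUMOUR_SUBTYPES)) {
    idx <- marker_idx[(i - 1L) * p$n_markers_per_subtype +
                        seq_len(p$n_markers_per_subtype)]
    is_marker[idx, i] <- TRUE
    planted_markers[[TUMOUR_SUBTYPES[i]]] <-
      tibble::tibble(feature_id = sort(feature_id[idx]), direction = "UP")
  }

  baseline <- stats::rnorm(nf, 0, p$biological_sd)
  decouple <- stats::rnorm(nf, 0, p$rna_protein_decoupling_sd)
  tumor_shift <- stats::rnorm(nf, 0, p$tumor_shift_sd)
  shift <- matrix(stats::rnorm(nf * 3L, 0, p$subtype_shift_sd), nf, 3L,
                  dimnames = list(NULL, TUMOUR_SUBTYPES))

  group_col <- function(s) {
    # per-feature mean components for a sample of subtype s, excluding omic
    # specifics (dosage magnitude / decoupling / baseline offsets)
    if (s == "NORMAL") rep(0, nf)
    else tumor_shift + shift[, s] + is_marker[, s] * p$marker_effect
  }
  mu_common <- vapply(subtype, group_col, numeric(nf))
  dos <- outer(on_del, subtype == "TYPE_I")

  eps_rna <- matrix(stats::rnorm(nf * ns, 0, p$noise_sd), nf, ns)
  eps_prot <- matrix(stats::rnorm(nf * ns, 0, p$noise_sd), nf, ns)

  rna_vals <- 8 + baseline + mu_common + dos * p$dosage_effect_rna + eps_rna
  prot_vals <- 20 + baseline + decouple + mu_common +
    dos * p$dosage_effect_protein + eps_prot
  dimnames(rna_vals) <- dimnames(prot_vals) <- list(feature_id, sample_id)

  cic <- rep(NA_character_, ns)
  t1 <- which(subtype == "TYPE_I")
  cic[t1] <- rep_len(c("WT", "LOF", "MISSENSE"), length(t1))
  samples <- sample_sheet(tibble::tibble(
    sample_id = sample_id, subtype = subtype, cic_status = cic,
    grade = NA_character_))

  list(protein = expr_matrix(prot_vals, "log2"),
       rna = expr_matrix(rna_vals, "log2"),
       samples = samples,
       arms = arm_annotation(feature_id, arm_label = arm_label),
       truth = list(planted_markers = planted_markers,
                    arm_features = arm_features,
                    true_labels = samples))
}

#' Impose run-level missingness on a matrix
#'
#' Samples are grouped into consecutive simulated mass-spectrometry runs of
#' `run_size` samples; within each run, a random fraction of features is
#' blanked for every sample of that run, mimicking per-run identification
#' dropout. This gives [filter_complete_features()] nontrivial work.
#'
#' @param m an [expr_matrix()].
#' @param frac_runs_affected fraction of features dropped per run, in `[0, 1]`.
#' @param seed integer seed. It is scrambled internally (LCG step) before
#'   seeding, so that passing the same seed used for [simulate_cohort()]
#'   does not replay the cohort's random stream — with a shared stream the
#'   first dropout draw would coincide with the cohort's arm-assignment
#'   permutation and blank exactly the 1p/19q features.
#' @param run_size samples per run (default 9).
#' @return an [expr_matrix()] with missing entries.
#' @export
simulate_missingness <- function(m, frac_runs_affected, seed = 1L,
                                 run_size = 9L) {
  stopifnot(inherits(m, "expr_matrix"))
  if (frac_runs_affected < 0 || frac_runs_affected > 1) {
    stop("frac_runs_affected must lie in [0, 1]", call. = FALSE)
  }
  v <- em_values(m)
  set.seed(as.integer((as.numeric(seed) * 1103515245 + 12345) %% 2147483647))
  run <- ceiling(seq_len(ncol(v)) / run_size)
  n_drop <- round(frac_runs_affected * nrow(v))
  for (r in unique(run)) {
    drop <- sample.int(nrow(v), n_drop)
    v[drop, run == r] <- NA_real_
  }
  expr_matrix(v, em_scale(m))
}
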