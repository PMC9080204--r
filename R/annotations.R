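SUBTYPES <- c("NORMAL", "TYPE_I", "TYPE_II", "TYPE_III")
TUMOUR_SUBTYPES <- c("TYPE_I", "TYPE_II", "TYPE_III")
CIC_LEVELS <- c("WT", "LOF", "MISSENSE")
ARM_LABELS <- c("1p", "1q", "19p", "19q", "other")

#' Construct and validate a sample sheet
#'
#' One row per sample with the molecular subtype label: `NORMAL` (normal
#' brain), `TYPE_I` (IDH-mutant, 1p/19q-codeleted oligodendroglioma),
#' `TYPE_II` (IDH-mutant, 1p/19q-retained astrocytoma) or `TYPE_III`
#' (IDH-wildtype). CIC mutation status, when known, is only meaningful within
#' Type I tumours (CIC sits on 19q and is recurrently mutated in
#' oligodendroglioma), so a non-missing `cic_status` outside `TYPE_I` is
#' rejected.
#'
#' @param df data frame with columns `sample_id`, `subtype`, and optionally
#'   `cic_status` (`WT`/`LOF`/`MISSENSE`/`NA`) and `grade` (`II`/`III`/`IV`/`NA`).
#' @return a validated tibble.
#' @export
sample_sheet <- function(df) {
  df <- tibble::as_tibble(df)
  req <- c("sample_id", "subtype")
  if (!all(req %in% names(df))) {
    stop("sample sheet needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$subtype %in% SUBTYPES)) {
    stop("subtype must be one of ", paste(SUBTYPES, collapse = ", "),
         call. = FALSE)
  }
  if (!"cic_status" %in% names(df)) df$cic_status <- NA_character_
  df$cic_status[df$cic_status %in% c("NA", "")] <- NA_character_
  ok <- is.na(df$cic_status) | df$cic_status %in% CIC_LEVELS
  if (!all(ok)) stop("cic_status must be WT, LOF, MISSENSE or NA", call. = FALSE)
  bad <- !is.na(df$cic_status) & df$subtype != "TYPE_I"
  if (any(bad)) {
    stop("cic_status may only be set for TYPE_I samples (offending: ",
         paste(df$sample_id[bad], collapse = ", "), ")", call. = FALSE)
  }
  if (!"grade" %in% names(df)) df$grade <- NA_character_
  df$grade[df$grade %in% c("NA", "")] <- NA_character_
  if (!all(is.na(df$grade) | df$grade %in% c("II", "III", "IV"))) {
    stop("grade must be II, III, IV or NA", call. = FALSE)
  }
  df[, c("sample_id", "subtype", "cic_status", "grade")]
}

#' Read a sample sheet from CSV
#'
#' Expected columns: `sample_id,subtype,cic_status,grade`.
#'
#' @param path CSV file path.
#' @return a validated tibble (see [sample_sheet()]).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sample_sheet(df)
}

#' Construct a feature-to-chromosome-arm annotation
#'
#' Maps each feature to an arm label. Features on chromosomes 1 and 19 get
#' `"1p"`, `"1q"`, `"19p"` or `"19q"`; everything else is `"other"`. The map
#' is a function: one arm label per feature.
#'
#' @param feature_id character vector of feature IDs.
#' @param chrom chromosome (with or without a `chr` prefix); ignored when
#'   `arm_label` is given directly.
#' @param arm `"p"` or `"q"`; ignored when `arm_label` is given.
#' @param arm_label optionally, pre-resolved labels from
#'   `c("1p","1q","19p","19q","other")`.
#' @return tibble with columns `feature_id`, `arm_label`.
#' @export
arm_annotation <- function(feature_id, chrom = NULL, arm = NULL,
                           arm_label = NULL) {
  if (anyDuplicated(feature_id)) {
    stop("arm annotation must map each feature once; duplicated: ",
         paste(unique(feature_id[duplicated(feature_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(arm_label)) {
    if (is.null(chrom) || is.null(arm)) {
      stop("supply either arm_label or both chrom and arm", call. = FALSE)
    }
    if (!all(arm %in% c("p", "q"))) stop("arm must be 'p' or 'q'", call. = FALSE)
    chrom <- sub("^chr", "", as.character(chrom))
    arm_label <- ifelse(chrom %in% c("1", "19"), paste0(chrom, arm), "other")
  }
  if (!all(arm_label %in% ARM_LABELS)) {
    stop("arm_label must be one of ", paste(ARM_LABELS, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(feature_id = as.character(feature_id),
                 arm_label = as.character(arm_label))
}

#' Read a feature-to-arm annotation
#'
#' Two formats are accepted:
#' * pre-resolved 2-column TSV: `feature_id`, `arm_label`;
#' * BED-like 4-column TSV (`chrom`, `start`, `end`, `feature_id`) together
#'   with `arm_map_path`, a cytoband-style TSV with columns `chrom`, `p_end`
#'   (last base of the p arm). A feature is on the p arm when its interval
#'   ends at or before `p_end`, otherwise on q.
#'
#' @param path annotation file path (TSV, no header for the BED-like form;
#'   header `feature_id<TAB>arm_label` for the resolved form).
#' @param arm_map_path arm boundary map, required for the BED-like form.
#' @return tibble with columns `feature_id`, `arm_label`.
#' @export
read_arm_annotation <- function(path, arm_map_path = NULL) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(first) == 2L) {
    has_header <- identical(first, c("feature_id", "arm_label"))
    df <- utils::read.table(path, sep = "\t", header = has_header,
                            stringsAsFactors = FALSE)
    if (!has_header) names(df) <- c("feature_id", "arm_label")
    return(arm_annotation(df$feature_id, arm_label = df$arm_label))
  }
  if (length(first) != 4L) {
    stop("arm annotation must have 2 (resolved) or 4 (BED-like) columns",
         call. = FALSE)
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "feature_id"))
  if (is.null(arm_map_path)) {
    stop("BED-like annotation requires arm_map_path (chrom, p_end)",
         call. = FALSE)
  }
  amap <- utils::read.table(arm_map_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  if (!all(c("chrom", "p_end") %in% names(amap))) {
    stop("arm map needs columns chrom, p_end", call. = FALSE)
  }
  chrom <- sub("^chr", "", bed$chrom)
  p_end <- amap$p_end[match(chrom, sub("^chr", "", amap$chrom))]
  arm <- ifelse(!is.na(p_end) & bed$end <= p_end, "p", "q")
  arm_annotation(bed$feature_id, chrom = chrom, arm = arm)
}

arm_label_of <- function(feature_id, arms) {
  lab <- arms$arm_label[match(feature_id, arms$feature_id)]
  lab[is.na(lab)] <- "other"
  lab
}

#' Analysis configuration
#'
#' Bundles the tunable thresholds of the pipeline. Defaults reproduce the
#' study conditions: fold-change gate 1.5 for both omics, BH-adjusted p
#' cutoffs 0.01 (RNA differential expression) and 0.05 (protein differential
#' abundance), top 500 features by median absolute deviation for clustering,
#' and ten-fold cross-validation for the subtype classifier.
#'
#' @param fc_threshold linear fold-change cutoff (> 1).
#' @param padj_rna adjusted-p cutoff for RNA DE, in (0, 1).
#' @param padj_protein adjusted-p cutoff for protein DPA, in (0, 1).
#' @param top_n_mad number of most-variable features for clustering.
#' @param cv_folds cross-validation folds (>= 2).
#' @param ridge_lambda non-negative L2 penalty of the multinomial classifier.
#' @param rng_seed integer seed driving all stochastic steps.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(fc_threshold = 1.5, padj_rna = 0.01,
                            padj_protein = 0.05, top_n_mad = 500L,
                            cv_folds = 10L, ridge_lambda = 1.0,
                            rng_seed = 1L) {
  if (fc_threshold <= 1) stop("fc_threshold must be > 1", call. = FALSE)
  for (p in c(padj_rna, padj_protein)) {
    if (p <= 0 || p >= 1) stop("padj cutoffs must lie in (0, 1)", call. = FALSE)
  }
  if (top_n_mad < 1) stop("top_n_mad must be >= 1", call. = FALSE)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  if (ridge_lambda < 0) stop("ridge_lambda must be >= 0", call. = FALSE)
  structure(list(fc_threshold = fc_threshold, padj_rna = padj_rna,
                 padj_protein = padj_protein, top_n_mad = as.integer(top_n_mad),
                 cv_folds = as.integer(cv_folds), ridge_lambda = ridge_lambda,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Fields absent from the file keep their [analysis_config()] defaults;
#' unknown fields are an error.
#'
#' @param path YAML file path.
#' @return an `analysis_config` list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, cfg)
}
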