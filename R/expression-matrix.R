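#' Construct an expression matrix
#'
#' An `expr_matrix` is a features x samples numeric matrix carrying a scale
#' tag. It is the substrate of every stage of the pipeline: protein abundance
#' (TMT reporter intensities, typically pre-normalized upstream) or RNA
#' expression. Missing entries are `NA` and represent features not identified
#' in a given mass-spectrometry run; the pipeline never imputes them, it only
#' filters to complete cases (see [filter_complete_features()]).
#'
#' @param values numeric matrix with unique, non-empty rownames (feature IDs)
#'   and colnames (sample IDs).
#' @param scale_tag `"log2"` (values may be negative) or `"linear"` (all
#'   non-missing values must be >= 0).
#' @return an `expr_matrix`: the matrix with a `scale_tag` attribute.
#' @export
expr_matrix <- function(values, scale_tag = c("log2", "linear")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (nrow(values) > 0L && (is.null(fid) || anyNA(fid) || any(fid == ""))) {
    stop("feature IDs (rownames) must be present and non-empty", call. = FALSE)
  }
  if (ncol(values) > 0L && (is.null(sid) || anyNA(sid) || any(sid == ""))) {
    stop("sample IDs (colnames) must be present and non-empty", call. = FALSE)
  }
  if (anyDuplicated(fid)) {
    stop("duplicated feature IDs: ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicated sample IDs: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (scale_tag == "linear" && any(values < 0, na.rm = TRUE)) {
    stop("linear-scale matrix contains negative values", call. = FALSE)
  }
  structure(values, scale_tag = scale_tag,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples [%s scale, %d missing]\n",
              nrow(x), ncol(x), attr(x, "scale_tag"), sum(is.na(x))))
  invisible(x)
}

em_scale <- function(m) attr(m, "scale_tag")

em_values <- function(m) {
  v <- unclass(m)
  attr(v, "scale_tag") <- NULL
  v
}

#' Read an expression matrix from delimited text
#'
#' First column holds feature IDs, header row holds sample IDs. Tab and comma
#' delimiters are auto-detected from the header line; anything else is an
#' error. Empty cells and `"NA"` denote missing values. Duplicated feature IDs
#' and non-numeric cells are errors (naming the offending row/column), never
#' silently merged or coerced.
#'
#' @param path file path.
#' @param scale_tag scale of the stored values, `"log2"` or `"linear"`.
#' @return an [expr_matrix()].
#' @export
read_matrix <- function(path, scale_tag = c("log2", "linear")) {
  scale_tag <- match.arg(scale_tag)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  delim <- detect_delim(header, path)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) {
    stop("malformed header in ", path,
         ": need a feature-ID column plus at least one sample", call. = FALSE)
  }
  fid <- raw[[1L]]
  if (anyDuplicated(fid)) {
    stop("duplicated feature IDs in ", path, ": ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells_trim <- trimws(cells)
  vals <- suppressWarnings(array(as.numeric(cells_trim), dim = dim(cells)))
  bad <- is.na(vals) & !(cells_trim %in% c("", "NA"))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s' in %s",
                 cells[ij[1L], ij[2L]], fid[ij[1L]],
                 colnames(cells)[ij[2L]], path), call. = FALSE)
  }
  vals[cells_trim %in% c("", "NA")] <- NA_real_
  dimnames(vals) <- list(fid, colnames(cells))
  expr_matrix(vals, scale_tag)
}

detect_delim <- function(header, path) {
  if (grepl("\t", header, fixed = TRUE)) return("\t")
  if (grepl(",", header, fixed = TRUE)) return(",")
  stop("cannot detect delimiter (tab or comma) in ", path, call. = FALSE)
}

#' Write an expression matrix to TSV
#'
#' Values are written with 17 significant digits so that
#' `read_matrix(write_matrix(m))` reproduces `m` bit-identically; missing
#' entries are written as `NA`.
#'
#' @param m an [expr_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- em_values(m)
  chr <- array(sprintf("%.17g", v), dim = dim(v))
  chr[is.na(v)] <- "NA"
  lines <- c(paste(c("feature_id", colnames(v)), collapse = "\t"),
             paste(rownames(v), apply(chr, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Keep only features quantified in every sample
#'
#' Mirrors the complete-case filter applied to multiplexed TMT proteomes:
#' a protein is retained only if it was identified in all mass-spectrometry
#' runs, i.e. its row has no missing entry. Sample set and feature order are
#' unchanged; the operation is idempotent and an empty result is permitted.
#'
#' @param m an [expr_matrix()].
#' @return an [expr_matrix()] containing the complete-case features.
#' @export
filter_complete_features <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- em_values(m)
  keep <- rowSums(is.na(v)) == 0L
  expr_matrix(v[keep, , drop = FALSE], em_scale(m))
}

#' Log2-transform a linear-scale matrix
#'
#' @param m a linear-scale [expr_matrix()].
#' @param pseudocount non-negative offset added before taking log2; must be
#'   positive if the matrix contains zeros.
#' @return a log2-scale [expr_matrix()]; missing entries stay missing.
#' @export
log2_transform <- function(m, pseudocount = 0) {
  stopifnot(inherits(m, "expr_matrix"))
  if (em_scale(m) != "linear") {
    stop("log2_transform expects a linear-scale matrix", call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  v <- em_values(m)
  if (any(v + pseudocount <= 0, na.rm = TRUE)) {
    stop("values + pseudocount must be positive to take log2", call. = FALSE)
  }
  expr_matrix(log2(v + pseudocount), "log2")
}

# Every downstream module calls this: matrices whose samples are not all
# described in the sample sheet are rejected rather than silently subset.
check_samples <- function(m, samples) {
  missing <- setdiff(colnames(m), samples$sample_id)
  if (length(missing) > 0L) {
    stop("matrix samples absent from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
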