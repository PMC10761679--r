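#' Feature-by-sample count matrix with RNA-type and class annotations
#'
#' The central container of the pipeline: an integer matrix of raw read
#' counts (features in rows, samples in columns) together with per-feature
#' RNA-type labels and per-sample class/cohort labels. Normalized views are
#' computed on demand with [rpm()] and [log2rpm()].
#'
#' @param counts integer matrix, features x samples; must have row and
#'   column names and non-negative entries.
#' @param rna_type character vector of RNA-type labels, one per feature
#'   (e.g. "miRNA", "rsRNA").
#' @param sample_class optional character vector of class labels, one per
#'   sample (e.g. "control", "LC").
#' @param cohort optional character vector of cohort labels per sample.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `feature_meta` (data.frame: id, rna_type) and `sample_meta`
#'   (data.frame: id, class, cohort).
#' @export
count_matrix <- function(counts, rna_type, sample_class = NULL, cohort = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have row (feature) and column (sample) names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature IDs")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(rna_type) != nrow(counts)) {
    stop("rna_type must have one label per feature")
  }
  ns <- ncol(counts)
  sample_class <- sample_class %||% rep(NA_character_, ns)
  cohort <- cohort %||% rep(NA_character_, ns)
  if (length(sample_class) != ns || length(cohort) != ns) {
    stop("sample_class/cohort must have one entry per sample")
  }
  structure(list(
    counts = counts,
    feature_meta = data.frame(id = rownames(counts),
                              rna_type = as.character(rna_type),
                              stringsAsFactors = FALSE),
    sample_meta = data.frame(id = colnames(counts),
                             class = as.character(sample_class),
                             cohort = as.character(cohort),
                             stringsAsFactors = FALSE)
  ), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("RNA types:", paste(sort(unique(x$feature_meta$rna_type)), collapse = ", "), "\n")
  cls <- x$sample_meta$class
  if (!all(is.na(cls))) {
    tab <- table(cls)
    cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Reads-per-million normalization
#'
#' Scales each sample (column) so its counts sum to one million. Columns
#' with a zero total are an error: RPM is undefined for an empty library.
#'
#' @param x a [count_matrix()] or a plain numeric matrix.
#' @return numeric matrix of RPM values, same dimnames as the counts.
#' @export
rpm <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  tot <- colSums(m)
  if (any(tot == 0)) {
    bad <- colnames(m)[tot == 0]
    stop("zero column total for sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(m, 2, tot, "/") * 1e6
}

#' Log2-transformed RPM with a +1 pseudocount
#'
#' @inheritParams rpm
#' @return numeric matrix of `log2(rpm + 1)` values; a zero count maps to 0.
#' @export
log2rpm <- function(x) log2(rpm(x) + 1)

#' Number of RNA species detected per sample
#'
#' Counts features with RPM > 0 per sample, optionally per RNA type; the
#' detection census used to compare library preparation methods.
#'
#' @inheritParams rpm
#' @param by_type if TRUE and `x` is a `count_matrix`, return a type x
#'   sample matrix of detected-species counts.
#' @return integer vector per sample, or a matrix when `by_type = TRUE`.
#' @export
species_detected <- function(x, by_type = FALSE) {
  r <- rpm(x)
  if (by_type) {
    stopifnot(inherits(x, "count_matrix"))
    types <- unique(x$feature_meta$rna_type)
    out <- t(vapply(types, function(tt) {
      colSums(r[x$feature_meta$rna_type == tt, , drop = FALSE] > 0)
    }, numeric(ncol(r))))
    rownames(out) <- types
    return(out)
  }
  colSums(r > 0)
}

#' Subset a count matrix
#'
#' @param x a [count_matrix()].
#' @param features feature IDs (or logical/integer index) to keep.
#' @param samples sample IDs (or logical/integer index) to keep.
#' @return a `count_matrix` restricted to the requested rows/columns.
#' @export
subset_matrix <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  fi <- features %||% seq_len(nrow(x$counts))
  si <- samples %||% seq_len(ncol(x$counts))
  m <- x$counts[fi, si, drop = FALSE]
  fmeta <- x$feature_meta[match(rownames(m), x$feature_meta$id), ]
  smeta <- x$sample_meta[match(colnames(m), x$sample_meta$id), ]
  count_matrix(m, fmeta$rna_type, smeta$class, smeta$cohort)
}
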