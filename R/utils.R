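# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores whatever
#' RNG state existed before the call, so seeded generators never perturb the
#' caller's random stream.
#'
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a master seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629L) + 1L
}

# Random DNA string(s) over {A,C,G,T}.
random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

# Reverse complement of a character vector of DNA sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Stratified train/test split: samples train_frac of each class (rounded,
# at least 1 per class), mirroring per-class proportional partitioning.
stratified_partition <- function(labels, train_frac = 0.8) {
  stopifnot(train_frac > 0, train_frac < 1)
  idx <- unlist(lapply(split(seq_along(labels), labels), function(i) {
    k <- max(1L, round(length(i) * train_frac))
    if (k >= length(i)) k <- length(i) - 1L
    sample(i, k)
  }), use.names = FALSE)
  sort(idx)
}

# Mean Phred score of a Phred+33 quality string.
mean_phred <- function(qual) {
  if (nchar(qual) == 0L) return(NA_real_)
  mean(utf8ToInt(qual) - 33L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
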