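# Shared fixture builders. Everything is generated in code; no files.

# Tiny deterministic parent set for reference/counting tests.
toy_parents <- function() {
  reference_set(
    id = c("P1", "P2"),
    rna_type = "rRNA",
    sequence = c("ACGTACGTACGTACGTACGTGGCCATTAGCAGTC",
                 "TTTACCGGTTACCGGTTAAGGCCAATTGGCCAA")
  )
}

# Random DNA of given length under the current RNG state.
rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Minimal de_result for filter tests.
fake_de <- function(feature, log2fc, padj, base_mean_raw,
                    fdr_level = 0.1) {
  out <- data.frame(feature = feature,
                    base_mean = base_mean_raw, base_mean_raw = base_mean_raw,
                    log2fc = log2fc, se = 0.1, stat = log2fc / 0.1,
                    pvalue = padj, padj = padj,
                    de_flag = !is.na(padj) & padj < fdr_level,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

# Independent brute-force oracles -----------------------------------------

# Oracle for build_derived_reference: distinct fragment strings that occur
# in some parent, found by naive scanning.
oracle_derived_seqs <- function(reads, parents, min_len = 15L) {
  u <- unique(toupper(reads))
  u <- u[nchar(u) >= min_len]
  u[vapply(u, function(s) {
    any(vapply(parents$sequence, function(p) {
      grepl(s, p, fixed = TRUE)
    }, logical(1)))
  }, logical(1))]
}

# Oracle for count_exact: plain dictionary tally.
oracle_count_exact <- function(reads, reference) {
  vapply(reference$sequence, function(e) {
    sum(toupper(reads) == e)
  }, numeric(1), USE.NAMES = FALSE)
}

# Oracle for count_contained: naive scan excluding multi-feature hits.
oracle_count_contained <- function(reads, reference, min_len = 0L) {
  counts <- numeric(nrow(reference))
  for (r in toupper(reads)) {
    if (nchar(r) < min_len) next
    hits <- which(vapply(reference$sequence, function(e) {
      grepl(r, e, fixed = TRUE)
    }, logical(1)))
    if (length(hits) == 1L) counts[hits] <- counts[hits] + 1
  }
  counts
}

# Oracle for roc_auc: O(n^2) pairwise concordance with half-ties.
oracle_auc <- function(scores, labels, case_label) {
  pos <- scores[labels == case_label]
  neg <- scores[labels != case_label]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Oracle for bh_fdr: literal step-up on the non-NA entries.
oracle_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  o <- order(p[ok])
  q <- p[ok][o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out[ok[o]] <- pmin(q, 1)
  out
}

# Oracle for size_factors: literal median-of-ratios over all-nonzero rows.
oracle_size_factors <- function(m) {
  rows <- which(apply(m, 1, function(r) all(r > 0)))
  geo <- exp(rowMeans(log(m[rows, , drop = FALSE])))
  apply(m[rows, , drop = FALSE], 2, function(col) {
    stats::median(col / geo)
  })
}
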