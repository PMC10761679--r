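#' Exact-match read counting against a derived reference
#'
#' The counting rule for tsRNAs, rsRNAs, and ysRNAs: a read increments a
#' reference entry if and only if its sequence is identical to the entry's
#' sequence over the full length (100% match, no tolerance for extra or
#' missing bases). Reads equal to no entry contribute nothing.
#'
#' @param reads character vector of clean insert sequences (with
#'   multiplicity).
#' @param reference a [reference_set()].
#' @return named integer vector: count per reference entry ID (zeros
#'   included), in reference order.
#' @export
count_exact <- function(reads, reference) {
  stopifnot(inherits(reference, "reference_set"))
  counts <- stats::setNames(integer(nrow(reference)), reference$id)
  if (length(reads) == 0L) return(counts)
  tab <- table(toupper(reads))
  hit <- match(names(tab), reference$sequence)
  ok <- !is.na(hit)
  counts[reference$id[hit[ok]]] <- as.integer(tab[ok])
  counts
}

#' Containment read counting against mature/transcript references
#'
#' The counting rule for miRNAs, piRNAs, and transcript-level features: a
#' read of at least `min_len` nt increments an entry iff it is an exact
#' sense substring of that entry's sequence. Reads contained in more than
#' one distinct feature are dropped as ambiguous (mirroring the default
#' discard of multi-overlap assignments). The length gates are 19 nt for
#' miRNA and 23 nt for mRNA/lncRNA/snRNA/snoRNA calling.
#'
#' @param reads character vector of clean insert sequences.
#' @param reference a [reference_set()].
#' @param min_len minimum read length admitted to counting.
#' @return named integer vector of counts per entry ID.
#' @export
count_contained <- function(reads, reference, min_len = 0L) {
  stopifnot(inherits(reference, "reference_set"))
  counts <- stats::setNames(integer(nrow(reference)), reference$id)
  reads <- toupper(reads)
  reads <- reads[nchar(reads) >= min_len]
  if (length(reads) == 0L) return(counts)
  tab <- table(reads)
  for (j in seq_along(tab)) {
    s <- names(tab)[j]
    hits <- which(vapply(reference$sequence, function(e) {
      regexpr(s, e, fixed = TRUE) > 0L
    }, logical(1), USE.NAMES = FALSE))
    if (length(hits) == 1L) {
      counts[hits] <- counts[hits] + as.integer(tab[j])
    }
  }
  counts
}

#' Merge per-sample, per-type counts into one expression matrix
#'
#' Takes one named count vector per sample (each itself the concatenation
#' of the per-RNA-type counting results) and merges them over the union of
#' features; a feature undetected in a sample gets 0. Feature IDs must be
#' globally unique across RNA types.
#'
#' @param per_sample named list: sample ID -> named integer vector of
#'   counts.
#' @param rna_type named character vector mapping every feature ID to its
#'   RNA type.
#' @param sample_class optional named character vector of class labels.
#' @return a [count_matrix()].
#' @export
assemble_matrix <- function(per_sample, rna_type, sample_class = NULL) {
  stopifnot(is.list(per_sample), length(per_sample) > 0L,
            !is.null(names(per_sample)))
  feats <- unique(unlist(lapply(per_sample, names), use.names = FALSE))
  if (is.null(feats)) stop("no features found")
  if (!all(feats %in% names(rna_type))) {
    stop("rna_type must cover every feature")
  }
  m <- vapply(per_sample, function(v) {
    out <- stats::setNames(integer(length(feats)), feats)
    if (anyDuplicated(names(v))) stop("duplicate feature IDs within a sample")
    out[names(v)] <- as.integer(v)
    out
  }, integer(length(feats)))
  m <- matrix(m, nrow = length(feats),
              dimnames = list(feats, names(per_sample)))
  cls <- if (!is.null(sample_class)) {
    unname(sample_class[colnames(m)])
  } else {
    NULL
  }
  count_matrix(m, unname(rna_type[feats]), sample_class = cls)
}

#' Count reads of one sample across all per-type references
#'
#' Runs the exact-match rule for derived references (tsRNA/rsRNA/ysRNA)
#' and the containment rule, with its per-type length gate, for the rest.
#' A read may legitimately count in more than one RNA-type workflow; no
#' cross-type deduplication is performed.
#'
#' @param reads clean insert sequences of one sample.
#' @param references named list of [reference_set()] objects, keyed by RNA
#'   type.
#' @param exact_types RNA types counted with [count_exact()].
#' @param min_len_by_type named numeric: containment length gate per type
#'   (types absent default to 0); defaults to 19 for miRNA and 23 for
#'   mRNA/lncRNA/snRNA/snoRNA.
#' @return named integer vector over all entries of all references.
#' @export
count_sample <- function(reads, references,
                         exact_types = c("tsRNA", "rsRNA", "ysRNA"),
                         min_len_by_type = c(miRNA = 19, mRNA = 23,
                                             lncRNA = 23, snRNA = 23,
                                             snoRNA = 23)) {
  stopifnot(is.list(references), !is.null(names(references)))
  out <- lapply(names(references), function(tt) {
    ref <- references[[tt]]
    if (tt %in% exact_types) {
      count_exact(reads, ref)
    } else {
      gate <- if (tt %in% names(min_len_by_type)) min_len_by_type[[tt]] else 0L
      count_contained(reads, ref, min_len = gate)
    }
  })
  unlist(out)
}
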