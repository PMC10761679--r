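#' Typed small-RNA reference set
#'
#' A data.frame of reference entries: either parent transcripts (rRNAs,
#' Y RNAs, mature miRNA/piRNA/tsRNA sets, transcripts) or derived entries
#' (unique fragments located within a parent). Derived entries carry their
#' parent ID and 0-based start coordinate, and their sequence must occur in
#' the parent at exactly that position.
#'
#' @param id unique entry IDs.
#' @param rna_type RNA-type label per entry.
#' @param sequence nucleotide sequence per entry (non-empty, A/C/G/T/N).
#' @param parent optional parent ID per entry (NA for parents).
#' @param parent_start optional 0-based start within the parent.
#' @return data.frame of class `reference_set`.
#' @export
reference_set <- function(id, rna_type, sequence,
                          parent = NA_character_,
                          parent_start = NA_integer_) {
  if (anyDuplicated(id)) stop("reference IDs must be unique")
  if (any(nchar(sequence) == 0L)) stop("empty reference sequence")
  out <- data.frame(id = as.character(id),
                    rna_type = as.character(rna_type),
                    sequence = toupper(as.character(sequence)),
                    parent = as.character(parent),
                    parent_start = as.integer(parent_start),
                    stringsAsFactors = FALSE)
  # self-contained sets (parents included) are validated on construction;
  # a stand-alone derived set is validated against its parents with
  # validate_derived()
  derived <- !is.na(out$parent) & out$parent %in% out$id
  if (any(derived)) {
    ok <- substr_matches(out$sequence[derived], out$parent[derived],
                         out$parent_start[derived], out)
    if (!all(ok)) stop("derived entry not found in its parent at parent_start")
  }
  class(out) <- c("reference_set", "data.frame")
  out
}

# Check each derived sequence re-locates in its parent at the recorded
# 0-based coordinate.
substr_matches <- function(seqs, parents, starts, ref) {
  pseq <- ref$sequence[match(parents, ref$id)]
  found <- substr(pseq, starts + 1L, starts + nchar(seqs))
  !is.na(pseq) & found == seqs
}

#' Validate derived entries against their parent set
#'
#' Checks that every derived entry's sequence occurs in its parent at the
#' recorded 0-based coordinate.
#'
#' @param derived a derived [reference_set()].
#' @param parents the parent [reference_set()].
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_derived <- function(derived, parents) {
  stopifnot(inherits(derived, "reference_set"),
            inherits(parents, "reference_set"))
  ok <- substr_matches(derived$sequence, derived$parent,
                       derived$parent_start, parents)
  if (!all(ok)) {
    stop("entries not re-locatable in their parents: ",
         paste(utils::head(derived$id[!ok]), collapse = ", "))
  }
  invisible(TRUE)
}

#' Build a derived fragment reference from clean reads
#'
#' Implements the derived-reference construction for rsRNAs and ysRNAs:
#' every distinct clean-read sequence that occurs as an exact sense
#' substring of any parent becomes one reference entry (duplicates
#' collapse; zero mismatches tolerated; reads matching no parent are
#' dropped). A fragment found in several parents is assigned to the
#' lexicographically first (parent, start). Entries are ordered by
#' (parent, start, length) and named `{type}-{parent}-{start}-{length}`
#' with a 0-based start.
#'
#' @param reads character vector of clean insert sequences (>= `min_len` nt
#'   to be considered).
#' @param parents a [reference_set()] of parent sequences.
#' @param rna_type label given to the derived entries (e.g. "rsRNA").
#' @param min_len minimum admissible fragment length (clean-read floor).
#' @return a [reference_set()] of derived entries.
#' @export
build_derived_reference <- function(reads, parents, rna_type,
                                    min_len = 15L) {
  stopifnot(inherits(parents, "reference_set"))
  if (nrow(parents) == 0L) stop("parents must be non-empty")
  uniq <- unique(toupper(reads))
  uniq <- uniq[nchar(uniq) >= min_len]
  if (length(uniq) == 0L) {
    return(reference_set(character(0), character(0), character(0),
                         character(0), integer(0)))
  }
  ord <- order(parents$id)
  hits <- lapply(uniq, function(s) {
    for (i in ord) {
      p <- regexpr(s, parents$sequence[i], fixed = TRUE)
      if (p > 0L) return(c(parents$id[i], p - 1L))
    }
    NULL
  })
  keep <- !vapply(hits, is.null, logical(1))
  if (!any(keep)) {
    return(reference_set(character(0), character(0), character(0),
                         character(0), integer(0)))
  }
  uniq <- uniq[keep]
  parent <- vapply(hits[keep], `[`, character(1), 1L)
  start <- as.integer(vapply(hits[keep], `[`, character(1), 2L))
  len <- nchar(uniq)
  o <- order(parent, start, len)
  reference_set(
    id = sprintf("%s-%s-%d-%d", rna_type, parent[o], start[o], len[o]),
    rna_type = rna_type,
    sequence = uniq[o],
    parent = parent[o],
    parent_start = start[o]
  )
}

#' Per-position coverage along parents from derived-entry abundances
#'
#' Sums the abundance (typically RPM) of each derived entry over the
#' positions it covers in its parent, producing the coverage profiles used
#' to visualize read depth along rRNAs and Y RNAs.
#'
#' @param abundance named numeric vector, abundance per derived entry ID.
#' @param reference a [reference_set()] of derived entries (with parent
#'   coordinates) covering the names of `abundance`.
#' @param parents a [reference_set()] of parent sequences.
#' @return named list: one numeric depth vector per parent (length = parent
#'   length, position i = depth at 0-based position i-1).
#' @export
coverage_profile <- function(abundance, reference, parents) {
  stopifnot(inherits(reference, "reference_set"),
            inherits(parents, "reference_set"))
  idx <- match(names(abundance), reference$id)
  if (anyNA(idx)) stop("abundance names not all present in reference")
  ent <- reference[idx, ]
  if (any(is.na(ent$parent) | is.na(ent$parent_start))) {
    stop("derived entries must carry parent coordinates")
  }
  depth <- lapply(stats::setNames(nchar(parents$sequence), parents$id),
                  numeric)
  for (i in seq_along(abundance)) {
    p <- ent$parent[i]
    if (!p %in% names(depth)) stop("unknown parent: ", p)
    pos <- ent$parent_start[i] + seq_len(nchar(ent$sequence[i]))
    depth[[p]][pos] <- depth[[p]][pos] + abundance[i]
  }
  depth
}
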