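#' Trimming and demultiplexing specification
#'
#' Parameters of the read-1 cleanup: the adapter to cut, the minimum clean
#' insert length (15 nt), the minimum mean Phred quality (20), the minimum
#' trailing-A run treated as the poly-A tail, and the barcode-to-sample
#' table used on read 2.
#'
#' @param adapter_seq adapter sequence; its first 10 nt act as the exact
#'   search seed.
#' @param barcode_table named character vector: names are 8-nt barcodes,
#'   values the sample IDs they assign to.
#' @param min_len minimum clean read length; shorter inserts are rejected.
#' @param min_mean_q minimum mean Phred score of the trimmed insert.
#' @param polyA_min minimum trailing A-run length removed as the poly-A
#'   tail (shorter terminal A runs are kept as genuine insert bases).
#' @param adapter_suffix_min minimum adapter-prefix length trimmed when the
#'   adapter is only partially present at the read end.
#' @return list of class `trim_spec`.
#' @export
trim_spec <- function(adapter_seq, barcode_table = character(0),
                      min_len = 15L, min_mean_q = 20, polyA_min = 4L,
                      adapter_suffix_min = 6L) {
  if (min_len < 1L) stop("min_len must be >= 1")
  if (length(barcode_table)) {
    if (is.null(names(barcode_table))) stop("barcode_table must be named")
    if (anyDuplicated(names(barcode_table))) stop("duplicate barcodes")
    if (any(nchar(names(barcode_table)) != 8L)) {
      stop("barcodes must be 8 nt long")
    }
  }
  structure(list(adapter_seq = toupper(adapter_seq),
                 barcode_table = barcode_table,
                 min_len = as.integer(min_len),
                 min_mean_q = min_mean_q,
                 polyA_min = as.integer(polyA_min),
                 adapter_suffix_min = as.integer(adapter_suffix_min)),
            class = "trim_spec")
}

#' Trim one read-1 sequence to its clean cfRNA insert
#'
#' Locates the adapter by an exact match of its first 10 nt (falling back
#' to a partial adapter prefix of at least `adapter_suffix_min` nt at the
#' read end, then to the read end itself), removes it together with the
#' preceding 8-nt sample index, then strips the maximal trailing
#' A-homopolymer when it is at least `polyA_min` long. The result is
#' rejected (not an error) when shorter than `min_len` or when its mean
#' Phred score is below `min_mean_q`.
#'
#' @param seq read-1 sequence (A/C/G/T/N).
#' @param qual Phred+33 quality string of the same length.
#' @param spec a [trim_spec()].
#' @return list: `status` ("ok", "too_short" or "low_quality"), `insert`,
#'   `qual` (insert-aligned qualities; NA unless status is "ok").
#' @export
trim_read <- function(seq, qual, spec) {
  stopifnot(inherits(spec, "trim_spec"))
  seq <- toupper(seq)
  seed <- substr(spec$adapter_seq, 1L, 10L)
  pos <- regexpr(seed, seq, fixed = TRUE)
  found <- pos > 0L
  if (found) {
    end <- pos - 1L
  } else {
    end <- nchar(seq)
    # partial adapter at the read end: longest adapter prefix (>= minimum)
    # that suffixes the read
    for (k in seq(min(nchar(spec$adapter_seq), nchar(seq)) - 1L, # nolint
                  spec$adapter_suffix_min)) {
      if (k < spec$adapter_suffix_min) break
      if (substr(seq, nchar(seq) - k + 1L, nchar(seq)) ==
          substr(spec$adapter_seq, 1L, k)) {
        end <- nchar(seq) - k
        found <- TRUE
        break
      }
    }
  }
  # the 8-nt sample index sits immediately 5' of the adapter; it is only
  # removed when an adapter (full or partial) was actually located, so
  # trimming an already-clean insert is a no-op
  if (found) end <- max(end - 8L, 0L)
  core <- substr(seq, 1L, end)
  # maximal trailing A run, removed only when >= polyA_min
  run <- attr(regexpr("A*$", core), "match.length")
  if (run >= spec$polyA_min) core <- substr(core, 1L, nchar(core) - run)
  if (nchar(core) < spec$min_len) {
    return(list(status = "too_short", insert = NA_character_,
                qual = NA_character_))
  }
  q <- substr(qual, 1L, nchar(core))
  if (mean_phred(q) < spec$min_mean_q) {
    return(list(status = "low_quality", insert = NA_character_,
                qual = NA_character_))
  }
  list(status = "ok", insert = core, qual = q)
}

#' Demultiplex paired reads by the read-2 barcode and trim read 1
#'
#' A read pair is assigned to a sample iff the first 8 nt of read 2 equal
#' one of the table barcodes exactly (one substitution routes the pair to
#' "unassigned"; N counts as a mismatch). Assigned read-1 sequences are
#' trimmed with [trim_read()]; read-2 content is then discarded. Input may
#' be FASTQ paths or in-memory read tables.
#'
#' @param r1,r2 FASTQ file paths, or data.frames with columns id/seq/qual
#'   (as produced by [read_fastq()] or [gen_fragment_reads()]).
#' @param spec a [trim_spec()] with a non-empty `barcode_table`.
#' @return list with `reads` (data.frame: id, sample, status, insert,
#'   qual; unassigned pairs have sample NA and status "unassigned") and
#'   `summary` (data.frame per sample: total_reads, clean_reads,
#'   discarded_reads; plus one "unassigned" row).
#' @export
demultiplex <- function(r1, r2, spec) {
  stopifnot(inherits(spec, "trim_spec"))
  if (length(spec$barcode_table) == 0L) stop("barcode_table is empty")
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  if (nrow(r1) != nrow(r2)) {
    stop("R1/R2 record counts differ (", nrow(r1), " vs ", nrow(r2), ")")
  }
  bc <- substr(r2$seq, 1L, 8L)
  sample <- unname(spec$barcode_table[bc])

  status <- character(nrow(r1))
  insert <- rep(NA_character_, nrow(r1))
  qual <- rep(NA_character_, nrow(r1))
  assigned <- which(!is.na(sample))
  for (i in assigned) {
    tr <- trim_read(r1$seq[i], r1$qual[i], spec)
    status[i] <- tr$status
    insert[i] <- tr$insert
    qual[i] <- tr$qual
  }
  status[is.na(sample)] <- "unassigned"

  reads <- data.frame(id = r1$id, sample = sample, status = status,
                      insert = insert, qual = qual, stringsAsFactors = FALSE)
  samples <- unname(spec$barcode_table)
  summary <- data.frame(
    sample = c(samples, "unassigned"),
    total_reads = c(vapply(samples, function(s) sum(!is.na(sample) & sample == s),
                           integer(1)),
                    sum(is.na(sample))),
    clean_reads = c(vapply(samples, function(s) {
      sum(!is.na(sample) & sample == s & status == "ok")
    }, integer(1)), 0L),
    stringsAsFactors = FALSE
  )
  summary$discarded_reads <- summary$total_reads - summary$clean_reads
  summary$discarded_reads[summary$sample == "unassigned"] <- 0L
  list(reads = reads, summary = summary)
}
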