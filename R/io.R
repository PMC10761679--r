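#' Read and write FASTA files
#'
#' Reading goes through Biostrings; writing emits canonical two-line
#' records (header, unwrapped sequence, LF endings) so that
#' write-then-read round-trips are byte-stable.
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences (for a
#'   [reference_set()] use [write_reference()]).
#' @return `write_fasta()`: the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) stop("sequences must be named")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con, sep = "\n")
  invisible(path)
}

#' Write a reference set as FASTA
#'
#' @param ref a [reference_set()].
#' @param path output path.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "reference_set"))
  write_fasta(stats::setNames(ref$sequence, ref$id), path)
}

#' Read and write FASTQ files (Phred+33)
#'
#' Reading goes through Biostrings and validates that sequence and
#' quality lengths agree per record; writing emits the canonical 4-line
#' records with LF endings.
#'
#' @param path file path.
#' @return `read_fastq()`: data.frame with columns id, seq, qual.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- as.character(S4Vectors::mcols(x)$qualities)
  s <- as.character(x)
  bad <- which(nchar(s) != nchar(q))
  if (length(bad)) {
    stop("sequence/quality length mismatch at record ", bad[1L])
  }
  data.frame(id = unname(names(x)), seq = unname(s), qual = unname(q),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @param reads data.frame with columns id, seq, qual.
#' @return `write_fastq()`: the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence/quality length mismatch")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
             con, sep = "\n")
  invisible(path)
}

#' Read and write count-matrix TSV files
#'
#' The on-disk layout is tab-delimited with LF endings: first column
#' `feature_id`, second column `rna_type`, then one integer column per
#' sample. Sample class labels travel in an optional two-column design
#' table (sample, class). Round-trips are bit-exact.
#'
#' @param path TSV path.
#' @param design optional design data.frame (columns sample, class) or
#'   path to such a TSV.
#' @return `read_matrix()`: a [count_matrix()].
#' @export
read_matrix <- function(path, design = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L || names(df)[1L] != "feature_id" ||
      names(df)[2L] != "rna_type") {
    stop("expected columns: feature_id, rna_type, <samples...>")
  }
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$feature_id
  cls <- NULL
  if (!is.null(design)) {
    if (is.character(design)) design <- utils::read.delim(design)
    cls <- design$class[match(colnames(m), design$sample)]
  }
  count_matrix(m, df$rna_type, sample_class = cls)
}

#' @rdname read_matrix
#' @param cm a [count_matrix()].
#' @return `write_matrix()`: the path, invisibly.
#' @export
write_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  hdr <- paste(c("feature_id", "rna_type", colnames(cm$counts)),
               collapse = "\t")
  body <- paste(cm$feature_meta$id, cm$feature_meta$rna_type,
                apply(cm$counts, 1, paste, collapse = "\t"), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Write a sample design table
#'
#' @param cm a [count_matrix()] with class labels.
#' @param path output TSV path.
#' @export
write_design <- function(cm, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("sample\tclass",
               paste(cm$sample_meta$id, cm$sample_meta$class, sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Run the whole desk-scale pipeline on synthetic data
#'
#' Orchestrates both arms of the analysis end to end, writing every
#' artifact as plain text under `out_dir` and logging each stage. The
#' read-level arm simulates parents and structured paired reads,
#' demultiplexes and trims them, builds the derived fragment reference,
#' and counts reads per sample. The cohort arm simulates a case/control
#' count matrix, applies QC exclusion, runs the differential expression
#' test and candidate filter, LASSO stability selection, and the repeated
#' partition classifier with risk-score sensitivity/specificity. All
#' randomness derives from the configuration seed, so a rerun reproduces
#' every artifact bit for bit.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param n_read_samples number of simulated libraries in the read arm.
#' @param reads_per_sample read pairs per simulated library.
#' @param n_repeats partition repeats in selection/classification.
#' @param qc_thresholds QC thresholds, see [apply_exclusion()]; the
#'   default scales the clean-read floor to the synthetic depth.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the principal in-memory artifacts:
#'   demux summary, derived reference, read-arm counts, cohort matrix,
#'   QC table, DE table, candidates, selection result, model report.
#' @export
run_pipeline <- function(config, out_dir,
                         n_read_samples = 3L, reads_per_sample = 400L,
                         n_repeats = 20L,
                         qc_thresholds = list(clean_reads_min = 100),
                         quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[slipir] ", ...)
  log_lines <- character(0)
  note <- function(stage, what) {
    log_lines <<- c(log_lines, sprintf("%s\t%s", stage, what))
    say(stage, ": ", what)
  }

  # -- read-level arm -------------------------------------------------
  parents <- gen_parent_references(config)
  write_reference(parents, file.path(out_dir, "parents.fa"))
  note("simulate", sprintf("%d parent references", nrow(parents)))

  barcodes <- with_seed(derive_seed(config$seed, 21L), {
    stats::setNames(random_dna(n_read_samples, config$barcode_length),
                    sprintf("S%02d", seq_len(n_read_samples)))
  })
  sim <- gen_fragment_reads(parents, config, barcodes,
                            reads_per_sample = reads_per_sample)
  write_fastq(sim$r1, file.path(out_dir, "reads_R1.fastq"))
  write_fastq(sim$r2, file.path(out_dir, "reads_R2.fastq"))
  note("simulate", sprintf("%d read pairs from %d samples",
                           nrow(sim$r1), n_read_samples))

  spec <- trim_spec(config$adapter_seq,
                    barcode_table = stats::setNames(names(barcodes),
                                                    unname(barcodes)),
                    polyA_min = config$polyA_min)
  dm <- demultiplex(sim$r1, sim$r2, spec)
  utils::write.table(dm$summary, file.path(out_dir, "preprocess_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("preprocess", sprintf("%d/%d reads clean",
                             sum(dm$summary$clean_reads), nrow(sim$r1)))

  clean <- dm$reads[dm$reads$status == "ok", ]
  derived <- build_derived_reference(clean$insert, parents, "rsRNA")
  write_reference(derived, file.path(out_dir, "derived_reference.fa"))
  note("reference", sprintf("%d derived entries", nrow(derived)))

  per_sample <- lapply(split(clean$insert, clean$sample), count_exact,
                       reference = derived)
  read_counts <- assemble_matrix(
    per_sample, stats::setNames(derived$rna_type, derived$id))
  write_matrix(read_counts, file.path(out_dir, "read_arm_counts.tsv"))
  note("quantify", sprintf("%d x %d read-arm count matrix",
                           nrow(read_counts$counts), ncol(read_counts$counts)))

  # -- cohort arm -----------------------------------------------------
  sim_cm <- gen_count_matrix(config)
  cm <- sim_cm$matrix
  write_matrix(cm, file.path(out_dir, "cohort_counts.tsv"))
  write_design(cm, file.path(out_dir, "cohort_design.tsv"))

  tot <- colSums(cm$counts)
  qc <- apply_exclusion(
    qc_metrics(cm, total_reads = tot / 0.8, clean_reads = tot),
    thresholds = qc_thresholds)
  utils::write.table(qc, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  keep <- qc$sample[!qc$excluded]
  cm <- subset_matrix(cm, samples = keep)
  note("qc", sprintf("%d samples retained, %d excluded",
                     length(keep), sum(qc$excluded)))

  case <- config$classes[2L]
  de <- nb_wald_test(cm, cm$sample_meta$class, case_label = case)
  utils::write.table(de, file.path(out_dir, "de_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cand <- candidate_filter(de)
  writeLines(cand, file.path(out_dir, "candidates.txt"))
  note("diffexp", sprintf("%d DE features, %d candidates",
                          sum(de$de_flag, na.rm = TRUE), length(cand)))

  x <- t(log2rpm(cm))
  scfg <- selection_config(
    n_repeats = n_repeats,
    frequency_floor = max(1L, round(0.1 * n_repeats)),
    seed = derive_seed(config$seed, 31L))
  sel <- lasso_select(x[, cand, drop = FALSE], cm$sample_meta$class,
                      case, scfg)
  utils::write.table(
    data.frame(feature = names(sel$frequency), frequency = sel$frequency,
               selected = names(sel$frequency) %in% sel$selected),
    file.path(out_dir, "selection.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  note("select", sprintf("%d/%d features selected by lasso",
                         length(sel$selected), length(cand)))

  panel <- if (length(sel$selected) >= 2L) sel$selected else cand
  report <- repeat_harness(x, cm$sample_meta$class, case, panel = panel,
                           algorithm = "lr", n_repeats = n_repeats,
                           seed = derive_seed(config$seed, 41L))
  ss <- sens_spec(report$median_scores, cm$sample_meta$class, case)
  model_tab <- data.frame(sample = names(report$median_scores),
                          class = cm$sample_meta$class,
                          median_risk_score = unname(report$median_scores))
  utils::write.table(model_tab, file.path(out_dir, "risk_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(iteration = seq_len(n_repeats),
               auc_train = report$auc_train, auc_test = report$auc_test),
    file.path(out_dir, "model_auc.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  note("classify", sprintf(
    "median test AUC %.3f, sensitivity %.1f%%, specificity %.1f%%",
    stats::median(report$auc_test), ss$sensitivity, ss$specificity))

  writeLines(log_lines, file.path(out_dir, "run_log.tsv"))
  invisible(list(summary = dm$summary, derived = derived,
                 read_counts = read_counts, matrix = cm, qc = qc, de = de,
                 candidates = cand, selection = sel, report = report,
                 sens_spec = ss))
}
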