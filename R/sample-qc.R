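#' Per-sample QC metrics
#'
#' Combines the preprocessing summary with the count matrix to compute,
#' per sample: total and clean read numbers, the clean-read ratio, reads
#' assigned by any counting workflow ("mappable" at desk scale), per-type
#' read sums and their percentage ratios relative to clean reads, and the
#' number of RNA species detected (RPM > 0) per type.
#'
#' @param cm a [count_matrix()].
#' @param total_reads named numeric vector: raw read pairs per sample.
#' @param clean_reads named numeric vector: clean reads (>= 15 nt, passing
#'   quality) per sample.
#' @return data.frame, one row per sample: sample, total_reads,
#'   clean_reads, clean_ratio (percent), mappable_reads, one
#'   `pct_<type>` column per RNA type, and one `species_<type>` column.
#' @export
qc_metrics <- function(cm, total_reads, clean_reads) {
  stopifnot(inherits(cm, "count_matrix"))
  samp <- colnames(cm$counts)
  if (!all(samp %in% names(total_reads)) ||
      !all(samp %in% names(clean_reads))) {
    stop("total_reads/clean_reads must cover every sample")
  }
  total <- unname(total_reads[samp])
  clean <- unname(clean_reads[samp])
  types <- sort(unique(cm$feature_meta$rna_type))
  type_sum <- t(vapply(types, function(tt) {
    colSums(cm$counts[cm$feature_meta$rna_type == tt, , drop = FALSE])
  }, numeric(length(samp))))
  species <- species_detected(cm, by_type = TRUE)

  out <- data.frame(sample = samp,
                    total_reads = total,
                    clean_reads = clean,
                    clean_ratio = 100 * clean / total,
                    mappable_reads = colSums(cm$counts),
                    stringsAsFactors = FALSE)
  for (tt in types) {
    out[[paste0("pct_", tt)]] <- 100 * type_sum[tt, ] / clean
    out[[paste0("species_", tt)]] <- species[tt, ]
  }
  out
}

#' Apply the low-quality-sample exclusion criteria
#'
#' A sample is excluded when any of four predicates triggers:
#' (1) clean-read ratio below 20%; (2) fewer than 2 million clean reads;
#' (3) rsRNA ratio above 30%; (4) combined lncRNA + mRNA ratio above 30%.
#' All comparisons are strict, so a sample sitting exactly on every
#' threshold is retained. Thresholds are configurable (e.g. the clean-read
#' floor is scaled down for synthetic desk-scale runs).
#'
#' @param metrics data.frame from [qc_metrics()].
#' @param thresholds list: `clean_ratio_min` (percent, default 20),
#'   `clean_reads_min` (default 2e6), `rsrna_ratio_max` (default 30),
#'   `lnc_mrna_ratio_max` (default 30).
#' @return `metrics` with added columns `excluded` (logical) and
#'   `exclusion_reasons` (";"-separated reason codes, "" if retained).
#' @export
apply_exclusion <- function(metrics,
                            thresholds = list(clean_ratio_min = 20,
                                              clean_reads_min = 2e6,
                                              rsrna_ratio_max = 30,
                                              lnc_mrna_ratio_max = 30)) {
  th <- utils::modifyList(list(clean_ratio_min = 20, clean_reads_min = 2e6,
                               rsrna_ratio_max = 30, lnc_mrna_ratio_max = 30),
                          thresholds)
  rs <- metrics[["pct_rsRNA"]] %||% rep(0, nrow(metrics))
  lnc <- metrics[["pct_lncRNA"]] %||% rep(0, nrow(metrics))
  mr <- metrics[["pct_mRNA"]] %||% rep(0, nrow(metrics))
  crit <- cbind(
    low_clean_ratio = metrics$clean_ratio < th$clean_ratio_min,
    low_clean_reads = metrics$clean_reads < th$clean_reads_min,
    high_rsrna_ratio = rs > th$rsrna_ratio_max,
    high_lnc_mrna_ratio = (lnc + mr) > th$lnc_mrna_ratio_max
  )
  metrics$excluded <- rowSums(crit) > 0
  metrics$exclusion_reasons <- apply(crit, 1, function(z) {
    paste(colnames(crit)[z], collapse = ";")
  })
  metrics
}

#' Transcriptome-wide Pearson correlation between two expression profiles
#'
#' Pearson's r between, e.g., the per-feature mean log2 RPM of two groups,
#' with the two-sided p-value from the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param a,b numeric vectors over the same feature universe (length >= 3).
#' @return list: `r`, `p`, `n`.
#' @export
transcriptome_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  n <- length(a)
  if (n < 3L) stop("need at least 3 features")
  r <- stats::cor(a, b)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Gamma fit and kurtosis of a fragment-length distribution
#'
#' Fits a Gamma(shape = alpha, rate = beta) law by maximum likelihood —
#' Newton iteration on the shape equation
#' `log(a) - digamma(a) = log(mean) - mean(log)` with tolerance 1e-8 and
#' at most 100 iterations, rate = shape / mean — and reports the Pearson
#' (non-excess) kurtosis m4 / m2^2, the statistic used to contrast
#' peaked versus smooth fragment-size profiles.
#'
#' @param lengths positive fragment lengths (n >= 10 for a stable fit).
#' @return list of class `frag_stats`: `gamma_shape`, `gamma_rate`,
#'   `kurtosis`, `n`.
#' @export
fragment_stats <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (any(lengths <= 0)) stop("lengths must be positive")
  n <- length(lengths)
  if (n < 10L) stop("need at least 10 lengths for a Gamma fit")
  if (stats::var(lengths) == 0) stop("degenerate fit: constant lengths")
  m <- mean(lengths)
  s <- log(m) - mean(log(lengths))
  # Minka's closed-form initialization, then Newton on f(a) = log(a) -
  # digamma(a) - s
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in seq_len(100L)) {
    f <- log(a) - digamma(a) - s
    step <- f / (1 / a - trigamma(a))
    a_new <- a - step
    if (a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-8) {
      a <- a_new
      break
    }
    a <- a_new
  }
  m2 <- mean((lengths - m)^2)
  m4 <- mean((lengths - m)^4)
  structure(list(gamma_shape = a, gamma_rate = a / m,
                 kurtosis = m4 / m2^2, n = n),
            class = "frag_stats")
}

#' Sense/antisense orientation tally over annotated regions
#'
#' Labels each read by the region class (e.g. exon or intron) and strand
#' on which it is found: "sense" when the read is an exact substring of a
#' region sequence, "antisense" when its reverse complement is. The first
#' matching region (in table order) wins; unmatched reads are dropped.
#'
#' @param reads character vector of read sequences.
#' @param regions data.frame with columns `region` (e.g. "exon"/"intron")
#'   and `sequence`.
#' @return table of counts: region class x orientation.
#' @export
orientation_tally <- function(reads, regions) {
  stopifnot(all(c("region", "sequence") %in% names(regions)))
  reads <- toupper(reads)
  rc <- revcomp(reads)
  lab_region <- character(0)
  lab_orient <- character(0)
  for (i in seq_along(reads)) {
    for (j in seq_len(nrow(regions))) {
      if (regexpr(reads[i], regions$sequence[j], fixed = TRUE) > 0L) {
        lab_region <- c(lab_region, regions$region[j])
        lab_orient <- c(lab_orient, "sense")
        break
      }
      if (regexpr(rc[i], regions$sequence[j], fixed = TRUE) > 0L) {
        lab_region <- c(lab_region, regions$region[j])
        lab_orient <- c(lab_orient, "antisense")
        break
      }
    }
  }
  table(region = factor(lab_region, levels = unique(regions$region)),
        orientation = factor(lab_orient, levels = c("sense", "antisense")))
}
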