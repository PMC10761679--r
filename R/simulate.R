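#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode
#' the library design and the statistical structure the pipeline is built
#' for: an 8-nt sample barcode, fragment lengths following a
#' Gamma(shape = 10.22, rate = 0.24) law (the fitted plasma mRNA fragment
#' size distribution, mean ~42.6 nt), negative-binomial counts with
#' moderate overdispersion, and planted log2 fold-change effects in a small
#' fraction of features.
#'
#' @param seed integer master seed; every generator output is a pure
#'   function of the configuration including this seed.
#' @param n_samples_per_class samples simulated per class (scalar, or named
#'   vector over `classes`).
#' @param classes class labels; the first is the reference (control) class.
#' @param n_features_per_type named integer vector, features per RNA type.
#'   The default covers the nine plasma RNA types the pipeline quantifies.
#' @param type_abundance named numeric vector of relative read-share
#'   weights per RNA type. The default approximates the measured plasma
#'   cfRNA composition (tsRNA 14.4%, miRNA 10.3%, ysRNA 9.6%, lncRNA
#'   8.4%, mRNA 7.9%, rsRNA 6.0%, with smaller shares for
#'   snRNA/snoRNA/piRNA); types missing from the vector get weight 1.
#'   Weights are normalized over the types present, so only ratios
#'   matter.
#' @param de_fraction fraction of all features planted with a true effect
#'   in each case class.
#' @param planted_log2fc log2 fold change planted in case samples for
#'   planted features (positive = up in cases).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param library_size_range 2-vector, range of per-sample library sizes
#'   from which size factors are drawn uniformly.
#' @param frag_gamma_shape,frag_gamma_rate Gamma shape (alpha) and rate
#'   (beta) of the insert-length distribution.
#' @param barcode_length sample barcode length; the library design uses 8.
#' @param adapter_seq adapter sequence appended 3' of the barcode on R1.
#' @param polyA_min minimum length of the poly-A tract appended to the
#'   insert (also the trimmer's minimum trailing-A run).
#' @param polyA_range 2-vector, range of simulated poly-A tail lengths.
#' @param read_length sequencer read length for both mates.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples_per_class = 50L,
                       classes = c("control", "cancer"),
                       n_features_per_type = c(
                         miRNA = 150L, mRNA = 300L, lncRNA = 80L,
                         snRNA = 60L, snoRNA = 80L, tsRNA = 120L,
                         rsRNA = 150L, ysRNA = 40L, piRNA = 120L),
                       type_abundance = c(
                         tsRNA = 14.4, miRNA = 10.3, ysRNA = 9.6,
                         lncRNA = 8.4, mRNA = 7.9, rsRNA = 6.0,
                         snRNA = 4.0, snoRNA = 3.0, piRNA = 5.0),
                       de_fraction = 0.05,
                       planted_log2fc = 1.5,
                       nb_dispersion = 0.2,
                       library_size_range = c(5e5, 1.5e6),
                       frag_gamma_shape = 10.22,
                       frag_gamma_rate = 0.24,
                       barcode_length = 8L,
                       adapter_seq = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTATAGAGAGGTG",
                       polyA_min = 4L,
                       polyA_range = c(10L, 30L),
                       read_length = 150L) {
  if (length(classes) < 1L) stop("at least one class required")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0, 1]")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (frag_gamma_shape <= 0 || frag_gamma_rate <= 0) {
    stop("Gamma shape and rate must be > 0")
  }
  if (any(n_features_per_type <= 0)) stop("feature counts must be positive")
  if (barcode_length != 8L) {
    warning("the library design uses an 8-nt barcode; got ", barcode_length)
  }
  if (length(n_samples_per_class) == 1L) {
    n_samples_per_class <- stats::setNames(
      rep(as.integer(n_samples_per_class), length(classes)), classes)
  }
  if (!all(classes %in% names(n_samples_per_class))) {
    stop("n_samples_per_class must cover every class")
  }
  if (any(n_samples_per_class < 1L)) stop("sample counts must be positive")
  if (any(type_abundance <= 0)) stop("type_abundance weights must be > 0")
  structure(list(
    seed = as.integer(seed),
    n_samples_per_class = n_samples_per_class,
    classes = classes,
    n_features_per_type = n_features_per_type,
    type_abundance = type_abundance,
    de_fraction = de_fraction,
    planted_log2fc = planted_log2fc,
    nb_dispersion = nb_dispersion,
    library_size_range = library_size_range,
    frag_gamma_shape = frag_gamma_shape,
    frag_gamma_rate = frag_gamma_rate,
    barcode_length = as.integer(barcode_length),
    adapter_seq = adapter_seq,
    polyA_min = as.integer(polyA_min),
    polyA_range = as.integer(polyA_range),
    read_length = as.integer(read_length)
  ), class = "sim_config")
}

# Approximate lengths of the parent transcripts the derived references are
# built from: the four cytoplasmic rRNAs and the four Y RNAs.
default_parent_lengths <- function() {
  c("28S" = 5070L, "18S" = 1869L, "5.8S" = 157L, "5S" = 121L,
    "RNY1" = 113L, "RNY3" = 102L, "RNY4" = 94L, "RNY5" = 84L)
}

#' Generate synthetic parent reference sequences
#'
#' Emulates the full-length rRNA (28S, 18S, 5.8S, 5S) and Y RNA (RNY1,
#' RNY3, RNY4, RNY5) parents with random seeded sequences of comparable
#' lengths. Fragments are later simulated from, and aligned back to, these
#' parents.
#'
#' @param config a [sim_config()].
#' @param lengths named integer vector of parent lengths; names become
#'   parent IDs. Defaults to realistic rRNA / Y RNA lengths.
#' @return A [reference_set()] with one entry per parent; rRNA parents are
#'   typed `"rRNA"`, RNY parents `"Y_RNA"`, anything else `"parent"`.
#' @export
gen_parent_references <- function(config, lengths = default_parent_lengths()) {
  stopifnot(inherits(config, "sim_config"))
  if (any(lengths <= 0)) stop("parent lengths must be positive")
  if (is.null(names(lengths)) || anyDuplicated(names(lengths))) {
    stop("lengths must be uniquely named")
  }
  seqs <- with_seed(derive_seed(config$seed, 1L), {
    vapply(lengths, function(L) random_dna(1, L), character(1))
  })
  type <- ifelse(grepl("^RNY", names(lengths)), "Y_RNA",
                 ifelse(grepl("S$", names(lengths)), "rRNA", "parent"))
  reference_set(id = names(lengths), rna_type = type, sequence = seqs)
}

#' Simulate SLiPiR-seq structured paired reads
#'
#' Draws sense fragments from the parent references (lengths
#' Gamma-distributed, clipped so the poly-A tail, 8-nt barcode, and at
#' least the 10-nt adapter seed fit within the read), and assembles R1 as
#' `insert + poly-A + barcode + adapter`, padded with random bases or
#' truncated to the read length. R2 begins with the same barcode followed
#' by poly-T. Ground truth records every read's sample and origin.
#'
#' @param parents a [reference_set()] of parent sequences.
#' @param config a [sim_config()].
#' @param sample_barcodes named character vector: names are sample IDs,
#'   values their unique 8-nt barcodes.
#' @param reads_per_sample number of read pairs per sample.
#' @param low_quality_frac fraction of reads given uniformly low base
#'   qualities (Phred 2) to exercise the quality filter; default 0 gives
#'   constant high quality (Phred 40).
#' @return list with `r1` and `r2` (data.frames: id, seq, qual) and
#'   `truth` (data.frame: read_id, sample, parent, start, length, insert;
#'   start is 0-based).
#' @export
gen_fragment_reads <- function(parents, config, sample_barcodes,
                               reads_per_sample = 1000L,
                               low_quality_frac = 0) {
  stopifnot(inherits(parents, "reference_set"), inherits(config, "sim_config"))
  bc <- sample_barcodes
  if (anyDuplicated(bc)) stop("duplicate barcodes")
  if (any(nchar(bc) != config$barcode_length)) {
    stop("all barcodes must have length ", config$barcode_length)
  }
  if (is.null(names(bc))) names(bc) <- paste0("S", seq_along(bc))

  pl <- nchar(parents$sequence)
  rl <- config$read_length
  with_seed(derive_seed(config$seed, 2L), {
    out <- vector("list", length(bc))
    for (si in seq_along(bc)) {
      n <- reads_per_sample
      polyA_n <- sample(seq(config$polyA_range[1], config$polyA_range[2]),
                        n, replace = TRUE)
      # max insert so that poly-A + barcode + 10-nt adapter seed still fit
      max_ins <- rl - polyA_n - config$barcode_length - 10L
      pidx <- sample(seq_len(nrow(parents)), n, replace = TRUE, prob = pl)
      len <- round(stats::rgamma(n, shape = config$frag_gamma_shape,
                                 rate = config$frag_gamma_rate))
      len <- pmax(15L, pmin(len, pl[pidx], max_ins))
      start <- vapply(seq_len(n), function(i) {
        sample.int(pl[pidx[i]] - len[i] + 1L, 1L)
      }, integer(1))
      insert <- substr(rep(parents$sequence[pidx], 1L), start, start + len - 1L)
      r1 <- paste0(insert, strrep("A", polyA_n), bc[si], config$adapter_seq)
      short <- nchar(r1) < rl
      if (any(short)) {
        pad <- vapply(rl - nchar(r1)[short], function(k) random_dna(1, k),
                      character(1))
        r1[short] <- paste0(r1[short], pad)
      }
      r1 <- substr(r1, 1L, rl)
      qual <- rep(strrep("I", rl), n)
      if (low_quality_frac > 0) {
        bad <- stats::runif(n) < low_quality_frac
        qual[bad] <- strrep("#", rl)
      }
      r2 <- paste0(bc[si], strrep("T", rl - config$barcode_length))
      ids <- sprintf("%s_read%06d", names(bc)[si], seq_len(n))
      out[[si]] <- list(
        r1 = data.frame(id = ids, seq = r1, qual = qual,
                        stringsAsFactors = FALSE),
        r2 = data.frame(id = ids, seq = r2, qual = strrep("I", rl),
                        stringsAsFactors = FALSE),
        truth = data.frame(read_id = ids, sample = names(bc)[si],
                           parent = parents$id[pidx], start = start - 1L,
                           length = len, insert = insert,
                           stringsAsFactors = FALSE)
      )
    }
    list(r1 = do.call(rbind, lapply(out, `[[`, "r1")),
         r2 = do.call(rbind, lapply(out, `[[`, "r2")),
         truth = do.call(rbind, lapply(out, `[[`, "truth")))
  })
}

#' Simulate a case/control (or multi-class) count matrix
#'
#' Per-feature baseline abundances are log-normal; per-sample library sizes
#' are uniform over `library_size_range` and enter as size factors; counts
#' are negative binomial with mean
#' `baseline * sizefactor * 2^(planted_log2fc)` for planted features in the
#' corresponding case class, and `baseline * sizefactor` otherwise. Each
#' non-reference class receives its own disjoint planted set; `n_common`
#' extra features are planted in every case class, emulating a common
#' cancer signature shared across tumor types.
#'
#' @param config a [sim_config()].
#' @param n_common number of features planted in all non-reference classes.
#' @return list with `matrix` (a [count_matrix()]) and `truth` (list:
#'   `sample_class`, `planted_features` — named list per class plus
#'   `"common"` —, `baseline`, `size_factors`).
#' @export
gen_count_matrix <- function(config, n_common = 0L) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$classes) < 2L) stop("at least two classes required")
  if (any(config$n_samples_per_class < 3L)) {
    stop("need at least 3 samples per class")
  }
  types <- names(config$n_features_per_type)
  feat_type <- rep(types, config$n_features_per_type)
  feat_id <- unlist(lapply(types, function(tt) {
    sprintf("%s-%04d", tt, seq_len(config$n_features_per_type[[tt]]))
  }), use.names = FALSE)
  nf <- length(feat_id)

  cls <- rep(config$classes, config$n_samples_per_class[config$classes])
  ns <- length(cls)
  samp_id <- sprintf("%s_%03d", cls, unlist(lapply(
    config$n_samples_per_class[config$classes], seq_len), use.names = FALSE))

  # per-type mean scaling so expected read shares track the configured
  # composition regardless of how many features each type has
  w <- rep(1, length(types))
  names(w) <- types
  known <- intersect(types, names(config$type_abundance))
  w[known] <- config$type_abundance[known]
  w <- w / sum(w)
  per_feat_w <- (w / config$n_features_per_type[types])[feat_type]

  with_seed(derive_seed(config$seed, 3L), {
    baseline <- stats::rlnorm(nf, meanlog = log(80), sdlog = 1) *
      per_feat_w / mean(per_feat_w)
    lib <- stats::runif(ns, config$library_size_range[1],
                        config$library_size_range[2])
    sf <- lib / mean(lib)

    n_planted <- round(config$de_fraction * nf)
    case_classes <- config$classes[-1L]
    pool <- sample(feat_id)
    planted <- list()
    k <- 0L
    for (cc in case_classes) {
      planted[[cc]] <- sort(pool[seq_len(n_planted) + k])
      k <- k + n_planted
    }
    common <- character(0)
    if (n_common > 0L) {
      if (k + n_common > nf) stop("too many planted features requested")
      common <- sort(pool[seq_len(n_common) + k])
    }
    planted[["common"]] <- common

    lfc <- matrix(0, nf, ns, dimnames = list(feat_id, samp_id))
    for (cc in case_classes) {
      rows <- feat_id %in% c(planted[[cc]], common)
      lfc[rows, cls == cc] <- config$planted_log2fc
    }
    mu <- outer(baseline, sf) * 2^lfc
    counts <- matrix(stats::rnbinom(nf * ns, size = 1 / config$nb_dispersion,
                                    mu = mu),
                     nf, ns, dimnames = list(feat_id, samp_id))
    cm <- count_matrix(counts, feat_type, sample_class = cls)
    list(matrix = cm,
         truth = list(sample_class = stats::setNames(cls, samp_id),
                      planted_features = planted,
                      baseline = stats::setNames(baseline, feat_id),
                      size_factors = stats::setNames(sf, samp_id)))
  })
}
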