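#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over features
#' with nonzero counts in all samples, of the ratio of the sample's count
#' to the feature's geometric mean. When no feature is nonzero everywhere,
#' an optional fallback computes each feature's geometric mean over its
#' positive counts only.
#'
#' @param counts integer matrix (features x samples) or a
#'   [count_matrix()].
#' @param fallback use the positive-count fallback when no feature is
#'   nonzero in all samples (default TRUE); with `fallback = FALSE` this
#'   situation is an error.
#' @return named numeric vector of size factors (> 0), one per sample.
#' @export
size_factors <- function(counts, fallback = TRUE) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  all_pos <- rowSums(m == 0) == 0L
  if (any(all_pos)) {
    geo <- exp(rowMeans(log(m[all_pos, , drop = FALSE])))
    sf <- apply(m[all_pos, , drop = FALSE], 2, function(col) {
      stats::median(col / geo)
    })
  } else {
    if (!fallback) stop("no feature with nonzero counts in all samples")
    # positive-count geometric means; ratios from zero counts are ignored
    geo <- apply(m, 1, function(row) exp(mean(log(row[row > 0]))))
    keep <- is.finite(geo) & geo > 0
    sf <- vapply(seq_len(ncol(m)), function(j) {
      ratio <- m[keep, j] / geo[keep]
      stats::median(ratio[ratio > 0])
    }, numeric(1))
    names(sf) <- colnames(m)
  }
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf
}

# Method-of-moments NB dispersion per feature, pooled within groups on
# size-factor-normalized counts, floored at 1e-8.
mom_dispersion <- function(norm_counts, groups, floor = 1e-8) {
  disp <- apply(norm_counts, 1, function(y) {
    ests <- vapply(split(y, groups), function(yg) {
      mu <- mean(yg)
      if (mu <= 0) return(NA_real_)
      (stats::var(yg) - mu) / mu^2
    }, numeric(1))
    w <- table(groups) - 1L
    ok <- !is.na(ests)
    if (!any(ok)) return(floor)
    sum(ests[ok] * w[ok]) / sum(w[ok])
  })
  pmax(disp, floor)
}

#' Negative-binomial Wald differential expression test
#'
#' Per feature, fits a negative-binomial GLM (log link) of counts on a
#' two-group indicator with `log(size factor)` offsets; the dispersion is
#' estimated by method-of-moments on normalized counts (floored at 1e-8)
#' and then treated as known. The Wald statistic is the fold-change
#' estimate over its standard error, with a two-sided normal p-value, and
#' Benjamini-Hochberg adjusted q-values flag differential expression at
#' q < 0.1. Positive log2 fold change means higher in the case group.
#'
#' @param counts integer matrix (features x samples) or [count_matrix()].
#' @param labels sample class labels (two groups, each n >= 2).
#' @param case_label label of the case (e.g. cancer) group; default: the
#'   label that is not the reference, taken as the second factor level.
#' @param sf size factors; computed with [size_factors()] when NULL.
#' @param fdr_level q-value threshold for the `de_flag` (default 0.1).
#' @return data.frame of class `de_result`: feature, base_mean (mean
#'   normalized count), base_mean_raw, log2fc, se, stat, pvalue, padj,
#'   de_flag. All-zero features get NA statistics and are excluded from
#'   the FDR adjustment.
#' @export
nb_wald_test <- function(counts, labels, case_label = NULL, sf = NULL,
                         fdr_level = 0.1) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) stop("one label per sample required")
  lev <- unique(labels)
  if (length(lev) != 2L) stop("exactly two groups required")
  if (any(table(labels) < 2L)) stop("each group needs n >= 2")
  case_label <- case_label %||% lev[2L]
  if (!case_label %in% lev) stop("unknown case_label")
  x <- as.numeric(labels == case_label)
  if (is.null(sf)) sf <- size_factors(m)
  off <- log(sf)
  norm <- sweep(m, 2, sf, "/")
  disp <- mom_dispersion(norm, labels)

  nf <- nrow(m)
  log2fc <- se <- stat <- pvalue <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    y <- m[i, ]
    if (all(y == 0)) next
    fit <- tryCatch(suppressWarnings(
      stats::glm(y ~ x + offset(off),
                 family = MASS::negative.binomial(theta = 1 / disp[i]))
    ), error = function(e) NULL)
    if (is.null(fit)) next
    # dispersion fixed at 1: the NB variance with the plugged-in theta is
    # the model variance, not a quasi-dispersion to re-estimate
    cf <- summary(fit, dispersion = 1)$coefficients
    if (!"x" %in% rownames(cf)) next
    log2fc[i] <- cf["x", "Estimate"] / log(2)
    se[i] <- cf["x", "Std. Error"] / log(2)
    stat[i] <- cf["x", "Estimate"] / cf["x", "Std. Error"]
    pvalue[i] <- 2 * stats::pnorm(-abs(stat[i]))
  }
  padj <- bh_fdr(pvalue)
  out <- data.frame(feature = rownames(m) %||% as.character(seq_len(nf)),
                    base_mean = rowMeans(norm),
                    base_mean_raw = rowMeans(m),
                    log2fc = log2fc, se = se, stat = stat,
                    pvalue = pvalue, padj = padj,
                    de_flag = !is.na(padj) & padj < fdr_level,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values (capped at 1, monotone); NA p-values are
#' passed through as NA and do not enter the adjustment.
#'
#' @param p numeric vector of p-values in [0, 1]; NA allowed.
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Candidate-feature inclusion filter
#'
#' Restricts a differential expression result to initial biomarker
#' candidates: differentially expressed (q below the FDR level),
#' upregulated in cancer with log2 fold change strictly above `lfc_min`
#' (which subsumes fold change > 0), and moderately expressed with mean
#' raw read counts strictly above `mean_min`.
#'
#' @param de a `de_result` from [nb_wald_test()].
#' @param lfc_min log2 fold-change floor (strict; default 0.8).
#' @param mean_min mean raw-count floor (strict; default 10).
#' @param use_raw_mean filter on mean raw counts (default) or mean
#'   normalized counts.
#' @return character vector of candidate feature IDs.
#' @export
candidate_filter <- function(de, lfc_min = 0.8, mean_min = 10,
                             use_raw_mean = TRUE) {
  stopifnot(inherits(de, "de_result"))
  mu <- if (use_raw_mean) de$base_mean_raw else de$base_mean
  ok <- de$de_flag & !is.na(de$log2fc) &
    de$log2fc > 0 & de$log2fc > lfc_min & mu > mean_min
  de$feature[ok]
}

#' Cumulative-sum comparison of a feature set across groups
#'
#' Per sample, sums the RPM-normalized reads over a set of (upregulated
#' differentially expressed) features, then compares every requested group
#' pair with a two-sided Welch t-test — the analysis contrasting
#' early-stage cases, late-stage cases, and controls.
#'
#' @param cm a [count_matrix()].
#' @param features feature IDs to sum over (non-empty).
#' @param groups group label per sample (defaults to the matrix's class
#'   labels); each compared group needs n >= 2.
#' @param pairs list of 2-vectors of group labels to test; default: all
#'   pairs.
#' @return list: `sums` (named per-sample cumulative RPM), `tests`
#'   (data.frame: group1, group2, t, df, p).
#' @export
cumulative_sum_compare <- function(cm, features, groups = NULL, pairs = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(features) == 0L) stop("feature set is empty")
  groups <- groups %||% cm$sample_meta$class
  r <- rpm(cm)
  idx <- match(features, rownames(r))
  if (anyNA(idx)) stop("unknown feature(s) in set")
  sums <- colSums(r[idx, , drop = FALSE])
  lev <- unique(groups)
  pairs <- pairs %||% utils::combn(lev, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    a <- sums[groups == pr[1]]
    b <- sums[groups == pr[2]]
    if (length(a) < 2L || length(b) < 2L) stop("group n < 2: ", pr[1], "/", pr[2])
    tt <- stats::t.test(a, b)  # Welch by default
    data.frame(group1 = pr[1], group2 = pr[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  list(sums = sums, tests = tests)
}
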