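#' Stability feature-selection configuration
#'
#' @param n_repeats number of random train/test partitions (default 100).
#' @param train_frac training fraction per partition (default 0.8).
#' @param frequency_floor minimum number of repeats in which a feature
#'   must be selected to become a candidate (default 10 of 100).
#' @param topn_max largest N examined by the Top-N strategy (default 20).
#' @param boruta_max_runs cap on importance rounds per Boruta repeat
#'   (default 500).
#' @param boruta_ntree trees per importance forest (default 100).
#' @param boruta_alpha two-sided binomial test level for
#'   confirming/rejecting a feature against the best shadow (default 0.01).
#' @param seed master seed.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(n_repeats = 100L, train_frac = 0.8,
                             frequency_floor = 10L, topn_max = 20L,
                             boruta_max_runs = 500L, boruta_ntree = 100L,
                             boruta_alpha = 0.01, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  if (frequency_floor > n_repeats) {
    stop("frequency_floor cannot exceed n_repeats")
  }
  structure(list(n_repeats = as.integer(n_repeats), train_frac = train_frac,
                 frequency_floor = as.integer(frequency_floor),
                 topn_max = as.integer(topn_max),
                 boruta_max_runs = as.integer(boruta_max_runs),
                 boruta_ntree = as.integer(boruta_ntree),
                 boruta_alpha = boruta_alpha,
                 seed = as.integer(seed)),
            class = "selection_config")
}

selection_result <- function(strategy, selected, frequency, config) {
  structure(list(strategy = strategy, selected = selected,
                 frequency = frequency, n_repeats = config$n_repeats),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d features selected of %d scored\n",
              x$strategy, length(x$selected), length(x$frequency)))
  invisible(x)
}

# One fixed bank of stratified partitions so AUC comparisons across Top-N
# sets are paired.
partition_bank <- function(labels, config) {
  lapply(seq_len(config$n_repeats), function(it) {
    with_seed(derive_seed(config$seed, 5000L + it), {
      stratified_partition(labels, config$train_frac)
    })
  })
}

# Mean held-out test AUC of a feature set across the three classifiers
# over a fixed partition bank.
mean_panel_auc <- function(x, labels, case_label, panel, bank, config,
                           algorithms = c("lr", "rf", "svm")) {
  xp <- x[, panel, drop = FALSE]
  y <- factor(labels, levels = c(setdiff(unique(labels), case_label),
                                 case_label))
  aucs <- vapply(seq_along(bank), function(it) {
    idx <- bank[[it]]
    test <- setdiff(seq_len(nrow(xp)), idx)
    if (length(unique(labels[idx])) < 2L || length(unique(labels[test])) < 2L) {
      return(NA_real_)
    }
    mean(vapply(algorithms, function(alg) {
      pred <- with_seed(derive_seed(config$seed, 7000L + it), {
        fit_model(xp[idx, , drop = FALSE], y[idx], alg)
      })
      roc_auc(pred(xp[test, , drop = FALSE]), labels[test], case_label)
    }, numeric(1)))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Top-N filter selection over a significance ranking
#'
#' Starting from the two most significant features of the differential
#' expression ranking, the next-ranked feature is added one at a time; the
#' candidate set is evaluated by the mean held-out test AUC across the
#' three classifiers over a fixed bank of repeated partitions, and a
#' feature whose addition lowers that AUC is removed again. Ties keep the
#' smaller set. The accepted features at the end are the selected panel.
#'
#' @param x numeric matrix, samples x features.
#' @param labels two-class label per sample.
#' @param case_label the case class.
#' @param ranking feature IDs sorted by significance (most significant
#'   first, ties broken by smaller q, larger |log2FC|, then ID);
#'   at least 2.
#' @param config a [selection_config()]; `topn_max` caps how deep the
#'   ranking is examined.
#' @param algorithms classifiers averaged in the evaluation.
#' @return a `selection_result`; `frequency` here records, for
#'   bookkeeping, `n_repeats` for accepted and 0 for removed features.
#' @export
topn_select <- function(x, labels, case_label, ranking, config,
                        algorithms = c("lr", "rf", "svm")) {
  stopifnot(inherits(config, "selection_config"))
  if (length(ranking) < 2L) stop("need at least 2 ranked features")
  ranking <- ranking[seq_len(min(length(ranking), config$topn_max))]
  if (!all(ranking %in% colnames(x))) stop("ranking features missing from x")
  bank <- partition_bank(labels, config)
  accepted <- ranking[1:2]
  auc_prev <- mean_panel_auc(x, labels, case_label, accepted, bank, config,
                             algorithms)
  for (k in seq_along(ranking)[-(1:2)]) {
    trial <- c(accepted, ranking[k])
    auc_trial <- mean_panel_auc(x, labels, case_label, trial, bank, config,
                                algorithms)
    if (auc_trial > auc_prev) {
      accepted <- trial
      auc_prev <- auc_trial
    }
  }
  freq <- stats::setNames(ifelse(ranking %in% accepted,
                                 config$n_repeats, 0L), ranking)
  res <- selection_result("topn", accepted, freq, config)
  res$mean_auc <- auc_prev
  res
}

# One Boruta repeat: iterative shadow-feature importance rounds on the
# training split until every feature is confirmed or rejected (two-sided
# binomial test of hits against the best shadow) or the run cap is hit.
boruta_one_repeat <- function(xtr, ytr, config) {
  nf <- ncol(xtr)
  hits <- integer(nf)
  status <- rep("tentative", nf)
  rounds <- 0L
  while (any(status == "tentative") && rounds < config$boruta_max_runs) {
    rounds <- rounds + 1L
    shadow <- apply(xtr, 2, sample)
    colnames(shadow) <- paste0(".shadow", seq_len(nf))
    rf <- randomForest::randomForest(cbind(xtr, shadow), ytr,
                                     ntree = config$boruta_ntree,
                                     importance = TRUE)
    imp <- randomForest::importance(rf, type = 1)[, 1L]
    max_shadow <- max(imp[nf + seq_len(nf)])
    hits <- hits + as.integer(imp[seq_len(nf)] > max_shadow)
    if (rounds >= 5L) {
      p_hi <- stats::pbinom(hits - 1L, rounds, 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(hits, rounds, 0.5)
      status[status == "tentative" & p_hi < config$boruta_alpha / 2] <- "confirmed"
      status[status == "tentative" & p_lo < config$boruta_alpha / 2] <- "rejected"
    }
  }
  colnames(xtr)[status == "confirmed"]
}

#' Boruta-style shadow-feature selection over repeated partitions
#'
#' Per repeat, the training split is augmented with per-feature shuffled
#' "shadow" copies and random-forest permutation importance is computed in
#' rounds (up to `boruta_max_runs`); a feature scores a hit when its
#' importance exceeds the best shadow's, and is confirmed or rejected by a
#' two-sided binomial test on its hit count. Features confirmed in at
#' least `frequency_floor` of the repeats are selected.
#'
#' @inheritParams topn_select
#' @return a `selection_result` with per-feature confirmation frequencies.
#' @export
boruta_select <- function(x, labels, case_label, config) {
  stopifnot(inherits(config, "selection_config"))
  if (ncol(x) < 2L) stop("need at least 2 features")
  y_all <- factor(labels, levels = c(setdiff(unique(labels), case_label),
                                     case_label))
  freq <- stats::setNames(integer(ncol(x)), colnames(x))
  for (it in seq_len(config$n_repeats)) {
    confirmed <- with_seed(derive_seed(config$seed, 9000L + it), {
      idx <- stratified_partition(labels, config$train_frac)
      if (length(unique(labels[idx])) < 2L) {
        character(0)
      } else {
        boruta_one_repeat(x[idx, , drop = FALSE], y_all[idx], config)
      }
    })
    freq[confirmed] <- freq[confirmed] + 1L
  }
  selection_result("boruta", names(freq)[freq >= config$frequency_floor],
                   freq, config)
}

#' LASSO frequency selection over repeated partitions
#'
#' Per repeat, an L1-penalized binomial GLM is fit to the standardized
#' (z-scored) training features, with the penalty chosen as lambda.1se —
#' the largest penalty whose 10-fold cross-validated deviance is within
#' one standard error of the minimum, giving a sparser model at near-best
#' deviance — and the features with non-zero coefficients are recorded.
#' Features with non-zero coefficients in at least `frequency_floor` of
#' the repeats are selected. A degenerate single-class split is skipped
#' with a warning.
#'
#' @inheritParams topn_select
#' @return a `selection_result` with per-feature non-zero-coefficient
#'   frequencies.
#' @export
lasso_select <- function(x, labels, case_label, config) {
  stopifnot(inherits(config, "selection_config"))
  if (ncol(x) < 2L) stop("need at least 2 features")
  y_all <- factor(labels, levels = c(setdiff(unique(labels), case_label),
                                     case_label))
  freq <- stats::setNames(integer(ncol(x)), colnames(x))
  for (it in seq_len(config$n_repeats)) {
    nz <- with_seed(derive_seed(config$seed, 11000L + it), {
      idx <- stratified_partition(labels, config$train_frac)
      if (length(unique(labels[idx])) < 2L) {
        warning("repeat ", it, " skipped: single-class training split")
        character(0)
      } else {
        xtr <- scale(x[idx, , drop = FALSE])
        xtr[, attr(xtr, "scaled:scale") == 0] <- 0  # constant columns
        nfolds <- max(3L, min(10L, floor(length(idx) / 3)))
        cv <- suppressWarnings(
          glmnet::cv.glmnet(xtr, y_all[idx], family = "binomial",
                            alpha = 1, nfolds = nfolds,
                            standardize = FALSE))
        cf <- as.matrix(stats::coef(cv, s = "lambda.1se"))[-1L, 1L]
        names(cf)[cf != 0]
      }
    })
    freq[nz] <- freq[nz] + 1L
  }
  selection_result("lasso", names(freq)[freq >= config$frequency_floor],
                   freq, config)
}

#' Rank a differential expression result by significance
#'
#' Orders features by p-value with ties broken by smaller q-value, larger
#' absolute log2 fold change, then feature ID — the ranking consumed by
#' [topn_select()].
#'
#' @param de a `de_result` from [nb_wald_test()].
#' @param features optional subset to rank (e.g. candidates of one RNA
#'   type).
#' @return character vector of feature IDs, most significant first.
#' @export
de_ranking <- function(de, features = NULL) {
  stopifnot(inherits(de, "de_result"))
  d <- de[!is.na(de$pvalue), ]
  if (!is.null(features)) d <- d[d$feature %in% features, ]
  d <- d[order(d$pvalue, d$padj, -abs(d$log2fc), d$feature), ]
  d$feature
}
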