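# Model fitting backends. `x` rows are samples, columns features; `y` is a
# factor with the case class as the second level. Each returns a function
# mapping a new sample matrix to case-oriented scores (probabilities for
# lr/rf, decision values for svm).

fit_model <- function(x, y, algorithm, ntree = 500L) {
  case <- levels(y)[2L]
  switch(algorithm,
    lr = {
      if (ncol(x) < 2L) {
        # glmnet needs >= 2 columns; plain logistic fit for 1-feature panels
        df <- data.frame(y = y, v = x[, 1L])
        fit <- suppressWarnings(stats::glm(y ~ v, data = df, family = "binomial"))
        function(newx) {
          unname(stats::predict(fit, data.frame(v = newx[, 1L]),
                                type = "response"))
        }
      } else {
        nfolds <- max(3L, min(10L, floor(length(y) / 3)))
        # small desk-scale folds trigger glmnet's sparse-class warning;
        # harmless here, so keep the log quiet
        cv <- suppressWarnings(
          glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                            nfolds = nfolds))
        function(newx) {
          as.numeric(stats::predict(cv, newx, s = "lambda.min",
                                    type = "response"))
        }
      }
    },
    rf = {
      fit <- randomForest::randomForest(x, y, ntree = ntree)
      function(newx) unname(stats::predict(fit, newx, type = "prob")[, case])
    },
    svm = {
      fit <- e1071::svm(x, y, kernel = "linear", cost = 1, scale = TRUE)
      function(newx) {
        dv <- attr(stats::predict(fit, newx, decision.values = TRUE),
                   "decision.values")
        lab <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]]
        if (lab[1L] == case) as.numeric(dv) else -as.numeric(dv)
      }
    },
    stop("unknown algorithm: ", algorithm)
  )
}

#' Repeated-partition train/test evaluation of one panel
#'
#' The core evaluation loop: the cohort is randomly partitioned into 80%
#' training and 20% held-out test sets, stratified by class; a model is
#' fit on the training split and scored on the test split; the whole
#' process is repeated (100 times by default) to prevent random sampling
#' bias. Risk scores are strictly out-of-fold: a sample accumulates scores
#' only from iterations in which it was held out, and its median score
#' summarizes them. A partition missing a class in either split is
#' redrawn with the next seed.
#'
#' @param x numeric matrix, samples x features (e.g. t(log2rpm(cm))).
#' @param labels two-class label per sample.
#' @param case_label the case (positive) class.
#' @param panel feature IDs (columns of `x`) in the panel; default all.
#' @param algorithm "lr" (ridge logistic regression, penalty by internal
#'   cross-validation), "rf" (random forest, 500 trees), or "svm" (linear
#'   kernel, cost 1; scores are decision values, not probabilities).
#' @param n_repeats number of random partitions (default 100).
#' @param train_frac training fraction (default 0.8).
#' @param seed seed; the harness is exactly reproducible given it.
#' @return list of class `model_report`: `auc_train`, `auc_test`
#'   (per-iteration), `scores` (samples x iterations, NA when in
#'   training), `median_scores`, `algorithm`, `panel`, `case_label`,
#'   `threshold` (0.5), `n_repeats`.
#' @export
repeat_harness <- function(x, labels, case_label, panel = colnames(x),
                           algorithm = c("lr", "rf", "svm"),
                           n_repeats = 100L, train_frac = 0.8, seed = 1L) {
  algorithm <- match.arg(algorithm)
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) stop("two classes required")
  if (!case_label %in% labels) stop("case_label absent from labels")
  if (!all(panel %in% colnames(x))) stop("panel features missing from matrix")
  xp <- x[, panel, drop = FALSE]
  y <- factor(labels, levels = c(setdiff(unique(labels), case_label),
                                 case_label))
  n <- nrow(xp)
  scores <- matrix(NA_real_, n, n_repeats,
                   dimnames = list(rownames(x), NULL))
  auc_train <- auc_test <- numeric(n_repeats)
  for (it in seq_len(n_repeats)) {
    tries <- 0L
    repeat {
      idx <- with_seed(derive_seed(seed, it * 131L + tries), {
        stratified_partition(labels, train_frac)
      })
      test <- setdiff(seq_len(n), idx)
      if (length(unique(labels[idx])) == 2L &&
          length(unique(labels[test])) == 2L) break
      tries <- tries + 1L
      message("repartitioning iteration ", it, " (class missing)")
      if (tries > 50L) stop("cannot obtain a two-class partition")
    }
    pred <- with_seed(derive_seed(seed, it * 977L + 7L), {
      fit_model(xp[idx, , drop = FALSE], y[idx], algorithm)
    })
    s_tr <- pred(xp[idx, , drop = FALSE])
    s_te <- pred(xp[test, , drop = FALSE])
    auc_train[it] <- roc_auc(s_tr, labels[idx], case_label)
    auc_test[it] <- roc_auc(s_te, labels[test], case_label)
    scores[test, it] <- s_te
  }
  structure(list(auc_train = auc_train, auc_test = auc_test,
                 scores = scores,
                 median_scores = apply(scores, 1, stats::median, na.rm = TRUE),
                 algorithm = algorithm, panel = panel,
                 case_label = case_label, threshold = 0.5,
                 n_repeats = n_repeats),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("model_report (%s): %d features, %d iterations\n",
              x$algorithm, length(x$panel), x$n_repeats))
  cat(sprintf("median test AUC: %.3f (IQR %.3f-%.3f)\n",
              stats::median(x$auc_test),
              stats::quantile(x$auc_test, 0.25),
              stats::quantile(x$auc_test, 0.75)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' The Mann-Whitney concordance probability: the chance that a random case
#' scores above a random control, with ties counting one half.
#'
#' @param scores numeric scores (any monotone scale).
#' @param labels class label per score.
#' @param case_label the positive class; both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, case_label) {
  pos <- labels == case_label
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity from median risk scores
#'
#' Uses the risk-score definitions of the screening analysis: a sample is
#' called high-risk when its median out-of-fold risk score reaches the
#' threshold. Sensitivity is the fraction of cases called high-risk;
#' specificity (a precision-style definition) is the fraction of
#' high-risk calls that are true cases. Both are returned in percent.
#'
#' @param median_scores numeric median risk score per sample.
#' @param labels class label per sample.
#' @param case_label the case class.
#' @param threshold high-risk cutoff (default 0.5; a score equal to the
#'   threshold counts as high).
#' @return list: `sensitivity`, `specificity` (percent; specificity is NA
#'   when no sample is called high-risk), `n_cases`, `n_high`,
#'   `n_high_cases`.
#' @export
sens_spec <- function(median_scores, labels, case_label, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  # a sample with no out-of-fold score (NA median) cannot be called high
  high <- !is.na(median_scores) & median_scores >= threshold
  cases <- labels == case_label
  n_high <- sum(high)
  n_high_cases <- sum(high & cases)
  list(sensitivity = 100 * n_high_cases / sum(cases),
       specificity = if (n_high == 0L) NA_real_ else 100 * n_high_cases / n_high,
       n_cases = sum(cases), n_high = n_high, n_high_cases = n_high_cases)
}

#' Enumerate RNA-type combination panels
#'
#' All non-empty subsets of the given RNA types, in a deterministic order
#' (by subset size, then lexicographically); five types yield the 31
#' combination panels evaluated in the combination analysis.
#'
#' @param types character vector of RNA types (1 to 16).
#' @return list of character vectors, each one combination.
#' @export
enumerate_combos <- function(types) {
  if (length(types) == 0L) stop("empty type list")
  if (length(types) > 16L) stop("too many types")
  types <- sort(types)
  combos <- unlist(lapply(seq_along(types), function(k) {
    utils::combn(types, k, simplify = FALSE)
  }), recursive = FALSE)
  combos
}

#' One-vs-rest multi-class classification with per-class panels
#'
#' For each class panel (each cancer type, plus optionally a pooled
#' "cancers" panel covering all non-control samples), runs the binary
#' repeated-partition harness of that class against all other samples and
#' collects each sample's median out-of-fold risk score per class.
#'
#' @param x numeric matrix, samples x features.
#' @param labels multi-class label per sample.
#' @param panels named list: class label -> feature IDs. A panel named
#'   `"cancers"` is scored as all non-control samples vs the control
#'   class.
#' @param control_label label of the control (non-case) class.
#' @param algorithm,n_repeats,train_frac,seed passed to [repeat_harness()].
#' @return list: `reports` (named list of `model_report`), `score_matrix`
#'   (samples x panels, median risk scores).
#' @export
one_vs_rest <- function(x, labels, panels, control_label = "control",
                        algorithm = "lr", n_repeats = 100L,
                        train_frac = 0.8, seed = 1L) {
  stopifnot(is.list(panels), !is.null(names(panels)))
  labels <- as.character(labels)
  reports <- list()
  for (cls in names(panels)) {
    if (cls == "cancers") {
      bin <- ifelse(labels == control_label, "rest", "cancers")
    } else {
      if (sum(labels == cls) < 5L) {
        warning("class ", cls, " has n < 5; results will be unstable")
      }
      bin <- ifelse(labels == cls, cls, "rest")
    }
    reports[[cls]] <- repeat_harness(
      x, bin, case_label = setdiff(unique(bin), "rest"),
      panel = panels[[cls]], algorithm = algorithm, n_repeats = n_repeats,
      train_frac = train_frac, seed = derive_seed(seed, match(cls, names(panels)))
    )
  }
  score_matrix <- vapply(reports, `[[`, numeric(nrow(x)), "median_scores")
  list(reports = reports, score_matrix = score_matrix)
}

#' Two-step cancer diagnosis rule
#'
#' A sample is called positive only when both the common cancer risk score
#' and at least one cancer type-specific risk score are high (at or above
#' the threshold); the conjunction can only remove positives relative to
#' the common score alone, raising specificity at some cost in
#' sensitivity. All type panels reaching the threshold are reported.
#'
#' @param common_scores numeric common-cancer risk score per sample.
#' @param type_scores matrix, samples x cancer types, of type-specific
#'   risk scores.
#' @param threshold high-risk cutoff (default 0.5).
#' @return data.frame: sample, call ("negative"/"positive"), types
#'   (";"-separated high-scoring types, "" when negative).
#' @export
two_step_diagnosis <- function(common_scores, type_scores, threshold = 0.5) {
  type_scores <- as.matrix(type_scores)
  if (length(common_scores) != nrow(type_scores)) {
    stop("score dimensions disagree")
  }
  # an NA median (sample never held out) cannot support a positive call
  high_type <- !is.na(type_scores) & type_scores >= threshold
  pos <- !is.na(common_scores) & common_scores >= threshold &
    rowSums(high_type) > 0L
  types <- vapply(seq_len(nrow(type_scores)), function(i) {
    if (!pos[i]) return("")
    paste(colnames(type_scores)[high_type[i, ]], collapse = ";")
  }, character(1))
  data.frame(sample = rownames(type_scores) %||%
               as.character(seq_along(common_scores)),
             call = ifelse(pos, "positive", "negative"),
             types = types, stringsAsFactors = FALSE)
}
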