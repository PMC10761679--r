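test_that("AUC equals the Mann-Whitney concordance probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                       c("c", "c", "n", "n"), "c"), 1)
  expect_equal(roc_auc(rep(0.4, 6), rep(c("c", "n"), 3), "c"), 0.5)
  expect_error(roc_auc(1:3, rep("c", 3), "c"), "both classes")
  set.seed(14)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    labels <- sample(c("case", "ctrl"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("case", "ctrl")
    scores <- round(runif(n), 2)  # rounding provokes ties
    expect_equal(roc_auc(scores, labels, "case"),
                 oracle_auc(scores, labels, "case"))
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(exp(3 * scores) + 1, labels, "case"),
                 roc_auc(scores, labels, "case"))
  }
})

test_that("AUC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:20) {
    labels <- sample(c("case", "ctrl"), 30, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("case", "ctrl")
    scores <- runif(30)
    ext <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("ctrl", "case"),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(scores, labels, "case"), ext)
  }
})

test_that("sensitivity and specificity follow the risk-score definitions", {
  # discovery cohort arithmetic: 139 cases, 134 called high; 137 total high
  scores <- c(rep(1, 134), rep(0, 5), rep(1, 3), rep(0, 103))
  labels <- c(rep("LC", 139), rep("NOR", 106))
  ss <- sens_spec(scores, labels, "LC")
  expect_equal(round(ss$sensitivity, 2), 96.40)
  expect_equal(round(ss$specificity, 2), 97.81)
  # validation cohort: 33 called high, 7 of them not cases
  ss2 <- sens_spec(c(rep(1, 26), rep(1, 7), rep(0, 20)),
                   c(rep("LC", 26), rep("NOR", 27)), "LC")
  expect_equal(round(ss2$specificity, 2), 78.79)
  expect_equal(ss2$sensitivity, 100)
  # a score exactly at the threshold counts as high
  ss3 <- sens_spec(c(0.5, 0.49), c("LC", "LC"), "LC")
  expect_equal(ss3$sensitivity, 50)
  # no high scores: specificity undefined
  expect_true(is.na(sens_spec(c(0.1, 0.2), c("LC", "NOR"), "LC")$specificity))
  expect_error(sens_spec(0.4, "LC", "LC", threshold = 1.2), "threshold")
})

test_that("combination panels enumerate all non-empty type subsets", {
  five <- enumerate_combos(c("mRNA", "miRNA", "snRNA", "snoRNA", "tsRNA"))
  expect_length(five, 31L)
  expect_length(enumerate_combos("miRNA"), 1L)
  expect_length(enumerate_combos(c("a", "b", "c")), 7L)
  # deterministic order: by size, then lexicographic
  expect_equal(five[[1]], "mRNA")
  expect_equal(five[[31]], sort(c("mRNA", "miRNA", "snRNA", "snoRNA",
                                  "tsRNA")))
  expect_equal(anyDuplicated(vapply(five, paste, "", collapse = "+")), 0L)
  expect_error(enumerate_combos(character(0)), "empty")
})

test_that("repeat harness separates, nulls, and reproduces deterministically", {
  set.seed(3)
  n <- 60
  labels <- rep(c("control", "cancer"), each = n / 2)
  x <- cbind(f1 = rnorm(n, ifelse(labels == "cancer", 2.5, 0)),
             f2 = rnorm(n, ifelse(labels == "cancer", 2.0, 0)),
             f3 = rnorm(n))
  rownames(x) <- paste0("s", 1:n)
  rep1 <- repeat_harness(x, labels, "cancer", panel = c("f1", "f2"),
                         algorithm = "lr", n_repeats = 10, seed = 7)
  expect_equal(median(rep1$auc_test), 1)
  expect_true(all(rep1$auc_test >= 0 & rep1$auc_test <= 1))
  expect_true(all(rep1$scores >= 0 & rep1$scores <= 1, na.rm = TRUE))
  # out-of-fold bookkeeping: 12 held-out samples scored per iteration
  expect_equal(sum(!is.na(rep1$scores)), 10L * 12L)
  # permuted labels: chance-level AUC
  perm <- sample(labels)
  rep0 <- repeat_harness(x, perm, "cancer", panel = c("f1", "f2"),
                         algorithm = "lr", n_repeats = 20, seed = 7)
  expect_gte(median(rep0$auc_test), 0.3)
  expect_lte(median(rep0$auc_test), 0.7)
  # determinism
  rep2 <- repeat_harness(x, labels, "cancer", panel = c("f1", "f2"),
                         algorithm = "lr", n_repeats = 10, seed = 7)
  expect_identical(rep1$scores, rep2$scores)
  expect_identical(rep1$auc_test, rep2$auc_test)
  # the rf and svm backends run and separate the same data
  for (alg in c("rf", "svm")) {
    r <- repeat_harness(x, labels, "cancer", panel = c("f1", "f2"),
                        algorithm = alg, n_repeats = 5, seed = 2)
    expect_gte(median(r$auc_test), 0.9)
  }
  expect_error(repeat_harness(x, labels, "cancer", panel = "nope"),
               "missing")
})

test_that("one-vs-rest scores give each class its own panel signal", {
  cfg <- sim_config(seed = 33,
                    n_samples_per_class = c(control = 30, LC = 18, CRC = 18),
                    classes = c("control", "LC", "CRC"),
                    n_features_per_type = c(miRNA = 150L, mRNA = 150L),
                    de_fraction = 0.04, planted_log2fc = 2)
  g <- gen_count_matrix(cfg, n_common = 10L)
  cm <- g$matrix
  cls <- cm$sample_meta$class
  x <- t(log2rpm(cm))
  panels <- list(LC = g$truth$planted_features$LC,
                 CRC = g$truth$planted_features$CRC,
                 cancers = g$truth$planted_features$common)
  ovr <- one_vs_rest(x, cls, panels, control_label = "control",
                     n_repeats = 25, seed = 5)
  sm <- ovr$score_matrix
  # control samples score low in every panel
  expect_lt(median(sm[cls == "control", "LC"]), 0.5)
  expect_lt(median(sm[cls == "control", "CRC"]), 0.5)
  expect_lt(median(sm[cls == "control", "cancers"]), 0.5)
  # the highest type-specific score identifies the true class
  cancer <- cls != "control"
  best <- colnames(sm)[apply(sm[cancer, c("LC", "CRC")], 1, which.max)]
  expect_gte(mean(best == cls[cancer]), 0.9)
  # cancer patients score high in the pooled common-cancer panel
  expect_gt(median(sm[cancer, "cancers"]), 0.5)
  # deterministic rerun
  ovr2 <- one_vs_rest(x, cls, panels, control_label = "control",
                      n_repeats = 25, seed = 5)
  expect_identical(ovr$score_matrix, ovr2$score_matrix)
})

test_that("the two-step rule is a conjunction and never adds positives", {
  ts <- matrix(c(0.4, 0.8, 0.9,
                 0.4, 0.4, 0.9), 3, 2, byrow = FALSE,
               dimnames = list(c("s1", "s2", "s3"), c("LC", "GC")))
  dx <- two_step_diagnosis(c(0.9, 0.4, 0.9), ts)
  # s1: common high but no type high -> negative
  # s2: type high but common low -> negative
  # s3: both high -> positive, reporting every high panel
  expect_equal(dx$call, c("negative", "negative", "positive"))
  expect_equal(dx$types[3], "LC;GC")

  set.seed(21)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    common <- runif(n)
    types <- matrix(runif(n * 3), n, 3,
                    dimnames = list(NULL, c("A", "B", "C")))
    dx <- two_step_diagnosis(common, types)
    one_step <- common >= 0.5
    expect_true(all(which(dx$call == "positive") %in% which(one_step)))
  }
})
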