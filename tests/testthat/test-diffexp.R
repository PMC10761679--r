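test_that("size factors reproduce the median-of-ratios definition", {
  # two identical columns normalize to unit factors
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), 3, 2,
              dimnames = list(paste0("f", 1:3), c("A", "B")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # a column scaled by 2 gets twice the factor
  m2 <- cbind(A = c(10L, 20L, 30L), B = c(20L, 40L, 60L))
  rownames(m2) <- paste0("f", 1:3)
  sf <- size_factors(m2)
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  # random NB matrices match a literal recomputation
  set.seed(55)
  for (i in 1:100) {
    mm <- matrix(rnbinom(60, mu = 50, size = 5) + 1L, 10, 6)
    dimnames(mm) <- list(paste0("f", 1:10), paste0("S", 1:6))
    expect_equal(unname(size_factors(mm)), unname(oracle_size_factors(mm)))
  }
  # fallback path and its disabling
  # every row carries at least one zero: no all-nonzero feature exists
  mz <- matrix(c(0L, 5L, 7L, 3L, 0L, 0L), 3, 2,
               dimnames = list(paste0("f", 1:3), c("A", "B")))
  expect_error(size_factors(mz, fallback = FALSE), "no feature")
  expect_true(all(size_factors(mz) > 0))
})

test_that("identical groups give zero fold change and p near one", {
  m <- matrix(rep(c(30L, 80L, 12L, 55L), 6), 4, 6,
              dimnames = list(paste0("f", 1:4), paste0("S", 1:6)))
  de <- nb_wald_test(m, rep(c("control", "cancer"), each = 3),
                     case_label = "cancer")
  expect_equal(de$log2fc, rep(0, 4), tolerance = 1e-6)
  expect_equal(de$pvalue, rep(1, 4), tolerance = 1e-6)
  # all-zero features are excluded from testing and FDR
  m0 <- rbind(m, fz = 0L)
  de0 <- nb_wald_test(m0, rep(c("control", "cancer"), each = 3),
                      case_label = "cancer")
  expect_true(is.na(de0$pvalue[5]))
  expect_true(is.na(de0$padj[5]))
  expect_error(nb_wald_test(m, rep("a", 6)), "two groups")
})

test_that("planted fold changes are recovered at high depth", {
  g <- gen_count_matrix(sim_config(seed = 31, n_samples_per_class = 30,
                                   n_features_per_type = c(miRNA = 400L),
                                   de_fraction = 0.05, planted_log2fc = 2))
  cm <- g$matrix
  de <- nb_wald_test(cm, cm$sample_meta$class, case_label = "cancer")
  est <- de$log2fc[match(g$truth$planted_features$cancer, de$feature)]
  expect_equal(median(est), 2, tolerance = 0.1)  # within +-0.2 of truth
})

test_that("BH adjustment matches hand computation and is order-invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.04), 0.04)                 # single p: q = p
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))   # all equal stay equal
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(66)
  for (i in 1:100) {
    p <- runif(sample(3:40, 1))
    if (runif(1) < 0.3) p[sample(length(p), 1)] <- NA
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p, na.rm = TRUE))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
  }
})

test_that("candidate filter applies its boundaries strictly", {
  de <- fake_de(feature = paste0("f", 1:6),
                log2fc = c(1.0, 1.0, 0.8, -1.2, 1.0, 2.0),
                padj = c(0.05, 0.05, 0.05, 0.05, 0.15, 0.05),
                base_mean_raw = c(50, 9, 50, 50, 50, 10))
  got <- candidate_filter(de)
  # f1 passes; f2 mean 9 <= 10 fails; f3 log2FC exactly 0.8 fails (strict);
  # f4 downregulated fails; f5 not DE fails; f6 mean exactly 10 fails
  expect_equal(got, "f1")
  # boundary just above passes
  de2 <- fake_de("g1", log2fc = 0.8 + 1e-9, padj = 0.05,
                 base_mean_raw = 10 + 1e-9)
  expect_equal(candidate_filter(de2), "g1")
  # candidate set shrinks monotonically as thresholds tighten
  de3 <- fake_de(paste0("h", 1:50), log2fc = runif(50, 0, 3),
                 padj = runif(50, 0, 0.2), base_mean_raw = runif(50, 1, 100))
  loose <- candidate_filter(de3, lfc_min = 0.5, mean_min = 5)
  tight <- candidate_filter(de3, lfc_min = 1.2, mean_min = 20)
  expect_true(all(tight %in% loose))
})

test_that("cumulative sums separate planted groups and match Welch formula", {
  # textbook two-sample Welch check on fixed vectors
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2)
  m <- rbind(f1 = c(a, b) * 10)
  m <- rbind(m, f2 = 100 - m[1, ] / 10)
  colnames(m) <- paste0("S", 1:20)
  cm <- count_matrix(round(m), rep("miRNA", 2),
                     sample_class = rep(c("g1", "g2"), each = 10))
  res <- cumulative_sum_compare(cm, "f1")
  sa <- res$sums[1:10]
  sb <- res$sums[11:20]
  # closed-form Welch t and Satterthwaite df, computed by hand
  va <- var(sa) / 10
  vb <- var(sb) / 10
  t_hand <- (mean(sa) - mean(sb)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 9 + vb^2 / 9)
  expect_equal(res$tests$t, t_hand, tolerance = 1e-12)
  expect_equal(res$tests$df, df_hand, tolerance = 1e-12)
  expect_equal(res$tests$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  # planted-effect simulation: case sums dominate control sums
  g <- gen_count_matrix(sim_config(seed = 41, n_samples_per_class = 20,
                                   n_features_per_type = c(miRNA = 200L),
                                   planted_log2fc = 2))
  cmx <- g$matrix
  res2 <- cumulative_sum_compare(cmx, g$truth$planted_features$cancer)
  cls <- cmx$sample_meta$class
  expect_gt(median(res2$sums[cls == "cancer"]),
            median(res2$sums[cls == "control"]))
  expect_lt(res2$tests$p, 0.01)
  expect_error(cumulative_sum_compare(cmx, character(0)), "empty")
})
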