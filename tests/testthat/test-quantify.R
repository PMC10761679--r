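test_that("exact-match counting requires full-length identity", {
  ref <- reference_set(id = c("e1", "e2"), rna_type = "tsRNA",
                       sequence = c("ACGTACGTACGTACGT", "TTGGCCAATTGGCCAA"))
  reads <- c("ACGTACGTACGTACGT", "ACGTACGTACGTACGT",
             "ACGTACGTACGTACGTA",   # one trailing extra base: no count
             "ACGTACGTACGTACG")     # one missing base: no count
  cnt <- count_exact(reads, ref)
  expect_equal(unname(cnt), c(2L, 0L))
  expect_equal(names(cnt), c("e1", "e2"))
})

test_that("containment counting gates length and drops ambiguous reads", {
  ref <- reference_set(
    id = c("mir1", "mir2"), rna_type = "miRNA",
    sequence = c("TAGCTTATCAGACTGATGTTGA",   # 22 nt
                 "ACTGGCCTTATCAGACTGACCT"))
  # 18-nt read matching mir1 is dropped below the 19-nt miRNA gate
  expect_equal(unname(count_contained(substr(ref$sequence[1], 1, 18),
                                      ref, min_len = 19)), c(0L, 0L))
  # 22-nt read contained in exactly one mature sequence counts once
  expect_equal(unname(count_contained(ref$sequence[1], ref, min_len = 19)),
               c(1L, 0L))
  # a read contained in two distinct features is ambiguous: dropped
  amb <- reference_set(id = c("a", "b"), rna_type = "miRNA",
                       sequence = c("AAACGTACGTACGTACGTAAA",
                                    "CCACGTACGTACGTACGTCCC"))
  expect_equal(unname(count_contained("ACGTACGTACGTACGT", amb)), c(0L, 0L))
})

test_that("both counters match their brute-force oracles on random instances", {
  set.seed(303)
  for (i in 1:100) {
    nref <- sample(3:8, 1)
    ref <- reference_set(id = paste0("r", seq_len(nref)),
                         rna_type = "tsRNA",
                         sequence = vapply(seq_len(nref), function(j) {
                           rand_seq(sample(18:30, 1))
                         }, character(1)))
    reads <- c(
      sample(ref$sequence, 5, replace = TRUE),
      vapply(1:5, function(j) rand_seq(sample(15:30, 1)), character(1)),
      vapply(1:5, function(j) {
        e <- sample(ref$sequence, 1)
        len <- sample(15:nchar(e), 1)
        st <- sample(nchar(e) - len + 1L, 1)
        substr(e, st, st + len - 1L)
      }, character(1)))
    reads <- sample(reads)
    expect_equal(unname(count_exact(reads, ref)),
                 oracle_count_exact(reads, ref))
    gate <- sample(c(0L, 19L, 23L), 1)
    expect_equal(unname(count_contained(reads, ref, gate)),
                 oracle_count_contained(reads, ref, gate))
    # permutation invariance in read order
    expect_equal(count_exact(rev(reads), ref), count_exact(reads, ref))
  }
})

test_that("matrix assembly unions features and conserves counts", {
  per_sample <- list(S1 = c(f1 = 3L, f2 = 1L), S2 = c(f3 = 5L))
  types <- c(f1 = "miRNA", f2 = "miRNA", f3 = "tsRNA")
  cm <- assemble_matrix(per_sample, types)
  expect_equal(dim(cm$counts), c(3L, 2L))
  expect_equal(cm$counts["f3", "S1"], 0L)      # missing pairs are zero
  expect_equal(colSums(cm$counts), c(S1 = 4L, S2 = 5L))
  expect_equal(cm$feature_meta$rna_type[cm$feature_meta$id == "f3"], "tsRNA")
  expect_error(
    assemble_matrix(list(S1 = c(f1 = 1L, f1 = 2L)), c(f1 = "miRNA")),
    "duplicate")
})

test_that("assembly of simulator output reproduces the generator tally", {
  cfg <- sim_config(seed = 17)
  parents <- gen_parent_references(cfg)
  bc <- c(S1 = "AAACCCGG", S2 = "TTTGGGCC")
  sim <- gen_fragment_reads(parents, cfg, bc, reads_per_sample = 300L)
  spec <- trim_spec(cfg$adapter_seq,
                    barcode_table = setNames(names(bc), unname(bc)))
  clean <- demultiplex(sim$r1, sim$r2, spec)$reads
  clean <- clean[clean$status == "ok", ]
  ref <- build_derived_reference(clean$insert, parents, "rsRNA")
  cm <- assemble_matrix(lapply(split(clean$insert, clean$sample),
                               count_exact, reference = ref),
                        setNames(ref$rna_type, ref$id))
  # every clean insert is by construction a parent substring, so totals match
  expect_equal(unname(colSums(cm$counts)),
               unname(table(clean$sample)[colnames(cm$counts)]),
               ignore_attr = TRUE)
  # per-entry counts equal a direct dictionary tally per sample
  for (s in colnames(cm$counts)) {
    expect_equal(unname(cm$counts[, s]),
                 as.integer(oracle_count_exact(
                   clean$insert[clean$sample == s], ref)))
  }
})

test_that("RPM normalization scales columns to one million", {
  m <- matrix(c(1L, 1L, 3L, 1L), 2, 2,
              dimnames = list(c("f1", "f2"), c("S1", "S2")))
  cm <- count_matrix(m, c("miRNA", "miRNA"))
  r <- rpm(cm)
  expect_equal(r[, "S1"], c(f1 = 5e5, f2 = 5e5))
  expect_equal(unname(colSums(r)), c(1e6, 1e6))
  expect_equal(log2rpm(cm)["f1", "S2"], log2(7.5e5 + 1))
  # a zero count maps to log2rpm 0 under the +1 pseudocount
  m2 <- matrix(c(0L, 4L), 2, 1, dimnames = list(c("f1", "f2"), "S1"))
  expect_equal(log2rpm(count_matrix(m2, c("a", "b")))["f1", 1], 0)
  m3 <- matrix(c(0L, 0L, 1L, 2L), 2, 2,
               dimnames = list(c("f1", "f2"), c("S1", "S2")))
  expect_error(rpm(count_matrix(m3, c("a", "b"))), "S1")
})

test_that("species detection census is monotone in read depth", {
  set.seed(5)
  deep <- matrix(rpois(300, 2), 100, 3,
                 dimnames = list(paste0("f", 1:100), paste0("S", 1:3)))
  shallow <- matrix(rbinom(300, deep, 0.3), 100, 3,
                    dimnames = dimnames(deep))  # nested subsample
  deep[1, ] <- pmax(deep[1, ], 1L)  # keep columns non-zero
  shallow[1, ] <- pmax(shallow[1, ], 1L)
  cm_d <- count_matrix(deep, rep("miRNA", 100))
  cm_s <- count_matrix(shallow, rep("miRNA", 100))
  expect_true(all(species_detected(cm_s) <= species_detected(cm_d)))
})
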