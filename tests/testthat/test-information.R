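test_that("column entropy is Shannon entropy over residues only", {
  aln <- aln_from_cols("AAAA", "AACC", "AC-G", "----")
  expect_identical(column_entropy(aln, 1), 0)
  expect_equal(column_entropy(aln, 2), 1)
  # one gap removed: uniform over {A, C, G}, n_effective = 3
  expect_equal(column_entropy(aln, 3), log2(3))
  expect_true(is.na(column_entropy(aln, 4)))
  # agrees with the brute-force oracle on random gapped columns
  chars <- rand_chars(50, 6, c(ORACLE_RESIDUES[1:5], "-", "X"), 11)
  aln2 <- new_msa(chars)
  for (a in 1:6) {
    expect_equal(column_entropy(aln2, a), oracle_entropy(chars[, a]),
                 tolerance = 1e-12)
  }
})

test_that("contingency tables are nullified and recounted", {
  aln <- aln_from_cols("AA", "CC", "A-")
  ct <- contingency(aln, 1, 2)
  expect_identical(ct$counts["A", "C"], 2L)
  expect_identical(ct$n_effective, 2L)
  expect_identical(sum(ct$raw_counts), 2L)  # pre-nullification total = M
  # gap row zeroed: ("-", "C") survives only in raw_counts
  ct2 <- contingency(aln, 3, 2)
  expect_identical(ct2$n_effective, 1L)
  expect_identical(ct2$raw_counts["-", "C"], 1L)
  expect_identical(sum(ct2$counts), 1L)
  expect_true(ct2$nullified)
  expect_error(contingency(aln, 1, 1), "distinct")
})

test_that("n_effective equals the gap-free row count", {
  chars <- rand_chars(200, 2, c(ORACLE_RESIDUES[1:4], "-"), 21)
  aln <- new_msa(chars)
  brute <- sum(chars[, 1] != "-" & chars[, 2] != "-")
  expect_identical(contingency(aln, 1, 2)$n_effective, brute)
  expect_identical(pair_nmi(aln, 1, 2)$n_effective, brute)
})

test_that("NMI identity, relabeling invariance and flagging rules", {
  aln <- aln_from_cols("ACAC", "ACAC", "GTGT", "AAAA", "CCCC", "----")
  expect_identical(pair_nmi(aln, 1, 2)$nmi, 1)       # identical columns
  expect_identical(pair_nmi(aln, 1, 3)$nmi, 1)       # symbol bijection
  expect_identical(pair_nmi(aln, 1, 2)$status, "ok")
  # perfectly invariant pair: scored 1, flagged
  pi <- pair_nmi(aln, 4, 5)
  expect_identical(pi$nmi, 1)
  expect_identical(pi$status, "perfectly_invariant_pair")
  # invariant x variable: denominator 0, excluded
  expect_identical(pair_nmi(aln, 1, 4)$status, "undefined_low_entropy")
  # empty effective table
  expect_identical(pair_nmi(aln, 1, 6)$status, "undefined_low_entropy")
  expect_error(pair_nmi(aln, 2, 2), "distinct")
})

test_that("independent columns score near zero and match the oracle", {
  chars <- rand_chars(1000, 2, ORACLE_RESIDUES, 31)
  aln <- new_msa(chars)
  ps <- pair_nmi(aln, 1, 2)
  expect_identical(ps$status, "ok")
  expect_lt(ps$nmi, 0.1)  # finite-sample bias bound at M = 1000
  orc <- oracle_nmi(chars[, 1], chars[, 2])
  expect_equal(ps$nmi, orc$nmi, tolerance = 1e-12)
})

test_that("column classification separates invariant flavours", {
  near <- paste(c(rep("A", 999), "C"), collapse = "")
  aln <- aln_from_cols(strrep("A", 1000), near,
                       paste(rep(c("A", "C", "D", "E"), 250), collapse = ""))
  expect_identical(classify_column(aln, 1)$klass, "perfectly_invariant")
  cc <- classify_column(aln, 2, epsilon_inv = 0.05)
  expect_identical(cc$klass, "imperfectly_invariant")
  expect_equal(cc$entropy_bits, 0.0114, tolerance = 1e-2)
  expect_identical(classify_column(aln, 3)$klass, "variable")
  rep_df <- classify_columns(aln)
  expect_identical(rep_df$klass,
                   c("perfectly_invariant", "imperfectly_invariant",
                     "variable"))
})

test_that("NMI is symmetric bit-for-bit and row-permutation invariant", {
  chars <- rand_chars(80, 8, c(ORACLE_RESIDUES[1:6], "-", "X"), 41)
  aln <- new_msa(chars)
  for (a in 1:7) {
    for (b in (a + 1):8) {
      expect_identical(pair_nmi(aln, a, b)$nmi, pair_nmi(aln, b, a)$nmi)
    }
  }
  set.seed(42)
  perm <- sample.int(80)
  aln_p <- new_msa(chars[perm, ])
  m1 <- nmi_matrix(aln)
  m2 <- nmi_matrix(aln_p)
  expect_identical(m1$nmi, m2$nmi)
  expect_identical(m1$status, m2$status)
})

test_that("scores stay in [0, 1] and match the oracle on random alignments", {
  for (s in 1:30) {
    set.seed(s)
    m <- sample(2:8, 1)
    chars <- rand_chars(m, 4, c("A", "C", "G", "-"), s + 100)
    aln <- new_msa(chars)
    for (a in 1:3) {
      for (b in (a + 1):4) {
        got <- pair_nmi(aln, a, b)
        orc <- oracle_nmi(chars[, a], chars[, b])
        expect_identical(got$status, orc$status)
        if (got$status != "undefined_low_entropy") {
          expect_gte(got$nmi, 0)
          expect_lte(got$nmi, 1)
          expect_equal(got$nmi, orc$nmi, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("adding symbol noise to one column does not raise expected NMI", {
  diffs <- vapply(1:200, function(s) {
    set.seed(s)
    latent <- sample.int(6, 80, replace = TRUE)
    a <- ORACLE_RESIDUES[latent]
    b <- ORACLE_RESIDUES[latent + 6]
    aln <- new_msa(cbind(a, b))
    clean <- pair_nmi(aln, 1, 2)$nmi
    noisy_b <- b
    hit <- sample.int(80, 20)
    noisy_b[hit] <- sample(ORACLE_RESIDUES, 20, replace = TRUE)
    noisy <- pair_nmi(new_msa(cbind(a, noisy_b)), 1, 2)$nmi
    noisy - clean
  }, 0)
  expect_lt(mean(diffs), 0)
  expect_lt(t.test(diffs)$p.value, 1e-6)
})
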