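# Copy-number rounding and structural enumeration.

test_that("near-integer estimates round cleanly", {
  cn <- round_copies(c(promoter = 3.1, intron6 = 2.9, exon9 = 3.0))
  expect_equal(unname(cn$rounded), c(3L, 3L, 3L))
  expect_length(cn$flags, 0L)
})

test_that("a half-copy plateau across all probes flags a control-gene variant", {
  cn <- round_copies(c(promoter = 2.5, intron6 = 2.5, exon9 = 2.5))
  expect_true(all(is.na(cn$rounded)))
  expect_true("ambiguous_half_copy" %in% cn$flags)
  expect_true("suspect_control_gene_variant" %in% cn$flags)
  # a single ambiguous probe is not a control-gene signature
  cn <- round_copies(c(promoter = 2.5, intron6 = 3.0, exon9 = 3.0))
  expect_true("ambiguous_half_copy" %in% cn$flags)
  expect_false("suspect_control_gene_variant" %in% cn$flags)
})

test_that("estimates beyond the validated range are flagged", {
  cn <- round_copies(c(promoter = 14, intron6 = 3, exon9 = 3))
  expect_true("exceeds_validated_range" %in% cn$flags)
  expect_equal(cn$rounded[["promoter"]], 14L)
  expect_error(round_copies(c(promoter = -1, intron6 = 2, exon9 = 2)),
               "negative")
})

test_that("replicate estimates average per probe", {
  df <- data.frame(sample_id = "s", probe = rep(c("promoter", "intron6", "exon9"), each = 2),
                   replicate = rep(1:2, 3),
                   copy_estimate = c(3.0, 3.1, 2.9, 3.0, 3.0, 3.0))
  cn <- round_copies(df)
  expect_equal(unname(cn$estimates), c(3.05, 2.95, 3.0))
})

test_that("enumeration agrees with brute force over the whole probe cube", {
  for (p in 0:6) for (i in 0:6) for (e in 0:6) {
    got <- enumerate_structures(p, i, e)
    want <- brute_force_structures(p, i, e)
    got <- got[order(got$n_full, got$n_68, got$n_36, got$n_13), , drop = FALSE]
    expect_equal(unname(as.matrix(got[, 1:4])), unname(as.matrix(want)),
                 info = paste(p, i, e))
  }
})

test_that("the printed probe triples give the expected parsimonious hybrids", {
  top <- enumerate_structures(4, 3, 3)[1, ]
  expect_equal(top[, c("n_full", "n_68", "n_36", "n_13")],
               data.frame(n_full = 3, n_68 = 1, n_36 = 0, n_13 = 0))
  expect_equal(sum(enumerate_structures(4, 3, 3)$n_hybrids == 1), 1L)

  top <- enumerate_structures(4, 4, 3)[1, ]
  expect_equal(top$n_36, 1); expect_equal(top$n_full, 3)
  top <- enumerate_structures(3, 4, 4)[1, ]
  expect_equal(top$n_13, 1); expect_equal(top$n_full, 3)

  # the unresolvable multicopy case admits more than one structure
  expect_gt(nrow(enumerate_structures(6, 6, 5)), 1L)
})

test_that("every solution substitutes back into the probe equation", {
  for (p in 0:6) for (i in 0:6) for (e in 0:6) {
    sol <- enumerate_structures(p, i, e)
    if (nrow(sol) == 0L) next
    expect_true(all(sol$n_full + sol$n_68 + sol$n_36 == p))
    expect_true(all(sol$n_full + sol$n_36 + sol$n_13 == i))
    expect_true(all(sol$n_full + sol$n_13 == e))
  }
  # equal triples always contain the pure full-copy solution
  for (k in 0:6) {
    sol <- enumerate_structures(k, k, k)
    expect_true(any(sol$n_full == k & sol$n_hybrids == 0))
  }
})

test_that("SNV-derived copy totals filter structures to a unique call", {
  out <- consistency_check(enumerate_structures(3, 3, 3), n_full_expected = 3)
  expect_equal(nrow(out$hypotheses), 1L)
  expect_length(out$flags, 0L)

  # *68-containing structure survives when SNVs say three full copies
  out <- consistency_check(enumerate_structures(4, 3, 3), n_full_expected = 3)
  expect_equal(out$hypotheses$n_68, 1)
  expect_length(out$flags, 0L)

  # nothing survives -> recommend sequencing
  out <- consistency_check(enumerate_structures(4, 3, 3), n_full_expected = 9)
  expect_equal(nrow(out$hypotheses), 0L)
  expect_true("recommend_sequencing" %in% out$flags)
})
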