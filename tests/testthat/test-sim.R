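# The generative model of endpoint signals and copy-number estimates.

test_that("allele_fraction returns the variant share of gene copies", {
  expect_equal(allele_fraction(1, 1), 0.5)
  expect_equal(allele_fraction(1, 2), 2 / 3)
  expect_equal(allele_fraction(2, 1), 1 / 3)
  expect_error(allele_fraction(0, 0), "no gene copies")
  expect_error(allele_fraction(-1, 2), "nonnegative")
})

test_that("config validation rejects out-of-range noise and dropout", {
  expect_error(sim_config(sigma_f = 0.2), "sigma_f")
  expect_error(sim_config(eta_ctrl = 1.5), "eta_ctrl")
  expect_error(sim_config(dropout = data.frame(sample_id = NA,
                                               assay_id = "a", allele = "alt",
                                               eta = 2)), "eta")
})

test_that("per-assay truth counts follow the allele definitions", {
  cc <- truth_allele_counts("*1/*4×2", panel_pkg, defs_pkg)
  het <- cc[cc$call == "het", ]
  expect_setequal(het$assay_id, c("c.100C>T", "c.506-1G>A", "c.1457G>C"))
  expect_true(all(het$n_ref == 1 & het$n_alt == 2))
  # hybrid coverage: *68 contributes a reference base only upstream
  cc <- truth_allele_counts("*68+4/*41×2", panel_pkg, defs_pkg)
  expect_equal(cc$n_alt[cc$assay_id == "c.100C>T"], 2)   # *68 and *4
  expect_equal(cc$n_ref[cc$assay_id == "c.886C>T"], 1)   # *68 absent mid-gene
  expect_equal(cc$n_alt[cc$assay_id == "c.886C>T"], 2)
})

test_that("noise-free three-copy duplication lands at fraction 2/3 exactly", {
  cfg <- sim_config(seed = 11, sigma_f = 0, lot_sd = 0, sigma_c = 0,
                    n_concurrent = 0L)
  run <- simulate_run(mini_cohort("*1/*4×2"), cfg, make_mini_panel(),
                      make_mini_defs())
  q <- run$genotyper[run$genotyper$role == "query", ]
  f <- fraction_coordinate(q$vic, q$fam)
  expect_equal(f, rep(2 / 3, nrow(q)), tolerance = 1e-12)
})

test_that("the same seed reproduces a run byte for byte", {
  cohort <- make_table1_cohort(seed = 3, datasets = "ambiguous")
  f1 <- tempfile(); f2 <- tempfile()
  write_genotyper_export(simulate_run(cohort, sim_config(seed = 9))$genotyper, f1)
  write_genotyper_export(simulate_run(cohort, sim_config(seed = 9))$genotyper, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("replicate fractions converge to the dropout-adjusted truth", {
  dr <- data.frame(sample_id = NA, assay_id = "c.10C>T", allele = "ref",
                   eta = 0.5)
  cfg <- sim_config(seed = 2, sigma_f = 1e-6, lot_sd = 0, dropout = dr,
                    n_concurrent = 0L)
  run <- simulate_run(mini_cohort("*1×2/*4"), cfg, make_mini_panel(),
                      make_mini_defs())
  q <- run$genotyper[run$genotyper$role == "query", ]
  f <- fraction_coordinate(q$vic, q$fam)
  # dropout halves the two reference copies: fraction 1/(1+1) = 0.5
  expect_equal(mean(f[q$assay_id == "c.10C>T"]), 0.5, tolerance = 1e-4)
  # untouched assays stay at the 1:2 duplication ratio
  expect_equal(mean(f[q$assay_id == "c.20G>A"]), 1 / 3, tolerance = 1e-4)
})

test_that("copy estimates are unbiased without control-gene interference", {
  cohort <- do.call(rbind, replicate(500, mini_cohort(), simplify = FALSE))
  cohort$sample_id <- sprintf("Q%03d", seq_len(nrow(cohort)))
  cfg <- sim_config(seed = 4, sigma_c = 0.1, n_concurrent = 0L)
  run <- simulate_run(cohort, cfg, make_mini_panel(), make_mini_defs())
  est <- run$cnv$copy_estimate[run$cnv$probe == "promoter"]
  expect_equal(length(est), 1000L)
  expect_lt(abs(mean(est) - 3), 3 * 0.1 / sqrt(1000))
})

test_that("interference scales measured copies by 2/(1+eta)", {
  cohort <- mini_cohort("*1/*4")
  cohort$cnv_promoter <- cohort$cnv_intron6 <- cohort$cnv_exon9 <- 2
  cohort$interference <- TRUE
  cfg <- sim_config(seed = 5, sigma_c = 0, eta_ctrl = 0.6, n_concurrent = 0L)
  run <- simulate_run(cohort, cfg, make_mini_panel(), make_mini_defs())
  expect_equal(run$cnv$copy_estimate, rep(2.5, 6))   # 2 * 2/1.6
})

test_that("no negative fluorescence or copy estimate is ever emitted", {
  cfg <- sim_config(seed = 6, sigma_f = 0.14, sigma_c = 2, n_concurrent = 0L)
  cohort <- do.call(rbind, replicate(20, mini_cohort(), simplify = FALSE))
  cohort$sample_id <- sprintf("Q%02d", seq_len(nrow(cohort)))
  run <- simulate_run(cohort, cfg, make_mini_panel(), make_mini_defs())
  expect_true(all(run$genotyper$vic >= 0 & run$genotyper$fam >= 0))
  expect_true(all(run$cnv$copy_estimate >= 0))
  expect_true(any(run$cnv$copy_estimate == 0))   # the floor is exercised
})
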