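# The duplicated-allele decision procedure.

# Build a duplication call for a simulated three-copy case on the mini panel.
mini_call <- function(genotype = "*1/*4×2", seed = 21, config = default_config(),
                      dropout = NULL, sigma_f = 0.02) {
  cfg <- sim_config(seed = seed, sigma_f = sigma_f, n_concurrent = 0L,
                    dropout = dropout)
  run <- simulate_run(mini_cohort(genotype), cfg, make_mini_panel(),
                      make_mini_defs())
  call_one(run, "Q001", make_mini_panel(), make_mini_defs(), config)
}

test_that("heterozygosity patterns match the defining diplotype", {
  calls <- truth_allele_counts("*1/*4", panel_pkg, defs_pkg)[, c("assay_id", "call")]
  pairs <- match_diplotype(calls, panel_pkg, defs_pkg)
  expect_length(pairs, 1L)
  expect_setequal(pairs[[1]], c("*1", "*4"))
  calls <- truth_allele_counts("*2A/*41", panel_pkg, defs_pkg)[, c("assay_id", "call")]
  expect_setequal(match_diplotype(calls, panel_pkg, defs_pkg)[[1]], c("*2A", "*41"))
})

test_that("unanimous confident shifts name the duplicated allele", {
  dc <- mini_call("*1/*4×2")
  expect_identical(dc$result, "*4")
  expect_true(all(dc$votes$confident))
  dc <- mini_call("*1×2/*4")
  expect_identical(dc$result, "*1")   # shift toward reference votes *1
})

test_that("a single informative SNV defers to sequencing", {
  # only one assay distinguishes the pair
  defs1 <- make_mini_defs(vars4 = "c.10C>T")
  cfg <- sim_config(seed = 22, n_concurrent = 0L)
  run <- simulate_run(mini_cohort("*1×2/*4"), cfg, make_mini_panel(), defs1)
  dc <- call_one(run, "Q001", make_mini_panel(), defs1)
  expect_identical(dc$result, "DEFER")
  expect_true("too_few_informative_snvs" %in% dc$defer_reasons)
})

test_that("allelic dropout that skews one assay forces a conflict deferral", {
  dr <- data.frame(sample_id = NA, assay_id = "c.10C>T", allele = "ref",
                   eta = 0.25)
  dc <- mini_call("*1×2/*4", dropout = dr)
  expect_identical(dc$result, "DEFER")
  expect_true("conflicting_votes" %in% dc$defer_reasons)
  votes <- dc$votes
  expect_identical(votes$vote[votes$assay_id == "c.10C>T"], "*4")
  expect_true(all(votes$vote[votes$assay_id != "c.10C>T"] == "*1"))
})

test_that("a copy-number total other than three defers", {
  cohort <- mini_cohort("*1×2/*4")
  cohort$cnv_promoter <- cohort$cnv_intron6 <- cohort$cnv_exon9 <- 4
  cfg <- sim_config(seed = 23, n_concurrent = 0L)
  run <- simulate_run(cohort, cfg, make_mini_panel(), make_mini_defs())
  dc <- call_one(run, "Q001", make_mini_panel(), make_mini_defs())
  expect_identical(dc$result, "DEFER")
  expect_true("cnv_inconsistent" %in% dc$defer_reasons)
})

test_that("too few comparator samples defer even with clear shifts", {
  config <- default_config()
  config$min_comparators <- 10L
  dc <- mini_call("*1/*4×2", config = config)
  expect_identical(dc$result, "DEFER")
  expect_true("low_comparator_count" %in% dc$defer_reasons)
})

test_that("a sample homozygous at every assay cannot be assessed", {
  calls <- data.frame(assay_id = make_mini_panel()$assay_id, call = "hom_ref")
  expect_error(call_duplicated_allele(calls, list(), make_mini_panel(),
                                      make_mini_defs()),
               "no informative SNV")
})

test_that("raising z_min never converts a deferral into a call", {
  genotypes <- c("*1/*4×2", "*1×2/*4")
  z_grid <- c(2, 3, 5, 8, 20)
  for (g in genotypes) for (seed in 31:35) {
    cfg <- sim_config(seed = seed, n_concurrent = 0L)
    run <- simulate_run(mini_cohort(g), cfg, make_mini_panel(), make_mini_defs())
    deferred <- vapply(z_grid, function(z) {
      config <- default_config(); config$z_min <- z
      identical(call_one(run, "Q001", make_mini_panel(), make_mini_defs(),
                         config)$result, "DEFER")
    }, logical(1))
    # once deferred, deferred for every larger threshold
    expect_true(all(diff(deferred) >= 0), info = paste(g, seed))
    expect_true(deferred[length(z_grid)])   # an extreme threshold defers
  }
})

test_that("relabeling VIC/FAM and ref/alt leaves the call invariant", {
  panel <- make_mini_panel(); defs <- make_mini_defs()
  for (g in c("*1/*4×2", "*1×2/*4")) for (seed in 41:43) {
    cfg <- sim_config(seed = seed, n_concurrent = 0L)
    run <- simulate_run(mini_cohort(g), cfg, panel, defs)
    dc1 <- call_one(run, "Q001", panel, defs)
    run2 <- run
    run2$genotyper <- relabel_channels(run$genotyper)
    dc2 <- call_one(run2, "Q001", panel, complement_defs(defs, panel))
    expect_identical(dc2$result, dc1$result, info = paste(g, seed))
    expect_equal(dc2$votes$z, -dc1$votes$z, tolerance = 1e-9)
  }
})

test_that("balanced two-copy heterozygotes almost never shift confidently", {
  set.seed(99)
  pts <- make_points(rep(0.5, 8), "het")
  m <- fit_clusters(pts, "c.10C>T")
  m$het_spread <- 0.02   # calibrated spread at the default noise level
  n_confident <- 0L
  for (i in 1:1000) {
    f <- pmin(pmax(0.5 + stats::rnorm(2, 0, 0.02), 0), 1)
    sc <- shift_statistic(f, m)
    if (sc$confident) n_confident <- n_confident + 1L
  }
  expect_lte(n_confident, 10L)   # >= 99% non-confident
})
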