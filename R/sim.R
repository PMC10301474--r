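# Seeded generative model of endpoint-genotyping signals and three-probe
# copy-number estimates.
#
# The simulator works in the one-dimensional allelic-fraction coordinate
# (share of variant-allele signal) and maps back to (VIC, FAM) endpoint
# intensities through a radial gain and per-run, per-channel lot scale
# factors.  PCR kinetics and cycle-by-cycle trajectories are deliberately not
# modeled: endpoint cluster geometry is all the shift-based caller consumes.

#' Simulation configuration
#'
#' @param seed Integer seed; a run simulated twice from the same
#'   configuration is identical byte for byte.
#' @param n_controls_per_class Two-copy control samples per genotype class
#'   (homozygous reference, heterozygous, homozygous variant) per assay.
#' @param n_concurrent Concurrent two-copy patient samples on the run, drawn
#'   from a pool of common duplication-free diplotypes; these contribute to
#'   the per-assay comparator clusters.
#' @param f0,f1 Cluster centers, in the fraction coordinate, of the
#'   homozygous-reference and homozygous-variant classes.  With the identity
#'   geometry (0 and 1) a balanced heterozygote sits at 0.5 and a 2:1
#'   duplication heterozygote at 2/3.
#' @param gain Radial gain: total endpoint fluorescence of an amplified
#'   sample, in arbitrary units, before lot scaling.
#' @param sigma_f Standard deviation of replicate noise in the fraction
#'   coordinate.  The default 0.02 places the 1/6 fraction shift of a
#'   duplicated heterozygote at roughly eight standard deviations, matching
#'   the observation that most three-copy cases are visually unambiguous.
#' @param lot_sd Standard deviation (log scale) of the per-run multiplicative
#'   lot scale factors applied independently to the VIC and FAM channels.
#' @param sigma_c Standard deviation of copy-number estimate noise per
#'   replicate.
#' @param eta_ctrl Relative amplification efficiency of the variant control
#'   gene copy for samples flagged with control-gene interference: measured
#'   copies equal true copies times 2/(1 + eta_ctrl).  The default 0.6 turns
#'   2 true copies into a 2.5-copy plateau.
#' @param dropout Optional data frame describing allelic dropout:
#'   columns `sample_id` (NA applies to every query sample), `assay_id`,
#'   `allele` (`"ref"` or `"alt"`, the suppressed allele) and `eta`, the
#'   relative amplification efficiency in `[0, 1]` of that allele (0 is full
#'   dropout).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_controls_per_class = 3L,
                       n_concurrent = 6L,
                       f0 = 0, f1 = 1,
                       gain = 2000,
                       sigma_f = 0.02,
                       lot_sd = 0.1,
                       sigma_c = 0.1,
                       eta_ctrl = 0.6,
                       dropout = NULL) {
  if (sigma_f < 0 || sigma_f >= 0.15)
    stop("sigma_f must lie in [0, 0.15)")
  if (eta_ctrl < 0 || eta_ctrl > 1)
    stop("eta_ctrl must lie in [0, 1]")
  if (!is.null(dropout)) {
    stopifnot(is.data.frame(dropout),
              all(c("sample_id", "assay_id", "allele", "eta") %in% names(dropout)))
    if (any(dropout$eta < 0 | dropout$eta > 1))
      stop("dropout eta must lie in [0, 1]")
    if (!all(dropout$allele %in% c("ref", "alt")))
      stop("dropout allele must be 'ref' or 'alt'")
  }
  if (!(f0 < 0.5 && f1 > 0.5 && f0 >= 0 && f1 <= 1))
    stop("cluster geometry requires 0 <= f0 < 0.5 < f1 <= 1")
  structure(list(seed = as.integer(seed),
                 n_controls_per_class = as.integer(n_controls_per_class),
                 n_concurrent = as.integer(n_concurrent),
                 f0 = f0, f1 = f1, gain = gain,
                 sigma_f = sigma_f, lot_sd = lot_sd, sigma_c = sigma_c,
                 eta_ctrl = eta_ctrl, dropout = dropout),
            class = "sim_config")
}

#' Variant-allele fraction implied by allele copy counts
#'
#' The premise of shift-based duplication calling: a balanced heterozygote
#' has fraction 1/2, while a duplicated variant allele among three copies
#' gives 2/3.
#'
#' @param n_ref,n_alt Nonnegative copy counts of the reference and variant
#'   alleles (need not be integers once dropout efficiency is applied).
#' @return `n_alt / (n_ref + n_alt)`.
#' @export
allele_fraction <- function(n_ref, n_alt) {
  if (any(n_ref < 0) || any(n_alt < 0))
    stop("allele counts must be nonnegative")
  tot <- n_ref + n_alt
  if (any(tot == 0))
    stop("no gene copies at locus: n_ref + n_alt must be positive")
  n_alt / tot
}

# Common duplication-free diplotypes used for concurrent two-copy samples.
.concurrent_pool <- c("*1/*1", "*1/*2", "*1/*4", "*1/*41", "*2/*41", "*1/*17",
                      "*2/*4", "*1/*10", "*1/*9", "*1/*35", "*2/*17", "*4/*41")

#' True per-assay allele counts for a diplotype
#'
#' Sums, over every gene copy on both haplotypes, the reference/variant
#' allele carried at each panel assay.  Hybrid alleles contribute only at the
#' assays their gene structure covers; a `×N` term is evaluated at
#' `unknown_copies`.
#'
#' @param genotype A diplotype string or `diplotype` object.
#' @param panel An `assay_panel`.
#' @param defs An `allele_defs`.
#' @param unknown_copies Copy number at which `×N` terms are simulated.
#' @return Data frame with columns `assay_id`, `n_ref`, `n_alt` and the
#'   implied qualitative `call`.
#' @export
truth_allele_counts <- function(genotype, panel, defs, unknown_copies = 4L) {
  d <- if (is.character(genotype)) parse_diplotype(genotype) else genotype
  terms <- diplotype_terms(d)
  copies <- terms$copies
  copies[terms$unknown] <- as.integer(unknown_copies)
  n_ref <- n_alt <- numeric(nrow(panel))
  for (k in seq_len(nrow(terms))) {
    base <- vapply(seq_len(nrow(panel)), function(j)
      allele_base(defs, terms$allele[k], panel$assay_id[j], panel$region[j]),
      character(1))
    n_ref <- n_ref + copies[k] * (!is.na(base) & base == "ref")
    n_alt <- n_alt + copies[k] * (!is.na(base) & base == "alt")
  }
  call <- ifelse(n_ref + n_alt == 0, "undetermined",
          ifelse(n_alt == 0, "hom_ref",
          ifelse(n_ref == 0, "hom_var", "het")))
  data.frame(assay_id = panel$assay_id, n_ref = n_ref, n_alt = n_alt,
             call = call, stringsAsFactors = FALSE)
}

# Internal: map a raw allele fraction onto the [f0, f1] cluster geometry.
map_fraction <- function(mu_raw, cfg) cfg$f0 + (cfg$f1 - cfg$f0) * mu_raw

# Internal: one sample x assay signal block (2 replicates).
signal_rows <- function(sample_id, assay_id, mu, call, role, run_id, cfg, sV, sF) {
  if (is.na(mu)) {           # no amplification at this locus
    f <- c(NA_real_, NA_real_)
    vic <- fam <- c(0, 0)
  } else {
    f <- pmin(pmax(mu + stats::rnorm(2L, 0, cfg$sigma_f), 0), 1)
    vic <- cfg$gain * (1 - f) * sV
    fam <- cfg$gain * f * sF
  }
  data.frame(sample_id = sample_id, assay_id = assay_id, replicate = 1:2,
             vic = vic, fam = fam, call = call, role = role, run_id = run_id,
             stringsAsFactors = FALSE)
}

#' Simulate a genotyping + copy-number run
#'
#' Generates, for every sample in the truth cohort plus per-assay two-copy
#' controls and concurrent two-copy patient samples, duplicate endpoint
#' signal points and duplicate three-probe copy-number estimates, with
#' replicate noise in the fraction coordinate, per-run lot scaling of the
#' VIC/FAM channels, optional allelic dropout, and control-gene interference
#' for flagged samples.  Deterministic under a fixed seed.
#'
#' @param cohort A `truth_cohort` data frame (see [make_table1_cohort()]) or
#'   any data frame with columns `sample_id`, `genotype`, `cnv_promoter`,
#'   `cnv_intron6`, `cnv_exon9`, `interference`.
#' @param cfg A `sim_config`.
#' @param panel,defs Panel and allele definitions.
#' @param run_id Run label written to the genotyper export.
#' @return A list of class `sim_run` with data frames `genotyper` (the
#'   genotyper-export dialect), `cnv` (the copy-number dialect) and `truth`.
#' @export
simulate_run <- function(cohort, cfg = sim_config(),
                         panel = load_panel(), defs = load_allele_defs(),
                         run_id = "run1") {
  stopifnot(nrow(cohort) > 0L)
  needed <- c("sample_id", "genotype", "cnv_promoter", "cnv_intron6",
              "cnv_exon9", "interference")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0L)
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  set.seed(cfg$seed)

  lot <- exp(stats::rnorm(2L, 0, cfg$lot_sd))
  sV <- lot[1]; sF <- lot[2]
  het_mu <- map_fraction(0.5, cfg)

  blocks <- list()
  add <- function(b) blocks[[length(blocks) + 1L]] <<- b

  # Per-assay two-copy controls with known genotypes (reference materials).
  class_mu <- c(hom_ref = cfg$f0, het = het_mu, hom_var = cfg$f1)
  for (j in seq_len(nrow(panel))) {
    for (cls in names(class_mu)) {
      for (k in seq_len(cfg$n_controls_per_class)) {
        add(signal_rows(sprintf("CTL_%02d_%s_%d", j, cls, k),
                        panel$assay_id[j], class_mu[[cls]], cls,
                        "control", run_id, cfg, sV, sF))
      }
    }
  }

  # Concurrent two-copy patient samples drawn from a common-diplotype pool.
  if (cfg$n_concurrent > 0L) {
    cc_geno <- sample(.concurrent_pool, cfg$n_concurrent, replace = TRUE)
    for (i in seq_len(cfg$n_concurrent)) {
      counts <- truth_allele_counts(cc_geno[i], panel, defs)
      for (j in seq_len(nrow(counts))) {
        mu <- if (counts$call[j] == "undetermined") NA_real_ else
          map_fraction(allele_fraction(counts$n_ref[j], counts$n_alt[j]), cfg)
        add(signal_rows(sprintf("CC_%02d", i), counts$assay_id[j], mu,
                        counts$call[j], "concurrent", run_id, cfg, sV, sF))
      }
    }
  }

  # Query samples (the truth cohort), with optional allelic dropout.
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$sample_id[i]
    counts <- truth_allele_counts(cohort$genotype[i], panel, defs)
    for (j in seq_len(nrow(counts))) {
      n_ref <- counts$n_ref[j]; n_alt <- counts$n_alt[j]
      if (!is.null(cfg$dropout)) {
        hit <- (is.na(cfg$dropout$sample_id) | cfg$dropout$sample_id == sid) &
          cfg$dropout$assay_id == counts$assay_id[j]
        for (h in which(hit)) {
          if (cfg$dropout$allele[h] == "ref") n_ref <- cfg$dropout$eta[h] * n_ref
          else n_alt <- cfg$dropout$eta[h] * n_alt
        }
      }
      mu <- if (n_ref + n_alt == 0) NA_real_ else
        map_fraction(allele_fraction(n_ref, n_alt), cfg)
      add(signal_rows(sid, counts$assay_id[j], mu, counts$call[j],
                      "query", run_id, cfg, sV, sF))
    }
  }
  genotyper <- do.call(rbind, blocks)
  rownames(genotyper) <- NULL

  # Copy-number estimates: true copies scaled by control-gene interference,
  # plus replicate noise, floored at zero.
  probes <- c("promoter", "intron6", "exon9")
  truecol <- c("cnv_promoter", "cnv_intron6", "cnv_exon9")
  cnv <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    eta <- if (isTRUE(cohort$interference[i])) cfg$eta_ctrl else 1
    do.call(rbind, lapply(seq_along(probes), function(p) {
      est <- pmax(cohort[[truecol[p]]][i] * 2 / (1 + eta) +
                    stats::rnorm(2L, 0, cfg$sigma_c), 0)
      data.frame(sample_id = cohort$sample_id[i], probe = probes[p],
                 replicate = 1:2, copy_estimate = est,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(cnv) <- NULL

  structure(list(genotyper = genotyper, cnv = cnv,
                 truth = as.data.frame(cohort)),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat("Simulated run:", length(unique(x$truth$sample_id)), "query samples,",
      nrow(x$genotyper), "signal rows,", nrow(x$cnv), "copy-number rows\n")
  invisible(x)
}
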