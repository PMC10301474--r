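# Shared fixtures: the packaged panel/definitions, and a minimal two-allele
# panel used for symmetry and transformation properties.

panel_pkg <- load_panel()
defs_pkg <- load_allele_defs(panel = panel_pkg)

# A three-assay panel with one reference allele (*1) and one allele (*4)
# carrying the variant at every assay; both full-gene structures.
make_mini_panel <- function() {
  structure(data.frame(
    assay_id = c("c.10C>T", "c.20G>A", "c.30T>G"),
    legacy_name = c("10C>T", "20G>A", "30T>G"),
    ref_allele = c("C", "G", "T"),
    alt_allele = c("T", "A", "G"),
    region = "mid",
    panel_index = 1:3,
    stringsAsFactors = FALSE), class = c("assay_panel", "data.frame"))
}

make_mini_defs <- function(vars1 = character(0),
                           vars4 = c("c.10C>T", "c.20G>A", "c.30T>G")) {
  mk <- function(name, vars, act) {
    list(name = name, defining_variants = vars, activity_value = act,
         structure_class = "full",
         regions = c("promoter", "exon1", "mid", "late"),
         probe_vector = c(1L, 1L, 1L))
  }
  structure(list(alleles = list("*1" = mk("*1", vars1, 1.0),
                                "*4" = mk("*4", vars4, 0.0)),
                 tandem_partners = character(0)),
            class = "allele_defs")
}

# Hand-built signal points at given fraction coordinates.
make_points <- function(fracs, call, assay = "c.10C>T", role = "control",
                        gain = 1000) {
  n <- length(fracs)
  data.frame(sample_id = sprintf("P%02d", seq_len(n)), assay_id = assay,
             replicate = 1L, vic = gain * (1 - fracs), fam = gain * fracs,
             call = call, role = role, run_id = "r1",
             stringsAsFactors = FALSE)
}

# One-row truth cohort for a clean three-copy case.
mini_cohort <- function(genotype = "*1×2/*4", sample_id = "Q001") {
  data.frame(sample_id = sample_id, genotype = genotype,
             cnv_promoter = 3, cnv_intron6 = 3, cnv_exon9 = 3,
             interference = FALSE, stringsAsFactors = FALSE)
}

# Swap the VIC/FAM channels and the hom_ref/hom_var labels of a signal table.
relabel_channels <- function(genotyper) {
  out <- genotyper
  out$vic <- genotyper$fam
  out$fam <- genotyper$vic
  out$call <- c(hom_ref = "hom_var", het = "het", hom_var = "hom_ref",
                undetermined = "undetermined")[genotyper$call]
  out
}

# Complement each allele's defining set over the panel (ref <-> alt relabel).
complement_defs <- function(defs, panel) {
  out <- defs
  for (nm in names(out$alleles)) {
    out$alleles[[nm]]$defining_variants <-
      setdiff(panel$assay_id, out$alleles[[nm]]$defining_variants)
  }
  out
}

# Run the shift-vote caller on one simulated query sample.
call_one <- function(run, sample_id, panel, defs, config = default_config()) {
  g <- run$genotyper
  rows <- g[g$sample_id == sample_id, , drop = FALSE]
  genotype_calls <- rows[rows$replicate == 1L, c("assay_id", "call")]
  het <- genotype_calls$assay_id[genotype_calls$call == "het"]
  shift_calls <- list()
  for (a in het) {
    model <- fit_clusters(g, a, config)
    pts <- rows[rows$assay_id == a, ]
    shift_calls[[a]] <- shift_statistic(fraction_coordinate(pts$vic, pts$fam),
                                        model, config)
  }
  cn <- round_copies(run$cnv[run$cnv$sample_id == sample_id, , drop = FALSE],
                     config, sample_id = sample_id)
  call_duplicated_allele(genotype_calls, shift_calls, panel, defs,
                         cnv = cn, config = config, sample_id = sample_id)
}

# Independent brute-force enumeration of structures over a quadruple loop.
brute_force_structures <- function(p, i, e, max_n = 6L) {
  grid <- expand.grid(n_full = 0:max_n, n_68 = 0:max_n,
                      n_36 = 0:max_n, n_13 = 0:max_n)
  ok <- grid$n_full + grid$n_68 + grid$n_36 == p &
    grid$n_full + grid$n_36 + grid$n_13 == i &
    grid$n_full + grid$n_13 == e
  sol <- grid[ok, , drop = FALSE]
  sol[order(sol$n_full, sol$n_68, sol$n_36, sol$n_13), , drop = FALSE]
}
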