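# starshift

Resolving which CYP2D6 star allele is duplicated, from real-time PCR
signal, without reflex sequencing.

## Why

CYP2D6 copy-number variants are common and clinically consequential: when
a sample has three gene copies and two alleles of differing activity, the
metabolizer phenotype depends on *which* allele is duplicated
(`*1×2/*41` is ultrarapid, `*1/*41×2` is normal).  Standard targeted
genotyping plus a three-probe copy-number assay detects the duplication
but not its haplotype; laboratories either report "indeterminate" or run
long-range PCR followed by Sanger sequencing.  `starshift` implements the
signal-based alternative for clinical-laboratory and pharmacogenomics
tool developers: the extra copy shifts a heterozygous assay's allelic
signal ratio from 1:1 to 2:1, and that shift — measured against the run's
two-copy clusters — names the duplicated allele.

## The method in brief

For each informative (heterozygous) assay, project the VIC/FAM endpoint
onto the variant-signal fraction `f = FAM/(VIC+FAM)`, calibrate the
two-copy heterozygous cluster center μ and robust spread σ from the run's
control and concurrent samples, and score the query as

    z = (mean replicate fraction − μ) / σ

A vote is confident when both replicates agree in sign with |z| ≥ 3.
Confident votes map to haplotypes through the allele definitions (a shift
*toward reference* at a \*41-tagging site votes for duplication of \*1).
The duplicated allele is reported only when the copy-number total is 3,
at least two confident votes exist and no directional vote disagrees —
otherwise the case defers to sequencing with explicit reasons.  Around
this core the package provides CPIC/DPWG activity-score and phenotype
translation, integer enumeration of hybrid-gene structures (\*68-, \*36-,
\*13-like) from the (promoter, intron 6, exon 9) probe triple, detection
of control-gene interference ("2.5 copies" plateaus) and allelic-dropout
conflicts, a seeded simulator of runs, and a CLI.

## Worked example

```r
library(starshift)

# activity score and phenotype for a resolved diplotype
sc <- activity_score("*1×2/*41")
format(sc)                         # "2.5"
phenotype_from_score(sc)           # "Ultrarapid"

# simulate the packaged 73-case three-copy cohort and call it end to end
cohort <- make_table1_cohort(seed = 1, datasets = "main")
run    <- simulate_run(cohort, sim_config(seed = 1))
res    <- call_run(run$genotyper, run$cnv)
#> [info] resolved 73 samples: reflex_sequencing=9, reported=64
head(res$summary[, c("sample_id", "status", "diplotype", "activity_score", "phenotype")], 3)
#>   sample_id   status diplotype activity_score    phenotype
#> 1      S001 reported  *2A×2/*6              2       Normal
#> 2      S002 reported *2A×2/*41            2.5   Ultrarapid
#> 3      S003 reported   *1/*4×2              1 Intermediate
```

The 64 reported samples are exactly the cases with at least two
informative SNVs, every one matching its simulated truth; the 9 deferrals
are the single-SNV cases, which route to sequencing by design.

Structure interpretation from a probe triple:

```r
enumerate_structures(4, 3, 3)[1, ]
#>   n_full n_68 n_36 n_13 n_hybrids
#> 1      3    1    0    0         1     # three full genes plus one *68 hybrid
```

From the shell:

```sh
starshift simulate --seed 1 --out sim/
starshift call --genotyper sim/genotyper.tsv --cnv sim/cnv.tsv --out reports/
starshift score "*4×2/*17"
# *4×2/*17	activity score 0.5	Intermediate
```

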