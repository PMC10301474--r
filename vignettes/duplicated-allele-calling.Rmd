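---
title: "Calling the duplicated CYP2D6 allele from endpoint signal shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling the duplicated CYP2D6 allele from endpoint signal shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starshift)
```

## The problem

CYP2D6 metabolizes roughly a fifth of commonly prescribed drugs, and its
locus is structurally unstable: full-gene deletions, duplications, and
fusion genes with the neighboring pseudogene CYP2D7 are all common.  When a
sample carries **three copies** of CYP2D6 and two star alleles with
*different* activity values — say \*1 and \*41 — the metabolizer phenotype
depends on which of the two is duplicated: `*1×2/*41` scores 2.5
(ultrarapid) while `*1/*41×2` scores 2.0 (normal).  Targeted genotyping
plus a copy-number assay detects *that* a duplication is present but not
*which* haplotype carries it; the traditional resolution is long-range PCR
to isolate the duplicated copy followed by Sanger sequencing, which is
slow, labor-intensive and infeasible for some specimen types.

`starshift` implements the alternative: read the answer out of the raw
real-time-PCR genotyping signal itself.

## The shift model

Each panel assay is an allelic-discrimination reaction with two reporter
channels, VIC for the reference base and FAM for the variant base.  We
project the two-channel endpoint onto a single coordinate, the variant
signal fraction

$$ f = \frac{\mathrm{FAM}}{\mathrm{VIC} + \mathrm{FAM}} \in [0, 1]. $$

A two-copy heterozygote has one copy of each allele and sits near
$f = 1/2$.  A three-copy heterozygote is 2:1, so its fraction sits near
$2/3$ (variant duplicated) or $1/3$ (reference duplicated) — a fixed shift
of $1/6$ whose *sign* identifies the duplicated haplotype.  The radius
(total signal) carries no copy information at endpoint and is discarded;
this is a deliberate simplification of the two-axis cluster plot a human
reviewer sees.

Calibration is per assay and per run, because the channel gains vary
between array lots.  From the run's two-copy control and concurrent
samples, each genotype class gets a robust center (median fraction) and
spread (MAD × 1.4826, floored at `floor_sd`).  A query's shift statistic is

$$ z = \frac{\bar f_{\text{query}} - \hat\mu_{\text{het}}}{\hat\sigma_{\text{het}}}, $$

computed per replicate and combined.  A vote is **confident** when both
replicates deviate to the same side and each by at least `z_min` spreads.

Votes map to haplotypes through the allele definitions, not through allele
frequency: at a \*41-tagging assay a shift toward the *reference* cluster
is evidence that the \*1 haplotype is duplicated.  The final decision
requires all of:

* the three-probe copy-number total rounds cleanly to 3,
* at least `min_votes` confident votes exist,
* every directional vote names the same haplotype,
* at least one assay has `min_comparators` two-copy heterozygous
  comparator samples.

Anything else defers to reflex sequencing with machine-readable reasons
(`too_few_informative_snvs`, `weak_shift`, `replicate_discordance`,
`conflicting_votes`, `low_comparator_count`, `cnv_inconsistent`).  The
contract mirrors clinical practice: reviewers in the validation study were
perfectly accurate *because* ambiguity was routed to sequencing, so this
caller is engineered to make deferral, never a guess, the failure mode.

### Parameter defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `z_min` | 3 | cluster spreads | the duplication shift is ≈ 8 spreads at default noise, so 3 rejects noise without losing real shifts |
| `conflict_z` | 2 | cluster spreads | directional votes this strong participate in conflict detection; fixed independently of `z_min` so that raising `z_min` can only turn calls into deferrals (monotone threshold behavior) |
| `min_votes` | 2 | votes | a single informative SNV is exactly the case the dropout guard exists for |
| `min_comparators` | 3 | samples | below this a heterozygous cluster position is not trustworthy |
| `floor_sd` | 0.01 | fraction | a cluster fitted from identical points must not have zero spread |
| `zone_halfwidth` | 0.1 | fraction | classification zones around each center |
| `ambiguity_halfwidth` | 0.35 | copies | estimates further than this from an integer do not round; a reproducible 2.5 plateau always flags |
| `validated_max` | 6 | copies | the assay's validated range upper bound (not stated numerically in the source data; configurable) |

## Copy-number structure interpretation

The copy-number assay interrogates three positions — promoter, intron 6,
exon 9 — normalized to the RPPH1 control gene.  Full genes contribute
(1,1,1); the hybrid classes contribute their structural signatures:
\*68-like early fusions (1,0,0), \*36-like exon-9 fusions (1,1,0),
\*13-like CYP2D7::CYP2D6 fusions (0,1,1).  `enumerate_structures()` solves
the resulting integer equation exhaustively; solutions are ordered by
parsimony (fewest hybrids, then most full copies), and
`consistency_check()` intersects them with the full-copy total implied by
the SNV data.  A triple like (4,3,3) with a \*4 allele on board then
uniquely implies one \*68 hybrid riding in tandem with the \*4, whereas
(6,6,5) genuinely admits several structures and is reported as ambiguous.
At three-probe resolution all hybrids collapse onto these three
signatures, which is why the basis is restricted to them.

Two failure modes of the copy-number assay are modeled and detected:

* **Control-gene interference.** A heterozygous variant under the RPPH1
  primer/probe suppresses one control copy, scaling every measured value
  by $2/(1+\eta_{\text{ctrl}})$.  With $\eta_{\text{ctrl}} = 0.6$, two
  true copies read as exactly 2.5 at all three probes — the package flags
  the consistent half-copy plateau as `suspect_control_gene_variant`, and
  the signal side shows centered, unshifted heterozygotes, supporting the
  absence of a duplication.
* **Allelic dropout.** A rare variant under a genotyping primer (the
  motivating case: an intronic variant adjacent to the c.886C>T assay)
  suppresses one allele and skews that assay's fraction, mimicking a
  duplication of the other allele.  Because votes are collected across all
  informative SNVs and any directional disagreement defers, the poisoned
  assay produces `DEFER(conflicting_votes)` rather than a wrong call.

## Activity scores and phenotype

Per-copy activity values ship as data (`alleles.json`), not code:
normal-function alleles (\*1, \*2, \*2A, \*27, \*35) score 1, decreased
function (\*9, \*17, \*29, \*41, \*59) 0.5, \*10 scores 0.25, and null or
hybrid alleles (\*3, \*4, \*5, \*6, \*13, \*36, \*68) 0.  The diplotype
score is the sum over all gene copies; the consensus cutpoints are 0 →
poor, (0,1] → intermediate, (1,2.25] → normal, above 2.25 → ultrarapid.
A multiplication of unknown degree (`×N`) with a positive per-copy value
yields an open bound, evaluated at three copies and printed as `">3"`.
Users can substitute their own table via the `table` argument.

Two published table rows are deliberately not golden values: one
(`*4×2/*29×2`, printed 0.5) is inconsistent with any per-allele value
table that fits the remaining rows (with \*29 = 0.5 it must score 1.0),
and one (`*1×2/*36+*10`, printed 2) conflicts with `*1×2/*10` printing
2.25.  Both look like transcription slips in the source table; the
packaged values reproduce every other row exactly.

### Canonical diplotype strings

The published genotype strings order haplotypes by ascending star number
(with the letter suffix breaking ties, so \*2 precedes \*2A) in every
main-dataset row, and that is the canonical ordering used here.  An
ordering by haplotype activity was considered and rejected because the
published strings contradict it (`*4×2/*17` leads with the zero-activity
haplotype; `*1/*2×2` leads with the lower-activity one).  Alternatives
pairs — two arrangements that phasing cannot distinguish — keep their
reported arrangement, multiplied haplotype first, and are joined by
`" or "`; both arrangements always carry the same copies and therefore
the same activity score, which `resolve()` asserts.

## What the simulator emulates — and what it does not

`simulate_run()` is a generative model of one array run:

* per-assay two-copy **control** trios per genotype class plus
  **concurrent** two-copy patient samples from a pool of common
  duplication-free diplotypes (these form the comparator clusters);
* query samples with true per-assay allele counts derived from the star
  allele definitions, including hybrid gene-structure coverage;
* replicate noise (`sigma_f`, default 0.02) applied in the fraction
  coordinate, then mapped to (VIC, FAM) through a radial gain and per-run
  lognormal lot scale factors per channel (`lot_sd`, default 0.1) — the
  lot distortion moves all clusters coherently, which is exactly what
  per-run calibration absorbs;
* continuous dropout efficiency $\eta \in [0,1]$ per (sample, assay,
  allele), so both full dropout and partial skew are reachable;
* copy-number estimates per probe and replicate with Gaussian noise
  (`sigma_c`, default 0.1), the interference ratio model above, and a
  floor at zero.

The defaults are the study conditions: the packaged cohort composition
(73 three-copy cases over 30 genotypes, 11 exploratory hybrid/multicopy
cases with their probe triples, 3 interference cases) expands into truth
records via `make_table1_cohort()`.  Deliberately **not** modeled:
cycle-by-cycle amplification trajectories, plate-position effects,
cross-lot pooling of runs, and the instrument's native file formats.  The
published per-case counts of *human reviewers* requesting sequencing are
subjective quantities and are not reproduction targets; the package
replaces them with deterministic deferral contracts.  Passing tests
therefore demonstrate correctness of the inference given this generative
model, not robustness to every artifact of real chemistry.

One honest gap between the packaged panel and the published table: the
printed informative-SNV counts are not a pure function of the allele pair
(the table prints 3 het SNVs for one `*4/*35` duplication case and 5 for
another), reflecting sub-allele variation and extra assays on the
clinical panel.  The packaged definitions reproduce the printed count for
24 of 30 main genotypes; the fixture stores the printed counts verbatim
and the simulator derives its counts from the definitions.

## Numerical choices and degenerate inputs

* Cluster spread uses the scaled MAD with floor `floor_sd`; ten identical
  comparator points fit to the floor, not to zero.
* A class with fewer than two heterozygous points cannot calibrate
  (error); small homozygous classes merely lower downstream confidence.
* `z = 0` has direction `none`; opposite-sign replicates are
  `replicate_discordance` and never confident.
* Copy estimates use banker's-rounding-safe logic: ambiguity is decided
  by distance to the nearest integer (threshold 0.35 < 0.5), so exact
  half-copies are always ambiguous.
* Simulated fractions clamp to [0,1] and copy estimates floor at 0, so no
  negative signal is ever emitted.
* Enumeration problem sizes: the full probe cube $[0,6]^3$ is verified
  against a brute-force quadruple loop in the test suite (343 triples).
* Simulation problem sizes used in tests: the 73-case cohort for
  noise-free recovery, 200 cases for stochastic accuracy, 500–1000
  replicate draws for distributional properties — all chosen to keep the
  whole suite under a minute while leaving Monte-Carlo margins of at
  least three standard errors.

## A worked example

```{r example}
cohort <- make_table1_cohort(seed = 1, datasets = "main")
run <- simulate_run(cohort, sim_config(seed = 1))
res <- call_run(run$genotyper, run$cnv)
table(res$summary$status)
res$summary[1, c("diplotype", "activity_score", "phenotype")]
```

## Known limitations

* Only panel-resolvable star alleles that occur in the packaged cohort
  are shipped; this is not a full PharmVar catalog.
* Phasing beyond the duplication itself (e.g. which haplotype carries an
  unphaseable fourth copy) is out of reach of the assay and reported as
  alternatives or deferred.
* Whether RPPH1 interference can co-occur with a true duplication is not
  resolved — the interference flag and the duplication path are reported
  independently, and such samples defer.
* Exon-level breakpoint mapping and single-probe (exon-9-only) designs
  are out of scope; the three-probe signature cannot distinguish \*13
  sub-arrangements.
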