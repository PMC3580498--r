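---
title: "Methods: quantifying Pol II redistribution and Hog1-dependent nucleosome eviction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Pol II redistribution and Hog1-dependent nucleosome eviction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When budding yeast is hit by hyperosmotic shock, bulk transcription drops
while a specific set of stress-responsive genes is strongly induced.  The
stress-activated protein kinase Hog1 (the yeast p38 ortholog) coordinates
this switch in two ways: it redirects RNA polymerase II (Pol II) to
stress-responsive loci, and it drives nucleosome eviction around their
transcription start sites (TSSs).  `hogseq` implements the computational
side of a study of that phenomenon: differential ChIP-Seq enrichment of
Pol II and Hog1 between conditions and strains, MNase-Seq nucleosome
profiles and occupancy quantification, and gene classification from
expression fold changes — together with a synthetic-data generator whose
ground truth lets every step be validated by parameter recovery.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic scenario does and does not show
about real data.

# Coordinate conventions and inputs

All coordinates are 0-based half-open (BED convention) everywhere inside
the package; gene tables in 1-based inclusive coordinates are converted
once at `read_gene_table(one_based = TRUE)` and nowhere else, which removes
the usual off-by-one drift.  The pipeline consumes:

* aligned single-end reads as BED6, one file per factor x strain x
  condition (alignment itself is out of scope — upstream tools produce
  unique-mapper BED files);
* a gene-model table (`gene_id`, `chrom`, `strand`, `orf_start`,
  `orf_end`, `tss`).  The TSS is an input column, never inferred from the
  ORF, because TSS annotation comes from curated genome databases that the
  package does not download;
* a per-gene expression fold-change table (`fc_wt`, `fc_hog1`, linear
  scale).

The promoter is fixed at the 500 bp upstream of the TSS; the +1-nucleosome
window is the 200 bp downstream of the TSS.  Both follow the gene's strand.

# ChIP-Seq quantification

Reads are deduplicated (at most `max_per_position = 10` reads per
`(chrom, start, strand)`; PCR over-amplification control at the toy depths
the simulator produces), then extended from their 5' end to 250 bp — the
fragment-size proxy for single-end ChIP libraries.  "Extension" here means
*to* a total length of 250 bp, not *by* 250 bp; the alternative reading
would produce 286-bp intervals from 36-nt reads and an asymmetric
fragment model.  Extended fragments are assigned to promoter and ORF
regions by their midpoint (an unambiguous single assignment; overlap
counting is available via `count_regions(method = "overlap")`).

Counts become reads per kilobase (RPK), and RPK becomes **TRPK** by
dividing by a trimmed-mean-of-M-values (TMM) scaling factor: over regions
with signal in both samples, `M = log2(sample/reference)` and
`A = (log2 sample + log2 reference)/2`; the 30% of regions most extreme in
`|M - median(M)|` and the 5% most extreme in `|A - median(A)|` are dropped
and the factor is `2^mean(M)` over the survivors (uniform weights).  The
trim fractions are the method's canonical defaults.  The reference sample
is the unstressed wild type of each factor.  TMM makes TRPK exactly
invariant to global sequencing depth: scaling a sample's counts by *c*
scales its factor by *c*.

Trimming is applied over whatever region set is being compared (here
promoters and ORFs of all genes); with one-sided signal — e.g. 20% of
windows losing nucleosomes — the median anchor shifts slightly into the
signal and the factor is underestimated by roughly 1–2%.  On the default
scenario this inflates occupancy by about one percentage point; it is
visible in the simulated `unchanged` class sitting at ~101% occupancy
rather than 100%.

# Enrichment: MA transformation and stratified Z-scores

For each region, `M = log2((treated + pc)/(untreated + pc))` and
`A = (log2(treated + pc) + log2(untreated + pc))/2` on TRPK values, with
pseudocount `pc = 0.5` so empty regions stay finite.  Points are sorted by
A and divided into 20 equal-count strata (fewer for small inputs, keeping
at least 25 points per stratum), and M is standardized within each
stratum.

Two standardizations are provided.  `method = "moments"` is the classical
per-stratum mean/SD.  The default, `method = "robust"`, uses the stratum
median and MAD, and additionally passes the per-stratum centres and scales
through a running median across 5 neighbouring strata.  The regularization
matters because genuine enrichment raises A together with M: strongly
bound regions pile up in the top A-strata, and once they are a majority
there, any statistic estimated from that stratum alone — robust or not —
describes the signal instead of the null, and the very regions the
analysis exists to find get Z near 0.  The running median lets a
signal-dominated stratum inherit the null centre and scale of its
neighbours, under the mild assumption that the null M-trend and spread
vary smoothly with A.  Under a pure null the regularization is a no-op up
to estimation noise, and the empirical false-call rate at Z > 4 on null
simulations stays well below 0.5%.

Calls are one-sided and strict: a region is enriched when `Z > threshold`
(4 for Hog1 binding and for differential recruitment, 6 for Pol II
recruitment; a two-sided mode exists for down-regulation analyses).  A
fixed Z threshold is treated as primary — no normal-tail p-value is
attached to it, since the stratified null is empirical, not exactly
Gaussian.  A gene counts as bound/recruited when either its promoter or
its ORF region passes the threshold, which also yields the
promoter-only / ORF-only / both breakdown of `binding_assignment()`.

Differential recruitment runs the identical machinery with the
salt-treated wild type as "treated" and the salt-treated *hog1* strain as
"untreated", so significant regions are those whose Pol II recruitment
requires the kinase.

# MNase-Seq: profiles, peak calling, occupancy

Mononucleosome fragments are deduplicated, piled into per-base coverage,
and converted to reads per million (RPM).  `tss_profile()` builds a genes
x offsets matrix over TSS ± 1 kb with minus-strand rows reversed, so
positive offsets always run with transcription; its column means are the
familiar metagene profile.

`call_nucleosomes()` is a deliberately simplified peak caller: moving
average smoothing (75 bp), local maxima above 25% of the global maximum,
maxima closer than 120 bp merged keeping the higher, width at half peak
height, and a score combining relative height with raw/smoothed centre
agreement.  Dedicated nucleosome-positioning software does this with
FFT-based filtering and fuzziness models; the simplification is justified
because none of the pipeline's quantitative outputs depend on the caller —
it only localizes the phased array — and on the synthetic scenario it
recovers all 25 class-profile centres within a few bp.

Occupancy follows the strain-matched referencing rule: each strain's
unstressed sample defines 100% occupancy for that strain.  Per gene,
occupancy is `100 x TRPK_stress / TRPK_t0` over the 200-bp window
downstream of the TSS (TMM factor computed between the two samples over
all windows), and eviction is `100 - occupancy` exactly.  Genes without
untreated signal in the window are excluded with a warning.  Group values
average per-gene occupancies (rather than pooling reads), which is what
the paired per-gene test requires; whether to average per gene or pool
reads is genuinely open, and the per-gene choice keeps the estimator and
the test consistent.  The wild-type vs *hog1* comparison of per-gene
eviction uses a two-sided paired Student t-test, implemented in closed
form so that identical inputs give `t = 0, p = 1` instead of an error.

# Gene classification

From linear fold changes: osmoresponsive means `fc_wt > 1.75` (strict),
the strongly-induced group means `fc_wt > 3` (strict), housekeeping means
`fc_wt` in `[1, 1.1]` (inclusive), down-regulated means `fc_wt <= 0.5`
(inclusive).  Dependency among osmoresponsive genes uses the residual
induction ratio `r = fc_hog1 / fc_wt`: *Hog1-dependent* when `r <= 0.75`
("at least 25% of the induction requires the kinase", read on the linear
scale; a log2-scale mode is provided since the defining phrase does not
fix the scale), *Hog1-independent* when `r >= 0.90`, and *neither* in the
gap — excluded from dependent/independent comparisons, mirroring the use
of curated top-N subsets (`top_n_by_fc()`).  An override counting
coding-region-bound but expression-independent genes as independent is
deliberately not applied by default: it mixes binding evidence into an
expression-only classification.

# The synthetic scenario

The generator emulates the statistical structure of the real experiments
(deposited ChIP-Seq/MNase-Seq and expression-array data) on a toy genome:
genes tiled on one chromosome with 4-kb spacing and alternating strands,
1-kb ORFs, TSS 50 bp upstream of the ORF start.  Defaults (every value
chosen once, before any analysis, as what the study conditions state or a
plausible figure where they are silent):

* **Classes**: 50 Hog1-dependent, 50 Hog1-independent, 50 housekeeping,
  50 down-regulated, 300 unchanged (500 genes).  The split echoes the
  genome-scale proportions — roughly a tenth of genes strongly
  osmoresponsive, the majority transcriptionally stable — scaled to a
  desk-size problem; the dependent/independent sets of 50 parallel the
  curated top-100 subsets of the real analysis at half size.
* **ChIP model**: fragment midpoints are drawn from a mixture of uniform
  background (density 1) and per-gene foreground over promoter+ORF with
  density equal to the gene's multiplier.  Midpoints (not 5' starts) follow
  the mixture so that the closed-form expectation for region masses holds
  exactly under midpoint counting.  Reads are 36 nt at the fragment's 5'
  end on a random strand; 5e5 reads per sample.  Pol II: basal occupancy 4
  for housekeeping/down-regulated, 2 for unchanged, background for
  osmoresponsive genes; upon stress 8 for induced genes (collapsing to 1
  for dependent genes in the *hog1* strain), 2 for housekeeping (the
  initial Pol II loss at housekeeping genes, equal in both strains), 1 for
  down-regulated.  Hog1: background everywhere except stress in wild type —
  8 at dependent genes, 1.25 at independent genes (marginal association);
  in the *hog1* strain the Hog1 track is forced to pure background.
* **Per-gene heterogeneity**: a lognormal baseline factor (sd 1 in log2
  units) multiplies each gene's foreground in every sample.  It cancels
  from every M but spreads A, as real per-gene expression levels spanning
  orders of magnitude do; without it the discrete class structure would
  stack all signal into a few A-strata, which no stratified statistic
  survives.  A small per-sample multiplier noise (sd 0.1 log2) keeps
  within-class M values from being artificially identical.
* **MNase model**: 147-bp fragments centred on a canonical phased array at
  TSS-relative offsets −200, +50, +215, +380, +545 with Gaussian jitter
  (sd 20 bp); 5e5 fragments per sample.  Upon stress each nucleosome of a
  gene is thinned by the class/strain eviction fraction: 0.51 for
  dependent genes in wild type and 0 in the *hog1* strain; 0.25 for
  independent genes in both strains; 0 elsewhere.  Eviction covers the
  whole array because remodeling at these loci spans promoter and ORF.
  An optional +1 shift for dependent genes emulates the slightly displaced
  +1 nucleosome of stress genes (off by default).
* **Expression**: lognormal fold changes (sdlog 0.15) around class means
  `(fc_wt, fc_hog1)` = (8, 2), (2.2, 2.1), (1.05, 1.05), (0.4, 0.4),
  (1.3, 1.3) — chosen so the classifier rules recover every class exactly
  at zero noise, dependent genes are induced about four times more than
  independent ones, and the `unchanged` mean triggers no rule.

Everything is an exact function of `(config, seed)`: each sample derives
its own stream seed from the user seed and a sample tag, so any sample can
be regenerated in isolation.

**What the scenario does not model**: mappability and GC biases, MNase
digestion preference, sequencing errors, chromosomal context (one uniform
chromosome), tRNA/LTR loci (Hog1's association with Pol III genes is not
simulated), replicate-level biological variability, and fragment-size
dispersion.  Passing recovery tests therefore shows the estimators are
correct under the stated sampling model, not that they are robust to
every artifact of real libraries.

# Problem sizes and numerical choices

The default scenario (500 genes, 12 samples at 5e5 reads) runs the full
pipeline in well under a minute; unit tests use 100-gene scenarios at
5e4 reads, and the null-calibration check uses 1000 genes x 2e5 reads x
10 seeds.  Fixed tie-breaks keep everything reproducible: dedup keeps
first occurrences in input order, `top_n_by_fc()` breaks FC ties by gene
id, merged peaks keep the higher maximum.  Degenerate inputs are defined,
not accidental: zero-spread strata give Z = 0 with a warning, flat
profiles give zero nucleosome calls, identical eviction vectors give
`t = 0, p = 1`, genes without untreated window signal are excluded with a
warning, and zero-length regions, mismatched region sets and non-positive
fold changes are errors.

# Known limitations

* The TMM factor is biased by ~1–2% when a sizable minority of regions
  changes in one direction (see above); at the scale of the occupancy
  contrasts studied here this is negligible, but occupancy differences of
  a few percent should not be over-interpreted.
* The stratified Z is a calibration against the bulk, not a generative
  model: its null tail is empirical, and the fixed thresholds (4 and 6)
  are conventions carried over from the original analyses rather than
  corrected significance levels.
* The simplified peak caller reports array positions, not
  dyad-resolution positioning or fuzziness.
* With the default expression noise, genes near the dependency-ratio gap
  (0.75–0.90) are legitimately ambiguous; classification accuracy below
  100% on noisy tables reflects that gap, not an implementation defect.

# A minimal run

```{r, eval = FALSE}
library(hogseq)
config <- scenario_config(seed = 1)
run <- run_pipeline(config)
summary(run)
write_report(run, "results")
```
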