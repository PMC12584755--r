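---
title: "Designating active bacterial taxa from paired 16S rRNA and rRNA-gene counts"
author: "phantax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designating active bacterial taxa from paired 16S rRNA and rRNA-gene counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantax)
```

## The problem

A 16S rRNA-gene (DNA) amplicon survey counts gene copies and therefore
cells — growing, dormant, or dead alike. In soils, where most cells are
dormant at any given time, composition alone cannot say which taxa respond
to a stimulus. Sequencing the 16S rRNA transcript pool (as cDNA) from the
same lysate adds a second axis: ribosomes roughly track protein-synthesis
potential, so a taxon whose rRNA reads keep pace with its rRNA-gene reads
is plausibly active *at the population average*. `phantax` implements this
designation and the downstream dynamics for before-after-control-impact
(BACI) mesocosm time series in which a phytohormone (abscisic or salicylic
acid), a methanol carrier control, or a water control is added to
pre-dried, water-acclimated soil and the community is followed over 14
days.

## The designation procedure

Starting from a DNA and a cDNA OTU count table plus library metadata, the
pipeline runs, in order:

1. **Contaminant screen.** For each taxon, a one-sided Fisher-exact
   (hypergeometric) test of presence/absence in negative-control versus
   true libraries; taxa more prevalent in negatives at `p <= 0.05` are
   removed, as are mitochondrial and chloroplast lineages by taxonomy
   string. This prevalence test is a deliberately transparent screen: it
   conditions on presence/absence only, ignoring abundance.
2. **Rarefaction.** Both tables are subsampled without replacement
   (multivariate hypergeometric) to a common depth, default 12,000 reads.
   Equal depth matters because the ratio of two counts equals the ratio of
   two relative abundances only when the denominators match. Libraries
   below depth are dropped; if either member of a DNA/cDNA pair fails,
   the whole pair is excluded.
3. **Pairing.** DNA and cDNA libraries sharing a `pair_id` are aligned on
   the union of their taxa, with absent taxa zero-filled.
4. **Phantom adjustment.** Cells with `DNA = 0, RNA > 0` ("phantom taxa" —
   detectable ribosome pools from populations the DNA library missed) get
   `DNA := 1`. Discarding them would systematically erase rare-but-active
   taxa, exactly the populations a resuscitation experiment cares about.
5. **Classification.** ACTIVE iff `RNA > 0` and `RNA/DNA >= 1`
   (inclusive); INACTIVE if detected but below threshold; NOT_DETECTED if
   absent from both libraries. The threshold 1 means "ribosome pool at
   least as large as the gene pool"; it is exposed as a parameter because
   the literature also uses more conservative cuts.
6. **Active community.** The DNA (not RNA) counts of active taxa feed all
   ecology, limiting between-taxon transcription-level bias. By default
   inactive cells are zeroed per sample (the per-column semantics used in
   activity bubble plots); a global per-taxon filter is available via
   `per_sample = FALSE`.

The order — screen, rarefy, pair, adjust, classify — follows the
narrative order of the analyses this package systematizes; nothing
downstream depends on contaminants, and adjusting before rarefaction would
let phantom pseudo-counts compete for the subsampling quota.

## BACI dynamics

Activity calls are aggregated per soil x treatment x timepoint:

- **Consistency** is the fraction of replicate pairs (mesocosm x
  technical, up to 12; the denominator is the surviving pairs, not the
  nominal count) in which a taxon is ACTIVE. Technical replicates are
  pooled flatly with mesocosm replicates rather than averaged within
  mesocosms first; with balanced designs the two weightings coincide.
- **Reactivation** requires consistency exactly 0 at the soil's
  water-acclimated baseline (never active in any replicate — the
  conservative reading of "inactive or below detection") and day-1
  consistency at or above `c_min = 0.5`. The baseline is always the
  water-acclimated condition, not the field or dry states, so
  moisture-driven activation is already accounted for.
- **Persistence** requires consistency at or above `c_min` at day 1, 7 and
  14. The default `c_min = 0.5` ("active in at least half the
  replicates") is a parameter, not a constant, because consistency is
  reported continuously.
- **Treatment specificity** requires the day-1 versus baseline contrast to
  be enriched (`padj <= 0.05` and `log2FC >= 1`, i.e. a log twofold
  increase) in the hormone treatment and in *neither* the methanol carrier
  nor the water control — the BACI control-exclusion logic.

## The enrichment contrast

The differential-abundance engine is intentionally a minimal,
fully-specified negative-binomial Wald contrast rather than a full
shrinkage estimator: median-of-ratios size factors; per-taxon
method-of-moments dispersion `alpha = (s^2 - m)/m^2`, pooled across the
two groups by degrees of freedom and floored at `1e-8`; fold change
`log2((m_B + 0.5)/(m_A + 0.5))` on normalized group means (the
pseudo-count 0.5 stabilizes zero-mean groups); a delta-method standard
error from the NB variance `m + alpha m^2`; a two-sided normal tail; and
Benjamini–Hochberg adjustment. There is no dispersion-trend shrinkage,
outlier filtering, or fold-change moderation — results on real data will
therefore differ in detail from moderated estimators, and the simulations
here show the test is mildly anti-conservative at six replicates
(empirical size ~0.07 at nominal 0.05) while well powered (>0.99 at true
log2FC 2 with 12 replicates). For publication-grade analyses of real data
a moderated estimator is a reasonable substitute at this module boundary;
the contrast here is the transparent reference implementation.

## Community statistics

Richness, inverse Simpson (`1/sum p_i^2`), Bray–Curtis
(`sum|x-y| / sum(x+y)`), PERMANOVA, PCoA and partial constrained
ordination are implemented from first principles so that every statistic
in the pipeline is checkable against brute-force oracles; the test suite
additionally cross-checks them against vegan (`vegdist`, `adonis2`,
`dbrda`) to machine precision. PERMANOVA uses the squared-distance
partition `SS_total = sum_{i<j} d_ij^2 / n`, pseudo-F on `(k-1, n-k)`
degrees of freedom, and label-permutation p-values with the add-one rule
(the observed statistic counts); permutations can be restricted within
strata (e.g. mesocosm) because mesocosm effects are real in this design,
though the unrestricted test is the default. Bray–Curtis is the default
distance — a documented choice, since ordination workflows of this kind
rarely state it. Exhaustive enumeration is available for small n (the
four-point line instance has pseudo-F 18 and exhaustive p 1/3, which the
tests pin). Negative PCoA eigenvalues are dropped and reported, not
corrected.

## The simulator

`simulate_mesocosm()` emulates the full BACI design: 2 soils x 4
conditions (water, methanol, ABA, SA) x 4 mesocosms x 3 technical
replicates at water-acclimated, day-1, day-7 and day-14 timepoints (16
treatment mesocosms per soil; 12 water-acclimated samples per soil; 144
hormone time-series samples), each biological sample yielding a DNA and a
cDNA library.

The latent model, per taxon: a fixed log relative abundance (sd 1 across
taxa); a baseline dormancy probability (default 0.5 — of the right order
for soil communities — raised by 0.25 at the field/pre-dry/post-dry
baselines, which are generated but not used by the core contrasts);
optional responder status forcing dormancy at baseline and activation at
day 1 only under the taxon's own condition, with an 8x DNA growth
multiplier while active; persistence or reversion after day 1. Activity
states are drawn per taxon x mesocosm x timepoint so technical replicates
and the DNA/cDNA pair share their biology; ratios are drawn per pair from
lognormals with central values 4 (active) and 0.25 (inactive), log-sd
0.35 — well separated on purpose, since the recovery benchmarks ask what
the classifier does when the biology cooperates. Sequencing is multinomial
per library (cDNA intensities proportional to DNA abundance x ratio, the
population-average reading of activity) at lognormal library sizes with CV
0.2 around the design depth; the post-hoc rarefaction depth is the only
depth the emulated study states, so the library-size law is the package's
own documented choice.

What the simulator does *not* emulate: chimeras, primer and copy-number
bias, denoising artifacts, compositional spike effects, overdispersed
(Dirichlet-multinomial) sequencing, or partial activation between
timepoints. Passing recovery benchmarks therefore show the pipeline is
correct and well calibrated *given the ratio model*, not that real soil
data are this clean — on real data the dominant known failure mode is
false negatives (active taxa misclassified) as depth falls, and the
simulation reproduces that direction: per-call accuracy is ~96% at 30,000
paired reads and the false-negative rate roughly doubles by 1,000 reads.

## Numerical and design choices

- Rarefaction draws once per run under a recorded seed (not re-drawn per
  analysis); determinism under a fixed seed is a package-wide contract
  tested end to end.
- Ratio threshold comparisons are inclusive (`>= 1`); ties at the
  threshold are ACTIVE.
- Top-active selection breaks count ties by taxon ID for reproducibility.
- `select_top_active` defaults to 50 taxa per soil/treatment stratum, the
  usual size of activity bubble plots.
- All-zero taxa are excluded from testing and reported with `NA` rather
  than fabricated p-values; all-zero rows max-standardize to zero rather
  than NaN.
- Benchmark problem sizes (200 taxa, full 2-soil design, 30,000-read
  pairing for recovery; 1,000–2,000 taxa for calibration; 1,000 null
  data sets for PERMANOVA size) were chosen as the smallest instances
  whose Monte-Carlo error is comfortably below the margins being tested.

## Limitations

Activity here is binary and population-averaged: a ratio of 1 carries no
information about *how* active a taxon is, nor whether all of its cells or
only a fraction are active, and lineages differ in rRNA amplification
dynamics. Persistence over 14 days cannot distinguish direct substrate use
from indirect priming. The contaminant screen is a presence/absence
stand-in for frequency-based methods and will miss contaminants that are
also genuinely present in samples. These are properties of the method
itself, faithfully reproduced, not shortcomings the package attempts to
paper over.
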