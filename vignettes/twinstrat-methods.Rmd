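---
title: "Methods: trait-stratified twin association with twinstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-stratified twin association with twinstrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinstrat)
```

## Overview

`twinstrat` chains four analyses: ordinal item scores → cumulative trait
severity scores; per-SNP quantitative-trait regression within twin
subgroups; case-control allelic association with cases restricted to the
severity extremes (Q1/Q4 quartiles); and hypergeometric gene-set
enrichment of the implicated genes. A synthetic cohort generator with
known ground truth backs all of it. This vignette records the models, the
parameters that matter, the numerical conventions, and what the synthetic
data can and cannot demonstrate.

## The generative model

No generative model for this study design is published, so every
simulator parameter here is an explicit artifact choice, exposed in
`sim_config()` and documented below.

**Genotypes.** Founders carry biallelic SNPs in Hardy–Weinberg
equilibrium: dosage ~ Binomial(2, MAF), MAF drawn uniformly from
`maf_range` (default (0.05, 0.5], matching a post-QC marker panel).
There is deliberately no linkage disequilibrium, no X chromosome, no
assortative mating and no missingness at generation time (missingness is
a QC concern, injected by tests where needed). Each twin pair consumes
two founder parents; a DZ twin receives one allele per SNP from each
parent independently, with transmitted-haplotype indices recorded so the
realized identity-by-descent fraction of each pair is known exactly. An
MZ pair is a single Mendelian child duplicated, which makes MZ genotype
identity exact by construction rather than approximate.

**Liabilities.** Each of the five traits has liability
`L = g + s + e`, where `g` is the centred planted-QTN dosage score
rescaled so its in-sample variance is `h2_target`, `s` is one normal
draw per pair with variance `c2_shared`, and
`e ~ N(0, 1 − h2 − c2)` per individual. In-sample rescaling keeps the
population variance at 1 (up to covariance noise between components) and
makes the classical twin-correlation identities hold in expectation:
MZ correlation = h2 + c2, DZ correlation = h2/2 + c2. Defaults
`h2_target = 0.8`, `c2_shared = 0.1` reflect the high heritability and
modest shared-environment estimates conventional for autism-related
traits. The additive model has no dominance or epistasis — the simplest
structure consistent with an additive-association analysis; anything the
analysis finds is genuinely additive signal.

**Item scores.** Each of the 88 items belongs to one trait
(`default_trait_map()` allocates 20/18/15/20/15 items; the instrument's
true composition per trait is not public, so this map is a labelled
reconstruction and fully replaceable). An item's ordinal score in 0–3 is
the number of its three cut points (default −1, 0, 1 liability units)
lying below `L + N(0, item_noise_sd²)`. The default noise sd of 0.5
makes items within a trait correlated but not redundant; with zero noise
the cumulative score is exactly monotone in liability, a property the
tests exploit.

**Diagnosis and subgroups.** An individual is diagnosed when the mean of
the five liabilities exceeds the population quantile
`diagnosis_quantile` (default 0.75). A single threshold on the mean was
chosen for transparency over, say, per-trait thresholds with an OR rule.
Pair labels follow zygosity and concordance (cMZ, cDZ, dA.·, dNA.·);
both-unaffected pairs and unrelated simulated individuals stay unlabeled
and the undiagnosed unrelated pool plays the role of the unrelated
control panel (default size 2438). Default pair counts (113 MZ, 171 DZ)
mirror the cohort composition the workflow targets; note that the
*concordance split* within those pairs is an outcome of the liability
model, not an input, so simulated subgroup sizes differ from any
particular observed cohort — ascertainment (families recruited because a
twin is affected) is not modelled.

**Seeding.** One master seed feeds a fixed linear-congruential stream
split (`rng_seed × 48271 + 7919·k mod 2³¹−1`), so stages are
individually reproducible and two runs from the same config are
byte-identical.

## Statistical engines and numerical conventions

* **Item adjustment.** Administrative codes {6,7,8,9} → 0; severity
  capped at 3. The original adjustment procedure is described only in an
  inaccessible source; this reconstruction follows the instrument's
  coding convention (codes 8/9 mean "not applicable/unknown", code 4
  flags hyper-severity) and both the cap and the special-code set are
  arguments.
* **Quartiles.** Default Tukey hinges — medians of the lower/upper
  halves, halves including the overall median when n is odd — because
  that is what common box-plot software computes; type-7 linear
  interpolation is available by flag since the original tooling is not
  fully specified. Extreme selection is inclusive on both boundaries
  (`score ≤ Q1`, `score ≥ Q3`); under heavy ties an individual may fall
  in both strata and is kept in both with a warning rather than silently
  dropped, since dropping would bias both strata toward the centre.
* **t test.** Pooled-variance Student's t by default (the named method
  of the original analysis); Welch by flag. Zero pooled variance returns
  p = 1 with a warning instead of NaN. Per-item subgroup comparisons are
  deliberately *not* multiplicity-corrected: they mirror a descriptive
  raw-p ≤ 0.05 screen, and the tables carry raw p-values.
* **QTL scan.** Additive 0/1/2 dosage OLS with casewise deletion,
  exactly PLINK's quantitative model; implemented as closed-form column
  sums so a 10,000-SNP scan is a single vectorised pass, and verified
  against `lm()` to 1e-10 in the tests. Constant dosage or response is
  flagged untestable with p = 1. Family structure is ignored within a
  subgroup scan (as in the design this mirrors) — a known statistical
  caveat: concordant pairs contribute two correlated observations, so
  scan p-values inside twin subgroups are anticonservative relative to a
  mixed model. QTN selection is inclusive at p ≤ 1e-5 with ties broken
  by SNP id.
* **QC.** Call rate ≥ 0.95, MAF ≥ 0.05 (after re-orienting alleles so
  the recorded minor allele is the less frequent), Hardy–Weinberg
  1-df chi-square p ≥ 0.001, in that order, each SNP attributed to the
  first filter it fails. Frequency-based filters run on unrelated
  controls plus one twin per pair: duplicated MZ genomes would otherwise
  bias frequency and HWE estimates. The chi-square (not exact) HWE test
  matches era-standard QC practice; whether the original QC tested
  cases, controls or both is unstated, so the estimation set is an
  explicit argument.
* **Case-control.** Pearson allelic chi-square without continuity
  correction (the PLINK `--assoc` convention), closed form
  N(ad−bc)²/(r₁r₂c₁c₂). Odds ratios are reported for the minor allele;
  the Haldane–Anscombe +0.5 correction applies to all four cells only
  when some cell is zero, and only to the OR, never to the test
  statistic. The multiple-testing family is the QTN count within each
  (trait, subgroup, stratum) — the original correction denominator is
  unstated; correcting within each case-control run is the conservative
  reading consistent with per-run reporting. Benjamini–Hochberg is the
  hand-rolled step-up (verified against `p.adjust` to 1e-12) computed as
  `p·(m/j)` so the j = m term is exactly p.
* **Discordant-DZ analysis.** Affected vs unaffected co-twins, all
  QC-passing SNPs, unpaired allelic test, filtered at nominal p ≤ 0.05
  AND OR ≥ 3 (both inclusive, no correction — an exploratory screen
  whose binding constraint is the OR cut).
* **Enrichment.** Nearest-gene mapping on 0-based half-open intervals
  (MAP positions are 1-based and converted); distance is the gap to the
  nearest gene boundary, equidistant ties go to the lexicographically
  smaller symbol so the mapping is order-independent. The hypergeometric
  upper tail is `phyper(k−1, K, N−K, n, lower.tail = FALSE)`, which is
  the log-space-stable evaluation; the tests pin it to exact
  finite-sum enumeration on the full N ≤ 25 grid. The universe is a
  required, logged argument — published q-values of this kind rarely
  state their universe, and q is meaningless without it. Because the
  q-value is discrete it is super-uniform, not uniform, under the null:
  the correct calibration statement is P(q ≤ α) ≤ α, and that is what
  the tests assert.

## What the tests do and do not show

The property suite runs at deliberately modest sizes chosen as a
package design choice: 1,000 pairs for twin-correlation fidelity
(tolerance 0.05 ≈ 2 standard errors of a correlation at that n), 10,000
SNPs for null-scan uniformity (KS < 0.02), 50 replicates for
planted-QTN recovery, 20 replicates for null contrast emptiness. The
twin-fidelity check uses a polygenic architecture (20 loci per trait)
because the Falconer identities assume the infinitesimal limit; with a
handful of loci the realized sibling genetic correlation fluctuates by
O(1/√loci) around 1/2, which is architecture noise, not a model error.

One power figure deserves a note: a single QTN explaining 15% of trait
variance in 120 unrelated individuals has non-central-t detection power
of only ≈ 0.50 at two-sided α = 1e-5 (ncp = √(120·0.15/0.85) ≈ 4.60
against a critical value of 4.62), and the simulation reproduces ≈ 0.5.
The companion directional property — the Q4 odds ratio exceeding the Q1
odds ratio for a severity-increasing allele — holds in essentially all
replicates, because it needs only the sign of the frequency gradient
across strata, not genome-wide significance.

Passing tests on synthetic cohorts demonstrate internal statistical
correctness and calibration, not external validity: the generator has no
LD (so nearest-gene mapping of a hit is exact rather than a credible
region), no ascertainment, no population structure, no genotyping batch
effects, and item scores that are conditionally independent given the
trait liability. Results on real interview and array data inherit none
of those guarantees.

## Known limitations

* Subgroup scans ignore residual relatedness (see above).
* The Q1/Q4 design discards the middle half of every severity
  distribution; with the small discordant subgroups this leaves very few
  cases per stratum, and empty strata are skipped with warnings rather
  than imputed.
* Gene-symbol matching is case-insensitive exact string match; no alias
  resolution, deliberately, to avoid an external-database dependency.
* The pipeline's enrichment stage uses the synthetic annotation's full
  gene list as the universe; with a user-supplied annotation the
  universe should be chosen (and reported) to match how the query genes
  could have been discovered.
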