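---
title: "Somatic sSNV analysis in tissue trios: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic sSNV analysis in tissue trios: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicscan)
```

## The problem

A somatic single-nucleotide variant (sSNV) present in a small clone of
cells shows up in bulk sequencing as a low variant allele fraction
(VAF): at a VAF of 4% and 250× coverage, the expected alternate-read
count is just 10. At that signal level, sequencing error, alignment
artifacts and residual germline contamination all masquerade as
somatic candidates, so the design leans entirely on redundancy:
two independent somatic callers per specimen, three tissues per donor
(neuronal and non-neuronal nuclei from cortex plus a non-brain
reference), and a cascade of conservative filters evaluated across all
three tissues. `mosaicscan` implements everything downstream of the
callers: consensus, QC, burden modelling, spectrum/signature analysis,
and gene-set enrichment.

## Consensus and the QC cascade

A candidate enters the cascade only if both callers report the same
(chromosome, position, ref, alt) in the same specimen. When the two
callers disagree on read counts, the merged depth/VAF comes from the
caller reporting the higher depth (the better-powered estimate); both
are recorded.

The cascade applies eight rules, all strict inequalities, and a
candidate survives only if all of them hold:

| rule | requirement | scope |
|---|---|---|
| a | mapping quality > 10 | all three tissues |
| b | base quality > 10 | all three tissues |
| c | read depth > 10 | all three tissues |
| d | exactly 2 alleles observed | somatic specimen |
| e | single-base ref and alt (no indels) | site |
| f | nearest other candidate > 10 bp away | same specimen |
| g | distance outside nearest capture target < 350 bp | site |
| h | population allele frequency < 0.001 | site |

Numerical and definitional choices:

* **Rule d.** "Alleles observed" is a site-level summary supplied with
  the evidence: the number of distinct bases supported by at least 2
  reads (the 2-read floor suppresses sequencing-error third alleles).
  The count is configurable.
* **Rule f.** Proximity is evaluated on the *full* consensus set
  before any other filter, and every member of a ≤ 10 bp cluster is
  removed. Symmetric removal keeps the outcome independent of
  evaluation order and is the conservative reading of "near another
  putative call".
* **Rule g.** Distance is 0 for a base inside a target (BED intervals
  are 0-based half-open; variants are 1-based; conversion happens only
  at this boundary); a base just past an interval end is 1 bp outside.
* **Rule h.** A variant absent from the population database is treated
  as frequency 0 (novel), the standard somatic-filtering convention.
* Quality/depth thresholds are site-level summaries carried by the
  per-site metrics table; no BAM pileups are recomputed here.

Every candidate gets a ledger row with all eight outcomes, the measured
values, and the first failing rule, so the filter report partitions the
consensus set exactly into survivors and per-rule failures.

**Outlier specimens.** A specimen whose post-cascade count exceeds
`median + 5 × scale` over all specimens is excluded, where the scale is
the MAD (1.4826 scaling) floored at one count. The floor matters: in
the sparse regime this pipeline lives in (most specimens carry 0–3
candidates), the raw MAD is frequently 0, and an unfloored rule would
flag every specimen with any variant at all. With the floor, a
specimen needs roughly five more candidates than the cohort median —
an order-of-magnitude excess in practice — to be dropped.

**Identity concordance.** For each donor, pairwise genotype
concordance over a panel of germline sites (fractions of identical
0/1/2 dosage calls) replaces a full IBS/IBD workup. A pair below 0.80
flags the donor as a potential specimen swap; fewer than 100 shared
sites is reported as indeterminate, never as a pass.

## Burden model

The response is the untransformed per-specimen survivor count; the
model is Gaussian:

```
count ~ diagnosis * cell_type + sex (+ ancestry...) + (1 | donor)
```

fit by REML. With a single random intercept the profiled REML
log-likelihood is one-dimensional in the variance ratio, which is
optimised on a log grid with golden-section refinement; the boundary
(zero donor variance) is handled explicitly and flagged as singular.
Satterthwaite degrees of freedom for each fixed effect use the delta
method, `df = 2 f² / (g' A g)`, with `f` the estimated contrast
variance, `g` its numeric gradient in log-variance coordinates and `A`
the inverse negative Hessian of the REML log-likelihood in the same
coordinates; at the boundary the df collapse to the OLS residual df.
Tests are two-sided throughout.

A Gaussian model on counts is a deliberate fidelity choice rather than
a statistical taste choice: the burden analysis this package
reproduces used a linear mixed model on counts, so the default matches
it; a Poisson GLMM is available behind `family = "poisson"`. The test
suite checks the statistic's calibration under its own assumptions
(type-I error 5.0% ± 1.6% over 1000 null cohorts of 19 donors, one
CPU-minute) and its accuracy (diagnosis-effect recovery bias < 0.1 at
a planted effect of 2 over 200 replicates of 40 donors), and
cross-checks five fits against an independent mixed-model
implementation (coefficients to 1e-4, df to 0.5). Ancestry covariates
enter as numeric columns when the sample sheet carries them and are
dropped otherwise; the formula adapts. Donors missing one brain
specimen simply contribute one row.

## Spectrum and signatures

Substitutions are tallied into the 96 canonical pyrimidine-centric
trinucleotide channels (6 substitution classes × 16 flank pairs;
purine-strand variants are reverse-complemented first). Contexts come
from the annotation table, so no reference FASTA is required —
the synthetic genome carries its contexts as labels.

Signature extraction is maximum-likelihood KL (Poisson) NMF:
multiplicative updates, which are monotone in the generalised KL
divergence (asserted at every iteration), run to a relative tolerance
of 1e-8 or 5000 iterations, with 10–20 random restarts keeping the
best fit. The rank is selected by
`BIC = −2 logLik + (96k + kG − k) log(N)` (N = total mutations),
breaking near-ties (within 1 BIC unit) toward the smaller rank for
parsimony. This is a deliberate replacement of a Bayesian NMF with a
point estimate: the downstream use — how many signatures, their
profiles, and their clustering — depends only on the point estimates,
and the posterior machinery would be disproportionate. At convergence
the factorisation conserves mass (reconstructed column sums equal the
input column sums), profiles are column-stochastic, and the scale
lives in the exposures.

Extracted signatures are clustered together with a reference catalog
(and any externally supplied profiles) using 1 − Pearson correlation
and average linkage — the linkage is configurable since "hierarchical
clustering with correlation distance" underdetermines it. The package
ships a clearly-labelled *synthetic* catalog
(`synthetic_signature_catalog()`) for exercising this machinery; real
analyses should supply a published catalog TSV.

## Gene-set enrichment

For each gene set, each donor contributes the number of their
surviving variants (both brain specimens pooled) whose gene lies in
the set; the case and control count vectors are compared with a
Wilcoxon rank-sum test. Because the counts are tiny and tie-ridden,
the test enumerates the permutation distribution of the rank-sum
statistic exactly for total sample sizes ≤ 20 (tie-aware via
midranks); larger samples use the tie-corrected normal approximation.
Per-variant counting (not unique genes) is the default, matching the
cited enrichment tool's construction; the BH family is the set of
gene sets actually tested in one mode. In hypothesis-free mode, sets
outside 100–1000 genes are dropped before testing, a power
consideration. The bootstrap resamples donors within cohort with
replacement (B = 1000, per-replicate rejection at 0.05 using the
normal path for speed) and reports the percent of rejecting
replicates. Odds ratios use unique affected genes per cohort
(a = case genes in set, b = case genes outside, c/d the control
analogues), with 0.5 added to all cells only when a zero cell exists
(the textbook Haldane–Anscombe rule).

Two reproducibility caveats about the published enrichment table
shipped as a fixture. First, its printed odds ratios are not what the
Haldane–Anscombe formula yields on its own printed 2×2 overlaps (e.g.
(4, 19, 0, 7) gives 3.46, not the printed 8.63; the printed values are
affine in the overlap count, suggesting a different internal
construction in the original tool). Second, its printed per-set p
values (0.026 for the top sets) are not recovered by any rank-sum test
on the printed overlaps — this package computes 0.09–0.21 two-sided.
The package therefore reproduces, and tests against, what is
derivable: the per-set overlap counts, the set sizes, and the BH
re-adjustment of the printed p column (which does reproduce the
printed FDR column, 0.096/0.166). The implemented formulas are the
standard ones and are oracle-tested.

## The synthetic cohort

`sim_config()` defaults encode the emulated study conditions, chosen
once:

| parameter | default | rationale |
|---|---|---|
| donors | 9 cases / 10 controls | cohort size of the emulated design |
| specimens | 3 per donor | neuronal, non-neuronal, reference |
| depth | Poisson, mean 250× brain / 50× reference | stated target depths |
| planted VAF | Uniform(0.022, 0.071) | observed allele-fraction range |
| somatic mean / brain specimen | 1.39 cases, 0.35 controls | ×2 specimens ≈ the per-donor rates 2.78 / 0.70 |
| spectrum | 70% C>T mass, 3'-G-skewed | C>T-dominated, deamination-like |
| shared-tissue probability | 0.15 | occasional early-developmental variants in both brain tissues |
| sequencing error | 0.001/base | typical substitution error; makes reference-tissue leakage possible but rare |
| caller sensitivity | ≥ 5 alt reads, 5% dropout | low-VAF detection threshold of somatic callers |
| caller-private FPs | Poisson(3)/specimen/caller | exercises the consensus |
| shared artifacts | Poisson(0.5)/specimen | cycle through the eight rule violations, exercising each filter |

Counts are Poisson (an assumption — the emulated design publishes only
totals); alternate reads are Binomial(depth, VAF) in carrier tissues
and Binomial(depth, error) elsewhere. Genes come from a synthetic
5000-gene universe with a designated 500-gene risk set into which case
variants are drawn with probability 0.5, giving enrichment a known
truth. Reproducibility is structural: one master seed, with
per-specimen sub-streams derived by stable hashing of specimen ids, so
output does not depend on iteration order; seeded runs are
byte-identical.

What the simulation does *not* emulate — and hence what passing tests
do not show about real data: read-level artifacts (strand bias,
mapping ambiguity, OxoG-type damage), non-uniform capture efficiency,
contamination, caller-specific error models (detection is a simple
alt-read threshold plus dropout), and correlated false positives
between callers. The manual review stage of real pipelines is likewise
out of scope; the pipeline emits an inspection-queue TSV with empty
red-flag columns as the hook for it. Detection of 2–3% VAF variants at
250× is genuinely hard (the expected alternate count sits near the
caller threshold), so a simulated run recovers only part of what is
planted — the recovery guarantee tested end-to-end is over variants
detected by both pseudo-callers, which the cascade must then retain at
≥ 95%.

## Problem sizes used by the test-suite and acceptance runs

Fixture-based checks are instantaneous. The stochastic suites use:
1000 null cohorts (type-I calibration), 200 replicate cohorts of 40
donors (effect recovery), 10⁴ planted variants (spectrum convergence),
10⁴ multinomial draws per group across 8 groups (two-signature
recovery), and one full simulated study (end-to-end recovery); the
whole suite runs in about a minute on one CPU. `scripts/acceptance.R`
re-runs the fixture metrics, the enrichment engine at B = 1000, and a
seeded end-to-end simulation.

## Known limitations

* The Gaussian count model is exactly calibrated only under its own
  assumptions; for strongly skewed counts the Poisson option is the
  better-specified (if less faithful) alternative.
* Satterthwaite df rely on numeric derivatives of the REML surface;
  at near-boundary fits the implementation falls back to the OLS
  residual df rather than reporting unstable values.
* The enrichment p values for the published fixture cannot match the
  printed ones (see above); only overlaps, sizes and the FDR
  re-adjustment are reproducible, and only those are asserted.
* `genotype_concordance` is a deliberate simplification of IBS/IBD
  identity checking; it detects swaps, not relatedness.
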