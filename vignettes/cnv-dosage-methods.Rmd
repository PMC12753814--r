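---
title: "Methods: population-level CNV dosage calling and association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-level CNV dosage calling and association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvdosage)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite does
not itself compute.

## The problem

Common copy-number variants (CNVs) on SNP bead arrays leave two footprints:
the Log-R ratio (LRR) shifts down for deletions and up for duplications,
and the B-allele frequency (BAF) changes its cluster structure with the
allelic composition (a heterozygous deletion, for example, has no
heterozygous BAF cluster). Most callers decode each sample separately;
`cnvdosage` instead fits one shared emission model across the whole cohort,
so every sample's intensities inform the cluster positions used to decode
every other sample. The calls are then summarised not as hard segments but
as *expected CNV genotypes* (dosages), which behave like SNP allele dosages
in downstream regression.

## Intensity normalisation

`gc_correct()` regresses each sample's LRR on the probe GC fraction by
ordinary least squares and keeps the residuals. Because OLS residuals are a
projection, the operation is exactly idempotent and leaves each sample
mean-zero.

`wave_correct()` removes the slow "genomic wave" by subtracting a local
linear regression (loess, degree 1) of LRR on position, per sample and per
chromosome. Two choices matter:

- **Span** (default 0.3 of a chromosome's probes): the smoother can only
  remove structure slower than its bandwidth. Waves shorter than about one
  window survive; CNVs much shorter than the window are preserved.
- **Robustness** (default `family = "symmetric"`): on a compact synthetic
  probe grid a planted CNV occupies a non-negligible fraction of the
  window, and a plain least-squares smooth absorbs part of the deletion
  dip into the wave estimate. The robust (Tukey biweight) iterations
  downweight such excursions. On real chromosomes with tens of thousands
  of probes the two families differ little, but the robust default is the
  safer one everywhere. Unlike a projection smoother, loess is only
  approximately idempotent; the suite checks that a second application
  changes values by a few percent of the first correction.

Corrections run GC first, then wave; principal components (`lrr_pcs()`,
default 5) are computed afterwards so they capture residual batch
structure rather than artefacts already removed. The sign of each
component is fixed by making its largest-magnitude loading positive.

## The copy-number HMM

Hidden states are emission clusters with LRR means
`-4.5, -0.3, 0, 0.305, 0.528, 0.702, 0.8434, 0.9848, 1.126`. These nine
values are interpreted as total copies 0–8 and collapsed by a state map to
the five reported call classes 0–4 (copies ≥ 4 map to class 4); the
correspondence of clusters to states is a documented assumption, as is the
whole transition model. Emissions are:

- LRR: Gaussian at the cluster mean with one shared variance, ceiling
  0.25 (LRR² units). The ceiling keeps a pathological M-step from
  inflating the variance until all states blur together.
- BAF: an equal-weight mixture of truncated Gaussians (sd `baf_sd`,
  default 0.04) at the allelic ratios a copy number allows (copy 2: 0, ½,
  1; copy 3: 0, ⅓, ⅔, 1; …). Copy 0 has no allelic signal and emits
  uniformly on [0, 1]. Equal weights (rather than population-frequency
  weights) keep the emission symmetric in BAF about 0.5 for every probe;
  the population BAF is used only by the simulator. Missing LRR or BAF
  contributes log-density 0, i.e. is marginalised.

Transitions are distance-independent by default: stay probability 0.999,
the remainder spread uniformly. An optional `cnv_open_prob` overrides the
diploid row and `distance_scale` makes the stay probability decay with
inter-probe distance. The initial distribution is the stationary law of
the transition matrix. A practical consequence of the 0.999 stay
probability: a CNV must carry roughly 18 nats of cumulative emission
evidence (about 2 × log(0.999/0.000125)) to beat the prior, so very short
CNVs (a handful of probes) at modest signal-to-noise are deliberately not
called — the standard sensitivity/FDR trade-off of HMM callers.

Inference is scaled forward–backward (algebraically identical to log-space
recursion, underflow-free for arbitrarily long chromosomes; the suite
checks it against exhaustive path enumeration at 6 probes × 5 states) and
Viterbi with ties broken toward the lower copy number. Chains restart at
chromosome boundaries. EM (default 15 iterations) re-estimates the shared
LRR variance — capped at 0.25, floored at 1e-6 — and optionally the
cluster means, pooling posterior weights over all samples. Capping at the
boundary of the constraint set preserves the EM monotonicity guarantee,
which the suite asserts on every fit. `joint_call()` intersects cohorts'
probes by (chromosome, position), stacks their samples, fits one emission
model (the reference cohort's manifest defines the shared grid), and
returns per-cohort posteriors.

## Dosage ("countAll")

The expected CNV genotype at a probe is the posterior mean copy class,
`Σ_k k·P(copy = k)` over classes 0–4, so a probe with P(copy 1) = 0.8 and
P(copy 2) = 0.2 scores 1.2. Deletion-only and duplication-only variants
renormalise the posterior over classes {0,1,2} and {2,3,4} respectively;
these are reported but only countAll feeds association. Reporting
thresholds: a probe enters association only if its mean certainty (the
maximum class posterior, averaged over samples) is at least 0.5;
stratification calls countAll < 1.7 a deletion and > 2.5 a duplication;
allele frequencies count hard-classified carriers (nearest-integer copy):
deletion allele frequency (2·n₀ + n₁)/(2n), duplication analogous, each
folded to ≤ 0.5 (a frequency of 1 folds to 0) with the larger folded value
reported as the MAF. Counting carriers rather than averaging fractional
dosages makes the frequency reproducible and robust to posterior
miscalibration.

## Association models

Three Gaussian-likelihood models per probe:

1. **Univariate**: `glm(trait ~ covariates + dosage, family)` with a Wald
   test on the dosage coefficient. Families gaussian/binomial/poisson are
   per-trait options. Monomorphic dosage and binomial separation are
   flagged, not errors; an exact fit reports the smallest representable p
   with an `underflow` flag.
2. **Reverse (joint) regression**: `dosage ~ phenotypes + covariates`,
   phenotype block tested jointly against the covariates-only null. The
   reported p is the exact F test; the likelihood-ratio statistic
   `n·log(RSS₀/RSS₁)` (asymptotically χ² on one df per trait) is reported
   alongside. The F test is exact under normality at any n and reduces to
   the forward correlation t-test for a single trait with no covariates —
   the forward/reverse symmetry the suite asserts to 1e-8 — while the LR
   statistic provides the clean χ² null that is also checked. countAll is
   treated as a continuous Gaussian response; an ordinal variant on the
   stratified classes is out of scope.
3. **Backward selection**: starting from the full reverse model, the
   trait with the largest per-coefficient Wald p above 0.05 is dropped and
   the model refitted, until all retained traits are individually
   significant or none remain (then p = 1 by convention). The 0.05
   per-step criterion is a documented choice. Collinear traits are dropped
   with a warning before testing.

All three also run with corrected LRR as the response (`lrr_assoc()`),
giving secondary validation that does not depend on HMM calls. Covariates
are gender always, plus the LRR principal components when configured.
Missing phenotypes are handled by listwise deletion per probe, with the
sample count reported.

`cis_qtl()` pairs every unmasked CNV probe within a gene boundary ± 5 kb
(closed, 1-based intervals) with that gene's expression probes, per tissue
region. CNV probes carry their own gene-body annotation, so a probe inside
gene A that also lies in neighbouring gene B's window yields cross-gene
tests; `reciprocal_scan()` reports unordered gene pairs significant in
both directions, lexicographically ordered.

## Multiple testing

From the trait correlation matrix, the effective number of tests is
`M_eff = 1 + (M − 1)(1 − Var(λ)/M)` with Var(λ) the *sample* variance
(denominator M − 1) of the eigenvalues. That denominator makes both
analytic limits exact — independence gives M_eff = M, perfect correlation
gives 1 — which is why it was chosen; the result is clipped to [1, M].
Genome-wide correction multiplies M_eff by the number of probes tested
before the Šidák adjustment `1 − (1 − p)^{M_eff}` (computed via
`expm1`/`log1p` to keep precision for tiny p). Whether the original
trait/probe correction was joint or traits-only is not recoverable; the
joint product is the package's convention.

## NMF gene programs

Expression matrices (per region, the region-average `aveALL`, or the
column-concatenated full set — which one feeds the factorization is a
configuration choice, as the derived sets are equally legitimate inputs)
are shifted to non-negativity by their global minimum if needed, then
factorised by multiplicative updates minimising Frobenius error, 50
seeded restarts per rank (restart i uses base seed + i). Per restart each
probe is hard-assigned to its argmax program; the consensus matrix is the
co-assignment fraction, clustered by average-linkage on 1 − consensus and
cut at the rank. Because program labels are arbitrary per restart, the
occurrence counts align each restart's labels to the consensus clusters by
greedy maximum-overlap matching before counting; a probe's "relative
importance" is the fraction of restarts in which it lands in its modal
program. No cophenetic rank selection is performed — counts are reported
for all ranks (2–6 in the gene-by-gene regime; ranks 10 and 20 are used
for region-scale matrices).

## Methylation summaries

Region means average read counts over positions within each 1-based
inclusive region, first within each sample's track and then across
samples (the two orders coincide for a single track; which the original
convention was is not fully specified, so this one is documented). Regions
with mean methylated count strictly above 700 are flagged. The
"methylation wave" score is deliberately exploratory: the phenomenon is
described qualitatively (long-range periodic fluctuation, sometimes
phase-inverted in a subgroup), so the package operationalises it as the
first local maximum of the autocorrelation of the linearly detrended
count series (period, in bp via the median spacing) and half the
peak-to-trough range of a short running mean (amplitude). Detrending makes
the score invariant to constant offsets.

## The synthetic cohort generator

`simulate_cohort()` draws two haplotypes per locus per sample
(Hardy–Weinberg, no linkage), clips total copies to [0, 4], and emits LRR
at the copy-state cluster means plus GC slope, a single sinusoidal wave
per chromosome, and Gaussian noise; BAF comes from a binomial B-allele
count at the probe's population BAF plus truncated Gaussian spread.
Defaults are chosen as a realistic well-behaved bead array: LRR noise sd
0.2 (variance 0.04, well under the 0.25 emission ceiling, so the ceiling
is a guard rather than a binding constraint), BAF sd 0.04, GC slope and
wave amplitude 0 (artefacts are opt-in parameters, switched on where the
corrections themselves are under test). Phenotypes are linear/logit/log
links on dosage with optional correlated Gaussian noise blocks; expression
is `baseline + γ·dosage + noise` per region with reciprocal designs as
two effect rows; methylation tracks have per-region mean levels, a
sinusoidal wave, and a configurable fraction of phase-flipped samples.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: linkage disequilibrium and haplotype
structure, mosaicism, sex chromosomes, batch/plate effects beyond a
single smooth wave, heavy-tailed intensity noise, and probe-specific
variances. Results on real arrays will be noisier than the planted-truth
recovery shown here.

## Problem sizes and numerical conventions

The suite's larger computations use 200 samples × 500 probes for EM
fitting, 620 samples for allele-frequency recovery at frequency 0.47,
2,000 replicates (n = 300, 4 traits) for the joint model's null
calibration, 500 replicates for selection consistency, 50 NMF restarts,
and 20 seeds for the reciprocal QTL scan — sizes at which the checked
properties are sharp while the whole suite runs in minutes on one CPU.
Internal coordinates are 1-based inclusive throughout; BED output is
0-based half-open, converted in one place. All randomness flows through
a seed-restoring helper, so fixed seeds give bit-identical outputs
without disturbing the caller's RNG stream. Posterior normalisation is
asserted to 1e-9, forward vs backward log-likelihood to 1e-8, and EM
monotonicity to 1e-6.

## Known limitations

The haplotype-aware joint CNV–SNP model that full population callers use
is intentionally not implemented; population information enters only
through the shared emission fit. The transition model is a two-parameter
convenience, not a fitted genome map. MAF estimation ignores dosage
uncertainty. The methylation wave score is a descriptor, not a test, and
no differential-methylation statistics are provided. Survival-style
phenotypes, kinship/mixed models, and FDR machinery are out of scope.
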