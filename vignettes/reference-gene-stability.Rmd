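---
title: "Selecting and validating qRT-PCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating qRT-PCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative qRT-PCR quantification expresses every target gene against an
internal reference assumed to be uniformly expressed. That assumption is
routinely violated: within the classic housekeeping families (GAPDH,
actin, ubiquitin, cyclophilin) individual isogenes respond to genotype,
developmental stage, tissue and stress, and a drifting reference
contaminates every fold change normalized to it. `refstab` implements a
four-stage workflow to pick and then independently validate a reference
set: a broad in-silico pre-screen over expression compendia, an
exhaustive stability ranking of qRT-PCR candidates, ΔΔCt
quantification, and a cross-platform concordance check.

## Stage 1 — CV pre-screen and the weighted rank score

For each expression dataset, each gene's coefficient of variation
CV = sd/mean is computed on **linear-scale** intensities (log2-stored
matrices are exponentiated on read). CV on log-scale data conflates
additive and multiplicative variation; computing it on the linear scale
keeps the statistic interpretable as relative dispersion. The SD uses
the n − 1 denominator throughout the package so that small-sample tests
are exact.

CVs are ranked within each gene family (rank 1 = lowest CV, ties
averaged), and each rank is rescaled to a percentile-style stability
score

$$s_{g,d} = 1 - \frac{\mathrm{rank}_{g,d} - 1}{N_{\mathrm{fam},d} - 1},$$

which is 1 for the most stable isogene of a family of
$N_{\mathrm{fam},d}$ and 0 for the least (1 when the family has a
single member). The weighted rank score of a gene is
$\mathrm{WRS}_g = \sum_d w_d\, s_{g,d}$, where the weight $w_d$ of a
dataset defaults to its *sample variety* — the number of distinct
(genotype, stage, tissue, water status) annotation tuples — so that a
compendium spanning many conditions counts for more than a narrow one;
a gene absent from a dataset contributes 0 there. Finally WRS is
expressed as a percentage of its family's maximum, so every family tops
out at 100 %. This rank-percentile construction is one of several
aggregation rules consistent with the workflow's published description;
it was chosen because it is rank-based, family-relative, weightable by
sample variety, and normalizes to 100 % by construction. Candidate
selection takes a per-family quota of top-WRS genes; quota-boundary
ties break lexicographically on gene id and are reported.

## Stage 2 — the pairwise ΔCt stability ranking

Threshold-cycle values enter as a long table (gene, sample, technical
replicate, Ct); replicates are collapsed by arithmetic mean and
undetermined wells propagate as missing. Ct values outside a
configurable plausibility window (default 5–40 cycles, the usual
instrument range) are rejected at read time.

A candidate reference set $S$ of 1–4 genes gets the per-sample
pseudo-reference Ct $\bar{Ct}_S(s) = \frac{1}{|S|}\sum_{g\in S}
Ct_g(s)$ — the arithmetic mean on the Ct scale, i.e. the geometric mean
on the expression scale, the standard multi-gene normalization factor.
Its stability score is

$$\mathrm{meanSD}(S) = \frac{1}{|P|}\sum_{p \in P}
\mathrm{SD}_s\!\left(\bar{Ct}_S(s) - Ct_p(s)\right),
\qquad P = \text{candidates} \setminus S .$$

Because only differences of Ct values across samples enter, any
per-sample constant — unequal loading, unequal mRNA content per total
RNA — cancels exactly; this loading invariance is asserted to 1e−10 in
the tests. Partner genes exclude the set's own members: a member
differenced against itself contributes an artificial zero and would
deflate the score of larger sets. Missing data are handled
pairwise-complete with a floor of 3 shared samples per pair.

`enumerate_and_rank()` scores every subset of size 1..4 (385 sets for
10 candidates), ranks ascending by score within each size class and
overall with tie-averaging, and orders equal scores by the members'
lexicographic label so output files are reproducible. A combinatorial
guard refuses more than 50 000 sets.

As a comparator, `genorm_m()` computes the geNorm stability measure
$M_j$ = mean over partners $k$ of $\mathrm{SD}_s(Ct_k - Ct_j)$ in a
single pass, without geNorm's stepwise exclusion of the worst gene —
only the identity of the most stable gene is compared across methods,
and for single genes $M_j$ coincides with the ΔCt-approach score up to
the partner set, which is why the two methods agree essentially always
in the agreement experiment below.

## Stage 3 — ΔΔCt quantification

For target $t$ against reference set $S$:
$\Delta Ct = Ct_t - \bar{Ct}_S$ per sample,
$\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{\mathrm{cal}}$
against the mean of the calibrator samples, and fold change
$2^{-\Delta\Delta Ct}$. Amplification efficiency is fixed at 2 per
cycle — the classic assumption of the method; no efficiency correction
is attempted. Condition-level summaries are means of per-sample log2
fold changes with their standard error, the usual error-bar convention.
Targets whose calibrator ΔCt is entirely missing are skipped with a
warning rather than failing the run.

## Stage 4 — cross-platform concordance

Validation pairs each target's qRT-PCR log2 fold change $y$ with the
value $x$ from an independent platform (microarray) and scores a
reference set by the residual variance around the fixed identity line:

$$\mathrm{RV} = \frac{1}{n-1}\sum_i (y_i - x_i)^2 .$$

No parameters are fitted — concordance means agreement with $y = x$,
not merely correlation — and RV is symmetric in the platforms. The
n − 1 denominator is a documented convention choice; with the small
target panels involved, n, n − 1 and n − 2 differ by a constant factor
that does not affect the ranking of reference sets. Outlier handling is
explicit: flag the k largest residuals (the "omit the k worst points"
convention), a single-pass |residual| > c·SD cut (default c = 2), or an
explicit id list; one policy is applied uniformly to all reference sets
being compared, and RV is only reported when at least 3 points remain.

## The synthetic-data generator

All testing runs on simulated data with known truth. Ct values follow
an additive Gaussian model on the Ct scale (multiplicative on the
expression scale):

$$Ct_{g,s,r} = \mu_g + \lambda_s + \beta_g x_s + \varepsilon_{g,s,r},
\qquad \lambda_s \sim N(0, \lambda_{sd}^2),\;
\varepsilon \sim N(0, \sigma_{\varepsilon,g}^2),$$

with $x_s$ a centered ±0.5 contrast for drought vs well-watered (the
simplest two-condition stress design) and baselines $\mu_g$ drawn in
18–26 cycles. Expression matrices use the same gene model on the log2
scale, stored linear, without the $\lambda_s$ term (they represent
already-normalized compendia). The loading offsets make the central
property of the ΔCt approach — exact cancellation of per-sample
effects — true by construction and therefore testable; truth objects
(per-gene $\beta$, $\sigma_\varepsilon$, planted outlier labels) are
returned alongside the data and never written into the pipeline input
files.

Defaults, chosen once as plausible qPCR magnitudes since no empirical
values are available for them: $\lambda_{sd} = 2$ cycles (loading can
easily move Ct by a cycle or two), stable isogenes at
$\sigma_\varepsilon = 0.05$ cycles with $\beta = 0$, unstable isogenes
at $\sigma_\varepsilon \sim U(0.5, 1)$ and $|\beta| \sim U(0.5, 1.5)$
cycles. Two points deserve emphasis:

* **Condition effects are signed.** Stress both induces and represses
  genes, so $\beta$ gets a random sign. This is not cosmetic: if all
  unstable genes responded in the same direction, their pairwise ΔCt
  values would cancel the shared response and co-responding unstable
  genes would masquerade as stable pairs — the planted quiet gene would
  then *not* be recoverable by any pairwise statistic. The signed
  design reflects real stress-response panels, where co-regulation of
  an entire candidate set in one direction is the pathological case the
  pre-screen is meant to weed out.
* **$\sigma_\varepsilon$ is per-well residual variability, not purely
  instrument noise.** It carries the gene-level biological instability
  that makes a bad reference bad. The stability study conditions
  therefore simulate one well per (gene, sample) — an already-collapsed
  grid — rather than letting replicate averaging shrink the very signal
  being studied. The replicate machinery (default 3 replicates,
  arithmetic-mean collapse, independent missing wells) is exercised
  separately.

The generator emulates: families with heterogeneous isogene stability,
per-sample loading, a two-level stress design, technical replicates,
missing wells, and cross-platform disagreement with planted outliers.
It does **not** emulate amplification-efficiency differences, probe
cross-hybridization, plate/batch structure beyond the per-sample
offset, correlated noise between genes, or non-Gaussian Ct error.
Passing recovery tests therefore demonstrate that the statistics do
what they claim under the stated error model — not that any particular
laboratory panel will behave as cleanly.

## Study conditions and what the checks show

Two frozen scenario constructors define the simulation experiments
(sizes chosen to represent a realistic qPCR screen):

* `stability_scenario_config()` — 10 candidates, 12 samples, one quiet
  gene ($\sigma_\varepsilon = 0.05$, $\beta = 0$) among nine unstable
  ones. Over 100 seeded runs the quiet gene is the top single reference
  in ≈95 % of runs, attains WRS % = 100 in its family (3 simulated
  datasets per run) in ≈100 %, and the ΔCt approach and geNorm name the
  same top gene in 100 % (the two statistics coincide for singles).
* `combination_scenario_config()` — 10 candidates with independent
  noise $\sigma_\varepsilon \sim U(0.3, 0.8)$ and no condition effect.
  The best attainable mean ΔCt SD is non-increasing in set size
  k = 1..4 in ≈95 % of 100 runs: averaging independent references
  reduces reference noise. (With one near-noiseless gene planted, a
  single gene can already be optimal — the benefit of combinations is a
  statement about comparably noisy candidates.)

RV calibration uses 1000 concordant points ($y = x + N(0, \sigma^2)$),
where RV/σ² ≈ 1, and the planted-outlier scenario (8 targets, 2
outliers shifted by 4 log2 units over noise SD 0.3), where the
fixed-count policy recovers exactly the planted pair. The ordering of
four reference sets with platform-disagreement SDs 0.2/0.3/0.4/0.5 is
recovered reliably only with on the order of 100 shared targets —
distinguishing RVs that differ by a factor 1.5 is a large-sample
statement, which is worth remembering when reading RV comparisons over
panels of eight genes.

`scripts/acceptance.R` recomputes all of these quantities from scratch
at the sizes above (100 seeds per rate) and writes them as JSON;
`tests/testthat/test-acceptance.R` asserts them at their stated
thresholds.

## Numerical and degenerate-input conventions

* Sample SD with n − 1 everywhere; pairs need ≥ 3 shared samples, RV
  needs ≥ 3 retained points, geNorm needs ≥ 3 candidates.
* CV requires ≥ 2 finite values and a positive mean; offending genes
  are excluded from that dataset with a message, not an error.
* Rank ties average; equal-score rows order lexicographically.
* Exact invariances (loading shifts, CV scale invariance) are asserted
  at 1e−10 and 1e−12; they hold to machine precision.
* Seeds: every generator takes an explicit seed and is byte-
  deterministic given one; scenario constructors derive internal seeds
  by fixed offsets so that distinct stages of one run are independent
  but reproducible.

## Limitations

The WRS aggregation rule is a documented reconstruction (rank
percentile, variety-weighted, family-normalized), not a community
standard; alternative monotone aggregations would select similar
candidates but are not interchangeable score-for-score. The geNorm
comparator is single-pass and must not be read as a full geNorm
implementation. No efficiency correction means systematically wrong
fold changes when amplification efficiency deviates from 2, though
reference *ranking* is unaffected. All stochastic guarantees are
statements about the stated Gaussian error model.
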