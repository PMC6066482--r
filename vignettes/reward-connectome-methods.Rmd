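---
title: "Methods: FA-weighted reward connectomics, imaging genetics and mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FA-weighted reward connectomics, imaging genetics and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewardconn)
```

This vignette documents the statistical models the package implements, the
generative model behind its synthetic cohorts, and the numerical and design
choices made where the methodology left room for judgement.

## The network model

The reward circuit is represented as a fixed 24-node atlas: twelve regions
per hemisphere, split into a *reward-control* subnetwork (dlPFC, ACC, OFC,
INS — the prefrontal/insular nodes exerting inhibitory control) and a
*reward-driving* subnetwork (VTA, ventral striatum, amygdala, thalamus and
the other subcortical nodes carrying impulsive motivation). All
C(24,2) = 276 unordered node pairs are edges, partitioned into Control
(C(8,2) = 28), Driving (C(16,2) = 120) and between-subnetwork BTN
(8×16 = 128) classes.

An edge's *streamline region* is estimated from a group's probabilistic
streamline maps: a voxel enters the region when its values across subjects
are significantly greater than zero by a one-sample t-test at α = 0.05.
Three choices deserve comment:

* **One-sided test.** Streamline values are non-negative, so a two-sided
  test against zero is degenerate on the left; the test is one-sided
  (greater). With non-negative data the one-sided p < 0.05 rule is also
  what a practitioner's "p < 0.05 versus zero" threshold effectively does.
* **Zero-variance voxels.** A voxel constant and positive across subjects
  is included (the t statistic diverges to +∞ in the limit); a voxel
  constant at zero is excluded. Without this rule the t statistic is 0/0.
* **No voxel-level multiplicity correction.** The region definition uses
  raw p < 0.05 by design; family-wise control enters later, at the edge
  level.

The strength of an edge for one subject is the arithmetic mean of the
subject's FA over the region's voxels. By default regions are estimated per
group and each subject is scored against their own group's region
(`region_mode = "group"`); because group-specific supports can in principle
confound a group comparison, a pooled alternative scoring everyone against
the union of the two group regions is provided (`region_mode = "union"`)
and exercised in the tests. An empty region yields an explicitly flagged
undefined strength, never a silent zero.

## Edge-wise inference

Each edge is compared between groups by the t statistic of the group term
in `strength ~ group + age + cigarettes/day` (sign convention HA − HC).
The null distribution is obtained by permuting group labels B = 10,000
times with covariates fixed to their subjects and refitting the full model
— the plain permutation-of-raw-data scheme. A Freedman–Lane style
residual-permutation scheme is a recognised alternative and is deliberately
not implemented; the simple scheme matches the description "permutation
tests based on two-sample t-test scores with covariates" most literally.

The two-sided p-value uses the add-one estimator
p = (1 + #{|t\*| ≥ |t|}) / (B + 1), which never returns zero and has
minimum 1/(B+1); at B = 10,000 the Bonferroni threshold 0.05/276 =
0.00018116 is attainable (1/10001 < 0.05/276), which is precisely why a
permutation count of that order is required. Exceedance is counted with an
absolute tolerance of 1e-8 on |t| because a relabelling and its complement
produce equal |t| only up to floating-point rounding. An exhaustive mode
enumerates all label assignments for small samples and returns the exact
proportion (observed assignment included). Permutations are sampled with
replacement from the assignment space; duplicates are not removed.

One practical consequence documented here because it matters when planning
simulations: reaching p < 0.05/276 requires *zero* exceedances among
10,000 permutations, i.e. an observed |t| around 5 or more, and the strong
group difference in smoking inflates the variance of the adjusted group
coefficient (a variance-inflation factor near 2 under the default covariate
model). Moderate planted deficits (≈1.5 SD at 40 subjects per group) are
therefore recovered only partially; the package's recovery guarantees are
stated and tested in the large-effect regime (−3 SD), where sensitivity and
specificity are essentially 1.

## Statistical genetics

* **QC.** SNPs with call rate ≤ 0.98 are removed (the conventional "call
  rate > 98%" filter).
* **HWE.** Pearson χ² goodness-of-fit on 1 df from gene-counting allele
  frequencies, no continuity correction; monomorphic SNPs are flagged, not
  tested.
* **Case–control association.** Genotypic χ² on the 2×3 table (df 2) and
  allelic χ² on the 2×2 allele table with A-count = 2·n\_AA + n\_AG
  (df 1), both without Yates correction — the uncorrected statistics are
  what reproduce the published validation-cohort values (11.31 and 11.28)
  from the printed counts. The odds ratio is for allele A, case odds over
  control odds, with a Woolf log-scale CI at z = 1.96; no small-sample
  correction is applied (all cells in the motivating table are large), and
  a zero marginal is an error rather than a silent continuity fix.
* **LD.** Pairwise D′ and r² from haplotype frequencies estimated by EM
  over the double-heterozygote phase ambiguity: initialisation at
  linkage-equilibrium products, convergence when the largest
  haplotype-frequency change falls below 1e-8, hard cap 1000 iterations
  (non-convergence is an error). D′ = |D|/D\_max with the usual sign-split
  D\_max and is defined as 0 at D = 0; the identity r² ≤ D′² is asserted
  property-style in the tests, and the EM estimate is cross-checked against
  a direct numerical maximisation of the genotype likelihood.
* **Screen.** Dosage is the 0/1/2 count of the designated risk allele. The
  pooled main-effect p comes from `phenotype ~ dosage + covariates`; by
  default the pooled fit does not adjust for group (an option adds it); the
  interaction p is the Wald test of the product term in a model containing
  both main effects; within-group p-values come from per-group fits.
  Monomorphic strata are flagged NA. Wald rather than likelihood-ratio
  p-values are reported throughout.

## Mediation

Simple mediation with shared covariates in both equations: a from
`m ~ x + covs`, (b, c′) from `y ~ x + m + covs`, c from `y ~ x + covs`,
indirect effect a·b. For nested least-squares fits the decomposition
c = c′ + a·b is an algebraic identity and is asserted to 1e-10. The
bootstrap resamples subjects (rows) with replacement, recomputes a·b per
resample, and forms the *bias-corrected* percentile interval with
z₀ = Φ⁻¹(fraction of resamples below the point estimate); no acceleration
term is used (BC, not BCa), matching the default behaviour of the standard
macro implementation of this model. z₀ is clamped to the (1/(B+1),
B/(B+1)) range to avoid infinities; if every resampled indirect effect is
identical the degenerate interval (lower = upper) is returned with a
warning. B defaults to 10,000; tests use smaller B.

Two properties worth stating precisely, because naive versions of them are
false:

* The interval's width does **not** shrink to zero for "noiseless" data in
  general: a mediator exactly affine in the exposure makes the outcome
  model rank-deficient, and otherwise the bootstrap variance of a·b keeps
  an a-path resampling floor. The tested degenerate case is a constant-zero
  outcome (b = 0 identically, interval exactly [0, 0]); the tested
  monotonicities are width decreasing in outcome noise and in sample size.
* "Significant mediation" is defined as the CI excluding zero — the flag is
  exactly that predicate, per group, with the mediation fit run separately
  in HA and HC.

## The synthetic-cohort generator

The generator produces the statistical structure the analysis assumes, with
recorded ground truth; its defaults emulate the motivating study's
conditions.

* **Cohort.** 78 subjects per group. Age ~ N(36.2, 3.9) in HA and
  N(37.5, 5.0) in HC (years); cigarettes/day ~ N(26.0, 9.1) and
  N(8.7, 9.8) truncated at zero. The deliberately large smoking difference
  makes covariate adjustment non-trivial in every simulation.
* **Genotypes.** Haplotype-based: within an LD block a haplotype is a
  Markov chain along the block's SNPs with consecutive-pair disequilibrium
  D = r·√(p₁q₁p₂q₂), so the allele-indicator correlation between adjacent
  SNPs on a haplotype is the target r; each subject receives two
  independent haplotypes, which makes HWE hold exactly by construction,
  and infeasible targets (e.g. r = 1 with unequal frequencies) are
  rejected. Defaults: an rs279858-like focal SNP (alleles A/G, risk G,
  allele-A frequency 0.49) in a four-SNP block at r = 0.85 (r² ≈ 0.72,
  echoing the reported tight GABRA2 block), plus two independent null
  markers. Missingness is injected per SNP at a configurable rate
  (default 0) to exercise the call-rate filter.
* **Voxel data.** Grid 14×14×14, tiled into disjoint 2×2×2 blocks, one
  block per edge in deterministic edge order. A 12³ grid cannot host 276
  disjoint 2×2×2 regions (276·8 = 2208 > 1728 voxels), so 14³ — the
  smallest even cube with at least 276 blocks — is the default; regions
  are kept disjoint so planted edge strengths remain separable. Streamline
  values inside a region are positive (truncated normal, mean 5, SD 1);
  outside they are exactly zero. FA is baseline 0.5 plus voxel noise
  (SD 0.02), plus, inside a region, a subject-level deviation shared
  across the region (SD 0.03) and the planted effects. Effect sizes are in
  units of the null between-subject strength SD,
  √(σ²\_subject + σ²\_voxel/8) ≈ 0.031.
* **Planted effects.** Default group effect: −0.8 SD on every VTA-linked
  edge (45 edges), reflecting the motivating finding that deficits centre
  on VTA connections; the literature gives no numeric edge effect sizes,
  so the magnitude is a configurable package choice. Default genotype
  effect: −0.25 SD per risk allele on the affected edges in HC, abolished
  in HA (interaction +0.25) — the pattern in which addiction destroys the
  genotype–network association.
* **Cognition.** MoCA = group intercept (21.9 HA / 25.7 HC) + c′·dosage +
  b·(mediator − 0.5) + β\_age·(age − 37) + N(0, σ). The mediator is the
  subject's mean FA over the true planted regions of the affected edges,
  so the a path is realized physically through the genotype effect on FA
  rather than drawn separately. Defaults b = 150 MoCA points per unit FA,
  c′ = −0.2 per allele, σ = 2, β\_age = −0.05/yr, keeping total MoCA
  spread near the observed ~2.5–2.9.
* **Determinism.** All stage seeds derive from the single config seed by
  fixed offsets; the same config is bit-identical on rerun.

What the generator does *not* emulate: raw diffusion imaging, tractography
geometry, registration error, spatially correlated FA noise, anatomically
shaped (non-cubic, possibly overlapping) streamline regions, linkage maps
beyond pairwise-chain structure, and population stratification. Passing
tests therefore demonstrate the correctness and calibration of the
statistical machinery under the assumed generative structure, not the
robustness of the full imaging pipeline to real-data artefacts.

## Problem sizes used by the test and acceptance suites

Simulation-based checks run at sizes chosen to give stable verdicts in
seconds-to-a-minute on one CPU: planted-edge recovery at 40 subjects per
group with B = 10,000 permutations over the full 276-edge network; null
calibration over 1000 synthetic null edges at B = 999; LD recovery at
n = 5000; bootstrap coverage at a planted indirect effect of 0.3 with
n = 200, B = 2000 and 500 replicates; and the end-to-end pattern on an
8-node sub-atlas (28 edges) where B = 1000 suffices to reach the Bonferroni
threshold.

## Known limitations

* Group-specific streamline regions are the default because that is the
  described procedure, but scoring each group on its own support can mix
  support differences into strength differences; the union mode exists for
  sensitivity analysis.
* When Diff-connections are defined from the same HA-vs-HC contrast whose
  mean strength later serves as the mediator, the mediator is outcome-
  selected; the pipeline reproduces that design as described rather than
  altering it.
* The permutation scheme does not residualise covariates before permuting;
  with strongly group-associated covariates this is a known point of
  methodological debate, and the calibration of the implemented scheme is
  verified empirically in the tests.
* The pooled screen model omits the group main effect by default (the
  described additive analysis is ambiguous on this); `main_with_group`
  switches it on.
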