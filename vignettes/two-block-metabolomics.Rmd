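---
title: "Two-block metabolomics of aneurysmal risk: model, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-block metabolomics of aneurysmal risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocamet)
```

## The problem

Experimental abdominal aortic aneurysm in hypercholesterolemic
(`Ldlr`-deficient) mice is induced by a high-cholesterol diet plus
angiotensin-II infusion. A targeted metabolomics panel (p180-style: 188
analytes across acylcarnitines, amino acids, biogenic amines,
phosphatidylcholines, lysophosphatidylcholines, sphingomyelins and
hexoses) is measured in two compartments of the same animals — plasma and
aortic tissue — across three groups: SHAM (standard diet, n = 11), HCD
(high-cholesterol diet, n = 10) and ANG (high-cholesterol diet +
angiotensin II, the aneurysm group, n = 10).

The scientific questions this package operationalizes are:

1. Is there a single latent axis of *aneurysmal risk* expressed jointly in
   the plasma and aorta metabolomes, and does it order the three groups?
2. Which metabolites track that axis (variable importance with FDR
   control)?
3. Do simple concentration ratios (BCAA/Gly, BCAA/Gln, LysoPC/PC,
   unsaturated/saturated LysoPC) work as classifiers for high aneurysmal
   risk?

Because no per-animal concentration data are publicly deposited for this
design, the package ships a synthetic cohort generator that reproduces the
*structure* of such a study and provides exact ground truth. All recovery
statements in the test suite are statements about that generator — not
about any real cohort.

## The two-block decomposition

Let $X_{pl}$ ($m \times k$) and $X_{ao}$ ($m \times l$) be the
mean-centered, unit-variance-scaled concentration matrices for the same
$m$ mice. The model splits each block into a *joint* part (systematic
variation shared by both tissues), a *block-unique* part, and residual:

$$X_b = \sum_{a} t_{j,a}\, p_{b,a}^\top \;+\; \sum_{c} u_{b,c}\, q_{b,c}^\top \;+\; E_b,
\qquad b \in \{pl, ao\}.$$

The joint score $t_{j,a}$ is a *consensus* vector — one realization per
mouse, identical for both blocks. The construction, per joint component:

1. leading singular-vector pair $(w_{pl}, w_{ao})$ of the cross-product
   $X_{pl}^\top X_{ao}$;
2. block scores $t_{pl} = X_{pl} w_{pl}$, $t_{ao} = X_{ao} w_{ao}$, with
   $t_{ao}$ sign-aligned to $t_{pl}$;
3. consensus $t_j$ = leading left singular vector of $[\,t_{pl}\,|\,t_{ao}\,]$,
   unit norm;
4. least-squares deflation of both blocks on $t_j$
   ($p_b = X_b^\top t_j / t_j^\top t_j$).

Unique components are principal components of each block's deflated
residual. Deflation makes the residual orthogonal to every joint score,
so unique scores are orthogonal to joint scores by construction; the code
re-orthogonalizes only to remove floating-point leakage. For two blocks
this is the O2PLS-style member of the OnPLS family; it is deterministic
and fully checkable against small-instance SVD oracles (see the test
suite).

**Conventions.**

* Scaling uses the sample standard deviation ($m-1$ denominator);
  constant columns are an error, reported by name.
* The SVD sign is arbitrary. Before group information is available, the
  sign is pinned by making the largest-magnitude score entry positive
  (invariant to metabolite ordering). `orient_model()` then fixes the
  *reporting* convention: the first joint score is flipped, together with
  both blocks' first-component loadings, so that the ANG group mean
  exceeds the SHAM group mean. Orientation never changes $|\tau|$,
  p-values, or significance downstream.
* Variance bookkeeping: $R^2$ of each rank-one term is its squared
  Frobenius norm over the block's total sum of squares; joint + unique +
  residual sums to 1 within `1e-8`, and reconstruction (joint part +
  unique part + residual = scaled input) holds element-wise within
  `1e-8` on unit-variance data.
* `n_joint` defaults to 2. The number of unique components per block is
  user-specified or chosen by a sequential permutation test: a residual
  PC is retained while its singular value exceeds the 95th percentile of
  the singular values obtained after independently permuting each
  residual column (which preserves marginals, destroys correlation).
* With two *independent* blocks the first "joint" component captures only
  chance cross-block correlation; the permutation-null test in the suite
  checks that its $R^2$ is statistically indistinguishable from the
  row-shuffled null.

## Variable importance and the 3D volcano

Importance of metabolite $x_j$ for the risk axis is the Kendall
$\tau$-b rank correlation between $x_j$ and $t_{j,1}$ across mice, with a
two-sided p-value. $\tau$-b is used (rather than $\tau$-a) because LOD
imputation creates ties. The p-value is exact — from the full
permutation-null distribution of the concordance statistic, computed by
the inversion-count recursion and equal to brute-force enumeration — for
$n \le 9$ untied observations, and otherwise uses the normal
approximation with the standard tie-corrected variance. At the cohort
size ($m = 31$) the approximation branch is always taken, matching
common practice.

Benjamini–Hochberg selection is applied per block at $q = 0.05$ (plasma
and aorta have their own metabolite families and their own appendix-style
lists). The implementation is the step-up rule (largest $k$ with
$p_{(k)} \le k\,q/m$, everything at or below $p_{(k)}$ flagged); the test
suite verifies its equivalence to the adjusted-p formulation
(`p.adjust(p, "BH") <= q`) by brute force.

Each metabolite's volcano coordinates are (loading on $t_{j,1}$, $\tau$,
$-\log_{10} p$), plus a class color key; only the coordinates are
produced — 3D rendering is out of scope.

## Ratios, group tests, ROC

Class sums follow the panel taxonomy: BCAA = Leu + Ile + Val; LCAC = all
acylcarnitines with acyl chains of *strictly more than* 12 carbons; total
carnitine = C0 plus all acylcarnitines; the unsaturated/saturated LysoPC
partition is double bonds $\ge 1$ vs $= 0$. Ratio statistics are computed
per sample (numerator sum over denominator sum) — group medians of ratios
are medians of per-sample ratios, never ratios of medians — and are
unit-free.

Pairwise group comparisons use the two-sided Mann–Whitney–Wilcoxon test
(exact when $\min(n_1, n_2) \le 8$ without ties, else the tie-corrected
normal approximation without continuity correction), BH-adjusted over the
tested family.

Classifier performance is the ROC AUC: pair counting with ties scored
one half, identical to $U/(n_+ n_-)$. The variance is DeLong's
placement-value estimator, and the 95% interval is normal-theory on the
AUC scale, clipped to $[0,1]$. AUC is reported for the orientation making
AUC $\ge 0.5$ (the flip is recorded): discriminative performance, not
direction, is evaluated. The performance cutoff is AUC $\ge 0.80$, with a
flag for the caveat case where the lower confidence bound still includes
the cutoff. The default contrasts are ANG vs no-ANG (SHAM and HCD
pooled), HCD vs ANG, and SHAM vs HCD.

`friedewald_ldl()` implements the standard lipid-panel estimate
LDL = CT − HDL − TG/2.2 (mmol/L), warning above the formula's
triglyceride validity bound (4.5 mmol/L, configurable). Note that the
formula applied to group *means* does not generally equal the mean of
per-animal estimates; published summary tables built the other way round
cannot be reproduced from means alone.

## The synthetic cohort generator

The generator emulates, on the log scale, the data-generating structure
the analysis assumes:

$$z_{ij} = \log(\text{baseline}_{class(j)}) + \text{risk}_i\,\lambda_j
          + u_i\,\mu_j + \varepsilon_{ij}, \qquad
  x_{ij} = e^{z_{ij}},$$

per block, with:

* **Design**: 11/10/10 mice (SHAM/HCD/ANG); latent risk factor with group
  means (−1, 0, +1) and within-group SD 0.3, standardized in-sample. The
  within-group SD is the one free dispersion parameter: 0.3 gives clear
  but noisy group ordering (adjacent groups overlap in the tails), chosen
  once a priori as what a three-group design with "perfect ordering on
  the first component" plausibly looks like.
* **Variance split**: each block's log-scale energy is 40% joint, 30%
  unique, 30% noise by default, with total per-metabolite log-SD 0.35
  (≈36% CV, mid-range for targeted metabolomics).
* **Class baselines**: hexoses ≫ amino acids ≫ sphingomyelins ≫
  phosphatidylcholines ≫ biogenic amines ≈ lysoPC ≈ acylcarnitines,
  spanning ~4 orders of magnitude so unit-variance scaling is a
  meaningful step, as in real panel data.
* **Signature**: planted directions per block (plasma: BCAA and several
  amino acids up, Gly/Gln/taurine/C0/C2/C3 down, lipid classes mildly up;
  aorta: ADMA/putrescine/ornithine and related amines up, PC/SM and
  saturated lysoPC down, unsaturated lysoPC up, hexoses down). Class-wide
  rows carry magnitude 0.3, named metabolites 1.0; directions are fixed,
  magnitudes are free parameters of the generator.
* **Unique factor**: a sample-level *dilution-like* factor with equal
  loadings on every metabolite. This is the canonical technical/biological
  nuisance in concentration data (per-sample material, extraction
  efficiency) and is exactly what ratio biomarkers cancel: both members
  of a ratio carry the same dilution term, so it drops out of the
  quotient while the opposing planted effects add.
* **Aorta weights**: lognormal around 5 mg (SD ≈ 15% on the log scale);
  the aorta block is planted in per-mg space and multiplied back by the
  weights, so weight normalization recovers the planted matrix exactly.
* **Censoring**: the lowest 2% of each metabolite's measured values are
  marked below-LOD (one cell per column at m = 31); a heavy-censoring
  setting (e.g. 35%) pushes metabolites below the 70% retention rule and
  exercises the filter.

### Identifiability choices

Three design decisions make the planted ground truth *identifiable* by
the decomposition, i.e. make the generator's "truth" well-defined rather
than easier:

1. The two blocks' unique factors are made exactly uncorrelated
   in-sample with the risk factor and with each other. "Unique" means
   not shared: at m = 31, independently drawn factors correlate at ±0.2
   by chance, which would plant a weak second joint factor the model is
   then blamed for finding.
2. Class-wide signature magnitudes (0.3) are smaller than named-metabolite
   magnitudes (1.0), and the joint loading vector is renormalized so the
   block-level joint energy is exactly the configured fraction.
3. The background (untargeted) metabolites' random signs are rebalanced
   so each block's net signed loading is approximately zero. A signature
   that shifted *total* metabolite content would be statistically
   confounded with the dilution factor — no method could attribute that
   variance — so a well-posed planted signature is total-preserving.

### What the generator does not emulate

Correlated metabolite modules beyond one factor per block, heteroscedastic
(class- or abundance-dependent) noise, batch or injection-order effects,
QC drift, missingness mechanisms other than left-censoring, and any
nonlinearity in the risk response. Passing recovery tests therefore shows
the pipeline is correct *for data of this structure*; it does not certify
performance on real cohorts, where effect sizes and covariance are
unknown.

## Error control and its limits

Under cohorts with *no planted structure at all* (pure lognormal noise),
the fraction of metabolites flagged by the per-block BH selection stays
far below the nominal 5% plus Monte-Carlo allowance — this is what the
error-control tests check.

A genuine limitation is worth stating: the importance test correlates
metabolites with a score *fitted on the same data*. If the data contain a
strong block-level nuisance factor (e.g. dilution) and no joint signal,
the unsupervised joint component latches onto that nuisance, and the
importance test then flags the metabolites that track it — correctly, in
the in-sample sense, but these are not risk correlates. FDR control as
usually stated applies to testing against an externally fixed covariate;
post-selection inference against a fitted score is only as meaningful as
the fitted component. The variance-explained table and the permutation
null for joint $R^2$ are the intended guards: a "joint" component that
does not beat the row-shuffled null should not be interpreted.

Two further caveats at cohort size: with `n_joint = 2` the second joint
component partially absorbs chance cross-block correlation of the unique
factors (its variance share should be read with the permutation null in
mind); and classifier AUCs at n = 31 sit near the ceiling, so comparisons
between two strong classifiers (e.g. a ratio vs its numerator) are
compressed ties more often than their SNRs suggest.

## Numerical choices

* Orthogonality, reconstruction and variance-sum tolerances: `1e-8` on
  unit-variance data.
* Degenerate inputs error early with context: constant columns (by
  name), empty blocks, all-censored columns, missing groups for
  orientation, single-class ROC input, zero ratio denominators (by
  sample id).
* Below-LOD sentinels accepted on input: `<LOD`, `< LOD`, `NA`, empty
  cell. The 70% retention rule is strict (`> 0.70`): 7/10 valid is
  dropped, 8/10 kept. Half-minimum imputation is the default, applied
  after filtering and before scaling.
* Determinism: a cohort spec plus seed reproduces blocks bit-identically;
  the pipeline's outputs are byte-identical across reruns with the same
  configuration and seed.

## Problem sizes used in the checks

The test suite uses 200 seeded replicates for factor-recovery and
signature/biomarker rates, 100 for group-ordering and null error control,
full enumeration oracles up to n = 8 (Kendall) and n1 = n2 = 3
(Mann–Whitney), 1000 random vectors for the BH brute-force equivalence,
and a single m = 2000 cohort for large-sample variance bookkeeping. The
acceptance script recomputes the headline quantities with 100 signal and
50 pure-noise cohorts. These sizes give Monte-Carlo error comfortably
below the margins being checked while keeping a full run short.
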