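---
title: "Correcting collider bias in conditional GWAS: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting collider bias in conditional GWAS: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slopehunt)
```

## The problem

A GWAS of an outcome \(P\) conditioned on a phenotype \(I\) — survival among
disease cases, fasting insulin adjusted for BMI — opens a collider path.
Conditioning on \(I\) induces an association between every genetic cause of
\(I\) and the unmeasured common causes \(U\) of \(I\) and \(P\), and through
them with \(P\). Writing \(\beta_{GI}\) for a variant's effect on \(I\) and
\(\beta'_{GP}\) for its estimated association with \(P\) conditional on
\(I\), the bias is linear in the incidence effect:

\[
\beta'_{GP} = \beta_{GP} + b\,\beta_{GI},
\qquad
b = \frac{-\,\mathrm{cov}(I, P \mid G)_{\text{shared}}}{\mathrm{var}(I \mid G)},
\]

where the shared covariance collects the confounder contribution and any
genetic covariance from variants affecting both traits. Variants with
\(\beta_{GI} = 0\) are unbiased. Knowing \(b\) de-biases every variant at
once: \(\hat\beta_{GP} = \hat\beta'_{GP} - \hat b\,\hat\beta_{GI}\).

The regression approach (Dudbridge and colleagues) estimates \(b\) by OLS of
\(\hat\beta'_{GP}\) on \(\hat\beta_{GI}\) over all variants, with the
Hedges-Olkin dilution correction
\(\hat b_{\mathrm{HO}} = \mathrm{cov}/(\mathrm{var}(\hat\beta_{GI}) -
\overline{s_I^2})\) (the "DHO" comparator, `dho_estimate()`). It requires
incidence effects to be linearly uncorrelated with direct outcome effects;
shared pathways violate that and bias \(\hat b_{\mathrm{HO}}\) by
\((1-\pi_1)\,\sigma_{IP}/\sigma_I^2\).

## The mixture estimator

`hunt_slope()` instead identifies the *cluster* of variants affecting only
\(I\): their points lie on the line \(\hat\beta'_{GP} = b_1 \hat\beta_{GI}\)
through the origin, while variants with direct outcome effects scatter
about a second line. After selecting variants associated with \(I\)
(two-sided Wald \(p < \lambda\), default \(\lambda = 0.001\)), a
two-component bivariate Gaussian mixture is fitted by EM in a conditional
("two lines") parameterisation:

* component 1 (target): \(x \sim N(0, v)\),
  \(y \mid x \sim N(b_1 x,\; \sigma_1^2\, s_{P,i}^2)\);
* component 2: \(x \sim N(0, v)\),
  \(y \mid x \sim N(s_2 x,\; \sigma_2^2\, s_{P,i}^2)\), with
  \(\sigma_2^2 \ge \sigma_1^2\) and \(s_2 = b_1 + \sigma_{IP}/v\).

This is an exact reparameterisation of the constrained mixture whose first
component has the rank-one covariance
\(\bigl[\begin{smallmatrix} s_I^2 & b_1 s_I^2 \\ b_1 s_I^2 & b_1^2 s_I^2
\end{smallmatrix}\bigr]\): that covariance is singular, so the conditional
variance about the line is regularised by the free overdispersion
\(\sigma_1^2\) (near 1 when the scatter is pure sampling noise).

Two numerical choices matter and were made after the homoscedastic
alternatives failed on the package's own simulations:

* **Noise-proportional conditional variances.** Sampling variances of
  per-allele effect estimates scale as \(1/(2\,\mathrm{maf}(1-\mathrm{maf}))\),
  a factor of 25 across the allele-frequency range. With a single shared
  residual variance, low-frequency variants of the proportional cluster
  look like outliers and the EM collapses both clusters onto one broad
  line; scaling each variant's conditional variance by its squared
  standard error \(s_{P,i}^2\) removes the frequency dependence exactly,
  keeps every M-step in closed form (so the log-likelihood is
  monotone), and reduces to the homoscedastic model when the standard
  errors are constant.
* **Target identification by residual concentration.** The fitted
  components are exchangeable labels; the incidence-only cluster is the
  one whose line carries the *most common* outcome/incidence ratio — the
  operational form of the zero-modal-residual assumption (ZEMRA). The
  component maximising the residual-density height at its line,
  \(\pi_k / \sigma_k\), is chosen. Neither the larger mixing weight (after
  selection the incidence-only cluster can be outnumbered) nor the tighter
  scatter (a sliver of a diffuse cluster can be locally tighter) is
  reliable on its own; simulations with 1% incidence-only against 9%
  both-trait variants exercise exactly these failure modes.

Initialisation uses the geometric-mean (reduced-major-axis) slope
\(\mathrm{sign}(\mathrm{cov})\, \mathrm{sd}(y)/\mathrm{sd}(x)\), which —
unlike total least squares — is exactly equivariant to rescaling either
axis; restarts jitter the two initial slopes by the spread of per-variant
ratios (seeded, default 10 restarts, best final log-likelihood wins).
Convergence is declared when the log-likelihood changes by less than
`tol` (default 1e-8, relative); the floor on the overdispersion parameters
is 1e-10. The standard error of \(\hat b_1\) comes from a seeded
nonparametric bootstrap over variants (default 1000 resamples, each refitted
from the point estimate), with a percentile 95% interval.

### Selection threshold \(\lambda\)

\(\lambda\) trades cluster size against null contamination. At the default
0.001 the retained set is dominated by genuinely incidence-associated
variants. At very permissive thresholds the null variants — whose
incidence effects are pure estimation noise — concentrate near the origin;
they are absorbed by the proportional component (its weight approaches
\(\pi_1 + \pi_4\)), and because flat lines fit noise-dominated points
better once errors in \(\hat\beta_{GI}\) are acknowledged, the fitted slope
shrinks toward zero. A sensitivity sweep over several \(\lambda\) values is
recommended for real analyses.

## The simulation engine

`simulate_study()` implements the four-cluster generative model used to
evaluate the estimator: variants affect \(I\) only, both traits, \(P\)
only, or neither (default 5/5/5/85%), under Hardy-Weinberg genotypes with
allele frequencies uniform on \([0.01, 0.49]\), 20,000 individuals and
10,000 independent variants; both traits are quantitative with
heritability 0.5, and a standard-normal confounder with positive loadings
explains 40% of the variance of each. Incidence effects from marginal OLS;
outcome effects from OLS conditional on \(I\). Scenario presets vary which
cluster explains more of \(I\) (`sc1`/`sc2`/`sc3`: 0.35/0.15, 0.25/0.25,
0.15/0.35), shrink the incidence-only cluster (`s1`/`s2`: 1% vs 9%), or
route both-trait effects through a single exposure (`s3`/`s4`, perfectly
correlated direct effects; `s4` violates ZEMRA).

Two generative details are not fully pinned down by the published
description; both were resolved by matching the published true-slope grid
and are recorded as package defaults:

* **Effect-size scale.** Effects are drawn normal on the
  standardised-genotype scale (each variant's expected explained variance
  independent of frequency) and rescaled so each cluster's realised
  explained variance hits its target exactly. Drawing per-allele effects
  instead strengthens the regression-dilution attenuation (below) and
  shifts every empirical slope by ~0.04, away from the published grid.
* **Outcome-heritability split.** The share of \(P\)'s heritability
  explained by the both-trait cluster mirrors its share of \(I\)
  (configurable via `p_split`). The mirrored split reproduces the
  published slopes at negative correlation (−0.25/−0.17/−0.08 across the
  three main scenarios) almost exactly; an equal split does not.

`simulate_summary` mode draws effect estimates directly from their
sampling distributions (~100x faster); it ignores the sampling correlation
between the incidence and conditional-outcome estimates, which is zero for
this design (the conditional residual is orthogonal to \(I\)), so it is
used for replication grids, while individual-level mode remains the
reference process. Evaluation grids in the tests use 100 summary-mode
replicates per cell (the published grids use 1000 individual-level
replicates per cell; the scaled-down grids reproduce the qualitative
ordering, not per-cell decimals).

## Attenuation: what the fitted slope estimates

All estimation happens on the estimated-effect scale, so the fitted slope
recovers \(\lambda b\), where
\(\lambda = \mathrm{var}(\beta_{GI}) / (\mathrm{var}(\beta_{GI}) +
\overline{s_I^2}) \approx 0.91\text{–}0.93\) at the default design — the
familiar regression-dilution factor. The package's `true_slope()` oracle
therefore reports the *realised* slope (regressing the realised bias on
the estimated incidence effects), logging the closed-form population value
alongside; the two differ by the attenuation, up to ~0.1 for the strongest
simulated slopes. This is a property of the method, not of this
implementation: the bias actually present in \(\hat\beta'_{GP}\) is
\(b\,\beta_{GI}\) with the *population* \(b\), so subtracting
\(\lambda b\,\hat\beta_{GI}\) under-corrects slightly. Over the
incidence-only cluster this leaves a residual type-1 inflation of roughly
\(0.11\,\mathbb{E}[((1-\lambda) b z_I)^2]\) — about 0.002–0.004 at the
strongest confounding simulated here. It is invisible at the resolution of
the published figures but measurable with enough replicates; one
calibration check in the package's acceptance suite sits just outside a
3-MC-SE band for exactly this reason, and is left that way deliberately.

## Adjusted standard errors

The default adjusted standard error is independent-error propagation,
\(\sqrt{s_P'^2 + \hat b_1^2 s_I^2}\), which reproduces the published
adjusted SEs for the BMI/fasting-insulin loci at printed precision. The
published case-only breast-cancer table implies a different (smaller)
adjusted SE that no simple propagation form reproduces; since the exact
formula is not printed, both `"propagate"` and `"propagate+slope"`
(adding \(\hat\beta_{GI}^2\, s(\hat b_1)^2\)) are provided, and the
discrepancy is documented rather than imitated.

## What passing tests do and do not show

The synthetic generator emulates independent variants, purely linear
effects, a single normal confounder and quantitative traits. Real data add
linkage disequilibrium (addressed only by pruning), binary conditioning
traits (the linear bias form then holds approximately, on the liability of
small effects), allele-frequency-dependent architectures, winner's curse
when selection and estimation share a dataset (mitigated by the
`selection_pvalues` option), and non-normal effect-size distributions.
Passing tests demonstrate correctness of the machinery and recovery under
the stated model, not performance on any particular real cohort.

Known limitations, beyond those above: the two-component reduction assumes
the selection step has removed variants unrelated to \(I\); identification
rests on ZEMRA, which fails when a both-trait pathway dominates the modal
ratio (scenario `s4` reproduces the failure, and the same degradation under
strong negative correlation with a small incidence-only cluster is expected
and observed); and the bootstrap treats variants as independent, so the
interval is optimistic under residual LD.
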