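---
title: "Familial co-aggregation of two binary traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial co-aggregation of two binary traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famcoag)
```

# The scientific problem

Register-based family designs ask whether one lifetime condition in a
person (here an ADHD-like neurodevelopmental trait, "trait 1") is
associated with a *different* condition (an any-autoimmune-disease
composite, "trait 2") in that person and in their relatives, and what
mixture of genes and environment produces the association. The design
exploits the graded genetic relatedness of relative classes: mothers,
fathers and full siblings share on average 50% of additive-genetic
variance, aunts and uncles 25%, and full cousins 12.5%, while full
siblings additionally share their childhood family environment and
cousins essentially do not. A gradient of cross-trait odds ratios that
declines with relatedness but remains above one in cousins points to
shared genetic liability; an excess in maternal over paternal relatives
points to maternal (including gestational) mechanisms.

`famcoag` implements this design end to end on register-shaped data: a
four-table data model (persons, parent links, ICD-coded diagnosis events,
ATC-coded drug dispensations), cohort and pair construction, config-driven
lifetime phenotyping, cluster-robust logistic odds ratios with spline
adjustment, regression-standardized absolute risks, ratio-of-odds-ratio
contrasts, and a bivariate liability-threshold ACE model fitted by maximum
likelihood to sibling and cousin pairs. Because the real registers cannot
be shared, the package also contains a fully specified synthetic-data
generator whose truth is known, so every stage is testable and parameter
recovery can be demonstrated.

# The generative model

## Liabilities

Each person carries a bivariate latent liability
$L_k = A_k + C_k + E_k$, $k = 1, 2$, with standardized variance
components $a^2_k + c^2_k + e^2_k = 1$:

* $A$ (additive genetic): founders draw from a zero-mean bivariate normal
  with per-trait variance $a^2_k$ and cross-trait covariance
  $r_A\sqrt{a^2_1 a^2_2}$; a child's $A$ is the parental midpoint plus an
  independent segregation deviate with half the founder covariance, which
  reproduces the expected sharing of 1/2 for full siblings and
  parent-offspring, 1/4 for avuncular pairs and 1/8 for cousins.
* $C$ (shared environment): drawn once per nuclear sibship and shared by
  all full siblings; cousins and spouses share none. This matches the
  modelling assumption that sibling pairs share 100% and cousin pairs 0%
  of $C$.
* $E$ (unique environment): independent per person, cross-trait
  correlation $r_E$.

A person is a lifetime case of trait $k$ when
$L_k > t_k + s_k(\text{sex}) + b_{k1} z + b_{k3} z^3$, where $z$ is the
birth year standardized to $[-1, 1]$ by midrange and half-range (which
keeps the cubic term tame) and $t_k$ is calibrated by root finding so
that the population-average case probability over the realized covariates
equals the target prevalence exactly.

## Default study conditions

The generator's defaults encode the conditions the package is designed to
emulate: trait-1 prevalence 2.30% and trait-2 prevalence 4.14%;
variance components $a^2 = (0.84, 0.23)$, $c^2 = (0, 0.09)$,
$e^2 = (0.16, 0.68)$; $r_A = 0.13$ and $r_E = 0.02$ ($r_C$ is
structurally absent because trait 1 carries no shared-environment
variance). Sex threshold shifts default to $+0.22$ (trait 1) and
$-0.14$ (trait 2) liability SD for females, chosen to reproduce a
male-dominated neurodevelopmental trait (about 36% of cases female at a
48.6% female population share) and a female-dominated autoimmune
composite (about 56% female). Birth-year threshold trends default to
$(-0.5, -0.3)$ for trait 1 — a strong diagnostic-drift pattern in which
recent cohorts are far more likely to be diagnosed — and $(-0.15, 0)$
for trait 2. Pedigrees span birth years 1920–2010 with parent-child gaps
of at least 15 years; sibship sizes default to uniform on $\{1,2,3\}$;
4% of childless persons die or emigrate before age 10 (censoring is
never applied to persons with descendants, which real pedigrees also
forbid). Cases are emitted as diagnosis events coded by calendar era
(ICD-7 1964–67, ICD-8 1968–86, ICD-9 1987–96, ICD-10 from 1997) and,
for definitions with a drug stem, optionally as dispensations from 2005.

What the generator deliberately does *not* emulate: assortative mating
(the fitted ACE model assumes its absence), half-siblings, twins,
adoption, within-life diagnosis trajectories (only a first-event year is
drawn, uniformly over the years the person is alive, present, at least
age 3 and inside the register period), and false-positive coding. Tests
that pass on this generator therefore show internal consistency of
estimator and model, not robustness to those real-data features.

# Cohort and pair construction

The index cohort keeps persons born in a configurable window whose mother
is known and who did not die or emigrate before age 10; at year
granularity "before age 10" means death/emigration year minus birth year
of at most 9, so an event in the year the person turns 10 retains them.
Pair cohorts follow the pedigree strictly: full siblings share both
parents; aunts/uncles are *full* siblings of a parent (half-siblings of a
parent are excluded); cousins are children of a parent's full siblings;
the side label records the linking parent. Relatives failing the
survival rule are dropped with counts reported. For symmetric relations
the unordered pair is kept once. `family_cluster_id` is the connected
component of the parent-link graph — the most conservative clustering
unit, guaranteeing that any two pairs sharing a person share a cluster.

For variance-component modelling one pair is sampled per family unit
(nuclear sibship for siblings, grandparental lineage for cousins),
uniformly within the unit, visiting units in seeded random order and
skipping pairs whose members were already taken, so no person enters two
pairs.

# Association analyses

Odds ratios come from maximum-likelihood logistic regression (IRLS,
convergence `1e-8`, at most 100 iterations) with the exposure coefficient
exponentiated. Birth year enters as a natural cubic spline with five
knots at the 5th, 27.5th, 50th, 72.5th and 95th percentiles (a standard
default; the basis has dimension knots−1 and is linear beyond the
boundary knots). Pair analyses adjust for both members' birth-year
splines; within-individual analyses for the person's spline and sex.
Variance is the cluster-aggregated sandwich estimator on the family
cluster, with Wald 95% intervals ($\pm 1.96$ on the log scale) and
two-sided p-values; no multiple-testing adjustment is applied anywhere.
Perfect separation is flagged on the result rather than silently
diverging; a degenerate single-cluster analysis falls back to
heteroscedasticity-robust variance with a warning.

Standardized absolute risks average the model's predicted outcome
probability over *all* rows with the exposure forced to 1 and to 0 (the
total-population standard); the risk difference is their difference.
Interval estimation uses a nonparametric cluster bootstrap (default 500
replicates, percentile intervals, seed-reproducible) rather than the
delta method, because the pair rows are correlated within families.
Ratio-of-odds-ratio contrasts merge two disjoint pair cohorts and fit a
single exposure-by-group interaction (group main effect included,
group-specific covariate interactions deliberately not), exponentiating
the interaction coefficient; the three canonical contrasts are mothers vs
fathers, aunts vs uncles, and maternal-side vs paternal-side aunts and
uncles.

# The bivariate liability-threshold ACE model

For a relative pair the four liabilities
$(L^{m1}_1, L^{m1}_2, L^{m2}_1, L^{m2}_2)$ are multivariate normal with
unit variances and correlation matrix built from the components:
within-person cross-trait correlation
$r_A\sqrt{a^2_1a^2_2} + r_C\sqrt{c^2_1c^2_2} + r_E\sqrt{e^2_1e^2_2}$;
cross-person same-trait $\alpha\, a^2_k + \gamma\, c^2_k$; cross-person
cross-trait $\alpha\, r_A\sqrt{a^2_1a^2_2} + \gamma\, r_C\sqrt{c^2_1c^2_2}$,
where $(\alpha, \gamma)$ are the sharing coefficients (siblings
$(0.5, 1)$, cousins $(0.125, 0)$). The probability of each of the 16
joint diagnosis patterns is a rectangle probability of this 4-variate
normal, and the data enter as a 16-cell multinomial per relative class.
With both classes, $(a^2_k, c^2_k)$ solve a full-rank $2\times 2$ linear
system in the two cross-person same-trait correlations; the fitter
verifies this rank before optimizing and refuses structurally
unidentified requests.

## Numerics

Rectangle probabilities use the Genz separation-of-variables
transformation over a rank-1 Korobov lattice with the baker's transform
and fixed Cranley-Patterson shifts, evaluated in compiled code for all 16
patterns of a class in one batch. The point set is deterministic, so the
log-likelihood is a smooth deterministic function of the parameters —
the property the quasi-Newton optimizer needs — and repeated runs are
bit-identical. Lattice generators were selected by worst-case error
against a dense-grid reference on a panel of random positive-definite
problems; at the default fitting lattice (1021 points) the absolute error
on study-like matrices is below $10^{-5}$, and the reporting lattice
(4093 points, 2 shifts) is used for the final log-likelihood, AIC and
observed information. The 16 pattern probabilities of a class sum to one
exactly by construction (the conditional factorizations telescope), and
probabilities are floored at $10^{-300}$ in the log-likelihood.

## Parameterization, optimization and intervals

Variance proportions live on the simplex through log-ratio coordinates
with $e^2$ as reference, correlations through the inverse hyperbolic
tangent, thresholds freely; constraints are therefore satisfied exactly
throughout optimization. Optimization is BFGS with numerical gradients,
multi-start (default five: one method-of-moments start — thresholds from
the margins, variance shares from tetrachoric correlations through the
sharing system — plus dispersed restarts), relative tolerance $10^{-9}$.
Sub-models (AE, CE, E per trait) drop the corresponding coordinates; a
correlation whose component is absent from either trait is structurally
removed and reported as absent. Model selection ranks candidates by AIC
($2k - 2\log L$), ties broken toward fewer parameters. The cross-trait
covariance is decomposed into its A/C/E parts, each reported as a share
of the total.

Confidence intervals default to the delta method on the observed
information (numerical Hessian on the transformed scale, mapped through
the jacobian); profile-likelihood intervals are available through
`profile_ci()` but cost one constrained re-optimization per probe and are
therefore not the default. A caveat documented deliberately: at modest
sample sizes the trait-2 decomposition has a flat likelihood ridge —
$a^2_2$, $c^2_2$ and $r_A$ trade off through the sparse cousin cells —
so single-fit estimates of those parameters scatter widely (and Wald
intervals computed on a near-singular information matrix can degenerate),
while the within-person covariance, the sibling same-trait correlations,
the thresholds and $a^2_1$ are sharply identified. Recovery checks
therefore average replicate fits.

## Problem sizes

The packaged checks fit collapsed 16-cell counts from 400,000 sibling and
100,000 cousin pairs per replicate (a scaled-down register: the full
study would have about 1.66 million and 108 thousand), averaging five
replicate fits; the model-implied odds-ratio checks use 5,000,000
simulated individuals and 2,000,000 cousin pairs. The collapsed-count
likelihood costs the same regardless of pair count (32 orthant
evaluations per call), so these sizes are limited by simulation, not
fitting. Per-pair likelihood mode with covariate-specific threshold
shifts exists and agrees exactly with collapsed mode at zero shifts; it
groups pairs by identical shifts and is intended for coarse covariate
profiles (for example sex), not for continuous per-pair covariates.

# A note on the model-implied within-individual odds ratio

At the default generating values the exact model-implied crude
within-individual odds ratio between the two traits (homogeneous
thresholds at prevalences 2.30% / 4.14%, within-person cross-trait
liability correlation 0.0637) is 1.39. A covariate-adjusted logistic
estimate on register data is a different estimand and can sit a few
percent away; the package reports the model-implied quantity its
simulation actually computes. The analogous cousin-pair odds ratio is
1.039, in close agreement with the co-aggregation gradient the design
predicts.

# Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(overrides = list(n_families = 5000, seed = 1))
res <- pipeline_run_all(cfg, outdir = "results")
pipeline_report("results")
```

This simulates a register of 5000 three-generation families, builds the
index cohort and all six pair cohorts, phenotypes every person against
the illustrative case definitions, runs the within-individual and six
familial odds-ratio analyses, the standardized risks, the three ROR
contrasts, and the sibling/cousin variance-component fit, writing every
table into `results/`. Reruns with the same configuration are
byte-identical; per-stage seeds derive from the master seed by a fixed
scheme.

# Known limitations

* Year-granularity dates: every rule in scope (age-10 exclusion, birth
  windows, register eras) resolves at year resolution; full-date
  arithmetic is a documented coarsening.
* The register model is binary-sex, as the source registers are.
* The generator applies one birth-year trend per trait across all
  generations; generation-specific calibration is left to configuration.
* Shipped code lists are illustrative; the phenotyping engine is driven
  entirely by configuration and makes no claim to reproduce any study's
  operational definitions.
* The ACE fitter covers two traits and A/C/E components; dominance,
  sex-limitation and more than two traits are out of scope.
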