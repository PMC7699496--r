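---
title: "Clustered matched-pair diagnostic accuracy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustered matched-pair diagnostic accuracy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustsens)
```

## The inference problem

In a paired localization study two diagnostic tests are applied to the same
patients and scored against a reference standard (here: surgical findings in
primary hyperparathyroidism, where each patient's thyroid bed is divided into
four quadrant sites and each site either harbours a hyperfunctioning gland or
not). Two features of such data break textbook binomial inference:

* **Clustering.** Each patient contributes several gland sites, and
  detection outcomes within a patient are positively correlated — a patient
  with unfavourable anatomy is hard for *all* sites. Treating the 240 gland
  observations of a 60-patient cohort as independent understates standard
  errors and narrows confidence intervals.
* **Pairing.** Both tests score the same sites, so their errors are
  correlated; comparing them requires matched-pair methods (McNemar-type
  tests), again adjusted for clustering.

Sensitivity is the primary effect measure: in a surgical cohort every
enrolled patient is expected to carry at least one diseased gland, so
patient-level specificity is nearly vacuous, while site-level specificity is
dominated by the many healthy quadrants.

The package analyses data at two grains. At the **patient level** each
patient is one unit (the test must localize at least one truly diseased
site), units are independent, and exact binomial methods apply. At the
**gland level** each site is a unit nested in a patient cluster and all
inference is cluster-robust.

## Estimators

### Unclustered proportions

For patient-level sensitivity $x/n$ the default interval is
**Clopper–Pearson**, computed from beta quantiles:
$$L = B_{\alpha/2}(x,\ n-x+1), \qquad U = B_{1-\alpha/2}(x+1,\ n-x),$$
with $L=0$ at $x=0$ and $U=1$ at $x=n$; at $x=n$ the lower bound has the
closed form $(\alpha/2)^{1/n}$. The exact interval is chosen as default
because the trial-style tables the package reproduces (52/53 yielding
0.90–1.00 and 53/53 yielding 0.93–1.00 at two decimals) are consistent with
it; the **Wilson** score interval is offered as the asymptotic alternative.
Displayed values are rounded half-away-from-zero to two decimals.

### Cluster-robust proportions

Gland-level sensitivity uses the ratio-of-totals estimator over the $K$
clusters that contain diseased sites,
$$\hat p = \frac{\sum_i x_i}{\sum_i n_i},$$
with the sandwich (between-cluster empirical) variance
$$\widehat{\mathrm{Var}}(\hat p) = \frac{K}{K-1}\,
  \frac{\sum_i (x_i - \hat p\, n_i)^2}{\left(\sum_i n_i\right)^2}.$$
This is the standard design-based variance of a ratio estimator under
cluster sampling (a Rao–Scott-type correction) with a $K/(K-1)$
small-sample factor; with all clusters of size one it reduces to
$\hat p(1-\hat p)/(K-1)$. The literature contains several closely related
clustered-proportion variants; this one was chosen because it depends only
on per-cluster totals, reduces to familiar forms in the edge cases, and is
the common published approach for clustered matched pairs. Intervals are
normal-quantile on the identity scale, clamped to $[0,1]$; a logit-scale
option is provided because identity-scale intervals around estimates near 1
otherwise protrude above 1.

### Comparing the two tests

The classical McNemar test (exact binomial on the discordant pairs, or
$\chi^2 = (b-c)^2/(b+c)$) is provided for independent pairs. For clustered
pairs the package tests the difference of the two cluster-robust
sensitivities,
$$\hat D = \frac{\sum_i (x_{ai} - x_{bi})}{\sum_i n_i}, \qquad
  \hat V = \frac{K}{K-1}\,\frac{\sum_i e_i^2}{\left(\sum_i n_i\right)^2},
  \quad e_i = (x_{ai}-x_{bi}) - \hat D\, n_i,$$
and refers $\hat D^2/\hat V$ to $\chi^2_1$. Because the per-cluster
difference $x_{ai}-x_{bi}$ subtracts the shared patient effect, this
statistic absorbs both the within-patient clustering and the within-gland
correlation of the two tests. With singleton clusters and balanced
discordances it is exactly zero, agreeing with classical McNemar.

### Non-inferiority

With margin $\Delta < 0$ for the difference $d = Se_B - Se_A$, the test of
$H_0\!: d \le \Delta$ uses $z = (\hat d - \Delta)/\widehat{se}$ with the
cluster-robust standard error above, one-sided $p = 1 - \Phi(z)$, and a
companion two-sided CI at level $1 - 2\alpha$ so that the CI rule
("lower bound above $\Delta$") and the p-value rule coincide. Defaults —
$\Delta = -0.10$, one-sided $\alpha = 0.05$, 90% CI — mirror standard
non-inferiority practice for high-sensitivity imaging comparisons. $z$ is
reported with a sign that is positive when the data favour non-inferiority;
published analyses differ in orientation, so $|z|$ is what should be
compared across reports. A normal rather than $t$ reference is used, in
line with large-sample clustered-proportion inference; the cluster count
$K$ is reported so users can judge adequacy.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with exactly the structure the analyses
assume, so every inference stage is testable without patient data:

1. Each of `n_patients` (default 60) patients carries one diseased gland,
   or two with probability `p_two_glands` (default 0.1, matching six
   two-gland patients in a 60-patient cohort), placed uniformly among
   4 quadrant sites.
2. A per-patient detection propensity $p_i \sim
   \mathrm{Beta}(\mu, \rho)$ (moment parameterisation: mean $\mu = se$,
   $\mathrm{ICC} = \rho$) induces the intracluster correlation. The beta
   construction preserves the marginal sensitivity exactly for any ICC,
   which a latent-normal construction would not. The two tests' propensity
   quantiles are coupled by a bivariate normal copula with correlation
   `rho_patient` (default 1, one shared patient effect).
3. At each diseased gland the two tests' detections are a correlated
   Bernoulli pair via a Gaussian copula with correlation `rho_ab`
   (default 0.4). Any `rho_ab` in $[0,1)$ is feasible for arbitrary
   marginals; 1 is excluded because comonotone calls are attainable only
   for equal marginals.
4. Non-diseased sites generate independent false positives at rates
   `fp_a`, `fp_b` (default 0.02, roughly 4 calls per 165 healthy sites).

Defaults (`se_a = se_b = 0.85`, `icc = 0.3`) sit in the 0.8–0.9 gland-level
sensitivity range typical of parathyroid imaging and give a cohort of about
66 diseased among 240 sites. Generation is vectorised under a single
`set.seed(seed)` stream; the same seed reproduces a cohort byte for byte.
(Per-patient substreams were considered for parallel generation and
rejected: nothing in the package generates cohorts in parallel, and a
single stream keeps the generator simple and exactly reproducible.)

The `rho_patient` parameter deserves a note. With one fully shared patient
effect and equal marginal sensitivities, the per-gland differences
$a_j - b_j$ are *uncorrelated* within a cluster (the shared effect cancels
in expectation), and naive McNemar is approximately valid even under strong
ICC. Real tests plausibly have partially test-specific patient effects
(e.g. tracer-specific uptake physiology), and it is exactly then that naive
McNemar becomes anticonservative. `rho_patient < 1` makes that regime
representable; the size study in the validation suite uses it, together
with two diseased glands per patient so that within-cluster pairs exist at
all (with the trial's 1–2 glands per patient the naive design effect
$1 + (\bar m - 1)\rho_d$ is within Monte-Carlo noise of 1).

`estimate_generator_moments()` closes the loop: over replicate cohorts it
recovers marginal sensitivities and false-positive rates, the detection ICC
(pairwise product-moment estimator over within-patient gland pairs) and the
within-gland log odds ratio of paired detections (pooled over replicates —
per-replicate odds ratios are badly biased when a cell expectation falls
below one, as happens for near-perfect tests).

## What the simulations do and do not show

The validation suite checks, at fixed seeds:

* Clopper–Pearson coverage at or above nominal over
  $p \in \{0.5, 0.8, 0.95\}$, $n \in \{10, 53\}$ (10,000 replicates per
  cell);
* type-I error of the non-inferiority test at the margin
  (`se_a = 0.85`, `se_b = 0.75`, ICC 0.3, 60 patients, 5,000 replicates)
  within 1.5 percentage points of the nominal 5%;
* size of the cluster-adjusted McNemar test within the same band, under a
  configuration where the naive test demonstrably exceeds it;
* parameter recovery of the generator within 3 Monte-Carlo standard errors
  over the grid $se \in \{0.8, 0.95\} \times \mathrm{ICC} \in \{0, 0.3\}
  \times \rho_{ab} \in \{0, 0.4\}$ (150 replicate cohorts per cell).

Problem sizes (replicate counts, grid densities) are the package's chosen
compromise between Monte-Carlo resolution and suite runtime; rerunning with
larger counts is a one-line change in the test files.

Passing these checks shows the machinery is internally correct *for the
generator's data-generating process*: exchangeable within-patient
correlation via a beta propensity, a homogeneous copula dependence between
tests, and site-independent false positives. Real imaging data can violate
all three (site-specific difficulty, gland-size-driven heterogeneity,
reader effects), and no simulation here speaks to adjudication questions
such as how a "location match" is scored (side versus quadrant) — both
granularities are representable in the data model, but fidelity of
adjudication is an input problem, not a statistical one.

Known behaviour worth stating plainly: the Wald-type cluster-robust $z$
statistic is mildly anticonservative when the number of informative
clusters is small and sensitivities are extreme — the standard error is
nearly unbiased but negatively correlated with the estimate, which inflates
the upper tail. The size simulations in the suite quantify this at the
default design point; users planning studies at more extreme operating
points should rerun `run_power_grid()` at their own design and consider the
logit-scale interval for estimation.

## Degenerate inputs and numerical conventions

* Fewer than two informative clusters: cluster-robust estimators and tests
  raise a degenerate-variance error; `analyze_cohort()` catches it and
  reports the affected stage while still rendering point estimates.
* Zero between-cluster variance with zero difference: adjusted McNemar
  returns statistic 0, $p = 1$; with nonzero difference it errors.
* Zero standard error in the non-inferiority test: the verdict falls back
  to the sign of $\hat d - \Delta$, flagged `degenerate`, with no $z$.
* No discordant pairs: exact McNemar returns $p = 1$ with a warning;
  chi-square variants error.
* Surgery-negative patients are admitted with a warning (published
  patient-level tables contain them even when the design implies every
  patient has disease); `analyze_cohort()` records the warning as a note.
* All intervals are clamped to $[0,1]$; display rounding is two decimals,
  half away from zero.

## The packaged fixtures

`patient_level_tables()` and `gland_level_tables()` return the published
marginal 2×2 tables of the 60-patient trial the defaults mirror.
`synthetic_gland_cohort()` (also shipped as
`extdata/gland_cohort_synthetic.csv`) is a deterministic 240-record cohort
whose gland-level margins equal the published ones. It is *synthetic*: the
published tables fix only the margins, and the patient-level and
gland-level published tables are mutually inconsistent (six false-positive
patients cannot coexist with four false-positive gland calls), so the
cohort reproduces the gland level and makes no claim at the patient level.
Similarly, the published gland-level point sensitivities (0.83/0.87 in the
tables, 0.88/0.87 in the abstract of the source trial) disagree with each
other and with the pooled counts (59/75 = 0.787, 60/75 = 0.800); the
package reports the count-derived pooled and cluster-robust estimates and
leaves the discrepancy documented rather than resolved.
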