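---
title: "Methods: multivariate NB models, BACI effects, and bootstrap power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate NB models, BACI effects, and bootstrap power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacinb)
```

## The problem

`bacinb` analyses Before-After-Control-Impact (BACI) field experiments on
multivariate taxon-count data. The motivating setting is non-target
ecotoxicology: paired treated/control plots are sampled for ground-dwelling
arthropods before and after a treatment (for example a biopesticide spray),
arthropods are counted by order, and the question is whether treatment
changed community abundance. Counts per order are strongly skewed across
orders (a couple of orders dominate), overdispersed within cells, and
correlated across orders within a sample — all of which shape the methods
below.

## Data model and pooling

The central container, `taxon_counts()`, holds a samples-by-taxa matrix of
non-negative counts with one row of design metadata per sample: location,
treatment (treated/control), habitat (lawn/forest), occasion (`pre`,
`post1`, `post2`), a `period` factor (before/after) derived from occasion,
and the sample type (`bulk` or `pitfall`). Raw field samples carry a
component label (lawn core, forest soil, forest litter, pitfall trap);
`pool_samples()` sums components within each plot x habitat x occasion x
sample-type cell, producing the pooled samples that all analyses use. In
the default design this takes 467 raw bulk samples to 156 pooled rows and
129 usable pitfall samples to 68 pooled rows.

Very abundant taxa are counted in a fixed fraction of each bulk sample and
scaled up: `extrapolate_subsample(count, fraction)` returns
`count / fraction` (with the 15% protocol, (100/15) x count). Extrapolated
totals are fractional; pooled counts are rounded half-up to integers
because the negative binomial likelihood is defined on integer counts and
downstream fitting requires it. The rounding perturbs each pooled count by
at most 0.5, which is negligible against the counts involved (hundreds for
the subsampled taxa). Cells that lost a component sample are pooled from
the remaining components without rescaling — lost samples are rare (about
one bulk component in five hundred) and rescaling would inject a known
upward bias into cells whose remaining components happen to be large.

## The abundance model

Abundance of taxon $j$ in pooled sample $i$ is modeled as negative binomial,
$Y_{ij} \sim \mathrm{NB}(\mu_{ij}, \Phi_j)$, with the package-wide
parameterization: mean $\mu$, dispersion (size) $\Phi$, variance
$\mu + \mu^2/\Phi$, so $\Phi \to \infty$ recovers Poisson. The mean is
log-linear in the design factors:

$$\log \mu_{ij} = \beta_{0j} + \mathrm{period}_{p(i)} + \mathrm{habitat}_{h(i)} + \mathrm{location}_{l(i)} \,(+\ \mathrm{treatment}_{t(i)})$$

The null model contains period, habitat, and location; the alternative adds
treatment. Factors use treatment-contrast (reference level) coding. Taxa
are fit independently (the design is far too small to estimate a 20 x 20
cross-taxon correlation matrix); the multivariate fit is the collection of
per-taxon fits with the summed log-likelihood. Cross-taxon correlation is
respected where it matters — in resampling-based inference, which always
moves whole sample rows.

### Fitting

`fit_nb_glm()` maximizes the NB likelihood by alternating iteratively
reweighted least squares for the coefficients at fixed dispersion with
profile-ML updates of the dispersion (Newton steps on the profile score,
with a bisection fallback; dispersion constrained to $[10^{-4}, 10^7]$).
The outer alternation stops when the log-likelihood changes by less than a
relative $10^{-8}$ (at most 200 alternations; non-converged taxa are
flagged and the model AIC marked approximate in the run log). The fitter is
implemented in C++ with an R reference engine (`engine = "r"`) that the
test suite checks against it; both are validated against `MASS::glm.nb` and
a direct multi-start BFGS optimization of the likelihood.

Degenerate responses — taxa with all-zero counts under a model — are fit at
a mean floor ($\mu = 10^{-8}$) with the dispersion at its upper bound,
flagged, retained in the output, and excluded from likelihood-ratio
statistics. They are not dropped: dropping taxa would silently change the
AIC comparison that the decision rule below depends on.

### The AIC decision rule

`compare_models_aic()` fits the nested pair and reports
$\mathrm{AIC} = -2\ell + 2k$ totalled over taxa, counting each taxon's
dispersion as an estimated parameter (so a model with $p$ design columns
costs $(p+1)$ parameters per taxon). Treatment is declared to affect
abundance when the alternative model's AIC is strictly lower; exact ties
(within $10^{-9}$) go to the null by parsimony. The published AIC
accounting for this model family is not fully standardized — whether each
dispersion counts as free differs between implementations — which shifts
all AICs by a constant per model and can shift the delta by a constant;
sign and preference, which the decision rule uses, are unaffected in the
nested comparison here only by the per-taxon coefficient difference, so the
parameter accounting is stated explicitly and verified by an internal
identity test ($\Delta\mathrm{AIC} = 2 k_\mathrm{extra} - 2\Delta\ell$,
with $k_\mathrm{extra}$ = one coefficient per taxon for treatment).

### Analysis of deviance with row resampling

`anova_deviance()` tests terms sequentially (type I): term $k$ is the
likelihood-ratio statistic between the models with terms $1..k{-}1$ and
$1..k$, summed over non-degenerate taxa. P-values come from resampling
rather than asymptotic chi-square, because the per-taxon sample sizes are
small and taxa are correlated. The scheme is probability-integral-transform
(PIT) residual resampling: under the smaller model, each observation's
count is mapped to a uniform draw from its fitted NB mass interval
$u_{ij} \sim U(F_{ij}(y_{ij}-1),\, F_{ij}(y_{ij}))$; whole rows of the $U$
matrix are permuted (preserving cross-taxon correlation); and counts are
regenerated through each observation's fitted inverse CDF. Both models are
refit to each regenerated dataset and
$p = (1 + \#\{LR^\ast \ge LR\}) / (1 + R)$. At least 99 resamples are
required (p-value resolution 0.01); analyses in this package default to
199.

A Wald variant (`statistic = "wald"`, summing per-taxon quadratic forms in
the term's coefficients) is provided for the late-occasion pitfall
analysis, whose published table reports a Wald statistic; LR is the default
everywhere.

Calibration: with the fitted model matching the generating one, the null
p-values are uniform (verified by simulation in the test suite). When
balanced structure (habitat, location) is present in the data but omitted
from the model, the treatment test becomes conservative — the balanced
design makes the observed treatment contrast less variable than the
unstructured resamples imply. This is a property of the testing scheme, not
a defect; it argues for keeping location in the model wherever it is
identifiable, as the default analyses do.

## BACI effects

`baci_effect()` works on mean counts, not model coefficients. For each
(location, habitat) replicate the four cell means over pooled samples form
the replicate-level BACI value

$$(\bar Y_{\mathrm{treated, after}} - \bar Y_{\mathrm{control, after}}) - (\bar Y_{\mathrm{treated, before}} - \bar Y_{\mathrm{control, before}})$$

and the per-taxon effect is the mean of replicate values with its standard
error the replicate SD over $\sqrt{n}$ (sample SD with $n-1$ denominator;
the convention is stated because it is not standardized). Replicates
missing any of the four cells are dropped with a warning; with fewer than
two complete replicates the SE is reported missing. Category means are
computed at the pooled-sample level, which is the scale the models fit.
Because roughly twenty taxa are examined at once, the package deliberately
attaches no per-taxon p-values to BACI effects — with 20 unadjusted tests
one false positive is expected, while adjusting would bury real
community-level signal; inference belongs to the community-level AIC rule.
Effects spanning orders of magnitude in either direction are plotted on the
inverse hyperbolic sine scale (`asinh_scale()`), which is log-like but
defined and antisymmetric at zero.

## Bootstrap power analyses

Both power analyses are built directly on the AIC decision rule, so "power"
means: the probability that the rule selects the treatment model.

* `retrospective_power()`: each run draws $n$ pooled samples with
  replacement from the observed set (whole rows, metadata attached —
  preserving cross-taxon correlation), multiplies the counts of
  treated-after rows by a reduction factor (rounding half-up), fits both
  models, and scores whether the treatment model wins. The factor grid
  0.1–0.9 in steps of 0.05 with 10,000 runs per factor reproduces the
  full-study protocol; desk-scale runs use coarser grids and hundreds of
  runs, with Monte-Carlo standard errors $\sqrt{p(1-p)/R}$ reported per
  cell.
* `prospective_power()`: identical except each run draws
  $m \times n$ rows, simulating a future study $m$ times larger; with
  $m = 1$ it is the retrospective analysis (bit-identical under the same
  seed).

Resampling is unstratified across the rows of the occasion pair — the
resampled metadata, not a fixed design, determines which rows are reduced.
Resamples in which a model factor loses all its levels (or the design
becomes unfittable) are redrawn and counted; redraw counts are reported in
the grid. A negative control is built into the test suite: applying the
reduction to every row (treated and control alike) removes the treatment
contrast and collapses "power" to the rule's false-selection rate.

The summaries `detectable_reduction()` (smallest reduction with power at or
above 80%) and `required_multiplier()` (smallest sample-size multiplier
reaching 80%) are always derived from the grid, never stored independently.

## The synthetic-data generator

`simulate_dataset()` inverts the abundance model over a replica of the
field design: 13 locations with paired treated/control plots spanning lawn
and forest; bulk samples (2 lawn cores; 2 forest soil + 2 forest litter per
plot) at a pre-treatment and two post-treatment occasions; paired pitfall
traps at 7 locations (pre and one week post) plus a late occasion at 3 of
them; 20 taxa. Counts are drawn NB with log-mean = taxon intercept +
occasion effect + habitat effect + shared location effect
($\mathcal{N}(0, \sigma_\mathrm{loc})$, identical for the paired plots) +
log treatment multiplier on treated-after cells, divided by the number of
components in the cell so that pooled cells hit the intended means.

Defaults are chosen to mirror the field study's published abundance
structure rather than to be generic: two dominant taxa with pooled-sample
means near 570 and 170 against 18 minor taxa with means 0.5–8 (the
dominant-to-median ratio is a few hundred), per-taxon dispersion 1
(variance-to-mean ratios of tens to hundreds for the dominant taxa),
pitfall catches scaled down 20-fold, occasion effects of $-0.2$ and $-0.4$
log-units (mild seasonal decline), $\sigma_\mathrm{loc} = 0.5$, a
treatment multiplier of 1 (the null), one lost bulk litter sample and 7
unsortable pitfall samples. The two dominant taxa are "counted" by
simulating a 15% binomial subsample and extrapolating, so the generator
exercises the same estimation noise as the field protocol.

What the generator does not emulate: spatial autocorrelation beyond the
shared location effect, zero inflation, taxon-by-taxon correlated responses
to treatment beyond what the shared design factors induce, and
between-occasion dependence within a plot. Passing tests on synthetic data
therefore demonstrate that the machinery recovers what it assumes — not
that real arthropod communities satisfy those assumptions.

One consequence of pooling worth noting: summing $k$ components of
dispersion $\Phi$ yields a pooled variance profile close to NB with
dispersion $k\Phi$, so pooled-scale dispersion estimates sit above the
component-scale value (about 2 for lawn, 4 for forest cells at $\Phi = 1$).
Parameter-recovery tests therefore run on the raw component scale, where
the generating model and fitted model coincide exactly.

## Numerical choices

* NB likelihood floor $\mu \ge 10^{-8}$; linear predictors clamped to
  $\pm 30$ during IRLS.
* Dispersion search range $[10^{-4}, 10^7]$; estimates at the upper bound
  indicate effectively-Poisson data.
* Near-singular weighted least-squares systems (possible in bootstrap
  resamples with rare factor levels) receive a scale-relative ridge of
  $10^{-8}$; resamples that remain unfittable are redrawn.
* AIC ties within $10^{-9}$ prefer the null model.
* Counts are integerized by rounding half away from zero, once, at pooling
  (and again after bootstrap reduction, for the same likelihood reason).
* Every stochastic routine takes an explicit seed and restores the caller's
  RNG state; pipeline stage seeds are derived from the master seed by fixed
  offsets.

## Problem sizes used in examples and checks

The shipped checks run the full default design (156 + 68 pooled samples, 20
taxa) for single fits and model comparisons; decision-rule selection rates
use 100–200 simulated experiments; power grids use 100–200 bootstrap runs
on coarse factor grids (Monte-Carlo SE about 0.03 at $p = 0.8$); the
resampling anova uses 99–199 resamples. The full published-scale protocol
(10,000 retrospective and 1,000 prospective runs, 17-point factor grid) is
available by argument and scales linearly in runs and grid size.

## Known limitations

* Dispersion is per taxon but common across habitats within a taxon; the
  component-pooling argument above shows this is mildly misspecified for
  pooled bulk cells (lawn vs. forest pool different component counts),
  which slightly distorts per-coefficient standard errors but not the AIC
  comparison both models share.
* The sequential anova depends on term order, as in any type-I
  decomposition; order follows the model specification.
* The AIC rule is a community-level yes/no; it does not localize which
  taxa drive a detection (by design, mirroring the analysis it
  implements).
* Prospective resampling treats the observed pooled samples as the
  population; it cannot anticipate distributional change in a larger
  future study.
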