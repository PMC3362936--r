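---
title: "Reaction-norm models of disease resistance and tolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-norm models of disease resistance and tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tolnorm)
```

## The problem

Resistance and tolerance are complementary host defenses against a
disease. Resistance limits how sick an animal gets; tolerance limits the
performance cost of a given disease severity. In broiler chickens
challenged to ascites (a cardiopulmonary oxygen-supply disorder provoked
experimentally by cold and elevated CO2), resistance is indexed by the
heart ratio — the right-ventricle weight as a percentage of total heart
weight — and tolerance is the reaction-norm slope of 7-week body weight on
disease severity. `tolnorm` implements the full genetic analysis of this
design: pedigree algebra, REML animal models, a random-regression
tolerance model, covariance-function trajectories, and a synthetic
population generator so that every stage can be exercised and tested
without access to breeding-company data.

## Trait coding

Body weight responds to heart ratio only once the bird is actually
diseased, so the severity axis is plateau-linear: heart ratios at or below
a threshold (29 % by default) are coded 0, values above it as the excess
over the threshold (`code_ratioplat()`). The threshold itself is selected
by refitting the tolerance model over a candidate grid (27–30 %) and
comparing information criteria (`threshold_scan()`).

Two coding details matter:

* Class membership: residual variance is estimated separately in five
  severity classes, `0`, `(0,5]`, `(5,10]`, `(10,15]`, `(15,Inf)`. The
  exactly-zero class keeps healthy birds pure; interval boundaries are
  right-closed (the source analysis does not state the convention, so it
  is fixed here once and documented).
* Information criteria across codings: REML log-likelihoods contain a
  `log|X'V^-1X|` term that shifts with the scale of fixed covariate
  columns, so naively recoding the severity covariate makes AIC drift
  monotonically with the threshold regardless of fit. The fixed severity
  columns are therefore standardized to unit root-mean-square within each
  fit — a pure reparameterization (coefficients are rescaled back for
  reporting) that makes AIC/BIC comparable across thresholds and between
  the plateau and linear codings.

## The models

Trait-mean animal models for 2-week weight (BW2), 7-week weight (BW7) and
heart ratio (RATIO):

y = mu + animal + dam + GENDER + BATCH x STABLE + AGE (+ PERSON) + e,

with `animal` the additive genetic effect, cov = sigma^2_G A (A the
pedigree numerator relationship matrix), `dam` an independent maternal
environment effect, and `PERSON` the heart-cutter effect for RATIO (11
trained cutters introduce measurement-level differences). Ages are fitted
as class factors because recording ages take a handful of discrete day
values.

The tolerance model regresses BW7 on the plateau severity t:

y = (b0 + b0_animal + b0_dam) + (b1 + b1_animal + b1_dam) t
    + GENDER + BATCH x STABLE + AGE + PERSON
    + b1_BATCHxSTABLE t + b1_PERSON t + e(class(t)),

with an unstructured 2x2 (intercept, slope) covariance block at the animal
level (pedigree-structured) and at the dam level (independent; the
dam-level block is unstructured, which the reported maternal
intercept-slope correlation implies), and one residual variance per
severity class so residual heterogeneity cannot masquerade as genetic
slope variance. The fixed slope interactions use the same reference-level
constraints as their intercept counterparts; since the bare `t`
coefficient then refers to the reference cell, the reported population
slope is the record-averaged derivative of the fixed part with respect to
severity (`population_slope()`).

Joint models extend this: `bivariate_fit()` couples two trait means
through 2x2 genetic/dam/residual blocks (residual covariance contributes
only where both traits are observed on a bird), and `extended_fit()`
couples a trait mean with the reaction norm through 3x3 blocks, yielding
the correlations of BW2 and RATIO with the tolerance intercept and slope.

## The REML engine

All models reduce to one engine. For variance parameters the restricted
log-likelihood is evaluated through the mixed-model equations

C = W' R^-1 W + blockdiag(0, G^-1),   W = [X Z],

-2 logL = log|R| + log|G| + log|C| + y'Py + (n - p) log 2 pi.

Every term of C is linear in a small number of coefficients (inverse
residual-class variances, entries of the inverted intercept-slope blocks
times the sparse pedigree A-inverse), so the engine precomputes each
contribution's values and positions in a fixed sparsity pattern once, and
each likelihood evaluation is a vector update followed by a numeric
refactorization of a cached sparse Cholesky analysis. On the default
reduced population (3200 offspring) one tolerance-model likelihood
evaluation takes a few tens of milliseconds.

Design choices:

* Parameterization: log-variances and log-Cholesky factors for the 2x2
  and 3x3 blocks, plus `atanh` residual correlations. Every iterate is
  positive semidefinite by construction; no proposal ever needs repair.
* Optimization: quasi-Newton bound-constrained maximization (`nlminb`)
  over the transformed parameters. Exact REML gradients would require
  trace terms of the sparse inverse of C (a selected-inverse computation
  not exposed by the sparse linear algebra used here); with the cheap
  likelihood evaluations a derivative-free quasi-Newton search reaches the
  same optimum robustly. Optima that are flat in weakly identified
  directions (common for dam-level covariances) are accepted as converged
  when a restart cannot improve the objective.
* Convergence: relative log-likelihood change below 1e-12, at most 300
  iterations; on balanced designs the estimates match closed-form ANOVA
  estimators to better than 1e-6 relative.
* Standard errors: numerical curvature (observed information) of the
  restricted likelihood in the natural component parameterization,
  inverted to a covariance matrix; functions of components (h^2, m^2,
  correlations) get first-order delta-method SEs. At boundary optima
  (zero variances, |correlation| = 1) the likelihood is one-sided in the
  affected components: their SEs are reported as unavailable rather than
  fabricated, while the remaining components' SEs are computed from the
  clean curvature submatrix (i.e. conditional on the boundary components).
* Starting values are data-driven fractions of the (per-class) response
  variance; generating values are never used.

Pedigree algebra follows the standard animal-model toolkit: inbreeding
from the tabular relationship of each animal's parents (memoized
recursion, exact for arbitrary pedigrees), Henderson's rules with
inbreeding adjustment for the sparse A-inverse, and the dense tabular
method retained purely as a test oracle for small pedigrees.

## Covariance functions

A fitted intercept-slope block G gives the genetic (or maternal) variance
at severity t as x'Gx with x = (1, t)', the phenotypic variance as
V_P(t) = V_G(t) + V_M(t) + V_E(class(t)), variance ratios h^2 = V_G/V_P
and m^2 = V_M/V_P, and the genetic correlation between healthy (t = 0)
and affected birds as

r(t) = (v0 + t c) / (sqrt(v0) sqrt(v0 + 2 t c + t^2 v1)).

r(0) = 1 identically; r below 1 measures genotype re-ranking. The default
trajectory grid runs from severity 0 to 20 in steps of 0.5 (heart ratios
29–49 % after back-transformation). As a worked check on published
component values: v0 = 10640, v1 = 57.8 and an intercept-slope
correlation of -0.30 give

```{r}
g <- gencov2(10640, 57.8, -0.30 * sqrt(10640 * 57.8))
round(correlation_with_healthy(g, 46.5 - 29), 2)
```

## The synthetic population generator

`sim_config()` encodes the study conditions: 83 sires each mated to ~15.7
of 788 dams, 7722 offspring in 5 batches x 2 stables, 11 heart cutters,
two-day recording-age spread, 9 % mortality between the weighings, and a
4-variate additive-genetic and maternal covariance structure over (BW2,
RATIO, INTERCEPT, SLOPE) built from the published variance components and
correlation tables. Phenotypes follow the analysis model's own data
generating process: RATIO is a single normal trait (mean 28.2, total
variance 46.72, so ~45 % of birds exceed the 29 % threshold — the
closed-form normal tail is a generator test); BW7 is intercept plus
(population slope -14.6 + fixed offsets + animal slope + dam slope) times
severity with a class-specific residual.

Choices where the source is silent, fixed once:

* Class residual variances of BW7 are not published; they are calibrated
  analytically so the class-wise phenotypic coefficients of variation
  reproduce the published increasing sequence 11.5–19.1 % given the
  variance trajectories and the mean trajectory 2080 - 14.6 t, giving
  (43800, 44750, 60500, 64700, 93800) g^2.
* Fixed-effect level values are small centered constants (e.g. +/-60 g
  gender effect on BW7, +/-0.25 % on RATIO) — visible but non-dominant,
  and configurable.
* Mortality removes the 7-week records independently at random; a small
  extra rate removes RATIO alone, mimicking the published record counts.
* Reduced presets: `"small"` (40 sires x 8 dams x 10 offspring = 3200)
  for replicate recovery studies, `"large"` (50 x 10 x 10 = 5000) for
  single-fit precision. The acceptance checks use 100 replicates of the
  trait-mean model and 20 of the tolerance model at the small preset —
  sizes chosen so a full run stays comfortably on one desk CPU.

What the generator deliberately does not emulate: ascites physiology, a
two-component mixture for heart ratio (the single-normal treatment matches
the analysis model; the implied ~45 % affected fraction is higher than the
36 % sire-family average reported for the real birds and is tunable via
the RATIO mean), selection across generations, and non-random mortality.
Passing recovery tests therefore demonstrates correctness of the
estimation machinery under the analysis model's own assumptions, not
robustness to violations real data may carry.

## A structural property worth knowing

The published correlation structure couples the reaction-norm
coefficients to the severity covariate itself: RATIO correlates
genetically with SLOPE (-0.36; maternally -0.80) and with INTERCEPT
(0.15). In the generator this makes each bird's random slope correlated
with its own severity t, so the conditional mean E[BW7 | t] acquires
curvature beyond the plateau-linear kink. Two measurable consequences,
both verified by simulation in the test suite:

* The fixed population slope of the tolerance model estimates the
  realized mean individual slope among affected birds (~ -16 under the
  default conditions), not the marginal generating parameter -14.6. The
  fit is unbiased for the former; the two differ because birds that
  become severely affected carry systematically more negative slopes.
* The information-criterion threshold scan inherits the curvature: a
  broken stick fitted to a slightly concave response prefers a kink above
  the generating threshold. With the severity-linked correlations removed
  the scan recovers the generating threshold; under the full default
  correlation structure it tends one candidate high at reduced scale.

Neither effect is an estimation defect — re-fitting the same data with
matched (uncorrelated) generators recovers every component — but they are
exactly the kind of bias the original design guards against by requiring
large sire families and checking the initial-growth covariate, and they
set honest limits on what "recovering -14.6" can mean under the published
correlation structure.

A separate small-sample property affects the dam-level slope variance:
its generating value (23) sits below its own per-replicate sampling SD at
the reduced scale, so the positive-semidefinite-constrained REML estimate
behaves like a positive-part estimator and its replicate mean is inflated
(roughly doubled at 3200 offspring). This mirrors the original finding
that the maternal slope variance had a standard error as large as the
estimate; averages of near-boundary variance components should be read
with that censoring in mind.

## Significance conventions and reporting

Variances and variance ratios are called significant when the estimate
minus 0.98 times its SE stays above zero (a one-tailed convention taken
verbatim from the source analysis; it is not a likelihood-ratio test).
Correlations use the usual two-tailed 1.96 SE rule. EBV distributions are
summarized per pedigree role (phenotyped offspring, sires, dams) as
ranges and histogram bins; under the default conditions the sire slope
EBVs spread wider than the dam maternal-slope solutions, mirroring the
generating variance ordering (57.8 vs 23).

## Numerical edge cases

* Unknown parents (coded `0`, empty or `NA`) become unrelated founders.
* Zero-variance components run into the log-scale lower bound; the fit is
  flagged `boundary` and SEs of ratios involving that component are
  reported unavailable.
* Severity classes with no records are dropped from the residual model
  (with the class labels recording which remain).
* Single-level fixed factors after row exclusion are an error, except for
  recording age, which degrades to a constant and is dropped (a constant
  age carries no information).
* Rank-deficient fixed designs are an error naming the confounded
  columns, not a silent drop.

## Known limitations

The engine targets the desk scale of this design (up to ~10^4 animals,
up to 3x3 covariance blocks, at most two jointly modeled responses).
Average-information updates, eigenfunction decompositions of the
covariance function, spline reaction norms, genomic relationship matrices
and mixture models for the severity trait are out of scope.
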