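---
title: "Models and methods behind morphburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind morphburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(morphburden)
```

morphburden implements an inference chain for studies that relate a discrete
host phenotype — here the blue/brown color polymorphism of lingcod
(*Ophiodon elongatus*) — to metazoan parasite burden and body condition.
This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data tests do and do
not demonstrate about real data.

## The burden model

The central object is a negative-binomial mixed model for per-taxon parasite
counts. For parasite taxon $i$ in fish $j$ at sampling location $k$ in
region $l$,

$$
y_{ijkl} \sim \mathrm{NB2}(\mu_{ijkl}, \theta), \qquad
\log \mu_{ijkl} = \beta_0 + \beta_d\,\mathrm{depth}_j + \beta_s\,\mathrm{male}_j
 + \beta_c\,\mathrm{brown}_j + \beta_{sc}\,\mathrm{male}_j\mathrm{brown}_j
 + r_l + s_{kl} + f_{jkl} + \mathbf{x}_j^\top \mathbf{u}_i + \log L_j ,
$$

with nested random intercepts $r_l \sim N(0, \sigma_r^2)$,
$s_{kl} \sim N(0, \sigma_s^2)$, $f_{jkl} \sim N(0, \sigma_f^2)$ (fish within
location within region), a correlated taxon-level random vector
$\mathbf{u}_i \sim N(\mathbf{0}, \Sigma_t)$ on
$\mathbf{x}_j = (1, \mathrm{male}_j, \mathrm{brown}_j,
\mathrm{male}_j\mathrm{brown}_j)$, and an offset of log total length (cm)
whose coefficient is fixed at 1, so the response is effectively a rate of
parasites per unit length. NB2 means $\mathrm{Var}(y) = \mu + \mu^2/\theta$;
$\theta \to \infty$ recovers the Poisson.

Conventions:

* **Treatment contrasts, reference female/blue.** Reported terms are
  `sex[male]` and `color[brown]`, so a *negative* interaction means the
  blue-vs-brown contrast is larger in males than in females. The
  multiplicative blue-to-brown ratio within males is
  $\exp(-(\beta_c + \beta_{sc}))$ (`blue_to_brown_ratio()`).
* **Scale-then-add-2.** Depth is standardized as $(x - \bar x)/s + 2$
  (`scale_plus_two()`, sample SD with $n-1$), keeping standardized values
  positive; the constants are retained for back-transformation. Among the
  burden model's predictors only depth is numeric, so only depth is
  standardized. The offset uses raw log length: rescaling a variable inside
  an offset would change the model, not its parameterization.
* **Zeros are retained.** A dissected fish that yielded no individuals of a
  taxon contributes a zero count; zeros are informative under the NB model.
  Absent (fish, taxon) pairs in an input file are completed as structural
  zeros with a logged count.

## Estimation: Laplace-approximated maximum likelihood

The marginal likelihood integrates over all random effects. With the
spherical parameterization $\mathbf{u} = \Lambda \mathbf{v}$,
$\mathbf{v} \sim N(\mathbf 0, I)$, the Laplace approximation is

$$
\ell(\beta, \theta, \Lambda) \approx
\ell_c(\hat{\mathbf v}) - \tfrac12 \lVert \hat{\mathbf v}\rVert^2
 - \tfrac12 \log\det\!\big(\Lambda^\top Z^\top W Z \Lambda + I\big),
$$

where $\hat{\mathbf v}$ is the joint mode of the penalized conditional
log-likelihood and $W$ the NB working weights at the mode. The
implementation is split into:

* an **inner problem** — damped Newton iterations to the joint mode of all
  random effects (nested fish blocks plus crossed taxon blocks), converged
  when the infinity norm of the penalized gradient drops below `inner_tol`
  ($10^{-8}$ by default), implemented in C++ with dense Cholesky solves
  (the random-effect dimension is a few hundred at study scale);
* an **outer problem** — bounded quasi-Newton (`nlminb`) over the fixed
  effects, $\log\theta$, the log random-effect SDs, and the taxon
  covariance factor (log diagonal, free sub-diagonal), relative tolerance
  `outer_tol` ($10^{-6}$ by default). Optimizing scale parameters on the
  log scale enforces positivity; a log-SD at its lower bound ($e^{-7}$)
  is reported as a boundary (singular) fit.

Wald standard errors come from finite-difference curvature of the Laplace
objective in the fixed effects at the optimum, holding the variance
parameters at their estimates — the "conditional on the variance
parameters" convention of classic mixed-model software, slightly
anti-conservative when variance parameters are poorly determined. An
alternative `se_method = "full"` takes the fixed-effect block of the
inverse Hessian over all interior outer parameters (carrying
theta/variance uncertainty, with box-bounded parameters held fixed); as a
high-dimensional finite-difference Hessian it is slower and can be
numerically fragile on large models, which is why the conditional
curvature is the default. The permutation machinery pins both the
observed and replicate fits to the conditional statistic: the permutation
reference distribution self-calibrates, so only internal consistency of
the statistic matters there, not its absolute scale. p values are
two-sided standard normal, with no degrees-of-freedom correction; at 89
fish and 25 taxa the normal reference is the defensible default and
matches how such tables are conventionally reported.

Per-taxon interaction slopes (`extract_taxon_effects()`) are conditional
modes $\hat{\mathbf u}_i = \Lambda \hat{\mathbf v}_i$ with conditional SDs
from the corresponding blocks of the inverse inner Hessian, mapped through
$\Lambda$; the total slope for taxon $i$ is $\beta_{sc} + \hat u_{i,sc}$,
which is what a caterpillar plot should display.

The Laplace approximation is validated against an independent 50-node
adaptive Gauss-Hermite quadrature oracle on a shipped single-random-effect
toy (12 counts, 3 groups); agreement is required to $10^{-3}$ relative
error at the fitted parameters, and the full model is cross-checked against
an independent mixed-model implementation (glmmTMB) on moderate synthetic
datasets in the test suite.

A collinearity check runs before every fit: per-column VIFs of the
fixed-effect matrix, $1/(1 - R_j^2)$, warn above 5 but never abort —
severely unbalanced sex-color designs legitimately produce moderate VIFs,
and aborting would hide the fit the user asked for.

## The synthetic-data generator

`generate_dataset()` inverts the burden model into a simulator: it draws
the nested intercepts, the correlated taxon vectors, the covariates, and
NB2 counts from exactly the structure the model assumes. Defaults mirror
the study design: 89 fish across 4 regions and 28 sites (site occupancies
differing by at most one; the study's 26 sites cannot be allocated
symmetrically), 25 taxa, and sex-color cell probabilities proportional to
59 brown males, 4 blue males, 15 brown females, 11 blue females.

Parameter defaults the source material does not pin down were chosen once
as field-plausible values: lengths uniform on 45-100 cm (adult lingcod),
depths uniform on 7.6-72.2 m (the study's collection range), body mass from
the allometry $10^{-5} L^3$ kg with 10% log-normal scatter (Fulton's K
near $10^{-5}$ kg/cm$^3$), hepatosomatic ratio log-normal around 2%,
dispersion $\theta = 1$ (strong overdispersion, typical of
macroparasite counts), nested SDs $(0.3, 0.3, 0.5)$ and taxon SDs
$(1, 0.3, 0.3, 0.5)$ on the log scale. Fixed-effect defaults echo the
published coefficient table with an intercept set so that mean per-taxon
counts land near the study's reported detection totals.

Two allocation modes govern the sex-color cells. `"multinomial"` draws each
fish's cell independently — cell frequencies then fluctuate and converge to
the probabilities, which is what the generator's goodness-of-fit property
checks. `"proportional"` fixes the counts at the largest-remainder
apportionment (exactly 59/4/15/11 at 89 fish) and randomizes only the
assignment, i.e. it conditions on the realized study design. Parameter
recovery at study scale is evaluated under proportional allocation: with
only four expected blue males, unconditioned multinomial draws produce a
non-trivial fraction of datasets with 0-2 blue males in which the
interaction is essentially unidentified, and a recovery summary would then
measure identifiability failures of those draws rather than estimator
quality under the design the study actually had.

Random numbers are consumed through counter-based substreams (one for the
host table, one per taxon for its effects, one per taxon for its counts),
so enlarging `n_taxa` under a fixed seed never changes the host table.

What the generator does *not* emulate: spatial or depth gradients in
parasite exposure, taxon-specific aggregation differing from a common
$\theta$, within-fish correlation beyond the shared fish intercept, or any
transmission dynamics. Passing recovery tests therefore demonstrates the
estimator is correct under its assumed data-generating process — not that
the model is adequate for any particular field dataset.

## Constrained permutation tests

Because the study's interaction rests on very few blue males, significance
is re-assessed by constrained relabelling. Scheme 1 (`males_only`) assigns
exactly `n_blue_males` (default 4) males to blue uniformly at random,
leaving female colors untouched; scheme 2 (`both_sexes`) additionally
assigns exactly `n_blue_females` (default 11) females to blue. Each
replicate refits the full burden model and stores the interaction Wald z.

The reported `extreme_proportion` is the fraction of converged replicates
with $|z_{\text{rep}}| \ge |z_{\text{obs}}|$ — ties count as extreme, the
conservative two-sided convention, with z values agreeing to $10^{-4}$
treated as tied so that permutation-equivalent datasets whose refits differ
only by optimizer termination noise register as ties. The complementary
"observed strictly more extreme" proportion is reported alongside, since
published summaries are sometimes phrased in that direction. No $+1$
correction is applied by default (plain proportion over the replicates); a
corrected estimator is available by flag for users who need a guaranteed
positive p. Replicates whose refit fails to converge are excluded from the
denominator and counted in `n_failed`.

Per-replicate seeds are derived counter-style from `(seed,
replicate_index)`, so replicates are order-independent and reproducible
individually.

Calibration is checked by simulation: data from a null generator (no color
or interaction effect anywhere), observed colors themselves drawn by the
constrained mechanism so that observed and replicate statistics are
exchangeable by construction, 199 replicates per test. At a nominal 0.05
threshold the rejection rate across outer simulations must sit near 0.05.
The calibration runs at a reduced scale — 20 fish in 4 sites, 3 taxa,
fish-level nesting and the reduced (intercept, interaction) taxon
structure — chosen so several thousand model refits stay affordable; the
exactness property being tested does not depend on the data's size.

## PERMANOVA

Community composition is compared with a from-scratch permutational
MANOVA on Bray-Curtis dissimilarities
($\sum_i |u_i - v_i| / \sum_i (u_i + v_i)$ on raw counts; Jaccard on
presence/absence available as an alternative). Fish with all-zero parasite
vectors are excluded with a logged count — the distance is undefined for
them. Following the McArdle-Anderson direct decomposition, the
Gower-centered matrix $G = J(-\tfrac12 D^2)J$ is partitioned by sequential
(Type-I) projections in the stated term order — sex-color combination
first, then sampling location, then depth as a continuous 1-df term —
giving per-term sums of squares $\mathrm{tr}(\Delta H\, G)$, pseudo-F
against the residual mean square, and $R^2 = SS/SS_{\text{total}}$.
Significance uses free permutation of observation labels,
$p = (\#\{F^* \ge F\} + 1)/(B + 1)$ with the identity permutation
included. Degenerate partitions are reported, not hidden: zero residual df
or zero residual SS yield an undefined pseudo-F with a warning. The
implementation is verified against hand-computed closed forms, exhaustive
enumeration at $n = 6$, and vegan's `adonis2` on shared fixtures.

## Condition indices

Fulton's K is the bare ratio mass/length$^3$ (kg/cm$^3$) — no $\times 100$
or $\times 10^5$ display convention is applied by default, though a
multiplier argument exists. The hepatosomatic index is liver mass over body
mass, fourth-root transformed before modelling to improve normality. The
post-hoc models are Gaussian linear mixed models (ML, via lme4) with the
same fixed effects as the burden model and random intercepts for location
within region; Wald z and two-sided normal p are reported to mirror the
published table layout. Records whose K exceeds 10 times the median K are
flagged as mis-recorded masses and excluded with an audit log — the
flag-and-log design reflects that such exclusions must be visible, not
silent. Depth is assumed to be in meters throughout (collection depths
appear in both meters and feet in field descriptions; meters is the SI
choice and the one the depth range defaults use).

## Numerical edge cases

* `scale_plus_two()` refuses constant vectors (zero variance has no
  standardization).
* `nb_log_pmf(y, 0, theta)` is $0$ at $y = 0$ and $-\infty$ otherwise.
* A burden fit with every variance component constrained away reduces to a
  pooled NB regression; with counts (2, 4, 6) and nothing else, the
  intercept is $\log 4$ (the NB mean MLE is the sample mean for any fixed
  $\theta$).
* Adding a constant $c$ to the offset shifts the intercept by $-c$ and
  nothing else; the test suite asserts this contract.
* Exactly collinear fixed-effect columns give unbounded VIF, flagged but
  not fatal; the affected SEs are reported as NA.

## Problem sizes used by the shipped checks

The test suite exercises the chain at sizes chosen to keep a full run in
the tens of minutes on one core: 10 recovery datasets at full study scale
(89 fish, 25 taxa, reduced outer tolerance $10^{-5}$), 50 outer
calibration simulations with 199 permutation replicates each at the
reduced calibration scale above, 200 null fits for Wald-size checks, and
small exhaustively-enumerable PERMANOVA fixtures. These sizes are the
package's own trade-off between Monte-Carlo resolution and runtime; the
full-scale analogues (hundreds of recovery datasets or outer simulations)
tighten the Monte-Carlo bands without changing any of the logic.

## Known limitations

* Laplace (not quadrature) likelihood: for very small counts with large
  random-effect variances the approximation error is visible (order
  $10^{-3}$ relative on the shipped toy at extreme parameters); no AGQ
  fallback is provided for the full crossed model.
* Wald inference is anti-conservative in very small, very unbalanced
  designs (that is precisely why the permutation test exists; the Wald
  size check runs at a scale where the normal approximation is
  reasonable).
* The PERMANOVA permutes labels freely by default; a strata argument
  restricts permutation within groups, but no finer permutation designs
  (e.g. nested or sequential restrictions) are offered.
* No zero-inflated or hurdle variants, no spatial covariance, no model
  selection machinery — the package fits the one specified model family.
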