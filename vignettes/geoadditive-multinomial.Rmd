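---
title: "Bayesian geo-additive multinomial logit models for trichotomous nutritional status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian geo-additive multinomial logit models for trichotomous nutritional status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`geomultinom` fits structured additive (geo-additive) regression models for
a three-level nutritional outcome — underweight, normal, overweight/obese —
observed on women of reproductive age surveyed across administrative
divisions.  BMI (kg/m²) is classified with the WHO Asian-specific cutoffs
(underweight < 18.5, normal [18.5, 23), overweight [23, 27.5), obese
≥ 27.5), and the top two classes are merged for analysis.

With `normal` as the reference category, the outcome follows a multinomial
logit model: for non-reference categories $r = 1, \dots, K-1$ (here
$K = 3$),

$$P[y_i = r] = \frac{\exp(\eta_{i,r})}{1 + \sum_{s=1}^{K-1}\exp(\eta_{i,s})}.$$

Six nested predictor specifications are supported, combining four building
blocks — dummy-coded linear effects $u_i'\beta_r$ of the categorical
covariates (always included, with a per-category intercept), a smooth
nonlinear age effect $f_r(z_i)$, and structured/unstructured spatial
effects $g_r(S_i)$, $h_r(S_i)$ of the division $S_i$:

| variant | $f_r(\text{age})$ | $g_r(S)$ | $h_r(S)$ |
|---|---|---|---|
| M1 | – | – | – |
| M2 | yes | – | – |
| M3 | – | yes | yes |
| M4 | yes | yes | – |
| M5 | yes | – | yes |
| M6 | yes | yes | yes |

Priors follow the standard Bayesian structured-additive-regression setup:

* **Linear effects** get improper diffuse priors,
  $P(\beta_r) \propto \text{const}$.  This requires (and the package
  enforces) a full-column-rank design.
* **The smooth age effect** is a Bayesian P-spline: $f_r$ is expanded in
  $J = m + l$ B-spline basis functions on $m + 1$ equidistant knots
  (defaults: 20 knots spanning [15, 49] and degree $l = 3$, so $m = 19$
  and $J = 22$) whose coefficients $\vartheta_j$ carry a second-order
  random-walk prior
  $\vartheta_j = 2\vartheta_{j-1} - \vartheta_{j-2} + e_j$,
  $e_j \sim N(0, \sigma_e^2)$.  The implied prior precision is
  $K/\sigma_e^2$ with $K$ the second-difference penalty matrix (rank
  $J-2$; constants and linear trends are unpenalised).
* **Structured spatial effects** carry an intrinsic Gaussian Markov
  random field prior over the division adjacency graph: given all other
  divisions, $g(S_k)$ is normal with mean the average of its neighbours
  and variance $\delta/|N(k)|$.  The precision matrix is the ICAR matrix
  $Q$ with $Q_{kk} = |N(k)|/\delta$ and $Q_{kl} = -1/\delta$ for
  neighbours ($Q\mathbf{1} = 0$).
* **Unstructured spatial effects** are iid $N(0, \tau^2)$ per division.
* **All variance parameters** ($\sigma_e^2$, $\delta$, $\tau^2$) carry
  inverse-gamma(0.001, 0.001) hyperpriors.

A note on the "20 equidistant knots": the knot count fixes the basis
dimension only up to a convention, because the relation between the
number of knots and the number of interior intervals is not standardised
across software.  The package reads it as 20 knots spanning the age
range (19 intervals, $J = 22$ at degree 3), the common
structured-additive-regression convention; both `n_knots` and `degree`
are arguments, and none of the package's checks depend on the particular
$J$.

## Posterior computation

Inference is by Gibbs sampling with category-wise Pólya-Gamma data
augmentation.  Holding the other non-reference category's predictor
fixed, the conditional likelihood of category $r$ is binary-logistic with
a known offset $C_i = \log(1 + e^{\eta_{i,-r}})$; augmenting each record
with $\omega_i \sim \text{PG}(1, \eta_{i,r} - C_i)$ makes every
coefficient block conditionally Gaussian, so all updates are exact draws
(no tuning, no rejections):

1. per category: draw the PG variables given the current predictor;
2. draw each enabled block (linear, spline, structured, unstructured)
   from its Gaussian full conditional, with prior precision $0$,
   $K/\sigma_e^2$, $Q/\delta$, $I/\tau^2$ respectively;
3. re-centre the smooth and spatial blocks to mean zero, absorbing the
   mean into the per-category intercept (the usual sum-to-zero
   identification — without it the intercept, $f_r$, $g_r$ and $h_r$ are
   only jointly identified);
4. draw each variance from its conjugate inverse-gamma conditional, with
   effective dimension equal to the rank of its prior precision
   ($J-2$ for the spline, $R-1$ for a connected division graph, $R$ for
   the unstructured block).

The PG(1, z) sampler is the exact alternating-series rejection scheme
(Devroye-type), driven by R's RNG so that a single `seed` makes whole
chains byte-reproducible.  An independence Metropolis–Hastings backend
with IWLS proposals (`augmentation = "iwls_mh"`, pure R) implements the
same block structure; the historical software for such models uses IWLS
proposals, and the two backends agreeing in distribution is itself one of
the package's tests.

Initialisation is all-zero coefficients with variances at 0.1; the
posterior for these models is well-behaved enough that burn-in handles
the rest.  Chain defaults are 35,000 iterations, 5,000 burn-in, thinning
10 (3,000 retained draws).  The simulation studies in the test-suite and
the analysis scripts use shortened chains (typically 7,000/2,000/5 or
3,000/800/4) — chosen as the package's own working scale after checking
that DIC rankings and interval summaries are stable there.

Numerical safeguards worth knowing about: multinomial probabilities are
computed with a max-shift stabiliser so extreme predictors cannot
overflow; ages outside the training knot range abort a fit (they would
silently distort the penalty) but may be clamped for prediction; a
division absent from the graph, a rank-deficient design, or a
single-region graph with a structured term are all refused at validation
rather than mid-chain.

## Model choice and summaries

Models are compared by the deviance information criterion
$\text{DIC} = \bar D + p_D$, where $\bar D$ is the posterior mean of the
deviance ($-2 \times$ multinomial log-likelihood) over retained draws and
$p_D = \bar D - D(\bar\theta)$ is Spiegelhalter's effective number of
parameters, evaluated at the posterior means of all blocks.  Differences
of at most 5 DIC units are flagged as "similar" fits.  Effect summaries
report posterior means with central 95% credible intervals (empirical
type-7 quantiles, not normal approximations); an effect is called
significant when zero lies outside its interval.  (The published table
footnote states the opposite convention — significance when zero *is*
included — which contradicts every starred estimate in the same table;
the package deliberately implements the standard reading.)

Spatial summaries are exported as per-region tables (mean, interval, and
a three-class significance code) keyed by region label, ready to join to
any boundary file; the package deliberately does not render choropleths.
Nonlinear summaries are exported as pointwise mean-and-band curves over
an age grid.

## The synthetic-data generator

Because the underlying microdata are gated, the package ships a
generator that emulates the survey rounds: categorical covariates drawn
independently from the published frequency-table marginals of either
round, age continuous-uniform on [15, 49] (the marginal age distribution
is not published; uniform maximises coverage of the spline domain, and
only the conditional model matters for recovery tests), divisions uniform
over a preset graph (7 divisions for the 2014 round, 8 for 2017–18 —
approximate shared-boundary adjacencies, since the true analysis
adjacency is not published), and outcomes drawn from the full
geo-additive predictor with known effects.  Default ground truth: linear
coefficients echoing the published 2017–18 posterior means (e.g. 0.64
for `wealth=richest` on the overweight/obese log-odds), centred
sinusoidal age effects (a half-period cosine for underweight, declining
with age; a full-period sine for overweight/obese), and structured
spatial effects drawn once from the GMRF prior with $\delta = 0.15$ (the
realised values are recorded so recovery can be scored).  A BMI value is
drawn uniformly within the band of the realised category so the
classification path can be exercised end to end.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real survey data: two-stage cluster sampling,
stratification and sampling weights (the model itself ignores them too),
covariate dependence (covariates are independent by default; a
`covariate_sampler` hook accepts a user-supplied joint sampler), item
nonresponse patterns, and measurement error in height/weight.

## Descriptive statistics

`descriptive_table()` reproduces the survey-report style: per-level
counts, column percentages (half-up rounding at 2 decimals, the
convention of such reports), and a p-value for the change in each
level's share between rounds.  The "t-test for proportion" of the
source reports is implemented as the pooled two-sample z-test for
proportions; at these sample sizes the z and t references are
numerically indistinguishable, and the recomputed p-values match the
published ones (e.g. 0.041 for the poorest wealth quintile's change).
The inclusion filter drops flagged records (pregnancy, birth within two
months) and then applies listwise deletion over the modelled covariates,
logging each dropped record once under the first applicable reason in a
fixed, documented priority order.

## Design decisions that were genuinely open

* **BMI boundary convention.**  Verbal class definitions ("18.5 to 23.0")
  leave the boundaries ambiguous; intervals are implemented left-closed /
  right-open with the cutoffs exposed as an argument.
* **Category update order.**  Nothing in the model fixes whether
  underweight or overweight/obese is updated first; the order is a
  config field and a test checks the inference is indifferent to it.
* **$p_D$ definition.**  "Effective number of parameters" is computed as
  $\bar D - D(\bar\theta)$ with $\bar\theta$ the posterior means of all
  blocks — the original Spiegelhalter proposal, and consistent with the
  published table's internal arithmetic ($\bar D + p_D$ reproduces every
  printed DIC).
* **Centring weights.**  The spline block is centred by the mean of the
  *fitted* curve over the observed records (design-weighted), spatial
  blocks by the unweighted region mean; both leave the predictor
  unchanged to machine precision.
* **Intercept comparability.**  Because centring constants flow into the
  intercept, generative and fitted intercepts are not directly
  comparable; recovery checks therefore score all coefficients except
  the intercept, plus the shapes of the smooth and spatial surfaces.

## Known limitations

* The division adjacencies are plausible approximations for testing, not
  surveyed boundary files.
* DIC is the only model-choice criterion offered (no WAIC/LOO), matching
  the analysis the package reproduces.
* The improper prior on $\beta$ assumes the full-rank check is enough;
  heavily unbalanced covariates with near-empty cells will still mix
  slowly.
* Survey design (weights, clustering) is out of scope throughout.

## A minimal session

```{r, eval = FALSE}
library(geomultinom)

g <- make_region_graph("bdhs2018")
truth <- draw_spatial_truth(g, delta = 0.15, seed = 1)
cfg <- generator_config(4000,
                        true_smooth_functions = default_true_smooth_functions(),
                        true_spatial_structured = truth$structured,
                        seed = 2)
d <- simulate_dataset(cfg)

fits <- lapply(c("M1", "M2", "M4"), function(v)
  run_mcmc(d, v, mcmc_config(3000, 800, 4, seed = 3), graph = g))
compare_models(lapply(fits, compute_dic), reference = "M4")

fit4 <- fits[[3]]
head(summarize_effects(fit4))
export_spatial_effects(fit4)
head(export_nonlinear_effect(fit4, seq(16, 48, by = 1)))
```
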