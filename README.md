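# geomultinom

Bayesian geo-additive multinomial logit regression for the trichotomous
nutritional status (underweight / normal / overweight–obese) of
reproductive-age women, as used in spatial-epidemiological analyses of
Demographic and Health Survey rounds.

## The problem and the model

Surveys of women aged 15–49 record BMI, socio-demographic covariates and
the administrative division of residence.  BMI is classified with the WHO
Asian-specific cutoffs (underweight < 18.5, normal [18.5, 23), overweight
[23, 27.5), obese ≥ 27.5 kg/m²; the top two classes are merged), and the
three-level outcome is modelled with a multinomial logit, reference
category `normal`:

    P[y_i = r] = exp(η_ir) / (1 + Σ_s exp(η_is)),   r = 1, …, K−1.

Six nested predictors M1–M6 combine four blocks:

    M6:  η_ir = u_i' β_r + f_r(age_i) + g_r(S_i) + h_r(S_i)

with diffuse-prior linear effects β_r of the dummy-coded covariates, a
Bayesian P-spline f_r (cubic B-splines on 20 equidistant knots with a
second-order random-walk prior), an intrinsic GMRF (ICAR) structured
spatial effect g_r over the division adjacency graph, and iid unstructured
division effects h_r.  All variances carry inverse-gamma(0.001, 0.001)
hyperpriors.  Inference is category-wise Pólya-Gamma Gibbs sampling
(compiled; an IWLS Metropolis–Hastings backend is available as a
cross-check), and models are compared by DIC = D̄ + p_D, with differences
≤ 5 treated as equivalent.  Because the underlying survey microdata are
gated, the package includes a synthetic generator that draws DHS-like
records from this very model with known ground truth (covariate marginals
seeded from the published frequency tables of the 2014 and 2017–18
Bangladesh rounds, 7- and 8-division graphs).

See `vignettes/geoadditive-multinomial.Rmd` for the full model account
and design decisions.

## Worked example

Simulate a survey round with known effects, fit three specifications,
and compare them:

```r
library(geomultinom)

g <- make_region_graph("bdhs2018")               # 8 divisions
truth <- draw_spatial_truth(g, delta = 0.15, seed = 1)
cfg <- generator_config(4000,
                        true_smooth_functions = default_true_smooth_functions(),
                        true_spatial_structured = truth$structured,
                        seed = 4)
d <- simulate_dataset(cfg)

fits <- lapply(c("M1", "M2", "M4"), function(v)
  run_mcmc(d, v, mcmc_config(3000, 800, 4, seed = 3), graph = g))
compare_models(lapply(fits, compute_dic), reference = "M4")
```

```
  model mean_deviance       pD      dic dic_diff similar
1    M1      6835.186 34.46241 6869.648 218.7673   FALSE
2    M2      6710.266 43.30182 6753.568 102.6871   FALSE
3    M4      6598.345 52.53630 6650.881   0.0000    TRUE
```

The spatial model M4 wins by a wide DIC margin (these data contain real
smooth and spatial signal), and `similar` flags the models within 5 DIC
of the best.  `p_D` sits near the count of effectively free parameters
(M1 has 34 free coefficients; the penalised smooth and spatial blocks of
M4 add ~18 effective ones).  Posterior summaries recover the generative
coefficients — e.g. the `wealth=richest` effects, simulated at −0.454 on
the underweight and 0.64 on the overweight/obese log-odds:

```r
s <- summarize_effects(fits[[3]])
s[s$parameter == "wealth=richest", ]
```

```
    block         category      parameter       mean      lower      upper
7  linear      underweight wealth=richest -0.4734255 -0.8812817 0.01284975
26 linear overweight_obese wealth=richest  0.4799348  0.2469209 0.73193189
   significant
7        FALSE
26        TRUE
```

Both 95% intervals cover their generative values (single intervals miss
at the nominal ~5% rate; `analysis/05_recovery_check.R` scores coverage
over replicates).

`export_spatial_effects()` and `export_nonlinear_effect()` return the
per-division posterior surface (with a positive/none/negative
credible-interval code) and the fitted age curve with its 95% band.

## The analysis workflow

The `analysis/` scripts run the full study end to end on synthetic
rounds, writing CSV outputs under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | builds 2014-like (7 divisions) and 2017–18-like (8 divisions) synthetic rounds with recorded ground truth |
| `02_describe.R` | descriptive tables with two-proportion tests, plus a re-derivation of the published frequency table from its printed counts |
| `03_fit_models.R` | fits M1–M6 per round, exports DIC rows, effect summaries, spatial and age-curve estimates |
| `04_compare_models.R` | DIC comparison tables with differences against M6 and the ≤ 5-DIC similarity rule |
| `05_recovery_check.R` | replicate study: credible-interval coverage and shape recovery of the known truth |

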