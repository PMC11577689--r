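# jmblock

Blockwise Bayesian inference for joint models of a longitudinal biomarker
and a unidirectional multistate event process.

## The problem

In many clinical settings a repeatedly measured biomarker (blood pressure,
PSA, cognitive scores, ...) co-evolves with a patient's progression through
discrete health states — disease onsets, comorbidity combinations, death.
Joint models link the two: a Gaussian linear mixed model for the biomarker
trajectory,

    y_ij | b_i ~ N( mu_i(t_ij), sigma_e^2 ),    mu_i(t) = X_i(t)'beta + Z_i(t)'b_i,

and cause-specific transition intensities for every permitted transition
j -> k of an acyclic state graph,

    h_jk(t) = h0_jk(B(t)) exp( w_i' gamma_jk + f(beta, b_i, t, alpha_jk) ),

sharing the random effects b_i through an association structure f (current
value alpha*mu_i(t), current slope, shared random effects, quadratic or
covariate-interacted current value). Baselines are Weibull or log-B-spline,
on a clock-forward (Markov) or clock-reset (semi-Markov) timescale;
cumulative intensities are computed by 15-node Gauss-Legendre quadrature.

Sampling the full joint posterior (**JM-MSM**) is expensive for large
cohorts and complex graphs. Because the process is unidirectional, the event
likelihood factorizes exactly over the graph, which licenses two blockwise
strategies that fit smaller independent posteriors in parallel:

* **JM-CR** — one joint longitudinal-competing-risk model per block of
  transitions out of a single state;
* **JM-ST** — one joint longitudinal-survival model per transition, with
  competing events censored.

Blockwise fits condition on either all longitudinal data up to block exit
(*historical*) or only the measurements taken inside the block
(*concurrent*, with historical fallback), and candidate models are compared
per block with PSIS-LOO where the leave-out unit is the subject's joint
(longitudinal, event) data. A simulator generates datasets from the model's
own generative process by inverting cumulative intensities, with presets for
a realistic eight-transition multimorbidity-style design and a
ten-transition nonlinear-trajectory design.

The package is aimed at biostatisticians modelling disease progression with
endogenous longitudinal covariates — e.g. electronic-health-records cohorts
— who need the full joint model's structure at tractable cost.

## Worked example

Simulate a 300-subject dataset from the realistic preset (five states, eight
transitions, clock-reset Weibull baselines, current-value association,
biomarker visits that tighten after each transition), then fit the 0 -> 1
transition with the single-transition strategy:

```r
library(jmblock)

cfg <- model1_preset(n = 300, seed = 42)
dat <- simulate_joint_data(cfg)
dat
#> Joint dataset: 300 subjects, 1486 measurements, 581 observed transitions
#> Transition graph: 5 states, 8 permitted transitions
#>   states: 0 1 2 3 4
#>   transitions: 0->1, 0->2, 0->4, 1->3, 1->4, 2->3, 2->4, 3->4
#>   absorbing: 4

tmpl <- model_template(dat$graph, basis = "intercept_slope",
                       timescale = "clock_reset", baseline_family = "weibull",
                       association_kind = "current_value", n_covariates = 1)
ctl <- sampler_config(n_draws = 500, burn_in = 1000, seed = 1)

fit <- fit_jm_st(dat, tmpl, prior_spec(),
                 longitudinal_strategy("historical"), ctl)[["0->1"]]
summary(fit)
#>      parameter   mean     sd   q2.5  q97.5 rhat
#> 1        beta1  0.559 0.0316  0.502  0.610  1.1
#> 2        beta2  0.074 0.0065  0.063  0.086  1.2
#> 3     sigma_e2  0.167 0.0124  0.147  0.196  1.0
#> 4        sd_b1  0.544 0.0293  0.496  0.607  1.0
#> 5        sd_b2  0.099 0.0075  0.086  0.114  1.0
#> 6      rho_b12 -0.342 0.0772 -0.472 -0.165  1.5
#> 7   0->1.shape  1.288 0.0670  1.147  1.412  1.0
#> 8   0->1.scale  0.046 0.0088  0.029  0.066  1.0
#> 9  0->1.gamma1  0.366 0.0948  0.205  0.599  1.1
#> 10 0->1.alpha1  0.256 0.1355 -0.036  0.499  1.1
```

The rows are the longitudinal fixed effects (generating values 0.50 and
0.08), residual variance (0.16), random-effect standard deviations (0.50,
0.10) and correlation (-0.20), then the 0 -> 1 transition's Weibull shape
(1.2) and scale (0.045), the age log-hazard ratio gamma (0.30) and the
current-value association alpha (0.50): each posterior mean sits within
roughly two posterior standard deviations of its generating value at this
sample size, and `rhat` is the split-chain convergence diagnostic.

Comparing the two longitudinal-conditioning strategies for the same
transition by subject-level PSIS-LOO:

```r
fit_c <- fit_jm_st(dat, tmpl, prior_spec(),
                   longitudinal_strategy("concurrent"), ctl)[["0->1"]]
compare_models(list(concurrent = psis_loo(fit_c$pointwise),
                    historical = psis_loo(fit$pointwise)))
#>        model elpd_loo    se elpd_diff se_diff
#> 1 concurrent   -925.2 33.27      0.00    0.00
#> 2 historical   -930.4 34.52     -5.19   12.94
```

Here the concurrent fit is ranked first but the difference (-5.19, SE 12.9)
is not decisive — the expected behaviour when the trajectory model is
correctly specified, so the extra historical data carry no misspecification
penalty.

A YAML-driven command-line wrapper for `simulate` / `fit` / `loo` runs is
installed at `system.file("cli", "jmblock.R", package = "jmblock")`.

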