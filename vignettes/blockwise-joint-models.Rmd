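---
title: "Blockwise Bayesian inference for joint longitudinal-multistate models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blockwise Bayesian inference for joint longitudinal-multistate models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jmblock)
```

## The model

`jmblock` couples two submodels through shared subject-level random effects.

**Longitudinal submodel.** A Gaussian linear mixed model for a repeatedly
measured biomarker: for subject $i$ at measurement time $t_{ij}$,

$$y_{ij} \mid b_i \sim N\!\big(\mu_i(t_{ij}),\ \sigma_e^2\big), \qquad
\mu_i(t) = X_i^\top(t)\,\beta + Z_i^\top(t)\,b_i, \qquad
b_i \sim N(0, \Sigma_b).$$

Two basis presets are built in: the random-intercept-and-slope model
($X(t) = Z(t) = (1, t)$) and a nonlinear-decay model with
$f_1(t) = (1+t)^{-1.2} - 1$ and $f_2(t) = t$, covariate-interacted fixed
effects and three random effects. Custom bases can be supplied through
`custom_long_basis()`.

**Multistate submodel.** Subjects move among states $0, \dots, N$ of a
*unidirectional* (acyclic) transition graph. Each permitted transition
$j \to k$ has a proportional transition intensity

$$h_{jk}(t) = h_{0,jk}\!\big(B(t)\big)\,
\exp\!\big(w_i^\top \gamma_{jk} + f(\beta, b_i, t, \alpha_{jk})\big),$$

where $B(t)$ is study time under a clock-forward (Markov) timescale or the
time since entry into state $j$ under clock-reset (semi-Markov); $h_{0,jk}$
is either a Weibull baseline $h_0(u) = \delta u^{\delta - 1} \lambda$ (note
the scale multiplies the whole hazard, so the cumulative baseline is
$\lambda u^\delta$; `weibull_to_standard()` converts to the textbook
parameterization) or a log-B-spline baseline
$h_0(t) = \exp\{\sum_l \eta_l B_l(t)\}$; and $f$ is the association
structure: the current value $\alpha\,\mu_i(t)$, current slope
$\alpha\,\mu_i'(t)$, shared random effects $\alpha^\top b_i$, a quadratic
current-value term $\alpha_1 \mu_i(t) + \alpha_2 \mu_i(t)^2$, or a
covariate-interacted current value
$\alpha_1 \mu_i(t) + \alpha_2\, w\, \mu_i(t)$.

The likelihood of an observed path multiplies, over sojourn intervals, the
intensity of each realized transition at its time and the survival terms
$\exp\{-\int h_{jk'}(u)\,du\}$ of every transition leaving the occupied
state. The integrals have no closed form once an association term is present
and are computed by Gauss-Legendre quadrature (15 nodes by default, mapped
affinely onto each sojourn interval).

## Three inference strategies

For a unidirectional process the event likelihood *factorizes exactly*: a
subject's full multistate contribution is the sum of their contributions to
the competing-risk blocks they enter, and each block contribution is the sum
of cause-specific single-transition (survival) contributions. This identity
— asserted to $10^{-10}$ in the test suite — underlies the blockwise
strategies:

* **JM-MSM** (`fit_jm_msm()`): the standard full joint posterior over all
  transition parameters, longitudinal parameters and all random effects,
  conditioned on the complete dataset.
* **JM-CR** (`fit_jm_cr()`): one independent posterior per competing-risk
  block (all transitions out of one state). Each block conditions on its
  risk set, its event view, and a block-specific subset of the longitudinal
  data. Blocks can be fitted in parallel.
* **JM-ST** (`fit_jm_st()`): one independent posterior per transition;
  within a block, competing events are treated as censoring. This is the
  cheapest strategy and the natural one when interest lies in the
  transition intensities rather than in subject-level trajectory recovery —
  each subject receives one set of longitudinal parameter and random-effect
  estimates *per transition*, so trajectories are not uniquely estimated.

**Longitudinal conditioning.** Blockwise fits assign measurements to blocks
by one of two strategies (`longitudinal_strategy()`): *historical* uses all
measurements taken up to the subject's exit from the block; *concurrent*
uses only measurements taken during the time spent in the block, falling
back to the historical set for subjects without an in-block measurement.
Concurrent conditioning lets each block adapt the trajectory model locally
(a bias-variance trade-off under trajectory misspecification); the two can
be compared per block with PSIS-LOO.

Boundary ownership: a measurement taken exactly at a transition time belongs
to the state being exited (intervals are $(\text{entry}, \text{exit}]$), so
every measurement sits in exactly one block. The trajectory's time covariate
is always *study* time; only baseline intensities use the reset clock
$B(t)$.

## Priors

Defaults follow a weakly informative scheme: $N(0, 100^2)$ on fixed,
covariate and association effects; $N(0, 10^2)$ on spline coefficients and
log proportionality constants; half-Cauchy(0, 1) on Weibull shape and scale;
inverse-gamma(0.01, 0.01) on $\sigma_e^2$; half-Cauchy(0, 2.5) on
random-effect standard deviations; LKJ(2) on the random-effect correlation
matrix. For two random effects an alternative Beta prior on the transformed
correlation, $(\rho + 1)/2 \sim \text{Beta}(a, a)$, is available via
`prior_spec(rho_beta = a)`. The LKJ term is implemented through the C-vine
partial-correlation construction (each partial correlation's transform
carries a matching Beta density), which yields exactly the LKJ law on the
correlation matrix for any dimension; the `log_prior()` helper reports the
LKJ density up to its normalizing constant, which cancels in every posterior
kernel.

## The sampling backend

The sampler is a pluggable contract; the package ships one backend, an
adaptive Metropolis-within-Gibbs sampler on the unconstrained scale
(log shape/scale, log variance, log random-effect sds, `atanh` partial
correlations). It exploits the factorization above for blocking:

* one multivariate random-walk block per transition (baseline parameters,
  $\gamma$, $\alpha$) — its conditional depends only on that transition's
  survival view, so the update is cheap even inside JM-MSM. Transitions
  with proportional baselines are grouped with their anchor, since they
  share spline coefficients;
* one block each for $\beta$ (longitudinal terms plus every
  trajectory-dependent view), $\log \sigma_e^2$ (longitudinal only) and the
  random-effect covariance (random-effect density only);
* all subjects' random effects are proposed jointly and accepted or
  rejected per subject, preconditioned by the current $\Sigma_b$.

Proposal scales adapt by Robbins-Monro toward standard acceptance targets
(0.234 for multivariate blocks, 0.44 for scalars, 0.30 for the
random-effect sweep) and block proposal covariances are estimated from the
adaptation history; all adaptation is frozen at the end of burn-in, so the
retained draws come from a fixed Markov kernel. Initialization is at zero on
the unconstrained scale by default (`init = "random"` gives overdispersed
starts). Design matrices, spline bases and quadrature nodes are precomputed
once per fit; cached likelihood terms are updated selectively, and the
cached evaluation is tested to agree with the reference likelihood functions
to machine precision.

A random-walk backend needs longer adaptation than a gradient-based sampler:
the preset burn-in default (300) matches the reduced-scale study conditions,
but the package's own checks use 1000-1500 adaptation iterations for
moderate problems, and split-$\hat R$ (computed per parameter on split
chains) should always be inspected. The backend has no divergent-transition
diagnostic; acceptance rates per block are reported instead. Each blockwise
fit derives its own seed from the master seed, making a block's draws
identical whether fitted alone or alongside other blocks.

## Model comparison

`psis_loo()` estimates the expected log pointwise predictive density where
the leave-out unit is the *subject*: $D_i$ couples the subject's
longitudinal record (block-restricted, for blockwise fits — consistent with
the block's conditioning data) with the subject's block event outcome.
Importance ratios are smoothed by fitting a generalized Pareto distribution
(Zhang-Stephens profile fit) to the largest $\min(0.2\,S,\ 3\sqrt S)$
ratios, replacing them with expected order statistics truncated at the raw
maximum; the tail shape $\hat k$ is reported per subject and values above
0.7 trigger a warning, not a failure. `compare_models()` ranks candidates
fitted to identical block data, with difference standard errors computed
from the pointwise contributions.

## The simulator

`simulate_joint_data()` draws from the model's own generative process:
random effects, a censoring time (uniform or fixed), then the multistate
path by iterated competing-risks simulation — for each permitted exit from
the current state a latent time solves $H_k(s, t) = -\log U$ by bracketed
root finding (tolerance $10^{-8}$ in time units) on the quadrature-based
cumulative intensity, the earliest latent time within the censoring horizon
wins — then a visit grid, then biomarker values $\mu_i(t) + N(0,
\sigma_e^2)$ noise.

Two presets encode the study conditions the package's checks use.
`model1_preset()`: the five-state, eight-transition progressive structure
with clock-reset Weibull baselines, current-value associations, an
intercept-slope trajectory, one standardized mixed-uniform "age" covariate
(components $(18,65)$, $(65,80)$, $(80,90)$ with weights $0.55/0.30/0.15$),
censoring $C \sim U(13, 24)$, and visit gaps $\Delta = (2.6, 2, 1.2)$ that
tighten after the first and second transitions — an electronic-health-records
style design where sicker patients are measured more often.
`model2_preset()`: the ten-transition extension with clock-forward
log-B-spline baselines for three anchor transitions out of the initial
state, the remaining baselines proportional to an anchor through a free log
rescale constant (default anchor map: by target state; configurable, since
the appropriate tying is application-specific), the nonlinear-decay
trajectory, $C \sim U(4, 24)$ and an equidistant visit gap of 1.

The generating parameter *values* of both presets are this package's own
documented defaults, chosen once so that every transition is observed with
adequate frequency at moderate sample sizes; the studies these presets
emulate calibrated their values on restricted clinical data and do not print
them, so the defaults here are synthetic and non-canonical. Visit grids
start with a baseline measurement at $t = 0$ (configurable via
`start_offset`), end at the earlier of censoring and absorption, and gap
epochs switch at observed transition times, reusing the final gap beyond the
listed epochs. Follow-up is normalized to end at absorption
(`subject_record()` truncates the censoring time there), which also makes
records round-trip exactly through the counting-process file format.

What the simulator does *not* emulate: informative (outcome-dependent) visit
processes, interval-censored transition times, measurement-error structure
beyond i.i.d. Gaussian noise, time-varying exogenous covariates, and
reversible transitions. Passing checks on simulated data therefore establish
internal consistency of estimation and selection under the model's own
assumptions, not robustness to these real-data features.

## Numerical choices

* Quadrature: one cached Gauss-Legendre rule (default $Q = 15$), affinely
  mapped per interval; exact for polynomial integrands up to degree
  $2Q - 1$ and agreeing with 61-node rules and adaptive integration to
  better than $10^{-8}$ relative on smooth intensities. A clock-reset
  Weibull baseline with non-integer shape has a derivative singularity at
  the state-entry point, where fixed-order quadrature is accurate only to
  about $10^{-5}$ relative; this is inherent to fixed-node rules, shared by
  the standard implementations of this model class, and immaterial at the
  likelihood's scale.
* A numerically zero intensity at an observed event time contributes
  $-\infty$ rather than raising an error, so samplers can reject the
  proposal.
* Latent event times whose cumulative intensity never reaches $-\log U$
  within the censoring horizon are censored by construction; no unbounded
  root search is attempted.
* Degenerate split-$\hat R$ (zero pooled variance) returns 1 by convention.

## Problem sizes used in the package's checks

The simulation studies shipped in the test suite and the acceptance script
are desk-scale reductions chosen as this package's own verification
conditions: parameter recovery and cross-strategy agreement use one
preset dataset of $n = 500$ subjects (800 retained draws after 1500
adaptation iterations); interval coverage uses 12-16 replicates of a
single-transition model at $n = 150$; association-structure selection uses
3 replicates at $n = 250$; simulator distributional checks use
$10^4$ latent paths. Larger designs sharpen all of these checks
proportionally and require nothing but larger `n` and `sampler_config()`
values.

## Known limitations

* Transition graphs must be acyclic; reversible or recurrent processes
  would give subjects multiple episodes per block and are not supported.
* Transition times are assumed exactly observed; interval censoring is out
  of scope.
* The longitudinal response is Gaussian; the basis/association machinery is
  an extension point for other response families but none are implemented.
* Blockwise fitting of proportional-baseline models requires the anchor
  transition inside the same fit; for JM-ST-style fits, give each
  transition a free baseline instead.
* The random-walk backend mixes more slowly than gradient-based samplers on
  strongly correlated posteriors (notably Weibull shape/scale with
  $\alpha$); inspect $\hat R$ and increase burn-in rather than trusting
  defaults on new problems.
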