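#' Model specification: trajectories, hazards, association structures, priors
#'
#' The longitudinal submodel is a Gaussian linear mixed model
#' `y_ij | b_i ~ N(mu_i(t_ij), sigma_e^2)` with
#' `mu_i(t) = X_i(t)' beta + Z_i(t)' b_i`. Each permitted transition `j -> k`
#' carries a proportional-intensity model
#' `h_jk(t) = h0_jk(B(t)) exp(w' gamma_jk + f(beta, b_i, t, alpha_jk))`
#' where `B(t)` is study time (clock-forward, Markov) or time since state
#' entry (clock-reset, semi-Markov), `h0` is a Weibull or log-B-spline
#' baseline, and `f` is the association structure linking the biomarker
#' trajectory to the transition intensity.
#'
#' @name model_spec
NULL

# ---------------------------------------------------------------------------
# Longitudinal bases

#' Longitudinal design bases
#'
#' A basis supplies the fixed-effects design `X(t, w)` (n x q1), the
#' random-effects design `Z(t)` (n x r) and their time derivatives, all
#' vectorized over `t`. `w` is the subject's covariate vector (may be unused).
#'
#' @param name preset name: `"intercept_slope"` (X = Z = (1, t), q1 = r = 2)
#'   or `"nonlinear_decay"` (the nonlinear trend
#'   `mu(t) = (b1-part) + (.) f1(t) + (.) t` with `f1(t) = (1+t)^-1.2 - 1`,
#'   fixed effects interacted with the first covariate: q1 = 6, r = 3).
#' @return A `long_basis` object with elements `q1`, `r`, `X`, `Z`, `dX`, `dZ`.
#' @export
long_basis <- function(name = c("intercept_slope", "nonlinear_decay")) {
  name <- match.arg(name)
  if (name == "intercept_slope") {
    b <- list(
      name = name, q1 = 2L, r = 2L,
      X = function(t, w = NULL) cbind(1, t),
      Z = function(t) cbind(1, t),
      dX = function(t, w = NULL) cbind(0 * t, 1 + 0 * t),
      dZ = function(t) cbind(0 * t, 1 + 0 * t)
    )
  } else {
    f1 <- function(t) (1 + t)^(-1.2) - 1
    df1 <- function(t) -1.2 * (1 + t)^(-2.2)
    b <- list(
      name = name, q1 = 6L, r = 3L,
      X = function(t, w) {
        w1 <- if (is.matrix(w)) w[, 1] else w[1]
        cbind(1, w1, f1(t), w1 * f1(t), t, w1 * t)
      },
      Z = function(t) cbind(1, f1(t), t),
      dX = function(t, w) {
        w1 <- if (is.matrix(w)) w[, 1] else w[1]
        z <- 0 * t
        cbind(z, z, df1(t), w1 * df1(t), 1 + z, w1 + z)
      },
      dZ = function(t) cbind(0 * t, -1.2 * (1 + t)^(-2.2), 1 + 0 * t)
    )
  }
  structure(b, class = "long_basis")
}

#' Custom longitudinal basis
#'
#' @param X,Z,dX,dZ vectorized design functions; `X(t, w)` and `dX(t, w)`
#'   return n x q1 matrices, `Z(t)` and `dZ(t)` return n x r matrices.
#' @param q1,r dimensions of the fixed and random designs.
#' @return A `long_basis` object.
#' @export
custom_long_basis <- function(X, Z, dX, dZ, q1, r) {
  structure(
    list(name = "custom", q1 = as.integer(q1), r = as.integer(r),
         X = X, Z = Z, dX = dX, dZ = dZ),
    class = "long_basis"
  )
}

#' Longitudinal submodel
#'
#' @param basis a [long_basis()].
#' @param beta fixed-effects vector (length `basis$q1`).
#' @param sigma_e2 residual variance (> 0).
#' @param Sigma_b r x r random-effects covariance (symmetric positive
#'   definite).
#' @return A `long_model` object.
#' @export
long_model <- function(basis, beta, sigma_e2, Sigma_b) {
  stopifnot(inherits(basis, "long_basis"))
  beta <- as.numeric(beta)
  if (length(beta) != basis$q1) stop("beta must have length q1 = ", basis$q1, call. = FALSE)
  Sigma_b <- as.matrix(Sigma_b)
  if (!isTRUE(all.equal(Sigma_b, t(Sigma_b))) ||
      any(eigen(Sigma_b, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("Sigma_b must be symmetric positive definite", call. = FALSE)
  }
  if (sigma_e2 <= 0) stop("sigma_e2 must be positive", call. = FALSE)
  structure(
    list(basis = basis, beta = beta, sigma_e2 = sigma_e2, Sigma_b = Sigma_b),
    class = "long_model"
  )
}

#' Subject-specific biomarker mean and slope
#'
#' `mu(t) = X(t, w)' beta + Z(t)' b`; `dmu_dt` is its time derivative
#' (current-slope association input).
#'
#' @param t time(s), vectorized.
#' @param w subject covariate vector (passed to the basis; may be unused).
#' @param long_model a [long_model()], or any list with `basis` and `beta`.
#' @param b random-effects vector (length r).
#' @param beta optional override of the model's fixed effects.
#' @return Numeric vector of trajectory means (or slopes) at `t`.
#' @export
mu <- function(t, w, long_model, b, beta = long_model$beta) {
  bs <- long_model$basis
  drop(bs$X(t, w) %*% beta + bs$Z(t) %*% b)
}

#' @rdname mu
#' @export
dmu_dt <- function(t, w, long_model, b, beta = long_model$beta) {
  bs <- long_model$basis
  drop(bs$dX(t, w) %*% beta + bs$dZ(t) %*% b)
}

# ---------------------------------------------------------------------------
# Baseline hazards

#' Weibull baseline intensity
#'
#' Parameterized as `h0(u) = shape * u^(shape - 1) * scale`, i.e. the scale
#' multiplies the whole hazard (so the cumulative baseline is
#' `scale * u^shape`). Note this differs from the textbook
#' `shape/scale * (u/scale)^(shape-1)` form; use
#' [weibull_to_standard()] to convert.
#'
#' @param shape,scale strictly positive parameters.
#' @return A `baseline_hazard` object of family `"weibull"`.
#' @export
weibull_baseline <- function(shape, scale) {
  if (shape <= 0 || scale <= 0) stop("Weibull shape and scale must be positive", call. = FALSE)
  structure(list(family = "weibull", shape = shape, scale = scale),
            class = "baseline_hazard")
}

#' Convert the multiplicative-scale Weibull parameterization to the standard
#' `dweibull` one
#'
#' The baseline `h0(u) = shape * u^(shape-1) * scale` equals a standard
#' Weibull hazard with the same shape and `scale_std = scale^(-1/shape)`.
#'
#' @param shape,scale parameters of [weibull_baseline()].
#' @return List with `shape` and `scale` on the `stats::dweibull` scale.
#' @export
weibull_to_standard <- function(shape, scale) {
  list(shape = shape, scale = scale^(-1 / shape))
}

#' Log-B-spline baseline intensity
#'
#' `h0(t) = exp(sum_l eta_l B_l(t))` with cubic B-spline bases `B_l`. The
#' default knot layout is one interior knot with boundary knots covering the
#' observation window, giving `L = 5` coefficients at degree 3.
#'
#' @param eta spline coefficients (length `L`).
#' @param boundary_knots length-2 numeric, the boundary knots.
#' @param interior_knots numeric vector of interior knots (default: midpoint
#'   of the boundary; in model fitting the median observed transition time is
#'   used).
#' @param degree spline degree (default 3, cubic).
#' @return A `baseline_hazard` object of family `"bspline"`.
#' @export
bspline_baseline <- function(eta, boundary_knots, interior_knots = NULL,
                             degree = 3) {
  if (is.null(interior_knots)) interior_knots <- mean(boundary_knots)
  L <- length(interior_knots) + degree + 1
  if (length(eta) != L) {
    stop("eta must have length ", L, " for this knot layout", call. = FALSE)
  }
  structure(
    list(
      family = "bspline", eta = as.numeric(eta),
      boundary_knots = as.numeric(boundary_knots),
      interior_knots = as.numeric(interior_knots), degree = degree
    ),
    class = "baseline_hazard"
  )
}

#' Proportional baseline referencing an anchor transition
#'
#' The baseline is the anchor transition's baseline multiplied by
#' `exp(log_rescale)`; used for transition sets whose baselines are specified
#' proportional to a small number of anchor transitions.
#'
#' @param anchor transition id string `"j->k"` of the anchor.
#' @param log_rescale log proportionality constant.
#' @return A `baseline_hazard` object of family `"proportional"`.
#' @export
proportional_baseline <- function(anchor, log_rescale = 0) {
  structure(list(family = "proportional", anchor = anchor,
                 log_rescale = log_rescale),
            class = "baseline_hazard")
}

# log h0 evaluated at baseline-time u (vectorized). `resolve` maps anchor ids
# to concrete baselines (for proportional families).
log_h0 <- function(baseline, u, resolve = NULL) {
  switch(baseline$family,
    weibull = {
      # shape * u^(shape-1) * scale; at u = 0 with shape > 1 hazard is 0
      log(baseline$shape) + (baseline$shape - 1) * log(u) + log(baseline$scale)
    },
    bspline = {
      B <- splines::splineDesign(
        knots = c(
          rep(baseline$boundary_knots[1], baseline$degree + 1),
          baseline$interior_knots,
          rep(baseline$boundary_knots[2], baseline$degree + 1)
        ),
        x = pmin(pmax(u, baseline$boundary_knots[1]), baseline$boundary_knots[2]),
        ord = baseline$degree + 1
      )
      drop(B %*% baseline$eta)
    },
    proportional = {
      if (is.null(resolve)) stop("proportional baseline needs its anchor resolved", call. = FALSE)
      log_h0(resolve(baseline$anchor), u) + baseline$log_rescale
    },
    stop("unknown baseline family ", baseline$family, call. = FALSE)
  )
}

# ---------------------------------------------------------------------------
# Association structures

#' Association structure between trajectory and transition intensity
#'
#' Kinds: `none` (no link), `current_value` (`alpha * mu(t)`),
#' `current_slope` (`alpha * mu'(t)`), `shared_random_effects`
#' (`alpha' b`), `current_value_quadratic`
#' (`alpha1 * mu(t) + alpha2 * mu(t)^2`), and `current_value_by_covariate`
#' (`alpha1 * mu(t) + alpha2 * (w_cov * mu(t))`, an interaction with a
#' designated covariate such as age at entry to the current state).
#'
#' @param kind association kind (see above).
#' @param alpha parameter(s); scalar for value/slope kinds, length 2 for the
#'   quadratic and covariate-interaction kinds, length r for shared random
#'   effects, length 0 for `none`.
#' @param covariate for `current_value_by_covariate`: name or index of the
#'   interacting covariate (default 1, the first covariate).
#' @return An `association` object.
#' @export
association <- function(kind = c("none", "current_value", "current_slope",
                                 "shared_random_effects",
                                 "current_value_quadratic",
                                 "current_value_by_covariate"),
                        alpha = numeric(0), covariate = 1L) {
  kind <- match.arg(kind)
  alpha <- as.numeric(alpha)
  arity <- switch(kind,
    none = 0L, current_value = 1L, current_slope = 1L,
    shared_random_effects = NA_integer_,
    current_value_quadratic = 2L, current_value_by_covariate = 2L
  )
  if (!is.na(arity) && length(alpha) != arity) {
    stop("association kind '", kind, "' needs ", arity, " parameter(s)", call. = FALSE)
  }
  structure(list(kind = kind, alpha = alpha, covariate = covariate),
            class = "association")
}

n_alpha <- function(assoc, r) {
  switch(assoc$kind,
    none = 0L, current_value = 1L, current_slope = 1L,
    shared_random_effects = as.integer(r),
    current_value_quadratic = 2L, current_value_by_covariate = 2L
  )
}

# association term f(beta, b, t, alpha); mu_t / dmu_t precomputed values at
# the evaluation times, wcov the interacting covariate values (same length)
assoc_term <- function(assoc, mu_t, dmu_t = NULL, b = NULL, wcov = NULL) {
  a <- assoc$alpha
  switch(assoc$kind,
    none = 0,
    current_value = a * mu_t,
    current_slope = a * dmu_t,
    shared_random_effects = if (is.matrix(b)) drop(b %*% a) else sum(a * b),
    current_value_quadratic = a[1] * mu_t + a[2] * mu_t^2,
    current_value_by_covariate = a[1] * mu_t + a[2] * (wcov * mu_t)
  )
}

# ---------------------------------------------------------------------------
# Transition models

#' Per-transition intensity model
#'
#' @param from,to the transition `j -> k`.
#' @param baseline a `baseline_hazard`.
#' @param timescale `"clock_reset"` (semi-Markov: baseline evaluated at time
#'   since state entry) or `"clock_forward"` (Markov: study time).
#' @param gamma covariate log-hazard-ratio vector (length = number of
#'   baseline covariates; may be length 0).
#' @param assoc an [association()].
#' @return A `transition_model` object.
#' @export
transition_model <- function(from, to, baseline,
                             timescale = c("clock_reset", "clock_forward"),
                             gamma = numeric(0),
                             assoc = association("current_value", 0)) {
  timescale <- match.arg(timescale)
  stopifnot(inherits(baseline, "baseline_hazard"), inherits(assoc, "association"))
  structure(
    list(
      from = as.integer(from), to = as.integer(to), baseline = baseline,
      timescale = timescale, gamma = as.numeric(gamma), assoc = assoc
    ),
    class = "transition_model"
  )
}

#' Transition intensity at a time point
#'
#' Evaluates `h_jk(t) = h0(B(t)) exp(w' gamma + f(...))` where
#' `B(t) = t - state_entry_time` under clock-reset and `B(t) = t` under
#' clock-forward.
#'
#' @param t study time(s) (vectorized), each `>= state_entry_time`.
#' @param state_entry_time time the subject entered the transition's source
#'   state.
#' @param w subject covariate vector.
#' @param trans_model a [transition_model()].
#' @param long_model a [long_model()].
#' @param b subject random effects.
#' @param resolve anchor resolver for proportional baselines.
#' @return Nonnegative intensity value(s).
#' @export
hazard <- function(t, state_entry_time, w, trans_model, long_model, b,
                   resolve = NULL) {
  if (any(t < state_entry_time)) {
    stop("hazard evaluated before state entry", call. = FALSE)
  }
  u <- if (trans_model$timescale == "clock_reset") t - state_entry_time else t
  lh0 <- log_h0(trans_model$baseline, u, resolve)
  lin <- if (length(trans_model$gamma) > 0) sum(w * trans_model$gamma) else 0
  assoc <- trans_model$assoc
  mu_t <- if (assoc$kind %in% c("current_value", "current_value_quadratic",
                                "current_value_by_covariate")) {
    mu(t, w, long_model, b)
  } else NULL
  dmu_t <- if (assoc$kind == "current_slope") dmu_dt(t, w, long_model, b) else NULL
  wcov <- if (assoc$kind == "current_value_by_covariate") w[[assoc$covariate]] else NULL
  exp(lh0 + lin + assoc_term(assoc, mu_t, dmu_t, b, wcov))
}

# ---------------------------------------------------------------------------
# Full joint model specification

#' Joint model specification
#'
#' Couples a longitudinal submodel with one transition model per permitted
#' transition of a graph.
#'
#' @param graph a `transition_graph`.
#' @param long a [long_model()].
#' @param trans named list of [transition_model()]s, names `"j->k"` covering
#'   exactly the graph's transitions.
#' @return A `joint_model_spec` object.
#' @export
joint_model_spec <- function(graph, long, trans) {
  stopifnot(inherits(graph, "transition_graph"), inherits(long, "long_model"))
  want <- transition_id(graph$transitions[, 1], graph$transitions[, 2])
  if (!setequal(names(trans), want)) {
    stop("`trans` must contain exactly one model per graph transition: ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  ts <- unique(vapply(trans, function(m) m$timescale, ""))
  if (length(ts) != 1L) {
    stop("all transitions must share one timescale", call. = FALSE)
  }
  structure(
    list(graph = graph, long = long, trans = trans[want], timescale = ts),
    class = "joint_model_spec"
  )
}

#' @export
print.joint_model_spec <- function(x, ...) {
  cat(sprintf(
    "Joint model: %s basis (q1 = %d, r = %d), %d transitions, %s timescale\n",
    x$long$basis$name, x$long$basis$q1, x$long$basis$r,
    length(x$trans), x$timescale
  ))
  for (id in names(x$trans)) {
    m <- x$trans[[id]]
    cat(sprintf("  %s: %s baseline, association %s\n",
                id, m$baseline$family, m$assoc$kind))
  }
  invisible(x)
}

# resolver closure mapping anchor ids to baselines within a spec
make_resolver <- function(spec) {
  function(id) {
    bl <- spec$trans[[id]]$baseline
    if (is.null(bl)) stop("anchor transition ", id, " not in model", call. = FALSE)
    if (bl$family == "proportional") {
      stop("anchor transition ", id, " is itself proportional", call. = FALSE)
    }
    bl
  }
}

# ---------------------------------------------------------------------------
# Priors

#' Prior specification
#'
#' Defaults are weakly informative: `N(0, 100^2)` on association, covariate
#' and fixed effects; `N(0, 10^2)` on spline coefficients and log rescale
#' factors; half-Cauchy(0, 1) on Weibull shape and scale; inverse-gamma(0.01,
#' 0.01) on the residual variance; half-Cauchy(0, 2.5) on random-effect
#' standard deviations; LKJ(2) on the random-effect correlation matrix. For
#' two random effects the correlation prior can instead be set through
#' `rho_beta`: `(rho + 1)/2 ~ Beta(a, a)` (`rho_beta = 0.5` gives the
#' Jeffreys-type alternative; note LKJ(eta) on a 2 x 2 correlation is the
#' special case `a = eta`).
#'
#' @param sd_alpha,sd_gamma,sd_beta normal prior sds.
#' @param sd_eta normal prior sd on spline coefficients / log rescales.
#' @param hc_weibull half-Cauchy scale on Weibull shape and scale.
#' @param ig_shape,ig_scale inverse-gamma hyperparameters on `sigma_e2`.
#' @param hc_re_sd half-Cauchy scale on random-effect sds.
#' @param lkj_eta LKJ shape on the random-effect correlation matrix.
#' @param rho_beta optional Beta shape `a` replacing the LKJ prior via
#'   `(rho+1)/2 ~ Beta(a, a)` on each canonical partial correlation.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(sd_alpha = 100, sd_gamma = 100, sd_beta = 100,
                       sd_eta = 10, hc_weibull = 1,
                       ig_shape = 0.01, ig_scale = 0.01,
                       hc_re_sd = 2.5, lkj_eta = 2, rho_beta = NULL) {
  structure(
    list(
      sd_alpha = sd_alpha, sd_gamma = sd_gamma, sd_beta = sd_beta,
      sd_eta = sd_eta, hc_weibull = hc_weibull,
      ig_shape = ig_shape, ig_scale = ig_scale,
      hc_re_sd = hc_re_sd, lkj_eta = lkj_eta, rho_beta = rho_beta
    ),
    class = "prior_spec"
  )
}

# scalar density helpers -----------------------------------------------------

log_dhalfcauchy <- function(x, scale) {
  ifelse(x <= 0, -Inf, log(2) + stats::dcauchy(x, 0, scale, log = TRUE))
}

log_dinvgamma <- function(x, shape, scale) {
  ifelse(x <= 0, -Inf,
         shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x)
}

# LKJ log density on a correlation matrix, up to the normalizing constant
# (constant in the matrix, so irrelevant for posterior kernels)
log_dlkj_unnorm <- function(R, eta) {
  ld <- determinant(R, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  (eta - 1) * as.numeric(ld$modulus)
}

#' Log prior density of a full parameter set
#'
#' Sums independent log prior densities over all model parameters: normal on
#' `beta`, `gamma`, `alpha` and spline coefficients; half-Cauchy on Weibull
#' shape/scale; inverse-gamma on `sigma_e2`; half-Cauchy on random-effect
#' sds and LKJ (up to its normalizing constant) on the random-effect
#' correlation matrix. Out-of-support values return `-Inf`.
#'
#' @param theta a parameter set as used throughout: list with `beta`,
#'   `sigma_e2`, `sd_b`, `R_b` (correlation matrix) and `trans`, a named list
#'   per transition with baseline parameters (`shape`/`scale`, or `eta`, or
#'   `log_rescale`), `gamma` and `alpha`.
#' @param priors a [prior_spec()].
#' @return Scalar log density.
#' @export
log_prior <- function(theta, priors) {
  lp <- sum(stats::dnorm(theta$beta, 0, priors$sd_beta, log = TRUE))
  lp <- lp + log_dinvgamma(theta$sigma_e2, priors$ig_shape, priors$ig_scale)
  lp <- lp + sum(log_dhalfcauchy(theta$sd_b, priors$hc_re_sd))
  if (!is.null(theta$R_b) && nrow(theta$R_b) > 1) {
    lp <- lp + log_dlkj_unnorm(theta$R_b, priors$lkj_eta)
  }
  for (tm in theta$trans) {
    if (!is.null(tm$shape)) {
      lp <- lp + log_dhalfcauchy(tm$shape, priors$hc_weibull) +
        log_dhalfcauchy(tm$scale, priors$hc_weibull)
    }
    if (!is.null(tm$eta)) {
      lp <- lp + sum(stats::dnorm(tm$eta, 0, priors$sd_eta, log = TRUE))
    }
    if (!is.null(tm$log_rescale)) {
      lp <- lp + stats::dnorm(tm$log_rescale, 0, priors$sd_eta, log = TRUE)
    }
    lp <- lp + sum(stats::dnorm(tm$gamma, 0, priors$sd_gamma, log = TRUE))
    lp <- lp + sum(stats::dnorm(tm$alpha, 0, priors$sd_alpha, log = TRUE))
  }
  lp
}
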