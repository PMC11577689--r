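#' Likelihood components and posterior kernels
#'
#' All cumulative transition intensities are approximated by Gauss-Legendre
#' quadrature (default 15 nodes) affinely mapped onto each sojourn interval.
#' For a unidirectional process the event likelihood factorizes exactly: the
#' full multistate contribution of a subject equals the sum of that subject's
#' competing-risk block contributions, and each block contribution equals the
#' sum of its cause-specific single-transition contributions. This identity
#' is what makes the blockwise posteriors coherent with the full joint
#' posterior (up to the longitudinal-data conditioning).
#'
#' @name likelihood
NULL

#' Gauss-Legendre quadrature rule
#'
#' Nodes and weights on `[-1, 1]`, cached per node count; intervals are
#' handled by affine mapping at evaluation time.
#'
#' @param Q number of nodes (default 15).
#' @return A `quadrature_rule`: list with `nodes`, `weights`, `Q`.
#' @export
gauss_legendre_rule <- local({
  cache <- new.env(parent = emptyenv())
  function(Q = 15L) {
    key <- as.character(Q)
    if (is.null(cache[[key]])) {
      gl <- pracma::gaussLegendre(Q, -1, 1)
      cache[[key]] <- structure(
        list(nodes = gl$x, weights = gl$w, Q = as.integer(Q)),
        class = "quadrature_rule"
      )
    }
    cache[[key]]
  }
})

#' Gaussian longitudinal log-likelihood of one subject
#'
#' Sum over the given measurement index set of
#' `log N(y_ij; mu_i(t_ij), sigma_e2)`. An empty index set contributes 0.
#'
#' @param subject a `subject_record`.
#' @param long_index integer indices into the subject's measurements.
#' @param long_model a [long_model()].
#' @param b the subject's random effects.
#' @return Scalar log density.
#' @export
longitudinal_loglik <- function(subject, long_index, long_model, b) {
  if (length(long_index) == 0L) return(0)
  if (long_model$sigma_e2 <= 0) stop("sigma_e2 must be positive", call. = FALSE)
  t <- subject$obs_times[long_index]
  y <- subject$obs_values[long_index]
  m <- mu(t, subject$w, long_model, b)
  sum(stats::dnorm(y, m, sqrt(long_model$sigma_e2), log = TRUE))
}

#' Cumulative transition intensity over an interval
#'
#' Gauss-Legendre approximation of `int_{t0}^{t1} h(u) du` in study time; for
#' clock-reset models the baseline inside the integrand is evaluated at
#' `u - state_entry_time`.
#'
#' @param t0,t1 interval bounds in study time, `t0 <= t1`.
#' @param state_entry_time entry time into the source state.
#' @param w subject covariates.
#' @param trans_model a [transition_model()].
#' @param long_model a [long_model()].
#' @param b subject random effects.
#' @param rule a [gauss_legendre_rule()].
#' @param resolve anchor resolver for proportional baselines.
#' @return Nonnegative scalar.
#' @export
cumulative_hazard <- function(t0, t1, state_entry_time, w, trans_model,
                              long_model, b, rule = gauss_legendre_rule(),
                              resolve = NULL) {
  if (t1 < t0) stop("t1 must be >= t0", call. = FALSE)
  if (t1 == t0) return(0)
  half <- (t1 - t0) / 2
  u <- (t0 + t1) / 2 + half * rule$nodes
  h <- hazard(u, state_entry_time, w, trans_model, long_model, b, resolve)
  half * sum(rule$weights * h)
}

#' Full multistate log-likelihood of one subject
#'
#' For each sojourn interval the subject contributes minus the summed
#' cumulative intensities of every transition leaving the occupied state, and
#' the log intensity of the realized transition at its time (no event term on
#' the censored final interval).
#'
#' @param subject a `subject_record` whose path is valid in `spec$graph`.
#' @param spec a [joint_model_spec()] carrying parameter values.
#' @param b subject random effects.
#' @param rule a [gauss_legendre_rule()].
#' @return Scalar log density; `-Inf` if an observed event has zero intensity.
#' @export
multistate_loglik <- function(subject, spec, b, rule = gauss_legendre_rule()) {
  resolve <- make_resolver(spec)
  tr <- spec$graph$transitions
  iv <- sojourn_intervals(subject)
  ll <- 0
  for (l in seq_len(nrow(iv))) {
    from <- iv$state[l]
    entry <- iv$start[l]
    stop_t <- iv$stop[l]
    outs <- tr[tr[, 1] == from, 2]
    for (k in outs) {
      tm <- spec$trans[[transition_id(from, k)]]
      ll <- ll - cumulative_hazard(entry, stop_t, entry, subject$w, tm,
                                   spec$long, b, rule, resolve)
    }
    if (!is.na(iv$next_state[l])) {
      tm <- spec$trans[[transition_id(from, iv$next_state[l])]]
      h <- hazard(stop_t, entry, subject$w, tm, spec$long, b, resolve)
      ll <- ll + if (h > 0) log(h) else -Inf
    }
  }
  ll
}

#' Competing-risk block log-likelihood
#'
#' Per member: the log intensity of the realized cause at the exit time (if
#' any) minus the summed cumulative intensities of all the block's causes
#' over the member's exposure interval.
#'
#' @param block_dataset a `block_dataset` for a competing-risk block.
#' @param spec a [joint_model_spec()] containing models for the block's
#'   transitions.
#' @param b matrix of random effects, one row per block member.
#' @param rule a [gauss_legendre_rule()].
#' @return Numeric vector of per-member log densities.
#' @export
competing_risk_loglik <- function(block_dataset, spec, b,
                                  rule = gauss_legendre_rule()) {
  bd <- block_dataset
  stopifnot(inherits(bd$block, "competing_risk_block"))
  b <- as_b_matrix(b, length(bd$members), spec$long$basis$r)
  resolve <- make_resolver(spec)
  j <- bd$block$initial_state
  out <- numeric(length(bd$members))
  for (m in seq_along(bd$members)) {
    s <- bd$data$subjects[[bd$members[m]]]
    w <- replace_w(s$w, bd$W, m)
    for (k in bd$block$terminal_states) {
      tm <- spec$trans[[transition_id(j, k)]]
      out[m] <- out[m] - cumulative_hazard(
        bd$entry[m], bd$exit[m], bd$entry[m], w, tm, spec$long, b[m, ], rule, resolve
      )
    }
    if (!is.na(bd$event_target[m])) {
      tm <- spec$trans[[transition_id(j, bd$event_target[m])]]
      h <- hazard(bd$exit[m], bd$entry[m], w, tm, spec$long, b[m, ], resolve)
      out[m] <- out[m] + if (h > 0) log(h) else -Inf
    }
  }
  out
}

#' Single-transition (survival) log-likelihood
#'
#' Per member: `event * log h(exit) - H(entry, exit)` for the view's
#' transition only; competing events count as censoring.
#'
#' @param st_view a `block_dataset` produced by [single_transition_view()].
#' @param spec a [joint_model_spec()] containing the view's transition model.
#' @param b matrix of random effects, one row per member.
#' @param rule a [gauss_legendre_rule()].
#' @return Numeric vector of per-member log densities.
#' @export
single_transition_loglik <- function(st_view, spec, b,
                                     rule = gauss_legendre_rule()) {
  stopifnot(inherits(st_view$block, "transition_block"))
  b <- as_b_matrix(b, length(st_view$members), spec$long$basis$r)
  resolve <- make_resolver(spec)
  id <- transition_id(st_view$block$from_state, st_view$block$to_state)
  tm <- spec$trans[[id]]
  out <- numeric(length(st_view$members))
  for (m in seq_along(st_view$members)) {
    s <- st_view$data$subjects[[st_view$members[m]]]
    w <- replace_w(s$w, st_view$W, m)
    out[m] <- -cumulative_hazard(
      st_view$entry[m], st_view$exit[m], st_view$entry[m], w, tm,
      spec$long, b[m, ], rule, resolve
    )
    if (st_view$event[m] == 1L) {
      h <- hazard(st_view$exit[m], st_view$entry[m], w, tm, spec$long, b[m, ], resolve)
      out[m] <- out[m] + if (h > 0) log(h) else -Inf
    }
  }
  out
}

as_b_matrix <- function(b, n, r) {
  if (is.null(dim(b))) b <- matrix(b, n, r, byrow = TRUE)
  stopifnot(nrow(b) == n, ncol(b) == r)
  b
}

# covariates possibly entry-adjusted in the block dataset
replace_w <- function(w, W, m) {
  if (length(w) == 0L || nrow(W) == 0L) return(w)
  out <- W[m, ]
  names(out) <- colnames(W)
  out
}

# ---------------------------------------------------------------------------
# Parameter set <-> spec conversion

#' Extract the parameter set from a joint model specification
#'
#' @param spec a [joint_model_spec()].
#' @return A `theta` list: `beta`, `sigma_e2`, `sd_b`, `R_b`, and per
#'   transition the baseline parameters, `gamma` and `alpha`.
#' @export
get_parameters <- function(spec) {
  S <- spec$long$Sigma_b
  sd_b <- sqrt(diag(S))
  R_b <- stats::cov2cor(S)
  trans <- lapply(spec$trans, function(m) {
    bl <- m$baseline
    c(
      switch(bl$family,
        weibull = list(shape = bl$shape, scale = bl$scale),
        bspline = list(eta = bl$eta),
        proportional = list(log_rescale = bl$log_rescale)
      ),
      list(gamma = m$gamma, alpha = m$assoc$alpha)
    )
  })
  list(beta = spec$long$beta, sigma_e2 = spec$long$sigma_e2,
       sd_b = sd_b, R_b = R_b, trans = trans)
}

#' Write a parameter set into a joint model specification
#'
#' @param spec a [joint_model_spec()] providing the structure.
#' @param theta a parameter set as returned by [get_parameters()].
#' @return The spec with all parameter values replaced.
#' @export
set_parameters <- function(spec, theta) {
  Sigma_b <- diag(theta$sd_b, length(theta$sd_b)) %*% theta$R_b %*%
    diag(theta$sd_b, length(theta$sd_b))
  spec$long <- long_model(spec$long$basis, theta$beta, theta$sigma_e2, Sigma_b)
  for (id in names(theta$trans)) {
    tp <- theta$trans[[id]]
    m <- spec$trans[[id]]
    bl <- m$baseline
    if (!is.null(tp$shape)) {
      bl <- weibull_baseline(tp$shape, tp$scale)
    } else if (!is.null(tp$eta)) {
      bl$eta <- tp$eta
    } else if (!is.null(tp$log_rescale)) {
      bl$log_rescale <- tp$log_rescale
    }
    m$baseline <- bl
    m$gamma <- tp$gamma
    m$assoc$alpha <- tp$alpha
    spec$trans[[id]] <- m
  }
  spec
}

# ---------------------------------------------------------------------------
# Posterior kernels

#' Unnormalized log posterior kernel
#'
#' Assembles, for one inference strategy, the event log-likelihood, the
#' longitudinal log-likelihood over the strategy's index sets, the
#' random-effects density `sum_i log N(b_i; 0, Sigma_b)` and the log prior.
#' For `jm_msm`, `data` is a `joint_data` and all measurements of all
#' subjects are used; for `jm_cr` / `jm_st`, `data` is the corresponding
#' block dataset (views carry their longitudinal index sets).
#'
#' @param approach one of `"jm_msm"`, `"jm_cr"`, `"jm_st"`.
#' @param data a `joint_data` (jm_msm) or `block_dataset` (jm_cr, jm_st).
#' @param spec a [joint_model_spec()]; its parameter values are overridden by
#'   `theta` when supplied.
#' @param priors a [prior_spec()].
#' @param b matrix of random effects, one row per subject (jm_msm: all
#'   subjects of `data`; blockwise: one row per block member).
#' @param theta optional parameter set ([get_parameters()] layout).
#' @param rule a [gauss_legendre_rule()].
#' @return Scalar unnormalized log posterior density; `-Inf` when any
#'   component is (out of support and) non-finite.
#' @export
log_posterior_kernel <- function(approach = c("jm_msm", "jm_cr", "jm_st"),
                                 data, spec, priors, b, theta = NULL,
                                 rule = gauss_legendre_rule()) {
  approach <- match.arg(approach)
  if (!is.null(theta)) spec <- set_parameters(spec, theta)
  r <- spec$long$basis$r
  if (approach == "jm_msm") {
    stopifnot(inherits(data, "joint_data"))
    n <- length(data$subjects)
    b <- as_b_matrix(b, n, r)
    ev <- sum(vapply(
      seq_len(n),
      function(i) multistate_loglik(data$subjects[[i]], spec, b[i, ], rule), 0
    ))
    ll_long <- sum(vapply(seq_len(n), function(i) {
      s <- data$subjects[[i]]
      longitudinal_loglik(s, seq_along(s$obs_times), spec$long, b[i, ])
    }, 0))
    rel_trans <- names(spec$trans)
  } else {
    stopifnot(inherits(data, "block_dataset"))
    n <- length(data$members)
    b <- as_b_matrix(b, n, r)
    ev <- if (approach == "jm_cr") {
      sum(competing_risk_loglik(data, spec, b, rule))
    } else {
      sum(single_transition_loglik(data, spec, b, rule))
    }
    ll_long <- sum(vapply(seq_len(n), function(m) {
      s <- data$data$subjects[[data$members[m]]]
      longitudinal_loglik(s, data$long_index[[m]], spec$long, b[m, ])
    }, 0))
    rel_trans <- if (approach == "jm_cr") {
      transition_id(data$block$initial_state, data$block$terminal_states)
    } else {
      transition_id(data$block$from_state, data$block$to_state)
    }
  }
  th <- get_parameters(spec)
  th$trans <- th$trans[rel_trans]
  lp <- log_prior(th, priors)
  lre <- sum(dmvnorm_log(b, spec$long$Sigma_b))
  total <- ev + ll_long + lre + lp
  if (!is.finite(total)) return(-Inf)
  total
}

# multivariate normal log density, rows of B against N(0, Sigma)
dmvnorm_log <- function(B, Sigma) {
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  L <- chol(Sigma)
  z <- B %*% chol2inv(L) * B
  -0.5 * (ncol(B) * log(2 * pi) + 2 * sum(log(diag(L))) + rowSums(z))
}
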