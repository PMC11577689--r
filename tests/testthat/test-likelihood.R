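test_that("longitudinal log-likelihood matches direct normal-density summation", {
  spec <- toy_spec_single()
  s <- subject_record(1, c(0, 2, 5), c(0.4, 0.9, 1.1), w = c(age = 0.3),
                      path = rbind(c(0, 0)), censor_time = 6)
  b <- c(0.2, -0.05)
  # y exactly at mu with unit variance
  lm_unit <- long_model(long_basis("intercept_slope"), c(0.5, 0.1), 1, diag(2))
  s0 <- subject_record(2, 2, mu(2, numeric(0), lm_unit, b), path = rbind(c(0, 0)),
                       censor_time = 3)
  expect_equal(longitudinal_loglik(s0, 1L, lm_unit, b), -0.5 * log(2 * pi))
  # empty index set contributes nothing
  expect_identical(longitudinal_loglik(s, integer(0), spec$long, b), 0)
  # direct summation oracle
  direct <- sum(dnorm(
    s$obs_values,
    mu(s$obs_times, s$w, spec$long, b),
    sqrt(spec$long$sigma_e2), log = TRUE
  ))
  expect_equal(longitudinal_loglik(s, 1:3, spec$long, b), direct,
               tolerance = 1e-12)
})

test_that("quadrature reproduces closed-form cumulative hazards", {
  lm0 <- long_model(long_basis("intercept_slope"), c(0, 0), 0.1, diag(2))
  tm_exp <- transition_model(0, 1, weibull_baseline(1, 0.3), "clock_reset",
                             gamma = 0, assoc = association("current_value", 0))
  expect_equal(cumulative_hazard(0, 5, 0, c(w = 0), tm_exp, lm0, c(0, 0)),
               1.5, tolerance = 1e-14)
  tm_w <- transition_model(0, 1, weibull_baseline(2, 0.5), "clock_reset",
                           gamma = 0, assoc = association("current_value", 0))
  expect_equal(cumulative_hazard(0, 2, 0, c(w = 0), tm_w, lm0, c(0, 0)),
               0.5 * 2^2, tolerance = 1e-10)
  # clock-reset from a late entry: H = lambda * (t - entry)^shape
  expect_equal(cumulative_hazard(4, 7, 4, c(w = 0), tm_w, lm0, c(0, 0)),
               0.5 * 3^2, tolerance = 1e-10)
  expect_error(cumulative_hazard(3, 2, 0, c(w = 0), tm_w, lm0, c(0, 0)),
               "t1 must be")
})

test_that("quadrature agrees with adaptive integration on association-modulated intensities", {
  spec <- toy_spec_single(shape = 1.6, scale = 0.1, gamma = 0.4, alpha = 0.8,
                          beta = c(0.3, 0.15))
  tm <- spec$trans[["0->1"]]
  b <- c(0.25, -0.08)
  w <- c(age = 0.6)
  # fractional-shape baseline entered at time 0, integrated away from the
  # state-entry singularity
  for (iv in list(c(2, 9), c(0.5, 1), c(1, 4))) {
    ours <- cumulative_hazard(iv[1], iv[2], 0, w, tm, spec$long, b)
    oracle <- integrate(function(u) hazard(u, 0, w, tm, spec$long, b),
                        iv[1], iv[2], rel.tol = 1e-12)$value
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
  # integer shape is smooth at the state-entry boundary itself
  th <- get_parameters(spec)
  th$trans[["0->1"]]$shape <- 2
  spec2 <- set_parameters(spec, th)
  tm2 <- spec2$trans[["0->1"]]
  for (iv in list(c(0, 4), c(2, 9))) {
    ours <- cumulative_hazard(iv[1], iv[2], iv[1], w, tm2, spec2$long, b)
    oracle <- integrate(function(u) hazard(u, iv[1], w, tm2, spec2$long, b),
                        iv[1], iv[2], rel.tol = 1e-12)$value
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
})

test_that("15-node and 61-node rules agree on smooth intensities", {
  spec <- toy_spec_single(shape = 2, scale = 0.12, alpha = 0.6)
  tm <- spec$trans[["0->1"]]
  b <- c(0.3, 0.05)
  h15 <- cumulative_hazard(0, 8, 0, c(age = 0.4), tm, spec$long, b,
                           gauss_legendre_rule(15))
  h61 <- cumulative_hazard(0, 8, 0, c(age = 0.4), tm, spec$long, b,
                           gauss_legendre_rule(61))
  expect_equal(h15, h61, tolerance = 1e-6)
  rule <- gauss_legendre_rule(15)
  expect_equal(sum(rule$weights), 2)
  expect_equal(sort(rule$nodes), sort(-rule$nodes))
})

test_that("multistate log-likelihood matches hand closed forms under constant hazards", {
  spec <- const_hazard_spec(default_lambdas)
  lam <- default_lambdas
  b <- c(0, 0)
  # censored in state 0 at C = 6
  s_cens <- subject_record(1, 1, 0.2, w = c(age = 0), path = rbind(c(0, 0)),
                           censor_time = 6, graph = spec$graph)
  expect_equal(multistate_loglik(s_cens, spec, b),
               -6 * (lam[["0->1"]] + lam[["0->2"]] + lam[["0->4"]]),
               tolerance = 1e-10)
  # 0 -> 2 at t = 4 then censored at 8
  s_ev <- subject_record(2, c(1, 3, 5), c(0.3, 0.1, 0.4), w = c(age = 0),
                         path = rbind(c(0, 0), c(2, 4)), censor_time = 8,
                         graph = spec$graph)
  expected <- log(lam[["0->2"]]) -
    4 * (lam[["0->1"]] + lam[["0->2"]] + lam[["0->4"]]) -
    4 * (lam[["2->3"]] + lam[["2->4"]])
  expect_equal(multistate_loglik(s_ev, spec, b), expected, tolerance = 1e-10)
})

test_that("single-transition likelihood matches the Weibull closed form", {
  spec <- toy_spec_single(shape = 2, scale = 0.5, gamma = 0, alpha = 0)
  dat <- toy_data_single(n = 10, seed = 31, spec = spec)
  bd <- build_block_dataset(dat, competing_risk_blocks(dat$graph)[[1]])
  sv <- single_transition_view(bd, 1)
  b0 <- matrix(0, length(sv$members), 2)
  got <- single_transition_loglik(sv, spec, b0)
  tau <- sv$exit - sv$entry
  closed <- sv$event * log(2 * tau^(2 - 1) * 0.5) - 0.5 * tau^2
  expect_equal(got, closed, tolerance = 1e-10)
  # shape 1 reduces to the exponential survival likelihood
  spec_e <- toy_spec_single(shape = 1, scale = 0.3, gamma = 0, alpha = 0)
  got_e <- single_transition_loglik(sv, spec_e, b0)
  expect_equal(got_e, sv$event * log(0.3) - 0.3 * tau, tolerance = 1e-12)
})

test_that("the event likelihood factorizes exactly over blocks and causes", {
  cfg <- model1_preset(50, seed = 13)
  dat <- simulate_joint_data(cfg)
  spec <- cfg$spec
  b <- attr(dat, "b_true")
  blocks <- competing_risk_blocks(dat$graph)
  bds <- lapply(blocks, function(blk) build_block_dataset(dat, blk))
  cr_ll <- lapply(bds, function(bd) {
    competing_risk_loglik(bd, spec, b[bd$members, , drop = FALSE])
  })
  for (i in seq_along(dat$subjects)) {
    full <- multistate_loglik(dat$subjects[[i]], spec, b[i, ])
    crsum <- 0
    for (v in seq_along(bds)) {
      m <- match(i, bds[[v]]$members)
      if (!is.na(m)) crsum <- crsum + cr_ll[[v]][m]
    }
    expect_equal(full, crsum, tolerance = 1e-10)
  }
  for (v in seq_along(bds)) {
    bd <- bds[[v]]
    stsum <- Reduce(`+`, lapply(blocks[[v]]$terminal_states, function(k) {
      single_transition_loglik(single_transition_view(bd, k), spec,
                               b[bd$members, , drop = FALSE])
    }))
    expect_equal(cr_ll[[v]], stsum, tolerance = 1e-10)
  }
})

test_that("survival probabilities are nonincreasing and zero association decouples b", {
  spec <- toy_spec_single(alpha = 0)
  tm <- spec$trans[["0->1"]]
  w <- c(age = 0.5)
  H <- vapply(seq(0.5, 10, by = 0.5), function(t1) {
    cumulative_hazard(0, t1, 0, w, tm, spec$long, c(0.4, 0.1))
  }, 0)
  expect_true(all(diff(exp(-H)) <= 0))
  dat <- toy_data_single(n = 8, seed = 5, spec = spec)
  bd <- build_block_dataset(dat, competing_risk_blocks(dat$graph)[[1]])
  sv <- single_transition_view(bd, 1)
  n <- length(sv$members)
  set.seed(2)
  ll1 <- single_transition_loglik(sv, spec, matrix(rnorm(2 * n), n, 2))
  ll2 <- single_transition_loglik(sv, spec, matrix(rnorm(2 * n), n, 2))
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("posterior kernels collapse to each other in degenerate decompositions", {
  spec <- toy_spec_single()
  dat <- toy_data_single(n = 20, seed = 9, spec = spec)
  b <- attr(dat, "b_true")
  bd <- build_block_dataset(dat, competing_risk_blocks(dat$graph)[[1]])
  sv <- single_transition_view(bd, 1)
  pr <- prior_spec()
  k_msm <- log_posterior_kernel("jm_msm", dat, spec, pr, b)
  k_cr <- log_posterior_kernel("jm_cr", bd, spec, pr, b[bd$members, , drop = FALSE])
  k_st <- log_posterior_kernel("jm_st", sv, spec, pr, b[bd$members, , drop = FALSE])
  expect_equal(k_msm, k_cr, tolerance = 1e-10)
  expect_equal(k_cr, k_st, tolerance = 1e-10)
  # theta override reproduces set_parameters
  th <- get_parameters(spec)
  th$trans[["0->1"]]$alpha <- 0.9
  k_a <- log_posterior_kernel("jm_st", sv, spec, pr, b[bd$members, , drop = FALSE],
                              theta = th)
  k_b <- log_posterior_kernel("jm_st", sv, set_parameters(spec, th), pr,
                              b[bd$members, , drop = FALSE])
  expect_equal(k_a, k_b, tolerance = 1e-12)
})
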