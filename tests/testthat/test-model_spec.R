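test_that("trajectory mean and slope match the random-intercept-slope form", {
  lm1 <- long_model(long_basis("intercept_slope"), c(1, 0.5), 0.1, diag(2))
  expect_equal(mu(2, numeric(0), lm1, c(0, 0)), 2.0)
  expect_equal(mu(0, numeric(0), lm1, c(-1, -0.5)), 0)
  expect_equal(dmu_dt(c(0, 3, 7), numeric(0), lm1, c(0.2, 0.1)),
               rep(0.6, 3))
})

test_that("nonlinear-decay basis evaluates and differentiates correctly", {
  bs <- long_basis("nonlinear_decay")
  # at t = 0: f1(0) = (1+0)^-1.2 - 1 = 0 and f2(0) = 0, intercept terms only
  X0 <- bs$X(0, c(w1 = 2))
  expect_equal(unname(drop(X0)), c(1, 2, 0, 0, 0, 0))
  beta <- c(1.2, 0.25, 1.5, 0.3, 0.1, 0.04)
  lm2 <- long_model(bs, beta, 0.25, diag(3))
  b <- c(0.3, -0.2, 0.05)
  w <- c(w1 = 0.7)
  # derivative matches central finite differences
  h <- 1e-6
  for (t in c(0.5, 1, 4, 9)) {
    num <- (mu(t + h, w, lm2, b) - mu(t - h, w, lm2, b)) / (2 * h)
    expect_equal(dmu_dt(t, w, lm2, b), num, tolerance = 1e-6)
  }
  # beta-weighted f1 slope at t = 1 is -1.2 * 2^-2.2 per unit coefficient
  expect_equal(bs$dX(1, c(w1 = 0))[3], -1.2 * 2^(-2.2))
})

test_that("hazard evaluation follows the multiplicative Weibull parameterization", {
  lm1 <- long_model(long_basis("intercept_slope"), c(0, 0), 0.1, diag(2))
  tm_exp <- transition_model(0, 1, weibull_baseline(1, 0.3), "clock_reset",
                             gamma = 0, assoc = association("current_value", 0))
  expect_equal(hazard(c(1, 5, 9), 0, c(w = 0), tm_exp, lm1, c(0, 0)),
               rep(0.3, 3))
  tm_w <- transition_model(0, 1, weibull_baseline(2, 0.5), "clock_reset",
                           gamma = 0, assoc = association("current_value", 0))
  expect_equal(hazard(6, 4, c(w = 0), tm_w, lm1, c(0, 0)), 2 * 2 * 0.5)
  # association and covariate multipliers: 0.3 * exp(0.9)
  lm_c <- long_model(long_basis("intercept_slope"), c(0.7, 0), 0.1, diag(2))
  tm_a <- transition_model(0, 1, weibull_baseline(1, 0.3), "clock_reset",
                           gamma = 0.2, assoc = association("current_value", 1))
  expect_equal(hazard(2, 0, c(w = 1), tm_a, lm_c, c(0, 0)), 0.3 * exp(0.9))
  expect_error(hazard(1, 2, c(w = 0), tm_exp, lm1, c(0, 0)), "before state entry")
})

test_that("clock choice is irrelevant when state entry is at time zero", {
  lm1 <- long_model(long_basis("intercept_slope"), c(0.4, 0.1), 0.1, diag(2))
  for (ts in c("clock_reset", "clock_forward")) {
    tm <- transition_model(0, 1, weibull_baseline(1.7, 0.2), ts,
                           gamma = 0.3, assoc = association("current_value", 0.5))
    assign(paste0("h_", ts),
           hazard(c(1, 2.5, 6), 0, c(w = 0.8), tm, lm1, c(0.2, -0.1)))
  }
  expect_equal(h_clock_reset, h_clock_forward)
})

test_that("association structures produce the documented hazard multipliers", {
  lm1 <- long_model(long_basis("intercept_slope"), c(0.5, 0.2), 0.1, diag(2))
  b <- c(0.3, -0.05)
  w <- c(age = 2)
  t <- 3
  m <- mu(t, w, lm1, b)
  base <- weibull_baseline(1, 0.3)
  h_of <- function(kind, alpha, covariate = 1L) {
    tm <- transition_model(0, 1, base, "clock_reset", gamma = 0,
                           assoc = association(kind, alpha, covariate))
    hazard(t, 0, w, tm, lm1, b)
  }
  expect_equal(h_of("none", numeric(0)), 0.3)
  expect_equal(h_of("current_value", 0.7), 0.3 * exp(0.7 * m))
  expect_equal(h_of("current_slope", 0.7), 0.3 * exp(0.7 * (0.2 - 0.05)))
  expect_equal(h_of("shared_random_effects", c(1, 2)), 0.3 * exp(b[1] + 2 * b[2]))
  expect_equal(h_of("current_value_quadratic", c(0.5, 0.25)),
               0.3 * exp(0.5 * m + 0.25 * m^2))
  expect_equal(h_of("current_value_by_covariate", c(0.5, 0.25)),
               0.3 * exp(0.5 * m + 0.25 * 2 * m))
  expect_error(association("current_value", c(1, 2)), "needs 1 parameter")
})

test_that("log-B-spline baselines are smooth and reduce to their coefficients", {
  bl <- bspline_baseline(c(-2, -1.5, -1, -0.8, -0.6), c(0, 16), 8)
  lm1 <- long_model(long_basis("intercept_slope"), c(0, 0), 0.1, diag(2))
  tm <- transition_model(0, 1, bl, "clock_forward", gamma = 0,
                         assoc = association("none"))
  tt <- seq(0.01, 15.99, length.out = 400)
  h <- hazard(tt, 0, c(w = 0), tm, lm1, c(0, 0))
  expect_true(all(h > 0))
  # log-hazard is piecewise cubic: second differences continuous across knot
  lh <- log(h)
  d2 <- diff(lh, differences = 2)
  expect_lt(max(abs(diff(d2))), 1e-2)
  expect_error(bspline_baseline(c(1, 2), c(0, 16), 8), "length 5")
})

test_that("the multiplicative Weibull converts to the standard dweibull scale", {
  shape <- 1.4; scale <- 0.07
  std <- weibull_to_standard(shape, scale)
  u <- c(0.5, 2, 7)
  h_ours <- shape * u^(shape - 1) * scale
  h_std <- dweibull(u, std$shape, std$scale) / pweibull(u, std$shape, std$scale,
                                                        lower.tail = FALSE)
  expect_equal(h_ours, h_std)
})

test_that("log priors match textbook densities and support constraints", {
  pr <- prior_spec()
  th <- get_parameters(toy_spec_single())
  # alpha = 0 under N(0, 100^2) contributes -log(100 sqrt(2 pi))
  th0 <- th
  th0$trans[["0->1"]]$alpha <- 0
  diff_alpha <- log_prior(th0, pr) -
    (log_prior(th, pr) - dnorm(th$trans[["0->1"]]$alpha, 0, 100, log = TRUE))
  expect_equal(diff_alpha, -log(100 * sqrt(2 * pi)))
  # out-of-support Weibull shape
  th_bad <- th
  th_bad$trans[["0->1"]]$shape <- -1
  expect_identical(log_prior(th_bad, pr), -Inf)
  # inverse-gamma density formula at sigma_e2 = 1
  th1 <- th
  th1$sigma_e2 <- 1
  a <- 0.01; bb <- 0.01
  expected <- a * log(bb) - lgamma(a) - (a + 1) * log(1) - bb / 1
  got <- log_prior(th1, pr) - (log_prior(th, pr) -
    (a * log(bb) - lgamma(a) - (a + 1) * log(th$sigma_e2) - bb / th$sigma_e2))
  expect_equal(got, expected, tolerance = 1e-12)
})
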