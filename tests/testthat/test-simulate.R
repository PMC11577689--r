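test_that("covariate mixture draws respect weights and standardization", {
  set.seed(101)
  W <- draw_covariates(1e5, age_mixture_law())
  comp <- attr(W, "component")
  freq <- tabulate(comp, 3) / 1e5
  target <- c(0.55, 0.30, 0.15)
  mc_se <- sqrt(target * (1 - target) / 1e5)
  expect_true(all(abs(freq - target) < 3 * mc_se))
  expect_equal(mean(W), 0, tolerance = 1e-12)
  expect_equal(sd(W), 1, tolerance = 1e-12)
  # degenerate single component stays inside its interval
  one <- covariate_law(list(c(2, 3)), 1, standardize = FALSE)
  x <- draw_covariates(500, one)
  expect_true(all(x >= 2 & x <= 3))
  expect_error(covariate_law(list(c(0, 1)), 0.7), "sum to 1")
})

test_that("single constant-hazard latent times are exponential", {
  spec <- toy_spec_single(shape = 1, scale = 0.5, gamma = 0, alpha = 0)
  set.seed(77)
  times <- replicate(3000, {
    p <- simulate_event_process(c(0, 0), c(age = 0), 1e4, spec)
    if (nrow(p) > 1) p[2, 2] else NA_real_
  })
  expect_true(all(!is.na(times)))
  ks <- ks.test(times, pexp, rate = 0.5)
  expect_gt(ks$p.value, 0.001)
})

test_that("competing constant hazards produce cause fractions lambda_k / sum(lambda)", {
  g <- transition_graph(rbind(c(0, 1), c(0, 2)))
  spec <- model_template(g, "intercept_slope", "clock_reset", "weibull",
                         "current_value", 1)
  th <- get_parameters(spec)
  th$trans[["0->1"]] <- list(shape = 1, scale = 0.1, gamma = 0, alpha = 0)
  th$trans[["0->2"]] <- list(shape = 1, scale = 0.3, gamma = 0, alpha = 0)
  spec <- set_parameters(spec, th)
  set.seed(55)
  n <- 3000
  causes <- replicate(n, {
    p <- simulate_event_process(c(0, 0), c(age = 0), 1e3, spec)
    p[2, 1]
  })
  frac2 <- mean(causes == 2)
  mc_se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(frac2 - 0.75), 3 * mc_se)
})

test_that("Weibull sojourn times follow the multiplicative parameterization", {
  spec <- toy_spec_single(shape = 2, scale = 0.5, gamma = 0, alpha = 0)
  set.seed(88)
  times <- replicate(3000, {
    p <- simulate_event_process(c(0, 0), c(age = 0), 1e3, spec)
    p[2, 2]
  })
  # H(t) = 0.5 t^2  =>  t(p) = sqrt(-log(1 - p) / 0.5)
  for (p in c(0.25, 0.5, 0.75)) {
    expect_equal(unname(quantile(times, p)), sqrt(-log(1 - p) / 0.5),
                 tolerance = 0.05)
  }
  std <- weibull_to_standard(2, 0.5)
  ks <- ks.test(times, pweibull, shape = std$shape, scale = std$scale)
  expect_gt(ks$p.value, 0.001)
})

test_that("visit grids follow the per-epoch gaps and truncation rules", {
  spec <- toy_spec_single(sigma_e2 = 1e-12)
  g1 <- fig1_graph()
  lm0 <- spec$long
  # no transitions, C = 6, gap 2.6 -> visits at 0, 2.6, 5.2
  vis <- simulate_visits_and_biomarker(
    rbind(c(0, 0)), 6, c(2.6, 2, 1.2), lm0, c(0, 0), c(age = 0), g1
  )
  expect_equal(vis$times, c(0, 2.6, 5.2))
  # gap tightens after each observed transition
  path <- rbind(c(0, 0), c(1, 3), c(3, 7))
  vis2 <- simulate_visits_and_biomarker(
    path, 20, c(3, 2, 1), lm0, c(0, 0), c(age = 0), g1
  )
  expect_equal(vis2$times, c(0, 3, 5, 7, 8, 9, 10, 11, 12, 13, 14, 15,
                             16, 17, 18, 19, 20))
  # grid ends at entry to the absorbing state
  path_abs <- rbind(c(0, 0), c(4, 4.5))
  vis3 <- simulate_visits_and_biomarker(
    path_abs, 20, 2, lm0, c(0, 0), c(age = 0), g1
  )
  expect_equal(vis3$times, c(0, 2, 4))
  # zero noise puts measurements exactly on the latent trajectory
  lm_noiseless <- long_model(lm0$basis, lm0$beta, 1e-30, lm0$Sigma_b)
  b <- c(0.3, -0.1)
  vis4 <- simulate_visits_and_biomarker(
    rbind(c(0, 0)), 5, 1, lm_noiseless, b, c(age = 0), g1
  )
  expect_equal(vis4$values, mu(vis4$times, c(age = 0), lm_noiseless, b),
               tolerance = 1e-9)
})

test_that("residual noise has the configured variance", {
  spec <- toy_spec_single(sigma_e2 = 0.16)
  set.seed(3)
  b <- c(0, 0)
  vis <- simulate_visits_and_biomarker(
    rbind(c(0, 0)), 5000, 1, spec$long, b, c(age = 0), spec$graph
  )
  res <- vis$values - mu(vis$times, c(age = 0), spec$long, b)
  # 3 MC standard errors of a variance estimate, on the relative scale
  expect_equal(var(res), 0.16, tolerance = 3 * sqrt(2 / 5000))
})

test_that("simulated datasets are reproducible, valid and within follow-up", {
  cfg <- model1_preset(40, seed = 91)
  d1 <- simulate_joint_data(cfg)
  d2 <- simulate_joint_data(cfg)
  expect_identical(
    lapply(d1$subjects, function(s) s$obs_values),
    lapply(d2$subjects, function(s) s$obs_values)
  )
  abs_states <- absorbing_states(d1$graph)
  for (s in d1$subjects) {
    expect_true(all(s$obs_times <= s$censor_time))
    abs_idx <- which(s$path[, 1] %in% abs_states)
    if (length(abs_idx) > 0) {
      expect_true(all(s$obs_times <= s$path[abs_idx[1], 2]))
    }
  }
})

test_that("presets carry the documented study conditions", {
  cfg1 <- model1_preset(10, seed = 1)
  expect_equal(cfg1$censoring[c("lower", "upper")], list(lower = 13, upper = 24))
  expect_equal(cfg1$gaps, c(2.6, 2, 1.2))
  expect_equal(nrow(cfg1$spec$graph$transitions), 8L)
  expect_length(competing_risk_blocks(cfg1$spec$graph), 4L)
  expect_equal(cfg1$spec$timescale, "clock_reset")
  cfg2 <- model2_preset(10, seed = 1)
  expect_equal(cfg2$censoring[c("lower", "upper")], list(lower = 4, upper = 24))
  expect_equal(cfg2$gaps, 1)
  expect_equal(nrow(cfg2$spec$graph$transitions), 10L)
  expect_equal(cfg2$spec$timescale, "clock_forward")
  expect_error(model1_preset(10, overrides = list(graph = "x")), "structural")
  expect_error(simulation_config(cfg1$spec, 0, cfg1$censoring, 1,
                                 age_mixture_law()), "at least 1")
})
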