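# Shared fixtures, built in code.

fig1_graph <- function() illness_death_graph()

# a single-transition joint model with chosen parameter values
toy_spec_single <- function(shape = 1.3, scale = 0.2, gamma = 0.3, alpha = 0.4,
                            beta = c(0.5, 0.1), sigma_e2 = 0.2,
                            sd_b = c(0.4, 0.1), rho = -0.3,
                            assoc_kind = "current_value") {
  g <- transition_graph(rbind(c(0L, 1L)))
  spec <- model_template(g, "intercept_slope", "clock_reset", "weibull",
                         assoc_kind, n_covariates = 1)
  th <- get_parameters(spec)
  na <- length(th$trans[["0->1"]]$alpha)
  th$trans[["0->1"]] <- list(shape = shape, scale = scale, gamma = gamma,
                             alpha = rep(alpha, length.out = na))
  th$beta <- beta
  th$sigma_e2 <- sigma_e2
  th$sd_b <- sd_b
  th$R_b <- matrix(c(1, rho, rho, 1), 2)
  set_parameters(spec, th)
}

# simulated single-transition dataset
toy_data_single <- function(n = 25, seed = 9, spec = toy_spec_single(),
                            censor = c(5, 10), gaps = 2) {
  cfg <- simulation_config(
    spec, n, list(type = "uniform", lower = censor[1], upper = censor[2]),
    gaps = gaps, covariates = age_mixture_law(), seed = seed
  )
  simulate_joint_data(cfg)
}

# hand-built subject: path 0 -> 2 (t=4) -> 4 (t=8), visits 1,3,5,7
example_subject <- function(graph = fig1_graph()) {
  subject_record(
    id = 1, obs_times = c(1, 3, 5, 7), obs_values = c(0.4, 0.6, 0.5, 0.7),
    w = c(age = 0.2),
    path = rbind(c(0, 0), c(2, 4), c(4, 8)), censor_time = 8, graph = graph
  )
}

# Figure-1-graph spec with constant (exponential) hazards and no covariate or
# association effects; lambdas named by transition id
const_hazard_spec <- function(lambdas) {
  g <- fig1_graph()
  spec <- model_template(g, "intercept_slope", "clock_reset", "weibull",
                         "current_value", n_covariates = 1)
  th <- get_parameters(spec)
  for (id in names(th$trans)) {
    th$trans[[id]] <- list(shape = 1, scale = lambdas[[id]], gamma = 0, alpha = 0)
  }
  set_parameters(spec, th)
}

default_lambdas <- c(
  "0->1" = 0.10, "0->2" = 0.20, "0->4" = 0.05, "1->3" = 0.08,
  "1->4" = 0.06, "2->3" = 0.09, "2->4" = 0.07, "3->4" = 0.12
)

expect_equal_tol <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
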