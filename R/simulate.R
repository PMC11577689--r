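#' Joint-process simulator
#'
#' Data are generated from the model's own generative process: random effects
#' from `N(0, Sigma_b)`, a censoring time, then the multistate path by
#' iterated competing-risks simulation (one latent time per permitted exit,
#' obtained by inverting the quadrature-based cumulative intensity at a
#' uniform draw with bracketed root finding), then a visit grid with
#' per-epoch gaps, and finally biomarker values `y = mu(t) + N(0, sigma_e2)`
#' noise at the visits.
#'
#' @name simulate
NULL

#' Covariate law: mixture of uniforms
#'
#' @param intervals list of length-2 numeric vectors, the mixture components.
#' @param weights mixture weights (must sum to 1).
#' @param standardize if TRUE the drawn sample is empirically standardized to
#'   mean 0, sd 1.
#' @param name covariate name.
#' @return A `covariate_law` object.
#' @export
covariate_law <- function(intervals, weights, standardize = TRUE, name = "w1") {
  if (abs(sum(weights) - 1) > 1e-12 || any(weights < 0)) {
    stop("mixture weights must be nonnegative and sum to 1", call. = FALSE)
  }
  if (length(intervals) != length(weights)) {
    stop("one weight per interval required", call. = FALSE)
  }
  structure(list(intervals = intervals, weights = weights,
                 standardize = standardize, name = name),
            class = "covariate_law")
}

#' The mixed-uniform "age" law of the realistic simulation preset
#'
#' Uniform over (18, 65), (65, 80) and (80, 90) with weights 0.55, 0.30 and
#' 0.15, standardized to mean 0 and sd 1.
#' @export
age_mixture_law <- function() {
  covariate_law(list(c(18, 65), c(65, 80), c(80, 90)), c(0.55, 0.30, 0.15),
                standardize = TRUE, name = "age")
}

#' Draw baseline covariates
#'
#' @param n number of subjects.
#' @param laws a `covariate_law` or list of them (one column each).
#' @return Numeric matrix n x q2 with named columns; attribute `"component"`
#'   (matrix of mixture component indices) is attached for diagnostic use.
#' @export
draw_covariates <- function(n, laws) {
  if (inherits(laws, "covariate_law")) laws <- list(laws)
  comp_all <- matrix(NA_integer_, n, length(laws))
  W <- vapply(seq_along(laws), function(j) {
    law <- laws[[j]]
    comp <- sample.int(length(law$weights), n, replace = TRUE, prob = law$weights)
    comp_all[, j] <<- comp
    lo <- vapply(law$intervals, `[`, 0, 1)[comp]
    hi <- vapply(law$intervals, `[`, 0, 2)[comp]
    x <- stats::runif(n, lo, hi)
    if (law$standardize) x <- as.numeric(scale(x))
    x
  }, numeric(n))
  W <- matrix(W, n, length(laws))
  colnames(W) <- vapply(laws, function(l) l$name, "")
  attr(W, "component") <- comp_all
  W
}

#' Simulate one subject's multistate path
#'
#' Iterated competing-risks scheme: from the state occupied at entry time
#' `s`, a latent time is drawn for every permitted exit by solving
#' `H_k(s, t) = -log U`, `U ~ Uniform(0, 1)`, with bracketed root finding on
#' the quadrature-based cumulative intensity (tolerance 1e-8 in time units);
#' the earliest latent time within the horizon wins. The path ends at an
#' absorbing state or at the censoring time `C`, whichever comes first.
#'
#' @param b subject random effects.
#' @param w subject covariates (named vector).
#' @param C censoring time.
#' @param spec a [joint_model_spec()] with true parameter values.
#' @param initial_state starting state (default 0) at time 0.
#' @param rule a [gauss_legendre_rule()].
#' @return Matrix with columns `(state, entry_time)` (a subject path).
#' @export
simulate_event_process <- function(b, w, C, spec, initial_state = 0L,
                                   rule = gauss_legendre_rule()) {
  resolve <- make_resolver(spec)
  tr <- spec$graph$transitions
  path <- matrix(c(initial_state, 0), 1, 2)
  state <- initial_state
  s <- 0
  repeat {
    outs <- tr[tr[, 1] == state, 2]
    if (length(outs) == 0L || s >= C) break
    times <- rep(Inf, length(outs))
    for (ki in seq_along(outs)) {
      tm <- spec$trans[[transition_id(state, outs[ki])]]
      target <- -log(stats::runif(1))
      Hfun <- function(t) {
        cumulative_hazard(s, t, s, w, tm, spec$long, b, rule, resolve) - target
      }
      if (Hfun(C) < 0) next # latent time beyond the horizon
      times[ki] <- stats::uniroot(Hfun, c(s, C), tol = 1e-8)$root
    }
    if (all(is.infinite(times))) break
    ki <- which.min(times)
    s <- times[ki]
    state <- outs[ki]
    path <- rbind(path, c(state, s))
  }
  colnames(path) <- c("state", "entry_time")
  path
}

#' Simulate visit times and biomarker values along a path
#'
#' The visit grid starts at `start_offset` (default 0, a baseline
#' measurement) and advances by the gap of the current epoch: gap
#' `gaps[1 + e]` where `e` is the number of observed transitions at or before
#' the current visit (capped at `length(gaps) - 1`). The grid is truncated at
#' the earlier of the censoring time and entry into an absorbing state.
#'
#' @param path subject path matrix `(state, entry_time)`.
#' @param C censoring time.
#' @param gaps positive per-epoch visit gaps `(Delta1, Delta2, ...)`; epochs
#'   beyond the last reuse the final gap.
#' @param long_model a [long_model()] with true values.
#' @param b subject random effects.
#' @param w subject covariates.
#' @param graph the `transition_graph` (to identify absorbing entry).
#' @param start_offset time of the first visit.
#' @return List with `times` and `values` (possibly empty when the horizon
#'   precedes the first visit).
#' @export
simulate_visits_and_biomarker <- function(path, C, gaps, long_model, b, w,
                                          graph, start_offset = 0) {
  if (any(gaps <= 0)) stop("visit gaps must be positive", call. = FALSE)
  absorbing <- absorbing_states(graph)
  abs_idx <- which(path[, 1] %in% absorbing)
  horizon <- min(C, if (length(abs_idx) > 0) path[abs_idx[1], 2] else Inf)
  trans_times <- if (nrow(path) > 1) path[-1, 2] else numeric(0)
  times <- numeric(0)
  t <- start_offset
  while (t <= horizon) {
    times <- c(times, t)
    epoch <- min(sum(trans_times <= t) + 1L, length(gaps))
    t <- t + gaps[epoch]
  }
  if (length(times) == 0L) return(list(times = numeric(0), values = numeric(0)))
  m <- mu(times, w, long_model, b)
  values <- m + stats::rnorm(length(times), 0, sqrt(long_model$sigma_e2))
  list(times = times, values = values)
}

#' Simulation configuration
#'
#' @param spec a [joint_model_spec()] with true parameter values.
#' @param n number of subjects.
#' @param censoring either `list(type = "uniform", lower, upper)` or
#'   `list(type = "fixed", value)`.
#' @param gaps per-epoch visit gaps.
#' @param covariates a `covariate_law` or list of them.
#' @param seed integer RNG seed recorded with the output.
#' @param start_offset first-visit time.
#' @param initial_state starting state.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(spec, n, censoring, gaps, covariates,
                              seed = 1L, start_offset = 0, initial_state = 0L) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (censoring$type == "uniform" && censoring$lower >= censoring$upper) {
    stop("censoring support must be positive", call. = FALSE)
  }
  structure(
    list(spec = spec, n = as.integer(n), censoring = censoring, gaps = gaps,
         covariates = covariates, seed = as.integer(seed),
         start_offset = start_offset, initial_state = as.integer(initial_state)),
    class = "simulation_config"
  )
}

#' Simulate a joint longitudinal-multistate dataset
#'
#' @param config a [simulation_config()].
#' @return A `joint_data` object; attributes `b_true` (the generating random
#'   effects matrix), `W` (covariate matrix) and `config` are attached. Every
#'   simulated path is checked against the graph on construction.
#' @export
simulate_joint_data <- function(config) {
  set.seed(config$seed)
  spec <- config$spec
  n <- config$n
  W <- draw_covariates(n, config$covariates)
  b <- MASS::mvrnorm(n, rep(0, spec$long$basis$r), spec$long$Sigma_b)
  b <- matrix(b, n, spec$long$basis$r)
  C <- switch(config$censoring$type,
    uniform = stats::runif(n, config$censoring$lower, config$censoring$upper),
    fixed = rep(config$censoring$value, n),
    stop("unknown censoring type", call. = FALSE)
  )
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    w <- W[i, ]
    path <- simulate_event_process(b[i, ], w, C[i], spec,
                                   config$initial_state)
    vis <- simulate_visits_and_biomarker(
      path, C[i], config$gaps, spec$long, b[i, ], w, spec$graph,
      config$start_offset
    )
    if (length(vis$times) == 0L) {
      # horizon before the first scheduled visit: take a baseline measurement
      vis <- list(
        times = 0,
        values = mu(0, w, spec$long, b[i, ]) +
          stats::rnorm(1, 0, sqrt(spec$long$sigma_e2))
      )
    }
    subjects[[i]] <- subject_record(
      id = i, obs_times = vis$times, obs_values = vis$values, w = w,
      path = path, censor_time = C[i], graph = spec$graph
    )
  }
  out <- joint_data(subjects, spec$graph)
  attr(out, "b_true") <- b
  attr(out, "W") <- W
  attr(out, "config") <- config
  out
}

# ---------------------------------------------------------------------------
# Presets

#' Realistic five-state simulation preset (clock-reset Weibull)
#'
#' The eight-transition progressive graph of [illness_death_graph()] with
#' semi-Markov (clock-reset) Weibull baseline intensities, a current-value
#' association per transition, a random-intercept-and-slope Gaussian
#' trajectory, one standardized mixed-uniform "age" covariate, censoring
#' `C ~ U(13, 24)` and visit gaps `(2.6, 2, 1.2)` that tighten after the
#' first and second transitions.
#'
#' The generating parameter values are this package's own documented
#' defaults: the study this preset emulates calibrated its values by fitting
#' restricted clinical data and does not print them, so the defaults here are
#' synthetic (chosen so that every transition is observed with adequate
#' frequency at moderate sample sizes) and are not canonical.
#'
#' @param n number of subjects.
#' @param seed RNG seed.
#' @param overrides named list overriding non-structural config fields:
#'   `beta`, `sigma_e2`, `sd_b`, `rho_b`, and per-transition lists `shape`,
#'   `scale`, `gamma`, `alpha` (named by `"j->k"`), or `censoring`, `gaps`.
#' @return A [simulation_config()].
#' @export
model1_preset <- function(n, seed = 1L, overrides = list()) {
  if (!is.null(overrides$graph)) {
    stop("the preset graph is structural and cannot be overridden", call. = FALSE)
  }
  graph <- illness_death_graph()
  p <- utils::modifyList(list(
    beta = c(0.5, 0.08), sigma_e2 = 0.16, sd_b = c(0.5, 0.1), rho_b = -0.2,
    shape = c("0->1" = 1.2, "0->2" = 1.1, "0->4" = 1.3, "1->3" = 1.1,
              "1->4" = 1.2, "2->3" = 1.1, "2->4" = 1.2, "3->4" = 1.1),
    scale = c("0->1" = 0.045, "0->2" = 0.045, "0->4" = 0.020, "1->3" = 0.080,
              "1->4" = 0.050, "2->3" = 0.070, "2->4" = 0.050, "3->4" = 0.110),
    gamma = c("0->1" = 0.30, "0->2" = 0.15, "0->4" = 0.45, "1->3" = 0.20,
              "1->4" = 0.40, "2->3" = 0.25, "2->4" = 0.40, "3->4" = 0.35),
    alpha = c("0->1" = 0.50, "0->2" = -0.30, "0->4" = 0.60, "1->3" = 0.40,
              "1->4" = 0.30, "2->3" = -0.20, "2->4" = 0.40, "3->4" = 0.50),
    censoring = list(type = "uniform", lower = 13, upper = 24),
    gaps = c(2.6, 2, 1.2)
  ), overrides)
  Sigma_b <- diag(p$sd_b) %*% matrix(c(1, p$rho_b, p$rho_b, 1), 2) %*% diag(p$sd_b)
  long <- long_model(long_basis("intercept_slope"), p$beta, p$sigma_e2, Sigma_b)
  ids <- transition_id(graph$transitions[, 1], graph$transitions[, 2])
  trans <- lapply(ids, function(id) {
    transition_model(
      from = as.integer(sub("->.*", "", id)),
      to = as.integer(sub(".*->", "", id)),
      baseline = weibull_baseline(p$shape[[id]], p$scale[[id]]),
      timescale = "clock_reset",
      gamma = p$gamma[[id]],
      assoc = association("current_value", p$alpha[[id]])
    )
  })
  names(trans) <- ids
  spec <- joint_model_spec(graph, long, trans)
  simulation_config(
    spec, n, censoring = p$censoring, gaps = p$gaps,
    covariates = age_mixture_law(), seed = seed
  )
}

#' Nonlinear-trajectory ten-transition preset (clock-forward B-splines)
#'
#' The ten-transition graph of [extended_graph()] with Markov
#' (clock-forward) log-B-spline baseline intensities for the anchor
#' transitions 0->1, 0->3 and 0->4, the remaining baselines proportional to
#' an anchor through a free log-rescale constant (default anchor map: by
#' target state, transitions into 3 anchored at 0->3, into 4 at 0->4, all
#' others at 0->1), a nonlinear-decay trajectory with covariate-interacted
#' fixed effects and three random effects, censoring `C ~ U(4, 24)` and an
#' equidistant visit gap of 1. Parameter defaults are synthetic and
#' non-canonical (see [model1_preset()]); the anchor map is configurable via
#' `overrides$anchor`.
#'
#' @inheritParams model1_preset
#' @return A [simulation_config()].
#' @export
model2_preset <- function(n, seed = 1L, overrides = list()) {
  if (!is.null(overrides$graph)) {
    stop("the preset graph is structural and cannot be overridden", call. = FALSE)
  }
  graph <- extended_graph()
  ids <- transition_id(graph$transitions[, 1], graph$transitions[, 2])
  default_anchor <- vapply(ids, function(id) {
    to <- as.integer(sub(".*->", "", id))
    switch(as.character(to), "3" = "0->3", "4" = "0->4", "0->1")
  }, "")
  p <- utils::modifyList(list(
    beta = c(1.2, 0.25, 1.5, 0.30, 0.10, 0.04),
    sigma_e2 = 0.25, sd_b = c(0.7, 0.9, 0.08),
    R_b = matrix(c(1, 0.2, -0.1, 0.2, 1, 0.1, -0.1, 0.1, 1), 3),
    eta = list(
      "0->1" = c(-2.8, -2.6, -2.4, -2.3, -2.2),
      "0->3" = c(-4.2, -3.8, -3.5, -3.3, -3.1),
      "0->4" = c(-3.8, -3.5, -3.2, -3.0, -2.8)
    ),
    boundary_knots = c(0, 24), interior_knots = 6,
    log_rescale = c("0->2" = -0.2, "1->2" = 0.1, "1->3" = 0.4, "1->4" = 0.3,
                    "2->3" = 0.4, "2->4" = 0.3, "3->4" = 0.8),
    gamma = c("0->1" = 0.25, "0->2" = 0.15, "0->3" = 0.20, "0->4" = 0.40,
              "1->2" = 0.15, "1->3" = 0.20, "1->4" = 0.35, "2->3" = 0.20,
              "2->4" = 0.35, "3->4" = 0.30),
    alpha = c("0->1" = 0.25, "0->2" = -0.15, "0->3" = 0.30, "0->4" = 0.35,
              "1->2" = 0.15, "1->3" = 0.25, "1->4" = 0.30, "2->3" = -0.10,
              "2->4" = 0.30, "3->4" = 0.35),
    anchor = default_anchor,
    censoring = list(type = "uniform", lower = 4, upper = 24),
    gaps = 1
  ), overrides)
  Sigma_b <- diag(p$sd_b) %*% p$R_b %*% diag(p$sd_b)
  long <- long_model(long_basis("nonlinear_decay"), p$beta, p$sigma_e2, Sigma_b)
  trans <- lapply(ids, function(id) {
    baseline <- if (id %in% names(p$eta)) {
      bspline_baseline(p$eta[[id]], p$boundary_knots, p$interior_knots)
    } else {
      proportional_baseline(p$anchor[[id]], p$log_rescale[[id]])
    }
    transition_model(
      from = as.integer(sub("->.*", "", id)),
      to = as.integer(sub(".*->", "", id)),
      baseline = baseline,
      timescale = "clock_forward",
      gamma = p$gamma[[id]],
      assoc = association("current_value", p$alpha[[id]])
    )
  })
  names(trans) <- ids
  spec <- joint_model_spec(graph, long, trans)
  simulation_config(
    spec, n, censoring = p$censoring, gaps = p$gaps,
    covariates = age_mixture_law(), seed = seed
  )
}
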