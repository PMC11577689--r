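#' Blockwise model comparison by PSIS-LOO
#'
#' The leave-one-out unit is the subject: `D_i` couples the subject's
#' longitudinal record (restricted to the block's index set for blockwise
#' fits) with the subject's block event outcome. The LOO expected log
#' pointwise predictive density is estimated from posterior draws by
#' importance sampling with Pareto-smoothed tails: per subject, the raw
#' importance ratios `1 / f(D_i | draw)` have their largest
#' `min(0.2 S, 3 sqrt(S))` values replaced by expected order statistics of a
#' generalized Pareto distribution fitted to the ratio tail, whose shape
#' `k-hat` diagnoses estimator reliability (values above 0.7 are flagged).
#'
#' @name model_selection
NULL

#' Pointwise joint log-likelihood matrix of a fit
#'
#' Every `posterior_fit` carries the draws-by-subjects matrix of pointwise
#' joint log densities `log f(y_i | b_i, theta) + log f(event_i | b_i,
#' theta)`, accumulated during sampling. This accessor recomputes the matrix
#' from the stored parameter and random-effect draws through the reference
#' likelihood functions when `recompute = TRUE` (requires a fit run with
#' `store_random_effects = TRUE`), providing an independent cross-check of
#' the sampler's cached evaluation.
#'
#' @param fit a `posterior_fit`.
#' @param data the `joint_data` (jm_msm) or `block_dataset` the fit
#'   conditioned on; only needed when recomputing.
#' @param spec the [joint_model_spec()] used for fitting; only needed when
#'   recomputing.
#' @param recompute recompute through the reference likelihood path.
#' @return Matrix draws x subjects.
#' @export
pointwise_joint_loglik <- function(fit, data = NULL, spec = NULL,
                                   recompute = FALSE) {
  if (!recompute) return(fit$pointwise)
  if (is.null(fit$b_draws)) {
    stop("recomputation needs random-effect draws; refit with store_random_effects = TRUE",
         call. = FALSE)
  }
  if (is.null(data) || is.null(spec)) {
    stop("recomputation needs `data` and `spec`", call. = FALSE)
  }
  b_all <- do.call(abind_first, fit$b_draws)
  S <- nrow(fit$draws)
  n <- dim(b_all)[2]
  out <- matrix(NA_real_, S, n)
  for (s in seq_len(S)) {
    theta <- theta_from_draw(fit, s, spec)
    sp <- set_parameters(spec, theta)
    b <- matrix(b_all[s, , ], n)
    if (fit$approach == "jm_msm") {
      for (i in seq_len(n)) {
        subj <- data$subjects[[i]]
        out[s, i] <- multistate_loglik(subj, sp, b[i, ]) +
          longitudinal_loglik(subj, seq_along(subj$obs_times), sp$long, b[i, ])
      }
    } else {
      ev <- if (fit$approach == "jm_cr") {
        competing_risk_loglik(data, sp, b)
      } else {
        single_transition_loglik(data, sp, b)
      }
      for (i in seq_len(n)) {
        subj <- data$data$subjects[[data$members[i]]]
        out[s, i] <- ev[i] +
          longitudinal_loglik(subj, data$long_index[[i]], sp$long, b[i, ])
      }
    }
  }
  out
}

abind_first <- function(...) {
  arrs <- list(...)
  if (length(arrs) == 1L) return(arrs[[1]])
  do.call(abind_first2, arrs)
}
abind_first2 <- function(a, b, ...) {
  out <- array(NA_real_, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  if (length(list(...)) > 0) abind_first2(out, ...) else out
}

# reconstruct a theta parameter set from one row of the draws matrix
theta_from_draw <- function(fit, s, spec) {
  d <- fit$draws[s, ]
  nm <- colnames(fit$draws)
  r <- spec$long$basis$r
  beta <- unname(d[grep("^beta[0-9]+$", nm)])
  sd_b <- unname(d[grep("^sd_b[0-9]+$", nm)])
  R <- diag(r)
  for (j in grep("^rho_b", nm)) {
    ij <- as.integer(strsplit(sub("rho_b", "", nm[j]), "")[[1]])
    R[ij[1], ij[2]] <- R[ij[2], ij[1]] <- d[j]
  }
  trans <- list()
  for (id in names(spec$trans)) {
    pref <- paste0(id, ".")
    sel <- startsWith(nm, pref)
    pars <- d[sel]
    pn <- sub(pref, "", nm[sel], fixed = TRUE)
    tp <- list()
    if ("shape" %in% pn) tp$shape <- unname(pars[pn == "shape"])
    if ("scale" %in% pn) tp$scale <- unname(pars[pn == "scale"])
    if (any(startsWith(pn, "eta"))) tp$eta <- unname(pars[startsWith(pn, "eta")])
    if ("log_rescale" %in% pn) tp$log_rescale <- unname(pars[pn == "log_rescale"])
    tp$gamma <- unname(pars[startsWith(pn, "gamma")])
    tp$alpha <- unname(pars[startsWith(pn, "alpha")])
    trans[[id]] <- tp
  }
  list(beta = beta, sigma_e2 = unname(d[["sigma_e2"]]), sd_b = sd_b, R_b = R,
       trans = trans)
}

# Zhang & Stephens (2009) profile-posterior fit of the generalized Pareto to
# exceedances x > 0; returns shape k and scale sigma with quantile function
# q(p) = sigma * ((1 - p)^(-k) - 1) / k.
fit_gpd <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  jj <- seq_len(m)
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), 0)
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- 1 / vapply(jj, function(j) sum(exp(l_j - l_j[j])), 0)
  th_hat <- sum(theta * w)
  k <- -mean(log1p(-th_hat * x))
  list(k = k, sigma = k / th_hat)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * ((1 - p)^(-k) - 1) / k
}

#' PSIS leave-one-out cross-validation
#'
#' @param pointwise draws x subjects matrix of joint pointwise log
#'   likelihoods (see [pointwise_joint_loglik()]).
#' @return A `loo_result`: `elpd_loo` (sum of pointwise contributions), `se`,
#'   `pointwise` (per-subject elpd), `pareto_k` (per-subject tail-shape
#'   diagnostic; `-Inf` when the tail was too short to smooth), `n`.
#'   Subjects with `k-hat > 0.7` trigger a warning.
#' @export
psis_loo <- function(pointwise) {
  S <- nrow(pointwise)
  n <- ncol(pointwise)
  if (is.null(S) || S < 2L) stop("need at least 2 draws", call. = FALSE)
  if (!all(is.finite(pointwise))) stop("pointwise log-likelihoods must be finite", call. = FALSE)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  elpd <- numeric(n)
  khat <- numeric(n)
  for (i in seq_len(n)) {
    ll <- pointwise[, i]
    if (stats::sd(ll) == 0) {
      stop("degenerate pointwise column (all draws identical) for subject ", i,
           call. = FALSE)
    }
    lr <- -ll
    lr <- lr - max(lr)
    rw <- exp(lr) # raw ratios, max 1
    ord <- order(rw)
    tail_idx <- ord[(S - M + 1):S]
    u <- rw[ord[S - M]]
    exc <- rw[tail_idx] - u
    if (max(exc) <= 0) {
      khat[i] <- -Inf
      w <- rw
    } else {
      gp <- fit_gpd(exc[exc > 0])
      khat[i] <- gp$k
      z <- rank(rw[tail_idx], ties.method = "first")
      sm <- u + qgpd((z - 0.5) / M, gp$k, gp$sigma)
      w <- rw
      w[tail_idx] <- pmin(sm, max(rw))
    }
    lw <- log(w)
    elpd[i] <- logsumexp(lw + ll) - logsumexp(lw)
  }
  if (any(khat > 0.7)) {
    warning(sum(khat > 0.7), " subject(s) with Pareto k-hat > 0.7; ",
            "the PSIS-LOO estimate may be unreliable for them", call. = FALSE)
  }
  structure(
    list(
      elpd_loo = sum(elpd), se = sqrt(n * stats::var(elpd)),
      pointwise = elpd, pareto_k = khat, n = n
    ),
    class = "loo_result"
  )
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd = %.2f (SE %.2f) over %d subjects; max k-hat %.2f\n",
              x$elpd_loo, x$se, x$n, max(x$pareto_k)))
  invisible(x)
}

#' Compare candidate models on the same block data
#'
#' Candidates must be computed on identical subject sets (same block, same
#' members). Differences are computed pointwise against the top-ranked
#' candidate, with the standard error of each elpd difference taken over the
#' per-subject contributions.
#'
#' @param loo_results named list of `loo_result`s.
#' @return data.frame ranked by descending `elpd_loo`, with `elpd_diff` and
#'   `se_diff` relative to the best candidate.
#' @export
compare_models <- function(loo_results) {
  if (is.null(names(loo_results)) || any(!nzchar(names(loo_results)))) {
    names(loo_results) <- paste0("model", seq_along(loo_results))
  }
  ns <- vapply(loo_results, `[[`, 0L, "n")
  if (length(unique(ns)) != 1L) {
    stop("candidates were computed on different subject sets", call. = FALSE)
  }
  elpd <- vapply(loo_results, `[[`, 0, "elpd_loo")
  ord <- order(elpd, decreasing = TRUE)
  best <- loo_results[[ord[1]]]
  rows <- lapply(ord, function(k) {
    lr <- loo_results[[k]]
    dif <- lr$pointwise - best$pointwise
    data.frame(
      model = names(loo_results)[k],
      elpd_loo = lr$elpd_loo, se = lr$se,
      elpd_diff = sum(dif),
      se_diff = sqrt(lr$n * stats::var(dif))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
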