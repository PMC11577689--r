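#' Posterior sampling for the three inference strategies
#'
#' One sampling backend serves all three strategies: an adaptive
#' Metropolis-within-Gibbs sampler on the unconstrained parameter scale,
#' exploiting the exact factorization of the event likelihood over
#' transitions. Parameter groups (one per transition — or per anchor cluster
#' when baselines are tied proportionally — plus the fixed effects, the
#' residual variance, and the random-effect covariance) are updated with
#' multivariate random-walk proposals whose scale and covariance adapt during
#' burn-in; subject random effects are updated jointly across subjects with
#' independent per-subject accept/reject decisions. Adaptation is frozen at
#' the end of burn-in.
#'
#' @name inference
NULL

#' Sampler configuration
#'
#' @param n_draws posterior draws to keep per chain (post burn-in).
#' @param burn_in burn-in (and adaptation) iterations.
#' @param chains number of chains, run sequentially with seeds
#'   `seed, seed + 1, ...`.
#' @param seed integer RNG seed; recorded in the fit.
#' @param init `"zeros"` (all parameters at zero on the unconstrained scale)
#'   or `"random"` (overdispersed normal jitter).
#' @param Q Gauss-Legendre node count for cumulative intensities.
#' @param store_random_effects keep the random-effect draws (memory permitting).
#' @return A `sampler_config` object.
#' @export
sampler_config <- function(n_draws = 1000L, burn_in = 300L, chains = 1L,
                           seed = 1L, init = c("zeros", "random"), Q = 15L,
                           store_random_effects = FALSE) {
  init <- match.arg(init)
  if (n_draws < 1L) stop("n_draws must be at least 1", call. = FALSE)
  if (burn_in < 0L) stop("burn_in must be nonnegative", call. = FALSE)
  structure(
    list(n_draws = as.integer(n_draws), burn_in = as.integer(burn_in),
         chains = as.integer(chains), seed = as.integer(seed), init = init,
         Q = as.integer(Q), store_random_effects = store_random_effects),
    class = "sampler_config"
  )
}

# ---------------------------------------------------------------------------
# Workspace: precomputed design and quadrature structures

# one event view = one transition restricted to its risk set
make_view <- function(id, from, to, subj, entry, exit, event, W, spec, Q,
                      need_slope) {
  M <- length(subj)
  rule <- gauss_legendre_rule(Q)
  halfw <- (exit - entry) / 2
  mid <- (exit + entry) / 2
  tq <- outer(halfw, rule$nodes) + mid        # M x Q study times
  tm <- spec$trans[[id]]
  reset <- tm$timescale == "clock_reset"
  bq <- if (reset) tq - entry else tq
  be <- if (reset) exit - entry else exit
  bs <- spec$long$basis
  mrep <- rep(seq_len(M), Q)
  Wq <- W[mrep, , drop = FALSE]
  tqv <- as.vector(tq)
  v <- list(
    id = id, from = from, to = to, M = M, Q = Q, subj = subj,
    entry = entry, exit = exit, event = as.integer(event),
    W = W, halfw = halfw, wstd = rule$weights, mrep = mrep,
    subj_q = subj[mrep],
    Xq = bs$X(tqv, Wq), Zq = bs$Z(tqv),
    Xe = bs$X(exit, W), Ze = bs$Z(exit),
    kind = tm$assoc$kind
  )
  bl <- tm$baseline
  v$bl_family <- bl$family
  if (bl$family == "weibull") {
    v$log_bq <- log(as.vector(bq))
    v$log_be <- log(be)
  } else {
    base <- if (bl$family == "proportional") {
      spec$trans[[bl$anchor]]$baseline
    } else {
      bl
    }
    v$anchor <- if (bl$family == "proportional") bl$anchor else id
    spl <- function(u) {
      splines::splineDesign(
        knots = c(rep(base$boundary_knots[1], base$degree + 1),
                  base$interior_knots,
                  rep(base$boundary_knots[2], base$degree + 1)),
        x = pmin(pmax(u, base$boundary_knots[1]), base$boundary_knots[2]),
        ord = base$degree + 1
      )
    }
    v$Bq <- spl(as.vector(bq))
    v$Be <- spl(be)
  }
  if (need_slope) {
    v$dXq <- bs$dX(tqv, Wq); v$dZq <- bs$dZ(tqv)
    v$dXe <- bs$dX(exit, W); v$dZe <- bs$dZ(exit)
  }
  if (tm$assoc$kind == "current_value_by_covariate") {
    v$wcov <- W[, tm$assoc$covariate]
  }
  v
}

# Build the sampling workspace for one strategy.
#  - jm_msm: data = joint_data, all transitions, all measurements
#  - jm_cr:  data = block_dataset (competing-risk), the block's transitions
#  - jm_st:  data = block_dataset from single_transition_view()
build_workspace <- function(approach, data, spec, Q = 15L,
                            entry_adjusted = character(0), entry_scale = 1) {
  bs <- spec$long$basis
  need_slope <- any(vapply(spec$trans, function(m) m$assoc$kind == "current_slope", TRUE))
  if (approach == "jm_msm") {
    subjects <- data$subjects
    n <- length(subjects)
    subj_global <- seq_len(n)
    # event views: one per transition over the full data
    blocks <- competing_risk_blocks(data$graph)
    views <- list()
    for (blk in blocks) {
      mem <- integer(0); ent <- numeric(0); ext <- numeric(0); tgt <- integer(0)
      Wl <- list()
      for (i in seq_len(n)) {
        s <- subjects[[i]]
        pos <- match(blk$initial_state, s$path[, 1])
        if (is.na(pos)) next
        e0 <- s$path[pos, 2]
        if (pos < nrow(s$path)) {
          e1 <- s$path[pos + 1, 2]; tg <- s$path[pos + 1, 1]
        } else {
          e1 <- s$censor_time; tg <- NA_integer_
        }
        if (e1 <= e0) next
        mem <- c(mem, i); ent <- c(ent, e0); ext <- c(ext, e1); tgt <- c(tgt, tg)
        w <- s$w
        if (length(entry_adjusted) > 0L) {
          w[entry_adjusted] <- w[entry_adjusted] + e0 / entry_scale
        }
        Wl <- c(Wl, list(w))
      }
      if (length(mem) == 0L) next
      W <- do.call(rbind, Wl)
      if (is.null(W)) W <- matrix(0, length(mem), 0)
      for (k in blk$terminal_states) {
        id <- transition_id(blk$initial_state, k)
        views[[id]] <- make_view(
          id, blk$initial_state, k, mem, ent, ext,
          !is.na(tgt) & tgt == k, W, spec, Q, need_slope
        )
      }
    }
    # longitudinal: all measurements
    li <- lapply(seq_len(n), function(i) seq_along(subjects[[i]]$obs_times))
    long_subjects <- subjects
    loc_of <- seq_len(n)
  } else {
    bd <- data
    subjects <- bd$data$subjects
    subj_global <- bd$members
    n <- length(subj_global)
    loc_of <- seq_len(n)
    if (approach == "jm_cr") {
      j <- bd$block$initial_state
      views <- lapply(bd$block$terminal_states, function(k) {
        make_view(
          transition_id(j, k), j, k, loc_of, bd$entry, bd$exit,
          !is.na(bd$event_target) & bd$event_target == k,
          bd$W, spec, Q, need_slope
        )
      })
      names(views) <- transition_id(j, bd$block$terminal_states)
    } else {
      id <- transition_id(bd$block$from_state, bd$block$to_state)
      views <- list(make_view(
        id, bd$block$from_state, bd$block$to_state, loc_of,
        bd$entry, bd$exit, bd$event, bd$W, spec, Q, need_slope
      ))
      names(views) <- id
    }
    li <- bd$long_index
    long_subjects <- lapply(subj_global, function(i) subjects[[i]])
  }
  # stacked longitudinal design
  t_all <- unlist(lapply(seq_len(n), function(m) long_subjects[[m]]$obs_times[li[[m]]]))
  y_all <- unlist(lapply(seq_len(n), function(m) long_subjects[[m]]$obs_values[li[[m]]]))
  subj_obs <- rep(seq_len(n), vapply(li, length, 1L))
  Wlong <- do.call(rbind, lapply(seq_len(n), function(m) {
    w <- long_subjects[[m]]$w
    matrix(w, length(li[[m]]), length(w), byrow = TRUE)
  }))
  if (is.null(Wlong)) Wlong <- matrix(0, length(t_all), 0)
  list(
    approach = approach, n = n, subj_global = subj_global,
    q1 = bs$q1, r = bs$r,
    q2 = if (length(views) > 0) ncol(views[[1]]$W) else 0L,
    views = views, trans_ids = names(views),
    long = list(
      y = y_all, t = t_all, subj = subj_obs,
      X = bs$X(t_all, Wlong), Z = bs$Z(t_all), n_obs = length(y_all)
    ),
    need_slope = need_slope
  )
}

# ---------------------------------------------------------------------------
# Unconstrained parameterization

# C-vine partial correlations -> correlation matrix (Joe 2006 recursion)
vine_to_corr <- function(p, r) {
  P <- matrix(0, r, r)
  P[upper.tri(P)] <- p
  R <- diag(r)
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      rho <- P[i, j]
      if (i > 1) {
        for (k in (i - 1):1) {
          rho <- rho * sqrt((1 - P[k, i]^2) * (1 - P[k, j]^2)) + P[k, i] * P[k, j]
        }
      }
      R[i, j] <- R[j, i] <- rho
    }
  }
  R
}

# parameter map: list of segments over the unconstrained vector
build_param_map <- function(ws, spec, priors) {
  segs <- list()
  pos <- 0L
  add <- function(seg, len) {
    seg$idx <- pos + seq_len(len)
    pos <<- pos + len
    segs[[length(segs) + 1L]] <<- seg
  }
  r <- ws$r
  add(list(kind = "beta"), ws$q1)
  add(list(kind = "lsig"), 1L)
  nz <- r * (r - 1) / 2
  # Beta shape per vine level; rho_beta overrides LKJ when supplied
  lev <- unlist(lapply(seq_len(max(r - 1, 0)), function(i) rep(i, r - i)))
  a_lev <- if (!is.null(priors$rho_beta)) {
    rep(priors$rho_beta, nz)
  } else {
    priors$lkj_eta + (r - 1 - lev) / 2
  }
  add(list(kind = "re", r = r, nz = nz, a_lev = a_lev), r + nz)
  # transition clusters: proportional baselines sample with their anchor
  anchor_of <- vapply(ws$trans_ids, function(id) {
    bl <- spec$trans[[id]]$baseline
    if (bl$family == "proportional") bl$anchor else id
  }, "")
  if (!all(anchor_of %in% ws$trans_ids)) {
    stop("proportional baseline whose anchor transition is not part of this fit; ",
         "specify a free baseline for blockwise fitting", call. = FALSE)
  }
  clusters <- split(ws$trans_ids, factor(anchor_of, levels = unique(anchor_of)))
  for (cl in clusters) {
    layout <- list()
    len <- 0L
    for (id in cl) {
      tm <- spec$trans[[id]]
      bl <- tm$baseline
      nb <- switch(bl$family, weibull = 2L, bspline = length(bl$eta),
                   proportional = 1L)
      na <- n_alpha(tm$assoc, r)
      layout[[id]] <- list(family = bl$family, nb = nb,
                           ng = length(tm$gamma), na = na)
      len <- len + nb + layout[[id]]$ng + na
    }
    add(list(kind = "trans", ids = cl, layout = layout), len)
  }
  list(segments = segs, n_par = pos)
}

decode_segment <- function(seg, u) {
  switch(seg$kind,
    beta = list(beta = u),
    lsig = list(sigma_e2 = exp(u)),
    re = {
      r <- seg$r
      sd_b <- exp(u[seq_len(r)])
      p <- tanh(u[r + seq_len(seg$nz)])
      R <- if (seg$nz > 0) vine_to_corr(p, r) else diag(r)
      Sigma <- diag(sd_b, r) %*% R %*% diag(sd_b, r)
      list(sd_b = sd_b, p = p, R_b = R, Sigma_b = Sigma)
    },
    trans = {
      out <- list()
      at <- 0L
      for (id in names(seg$layout)) {
        ly <- seg$layout[[id]]
        bpar <- u[at + seq_len(ly$nb)]; at <- at + ly$nb
        gpar <- u[at + seq_len(ly$ng)]; at <- at + ly$ng
        apar <- u[at + seq_len(ly$na)]; at <- at + ly$na
        tp <- switch(ly$family,
          weibull = list(shape = exp(bpar[1]), scale = exp(bpar[2])),
          bspline = list(eta = bpar),
          proportional = list(log_rescale = bpar)
        )
        tp$gamma <- gpar
        tp$alpha <- apar
        out[[id]] <- tp
      }
      out
    }
  )
}

# log prior + log Jacobian of the transform, per segment
segment_lp <- function(seg, u, dec, priors) {
  switch(seg$kind,
    beta = sum(stats::dnorm(dec$beta, 0, priors$sd_beta, log = TRUE)),
    lsig = log_dinvgamma(dec$sigma_e2, priors$ig_shape, priors$ig_scale) + u,
    re = {
      lp <- sum(log_dhalfcauchy(dec$sd_b, priors$hc_re_sd)) + sum(log(dec$sd_b))
      if (seg$nz > 0) {
        p <- dec$p
        lp <- lp + sum(stats::dbeta((p + 1) / 2, seg$a_lev, seg$a_lev, log = TRUE) +
                         log((1 - p^2) / 2))
      }
      lp
    },
    trans = {
      lp <- 0
      for (id in names(seg$layout)) {
        ly <- seg$layout[[id]]
        tp <- dec[[id]]
        lp <- lp + switch(ly$family,
          weibull = log_dhalfcauchy(tp$shape, priors$hc_weibull) +
            log_dhalfcauchy(tp$scale, priors$hc_weibull) +
            log(tp$shape) + log(tp$scale),
          bspline = sum(stats::dnorm(tp$eta, 0, priors$sd_eta, log = TRUE)),
          proportional = stats::dnorm(tp$log_rescale, 0, priors$sd_eta, log = TRUE)
        )
        lp <- lp + sum(stats::dnorm(tp$gamma, 0, priors$sd_gamma, log = TRUE)) +
          sum(stats::dnorm(tp$alpha, 0, priors$sd_alpha, log = TRUE))
      }
      lp
    }
  )
}

# flatten decoded parameters into a named natural-scale vector
flatten_theta <- function(beta, sigma_e2, re, trans) {
  out <- c(beta, sigma_e2, re$sd_b)
  nm <- c(paste0("beta", seq_along(beta)), "sigma_e2",
          paste0("sd_b", seq_along(re$sd_b)))
  r <- length(re$sd_b)
  if (r > 1) {
    ut <- which(upper.tri(re$R_b), arr.ind = TRUE)
    out <- c(out, re$R_b[upper.tri(re$R_b)])
    nm <- c(nm, sprintf("rho_b%d%d", ut[, 1], ut[, 2]))
  }
  for (id in names(trans)) {
    tp <- trans[[id]]
    if (!is.null(tp$shape)) {
      out <- c(out, tp$shape, tp$scale)
      nm <- c(nm, paste0(id, ".shape"), paste0(id, ".scale"))
    }
    if (!is.null(tp$eta)) {
      out <- c(out, tp$eta)
      nm <- c(nm, paste0(id, ".eta", seq_along(tp$eta)))
    }
    if (!is.null(tp$log_rescale)) {
      out <- c(out, tp$log_rescale)
      nm <- c(nm, paste0(id, ".log_rescale"))
    }
    if (length(tp$gamma) > 0) {
      out <- c(out, tp$gamma)
      nm <- c(nm, paste0(id, ".gamma", seq_along(tp$gamma)))
    }
    if (length(tp$alpha) > 0) {
      out <- c(out, tp$alpha)
      nm <- c(nm, paste0(id, ".alpha", seq_along(tp$alpha)))
    }
  }
  stats::setNames(out, nm)
}

# ---------------------------------------------------------------------------
# Fast likelihood evaluation on the workspace

# trajectory values at a view's quadrature nodes and exit times
view_mu <- function(v, beta, b, need_slope) {
  out <- list(
    mu_q = drop(v$Xq %*% beta) + rowSums(v$Zq * b[v$subj_q, , drop = FALSE]),
    mu_e = drop(v$Xe %*% beta) + rowSums(v$Ze * b[v$subj, , drop = FALSE])
  )
  if (need_slope) {
    out$dmu_q <- drop(v$dXq %*% beta) + rowSums(v$dZq * b[v$subj_q, , drop = FALSE])
    out$dmu_e <- drop(v$dXe %*% beta) + rowSums(v$dZe * b[v$subj, , drop = FALSE])
  }
  out
}

# per-member event log-likelihood of a view given its transition parameters
# (anchor_eta supplies the spline coefficients for proportional baselines)
view_loglik <- function(v, tp, muv, b, anchor_eta = NULL) {
  lh0q <- switch(v$bl_family,
    weibull = log(tp$shape) + (tp$shape - 1) * v$log_bq + log(tp$scale),
    bspline = drop(v$Bq %*% tp$eta),
    proportional = drop(v$Bq %*% anchor_eta) + tp$log_rescale
  )
  lh0e <- switch(v$bl_family,
    weibull = log(tp$shape) + (tp$shape - 1) * v$log_be + log(tp$scale),
    bspline = drop(v$Be %*% tp$eta),
    proportional = drop(v$Be %*% anchor_eta) + tp$log_rescale
  )
  linp <- if (length(tp$gamma) > 0) drop(v$W %*% tp$gamma) else numeric(v$M)
  a <- tp$alpha
  assoc_q <- switch(v$kind,
    none = 0,
    current_value = a * muv$mu_q,
    current_slope = a * muv$dmu_q,
    shared_random_effects = drop(b[v$subj_q, , drop = FALSE] %*% a),
    current_value_quadratic = a[1] * muv$mu_q + a[2] * muv$mu_q^2,
    current_value_by_covariate = a[1] * muv$mu_q + a[2] * v$wcov[v$mrep] * muv$mu_q
  )
  assoc_e <- switch(v$kind,
    none = 0,
    current_value = a * muv$mu_e,
    current_slope = a * muv$dmu_e,
    shared_random_effects = drop(b[v$subj, , drop = FALSE] %*% a),
    current_value_quadratic = a[1] * muv$mu_e + a[2] * muv$mu_e^2,
    current_value_by_covariate = a[1] * muv$mu_e + a[2] * v$wcov * muv$mu_e
  )
  logh_q <- lh0q + linp[v$mrep] + assoc_q
  H <- v$halfw * drop(matrix(exp(logh_q), v$M, v$Q) %*% v$wstd)
  logh_e <- lh0e + linp + assoc_e
  ifelse(v$event == 1L, logh_e, 0) - H
}

long_loglik_obs <- function(ws, beta, b, sigma_e2) {
  m <- drop(ws$long$X %*% beta) + rowSums(ws$long$Z * b[ws$long$subj, , drop = FALSE])
  stats::dnorm(ws$long$y, m, sqrt(sigma_e2), log = TRUE)
}

# ---------------------------------------------------------------------------
# The Metropolis-within-Gibbs chain

run_chain <- function(ws, spec, priors, control, chain_seed) {
  set.seed(chain_seed)
  map <- build_param_map(ws, spec, priors)
  segs <- map$segments
  n <- ws$n; r <- ws$r
  u <- numeric(map$n_par)
  b <- matrix(0, n, r)
  if (control$init == "random") {
    u <- stats::rnorm(map$n_par, 0, 0.5)
    b <- matrix(stats::rnorm(n * r, 0, 0.5), n, r)
  }
  dec <- lapply(segs, function(s) decode_segment(s, u[s$idx]))
  lp_seg <- vapply(seq_along(segs), function(k) {
    segment_lp(segs[[k]], u[segs[[k]]$idx], dec[[k]], priors)
  }, 0)
  kind_of <- vapply(segs, `[[`, "", "kind")
  i_beta <- which(kind_of == "beta"); i_lsig <- which(kind_of == "lsig")
  i_re <- which(kind_of == "re"); i_tr <- which(kind_of == "trans")
  get_theta_trans <- function() {
    out <- list()
    for (k in i_tr) out <- c(out, dec[[k]])
    out
  }
  beta <- dec[[i_beta]]$beta
  sigma_e2 <- dec[[i_lsig]]$sigma_e2
  Sigma_b <- dec[[i_re]]$Sigma_b
  theta_tr <- get_theta_trans()
  # caches
  muv <- lapply(ws$views, view_mu, beta = beta, b = b, need_slope = ws$need_slope)
  anchor_eta <- function(v, th) if (is.null(v$anchor)) NULL else th[[v$anchor]]$eta
  vll <- lapply(seq_along(ws$views), function(k) {
    v <- ws$views[[k]]
    view_loglik(v, theta_tr[[v$id]], muv[[k]], b, anchor_eta(v, theta_tr))
  })
  ll_obs <- long_loglik_obs(ws, beta, b, sigma_e2)
  ll_long_subj <- as.vector(rowsum(ll_obs, ws$long$subj, reorder = TRUE))
  re_dens <- dmvnorm_log(b, Sigma_b)
  # beta affects a view unless its association ignores the trajectory mean
  beta_views <- which(vapply(ws$views, function(v)
    !(v$kind %in% c("none", "shared_random_effects")), TRUE))
  # adaptation state
  prop <- lapply(segs, function(s) {
    d <- length(s$idx)
    list(ls = log(2.38 / sqrt(d)) - 1, mean = numeric(d),
         M2 = matrix(0, d, d), count = 0, L = diag(d), target = if (d == 1) 0.44 else 0.234)
  })
  ls_b <- rep(-1, n)
  Lb <- chol(Sigma_b)
  n_iter <- control$burn_in + control$n_draws
  # output
  theta_nat <- flatten_theta(beta, sigma_e2, dec[[i_re]], theta_tr)
  draws <- matrix(NA_real_, control$n_draws, length(theta_nat),
                  dimnames = list(NULL, names(theta_nat)))
  pointwise <- matrix(NA_real_, control$n_draws, n)
  b_draws <- if (control$store_random_effects) {
    array(NA_real_, c(control$n_draws, n, r))
  } else NULL
  acc_seg <- numeric(length(segs))
  views_by_id <- stats::setNames(seq_along(ws$views), names(ws$views))
  # views whose likelihood depends on a given trans segment (own ids + any
  # proportional views anchored at one of them)
  seg_views <- lapply(segs, function(s) {
    if (s$kind != "trans") return(integer(0))
    dep <- vapply(ws$views, function(v) {
      v$id %in% s$ids || (!is.null(v$anchor) && v$anchor %in% s$ids)
    }, TRUE)
    which(dep)
  })
  adapt_gamma <- function(t) min(0.5, 3 / (t + 10)^0.6)

  for (t in seq_len(n_iter)) {
    adapting <- t <= control$burn_in
    # --- transition groups, residual variance, fixed effects, RE covariance
    for (k in seq_along(segs)) {
      s <- segs[[k]]
      d <- length(s$idx)
      step <- exp(prop[[k]]$ls) * drop(stats::rnorm(d) %*% prop[[k]]$L)
      u_new <- u[s$idx] + step
      dec_new <- decode_segment(s, u_new)
      lp_new <- segment_lp(s, u_new, dec_new, priors)
      if (is.finite(lp_new)) {
        if (s$kind == "trans") {
          th_new <- theta_tr
          for (id in names(dec_new)) th_new[[id]] <- dec_new[[id]]
          vll_new <- lapply(seg_views[[k]], function(vk) {
            v <- ws$views[[vk]]
            view_loglik(v, th_new[[v$id]], muv[[vk]], b, anchor_eta(v, th_new))
          })
          dll <- sum(unlist(vll_new)) - sum(unlist(vll[seg_views[[k]]]))
          ratio <- dll + lp_new - lp_seg[k]
          if (is.finite(ratio) && log(stats::runif(1)) < ratio) {
            u[s$idx] <- u_new; dec[[k]] <- dec_new; lp_seg[k] <- lp_new
            theta_tr <- th_new
            vll[seg_views[[k]]] <- vll_new
            acc <- 1
          } else acc <- if (is.finite(ratio)) min(1, exp(ratio)) else 0
        } else if (s$kind == "beta") {
          beta_new <- dec_new$beta
          ll_obs_new <- long_loglik_obs(ws, beta_new, b, sigma_e2)
          muv_new <- muv; vll_new <- vll
          for (vk in beta_views) {
            v <- ws$views[[vk]]
            muv_new[[vk]] <- view_mu(v, beta_new, b, ws$need_slope)
            vll_new[[vk]] <- view_loglik(v, theta_tr[[v$id]], muv_new[[vk]], b,
                                         anchor_eta(v, theta_tr))
          }
          dll <- sum(ll_obs_new) - sum(ll_obs) +
            sum(unlist(vll_new[beta_views])) - sum(unlist(vll[beta_views]))
          ratio <- dll + lp_new - lp_seg[k]
          if (is.finite(ratio) && log(stats::runif(1)) < ratio) {
            u[s$idx] <- u_new; dec[[k]] <- dec_new; lp_seg[k] <- lp_new
            beta <- beta_new; ll_obs <- ll_obs_new
            ll_long_subj <- as.vector(rowsum(ll_obs, ws$long$subj, reorder = TRUE))
            muv <- muv_new; vll <- vll_new
            acc <- 1
          } else acc <- if (is.finite(ratio)) min(1, exp(ratio)) else 0
        } else if (s$kind == "lsig") {
          sig_new <- dec_new$sigma_e2
          # residuals are unchanged; rescale the cached Gaussian terms:
          # q = res^2 / (2 sigma^2) recovered from the cached log density
          qres <- -ll_obs - 0.5 * log(2 * pi * sigma_e2)
          ll_obs_new <- -0.5 * log(2 * pi * sig_new) - qres * sigma_e2 / sig_new
          dll <- sum(ll_obs_new) - sum(ll_obs)
          ratio <- dll + lp_new - lp_seg[k]
          if (is.finite(ratio) && log(stats::runif(1)) < ratio) {
            u[s$idx] <- u_new; dec[[k]] <- dec_new; lp_seg[k] <- lp_new
            sigma_e2 <- sig_new; ll_obs <- ll_obs_new
            ll_long_subj <- as.vector(rowsum(ll_obs, ws$long$subj, reorder = TRUE))
            acc <- 1
          } else acc <- if (is.finite(ratio)) min(1, exp(ratio)) else 0
        } else { # re
          re_new <- dmvnorm_log(b, dec_new$Sigma_b)
          ratio <- sum(re_new) - sum(re_dens) + lp_new - lp_seg[k]
          if (is.finite(ratio) && log(stats::runif(1)) < ratio) {
            u[s$idx] <- u_new; dec[[k]] <- dec_new; lp_seg[k] <- lp_new
            Sigma_b <- dec_new$Sigma_b; re_dens <- re_new
            if (adapting) Lb <- chol(Sigma_b)
            acc <- 1
          } else acc <- if (is.finite(ratio)) min(1, exp(ratio)) else 0
        }
      } else acc <- 0
      acc_seg[k] <- acc_seg[k] + acc
      if (adapting) {
        pk <- prop[[k]]
        pk$ls <- pk$ls + adapt_gamma(t) * (acc - pk$target)
        pk$count <- pk$count + 1
        delta <- u[s$idx] - pk$mean
        pk$mean <- pk$mean + delta / pk$count
        pk$M2 <- pk$M2 + outer(delta, u[s$idx] - pk$mean)
        if (d > 1 && pk$count > 50 && pk$count %% 25 == 0) {
          cv <- pk$M2 / (pk$count - 1) + diag(1e-6, d)
          pk$L <- tryCatch(chol(cv), error = function(e) pk$L)
        }
        prop[[k]] <- pk
      }
    }
    # --- random effects: joint proposal, per-subject accept/reject
    eps <- (matrix(stats::rnorm(n * r), n, r) %*% Lb) * exp(ls_b)
    b_new <- b + eps
    ll_obs_new <- long_loglik_obs(ws, beta, b_new, sigma_e2)
    ll_long_new <- as.vector(rowsum(ll_obs_new, ws$long$subj, reorder = TRUE))
    re_new <- dmvnorm_log(b_new, Sigma_b)
    dll_subj <- (ll_long_new - ll_long_subj) + (re_new - re_dens)
    muv_new <- muv; vll_new <- vll
    for (vk in seq_along(ws$views)) {
      v <- ws$views[[vk]]
      muv_new[[vk]] <- view_mu(v, beta, b_new, ws$need_slope)
      vll_new[[vk]] <- view_loglik(v, theta_tr[[v$id]], muv_new[[vk]], b_new,
                                   anchor_eta(v, theta_tr))
      dv <- vll_new[[vk]] - vll[[vk]]
      dv[!is.finite(dv)] <- -Inf
      agg <- rowsum(dv, v$subj)
      idx <- as.integer(rownames(agg))
      dll_subj[idx] <- dll_subj[idx] + agg[, 1]
    }
    accept <- log(stats::runif(n)) < dll_subj
    accept[!is.finite(dll_subj)] <- FALSE
    if (any(accept)) {
      b[accept, ] <- b_new[accept, ]
      keep_obs <- accept[ws$long$subj]
      ll_obs[keep_obs] <- ll_obs_new[keep_obs]
      ll_long_subj[accept] <- ll_long_new[accept]
      re_dens[accept] <- re_new[accept]
      for (vk in seq_along(ws$views)) {
        v <- ws$views[[vk]]
        kq <- accept[v$subj_q]; km <- accept[v$subj]
        muv[[vk]]$mu_q[kq] <- muv_new[[vk]]$mu_q[kq]
        muv[[vk]]$mu_e[km] <- muv_new[[vk]]$mu_e[km]
        if (ws$need_slope) {
          muv[[vk]]$dmu_q[kq] <- muv_new[[vk]]$dmu_q[kq]
          muv[[vk]]$dmu_e[km] <- muv_new[[vk]]$dmu_e[km]
        }
        vll[[vk]][km] <- vll_new[[vk]][km]
      }
    }
    if (adapting) {
      ls_b <- ls_b + adapt_gamma(t) * (pmin(1, exp(dll_subj)) - 0.30)
    }
    # --- record
    if (t > control$burn_in) {
      s_idx <- t - control$burn_in
      draws[s_idx, ] <- flatten_theta(beta, sigma_e2, dec[[i_re]], theta_tr)
      ev_subj <- numeric(n)
      for (vk in seq_along(ws$views)) {
        v <- ws$views[[vk]]
        agg <- rowsum(vll[[vk]], v$subj)
        idx <- as.integer(rownames(agg))
        ev_subj[idx] <- ev_subj[idx] + agg[, 1]
      }
      pointwise[s_idx, ] <- ll_long_subj + ev_subj
      if (!is.null(b_draws)) b_draws[s_idx, , ] <- b
    }
  }
  list(
    draws = draws, pointwise = pointwise, b_draws = b_draws,
    accept_rates = acc_seg / n_iter, b_mean_accept = NA_real_
  )
}

# ---------------------------------------------------------------------------
# Fit drivers

new_posterior_fit <- function(approach, block_label, chains_out, ws, control,
                              seed, wall_time) {
  draws <- do.call(rbind, lapply(chains_out, `[[`, "draws"))
  pointwise <- do.call(rbind, lapply(chains_out, `[[`, "pointwise"))
  chain_id <- rep(seq_along(chains_out), each = control$n_draws)
  rhat <- apply(draws, 2, function(x) {
    split_rhat(matrix(x, ncol = length(chains_out)))
  })
  structure(
    list(
      approach = approach, block = block_label,
      draws = draws, chain_id = chain_id, pointwise = pointwise,
      b_draws = if (control$store_random_effects) {
        lapply(chains_out, `[[`, "b_draws")
      } else NULL,
      subjects = ws$subj_global,
      rhat = rhat,
      divergences = 0L,
      accept_rates = rowMeans(vapply(chains_out, `[[`,
                                     numeric(length(chains_out[[1]]$accept_rates)),
                                     "accept_rates")),
      n_draws = control$n_draws, chains = control$chains,
      burn_in = control$burn_in, seed = seed, wall_time = wall_time
    ),
    class = "posterior_fit"
  )
}

fit_workspace <- function(approach, data, spec, priors, control, block_label) {
  t0 <- proc.time()[["elapsed"]]
  ws <- build_workspace(approach, data, spec, control$Q)
  chains_out <- lapply(seq_len(control$chains), function(ch) {
    run_chain(ws, spec, priors, control, chain_seed = control$seed + ch - 1L)
  })
  wall <- proc.time()[["elapsed"]] - t0
  new_posterior_fit(approach, block_label, chains_out, ws, control,
                    control$seed, wall)
}

#' Fit the full joint longitudinal-multistate model (JM-MSM)
#'
#' Samples the joint posterior of all transition parameters, the longitudinal
#' parameters and all subjects' random effects, conditioning on the full
#' dataset.
#'
#' @param data a `joint_data` object.
#' @param spec a [joint_model_spec()] defining the model structure (its
#'   parameter values are ignored; sampling starts from the configured
#'   initialization).
#' @param priors a [prior_spec()].
#' @param control a [sampler_config()].
#' @return A `posterior_fit`.
#' @export
fit_jm_msm <- function(data, spec, priors = prior_spec(),
                       control = sampler_config()) {
  fit_workspace("jm_msm", data, spec, priors, control, "full")
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% .Machine$integer.max)
}

#' Fit joint longitudinal-competing-risk models per block (JM-CR)
#'
#' One independent posterior per competing-risk block, each conditioning only
#' on the block's risk set, its event view and the longitudinal measurements
#' assigned by `strategy`. Blocks are independent by construction; per-block
#' seeds are derived from `control$seed`, so a block's draws are identical
#' whether it is fitted alone or alongside the others.
#'
#' @inheritParams fit_jm_msm
#' @param strategy a [longitudinal_strategy()].
#' @param parallel fit blocks in parallel forked processes.
#' @param entry_adjusted,entry_scale see [build_block_dataset()].
#' @return Named list of `posterior_fit`s, one per non-empty block
#'   (`"B<initial state>"`); empty blocks are skipped with a warning.
#' @export
fit_jm_cr <- function(data, spec, priors = prior_spec(),
                      strategy = longitudinal_strategy("historical"),
                      control = sampler_config(), parallel = FALSE,
                      entry_adjusted = character(0), entry_scale = 1) {
  blocks <- competing_risk_blocks(data$graph)
  one <- function(vi) {
    blk <- blocks[[vi]]
    bd <- build_block_dataset(data, blk, strategy, entry_adjusted, entry_scale)
    if (length(bd$members) == 0L) {
      warning("block B", blk$initial_state, " has no members; skipped", call. = FALSE)
      return(NULL)
    }
    ctl <- control
    ctl$seed <- derive_seed(control$seed, vi)
    fit_workspace("jm_cr", bd, spec, priors, ctl,
                  paste0("B", blk$initial_state))
  }
  fits <- if (parallel) {
    parallel::mclapply(seq_along(blocks), one,
                       mc.cores = min(length(blocks), parallel::detectCores()))
  } else {
    lapply(seq_along(blocks), one)
  }
  names(fits) <- paste0("B", vapply(blocks, `[[`, 0L, "initial_state"))
  fits[!vapply(fits, is.null, TRUE)]
}

#' Fit joint longitudinal-survival models per transition (JM-ST)
#'
#' One independent posterior per permitted transition; within a block,
#' competing events are censored. The risk set and longitudinal index sets
#' are those of the enclosing competing-risk block.
#'
#' @inheritParams fit_jm_cr
#' @return Named list of `posterior_fit`s, one per transition (`"j->k"`).
#' @export
fit_jm_st <- function(data, spec, priors = prior_spec(),
                      strategy = longitudinal_strategy("historical"),
                      control = sampler_config(), parallel = FALSE,
                      entry_adjusted = character(0), entry_scale = 1) {
  blocks <- competing_risk_blocks(data$graph)
  tasks <- list()
  for (blk in blocks) {
    for (k in blk$terminal_states) {
      tasks[[length(tasks) + 1L]] <- list(blk = blk, k = k)
    }
  }
  one <- function(ti) {
    task <- tasks[[ti]]
    bd <- build_block_dataset(data, task$blk, strategy, entry_adjusted, entry_scale)
    if (length(bd$members) == 0L) {
      warning("transition ", transition_id(task$blk$initial_state, task$k),
              " has an empty risk set; skipped", call. = FALSE)
      return(NULL)
    }
    sv <- single_transition_view(bd, task$k)
    if (sum(sv$event) == 0L) {
      warning("transition ", transition_id(task$blk$initial_state, task$k),
              " has no observed events; the association posterior is prior-dominated",
              call. = FALSE)
    }
    ctl <- control
    ctl$seed <- derive_seed(control$seed, ti)
    fit_workspace("jm_st", sv, spec, priors, ctl,
                  transition_id(task$blk$initial_state, task$k))
  }
  fits <- if (parallel) {
    parallel::mclapply(seq_along(tasks), one,
                       mc.cores = min(length(tasks), parallel::detectCores()))
  } else {
    lapply(seq_along(tasks), one)
  }
  names(fits) <- vapply(tasks, function(tk) transition_id(tk$blk$initial_state, tk$k), "")
  fits[!vapply(fits, is.null, TRUE)]
}

#' Split-chain potential scale reduction
#'
#' Each chain is split in half; the classic potential scale reduction factor
#' is computed across the split halves. When the pooled variance is zero
#' (identical constant chains) the degenerate convention 1 is returned.
#'
#' @param x numeric matrix of draws, one column per chain (a vector is one
#'   chain).
#' @return Scalar `R-hat`.
#' @export
split_rhat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n_tot <- nrow(x)
  if (n_tot < 4L) stop("split R-hat needs at least 4 draws per chain", call. = FALSE)
  half <- floor(n_tot / 2)
  pieces <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[n_tot - half + seq_len(half), j])
  }))
  m <- ncol(pieces); n <- nrow(pieces)
  means <- colMeans(pieces)
  vars <- apply(pieces, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf(
    "Posterior fit [%s, block %s]: %d draws x %d chains, %d parameters\n",
    x$approach, x$block, x$n_draws, x$chains, ncol(x$draws)
  ))
  cat(sprintf("  max split R-hat %.3f; wall time %.1fs; seed %d\n",
              max(x$rhat), x$wall_time, x$seed))
  invisible(x)
}

#' Posterior summary table
#'
#' @param object a `posterior_fit`.
#' @param ... unused.
#' @return data.frame with posterior mean, sd, 2.5/50/97.5 percentiles and
#'   split R-hat per parameter.
#' @export
summary.posterior_fit <- function(object, ...) {
  qs <- t(apply(object$draws, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  data.frame(
    parameter = colnames(object$draws),
    mean = colMeans(object$draws),
    sd = apply(object$draws, 2, stats::sd),
    q2.5 = qs[, 1], q50 = qs[, 2], q97.5 = qs[, 3],
    rhat = object$rhat,
    row.names = NULL
  )
}
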