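# Variational EM for the dynamic SBM.
#
# Latent structure: each node's group trajectory is a hidden Markov chain
# over 1..Q on the node's present steps (initial law alpha, common
# transition matrix pi). Dyads are emitted from a zero-inflated
# multinomial: P(Y = 0) = 1 - beta, P(Y = m) = beta * gamma(m). The
# variational family is a product over nodes of Markov chains, so the
# cross-node coupling is broken while within-node temporal dependence is
# kept exactly (forward-backward smoothing per node).

EPS_SMOOTH <- 1e-6

# Q x Q x (M+1) x T array of log emission probabilities per category
logf_array <- function(params) {
  q <- params$q_groups; t_steps <- params$n_steps; m <- params$n_categories
  lf <- array(-Inf, c(q, q, m + 1L, t_steps))
  for (t in seq_len(t_steps)) {
    b <- params$beta[, , t]
    lf[, , 1L, t] <- log1p(-b)
    if (m == 1L) {
      lf[, , 2L, t] <- log(b)
    } else {
      for (mm in seq_len(m))
        lf[, , mm + 1L, t] <- log(b) + log(params$gamma[, , t, mm])
    }
  }
  lf
}

# sufficient statistics of the dyad part under tau:
#   S[q, l, c+1, t]  = sum over ordered present dyads (i != j) of
#                      tau_itq * tau_jtl * 1{Y_ijt = c}
#   self[q, c+1, t]  = sum over present i of tau_itq * 1{Y_iit = c}
dyad_stats <- function(net, tau) {
  n <- net$n_nodes; t_steps <- net$n_steps; m <- net$n_categories
  q <- dim(tau)[3L]
  s <- array(0, c(q, q, m + 1L, t_steps))
  self <- array(0, c(q, m + 1L, t_steps))
  for (t in seq_len(t_steps)) {
    pres <- net$presence[, t] == 1L
    taut <- matrix(0, n, q)
    taut[pres, ] <- tau[pres, t, ]
    yt <- net$values[, , t]
    for (cc in 0:m) {
      a <- (yt == cc)
      a[!pres, ] <- FALSE
      a[, !pres] <- FALSE
      diag(a) <- FALSE
      s[, , cc + 1L, t] <- crossprod(taut, (a + 0) %*% taut)
      if (net$self_loops) {
        di <- pres & (diag(yt) == cc)
        self[, cc + 1L, t] <- colSums(taut[di, , drop = FALSE])
      }
    }
  }
  list(s = s, self = self)
}

# NA for nodes never present (such nodes contribute nothing anywhere)
first_present <- function(presence) {
  out <- apply(presence, 1L, function(r) which(r == 1L)[1L])
  as.integer(out)
}

# ---------------------------------------------------------------------------
# E-step

#' One variational E-step
#'
#' Runs up to `max_inner` Gauss-Seidel sweeps over the nodes in index
#' order. For each node, emission messages are assembled from the current
#' marginals of all other present nodes (both edge directions for directed
#' networks; the self-loop adds its diagonal-block term), and an exact
#' forward-backward pass along the node's present steps with initial law
#' `alpha` and transitions `pi` yields its new marginals `tau` and
#' pairwise weights `xi`. Sweeping stops early once the largest change in
#' `tau` falls below `tol`.
#'
#' @param net a [dynamic_network()].
#' @param params a [dynsbm_params()].
#' @param state optional previous `variational_state`; defaults to uniform
#'   marginals on present node-steps.
#' @param max_inner maximum number of sweeps.
#' @param tol sweep convergence tolerance on `max |delta tau|`.
#' @return a `variational_state`: list with `tau` (`N x T x Q`), `xi`
#'   (`N x (T-1) x Q x Q`, slot `k` = the node's k-th consecutive-present
#'   step pair), `logrho` (emission messages), `n_sweeps`, `max_change`.
#' @export
e_step <- function(net, params, state = NULL, max_inner = 5L, tol = 1e-4) {
  check_compatible(net, params)
  q <- params$q_groups
  n <- net$n_nodes; t_steps <- net$n_steps
  tau <- if (is.null(state)) uniform_tau(net, q) else state$tau
  lf <- logf_array(params)
  out <- estep_sweep_cpp(
    as.integer(net$values), net$presence, as.numeric(tau),
    as.numeric(lf), log(params$pi), log(params$alpha),
    net$directed, net$self_loops, as.integer(max_inner), tol)
  tp <- max(t_steps - 1L, 1L)
  structure(list(
    tau = array(out$tau, c(n, t_steps, q)),
    xi = array(out$xi, c(n, tp, q, q)),
    logrho = array(out$logrho, c(n, t_steps, q)),
    n_sweeps = out$n_sweeps, max_change = out$max_change
  ), class = "variational_state")
}

uniform_tau <- function(net, q) {
  tau <- array(0, c(net$n_nodes, net$n_steps, q))
  for (t in seq_len(net$n_steps))
    tau[net$presence[, t] == 1L, t, ] <- 1 / q
  tau
}

check_compatible <- function(net, params) {
  if (net$n_steps != params$n_steps)
    stop("network and params disagree on T", call. = FALSE)
  if (net$n_categories != params$n_categories)
    stop("network and params disagree on M", call. = FALSE)
  if (net$directed != params$directed || net$self_loops != params$self_loops)
    stop("network and params disagree on directedness/self-loops",
         call. = FALSE)
  invisible(TRUE)
}

# variational state from hard memberships (0 = absent)
state_from_memberships <- function(net, z, q) {
  n <- net$n_nodes; t_steps <- net$n_steps
  tau <- array(0, c(n, t_steps, q))
  tp <- max(t_steps - 1L, 1L)
  xi <- array(0, c(n, tp, q, q))
  for (i in seq_len(n)) {
    steps <- which(net$presence[i, ] == 1L)
    if (length(steps) == 0L) next
    tau[cbind(i, steps, z[i, steps])] <- 1
    if (length(steps) > 1L) {
      for (k in seq_len(length(steps) - 1L))
        xi[i, k, z[i, steps[k]], z[i, steps[k + 1L]]] <- 1
    }
  }
  structure(list(tau = tau, xi = xi, logrho = NULL),
            class = "variational_state")
}

# ---------------------------------------------------------------------------
# M-step

#' Closed-form M-step
#'
#' Maximises the expected complete log-likelihood given a variational
#' state: `alpha` from the marginals at first present steps, `pi` from the
#' pairwise weights, `beta`/`gamma` from tau-weighted dyad frequencies.
#' Within-group (diagonal) emission parameters are pooled over all time
#' steps (identifiability constraint); between-group parameters are per
#' step. All ratios are smoothed with `1e-6` so empty groups keep valid
#' parameters and no `log(0)` can arise downstream.
#'
#' @param net a [dynamic_network()].
#' @param state a `variational_state` from [e_step()].
#' @return a [dynsbm_params()].
#' @export
m_step <- function(net, state) {
  m_step_internal(net, state, dyad_stats(net, state$tau))
}

m_step_internal <- function(net, state, stats) {
  eps <- EPS_SMOOTH
  tau <- state$tau
  q <- dim(tau)[3L]
  n <- net$n_nodes; t_steps <- net$n_steps; m <- net$n_categories
  half <- if (net$directed) 1 else 2

  fs <- first_present(net$presence)
  act <- which(!is.na(fs))
  tau_first <- vapply(seq_len(q), function(g)
    sum(tau[cbind(act, fs[act], rep(g, length(act)))]), numeric(1))
  alpha <- (tau_first + eps) / (sum(tau_first) + q * eps)

  if (q == 1L) {
    pi_mat <- matrix(1, 1, 1)
  } else {
    cnt <- apply(state$xi, c(3L, 4L), sum)
    pi_mat <- (cnt + eps) / (rowSums(cnt) + q * eps)
  }

  s <- stats$s / half          # unordered pair counts when undirected
  self <- stats$self
  beta <- array(0, c(q, q, t_steps))
  gamma <- if (m > 1L) array(0, c(q, q, t_steps, m)) else NULL

  for (g in seq_len(q)) for (l in seq_len(q)) {
    if (g == l) next
    for (t in seq_len(t_steps)) {
      all_c <- sum(s[g, l, , t])
      pos_c <- all_c - s[g, l, 1L, t]
      beta[g, l, t] <- (pos_c + eps) / (all_c + 2 * eps)
      if (m > 1L)
        gamma[g, l, t, ] <- (s[g, l, 1L + seq_len(m), t] + eps) /
          (pos_c + m * eps)
    }
  }
  for (g in seq_len(q)) {
    counts <- vapply(0:m, function(cc)
      sum(s[g, g, cc + 1L, ]) + sum(self[g, cc + 1L, ]), numeric(1))
    all_c <- sum(counts)
    pos_c <- all_c - counts[1L]
    beta[g, g, ] <- (pos_c + eps) / (all_c + 2 * eps)
    if (m > 1L)
      for (mm in seq_len(m))
        gamma[g, g, , mm] <- (counts[mm + 1L] + eps) / (pos_c + m * eps)
  }

  dynsbm_params(alpha = alpha, pi = pi_mat, beta = beta, gamma = gamma,
                directed = net$directed, self_loops = net$self_loops)
}

# ---------------------------------------------------------------------------
# objective

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
xmul <- function(x, logv) ifelse(x > 0, x * logv, 0) # 0 * -Inf := 0

expected_cll <- function(net, state, params,
                         stats = dyad_stats(net, state$tau)) {
  tau <- state$tau
  n <- net$n_nodes
  q <- params$q_groups
  fs <- first_present(net$presence)
  act <- which(!is.na(fs))
  tau_first <- vapply(seq_len(q), function(g)
    sum(tau[cbind(act, fs[act], rep(g, length(act)))]), numeric(1))
  total <- sum(xmul(tau_first, log(params$alpha)))
  if (q > 1L || net$n_steps > 1L) {
    cnt <- apply(state$xi, c(3L, 4L), sum)
    total <- total + sum(xmul(cnt, log(params$pi)))
  }
  lf <- logf_array(params)
  half <- if (net$directed) 1 else 2
  qs <- seq_len(q)
  for (t in seq_len(net$n_steps)) for (cc in 0:net$n_categories) {
    dg <- lf[cbind(qs, qs, cc + 1L, t)]
    total <- total +
      sum(xmul(stats$s[, , cc + 1L, t], lf[, , cc + 1L, t])) / half +
      sum(xmul(stats$self[, cc + 1L, t], dg))
  }
  total
}

chain_entropy <- function(net, state) {
  tau <- state$tau
  n <- net$n_nodes
  h <- -sum(xlogx(state$xi))
  for (i in seq_len(n)) {
    steps <- which(net$presence[i, ] == 1L)
    if (length(steps) == 0L) next
    h <- h - sum(xlogx(tau[i, steps[1L], ]))
    if (length(steps) > 1L) {
      left <- steps[-length(steps)]
      h <- h + sum(xlogx(tau[i, left, ]))
    }
  }
  h
}

#' Evidence lower bound of a variational state
#'
#' Expected complete log-likelihood under the variational distribution
#' plus the entropy of the per-node variational Markov chains. Never
#' exceeds the exact log marginal likelihood.
#'
#' @param net a [dynamic_network()].
#' @param state a `variational_state`.
#' @param params a [dynsbm_params()].
#' @return a scalar.
#' @export
elbo <- function(net, state, params) {
  expected_cll(net, state, params) + chain_entropy(net, state)
}

# ---------------------------------------------------------------------------
# likelihood oracles

#' Complete-data log-likelihood
#'
#' `log P(Y, Z; params)`: chain terms (initial law at each node's first
#' present step, one transition per consecutive-present pair) plus
#' zero-inflated multinomial emission terms over observable dyads
#' (unordered pairs once when undirected; self-loops iff enabled).
#' Returns `-Inf` for a zero-probability configuration.
#'
#' @param net a [dynamic_network()].
#' @param z membership matrix (`0` = absent, consistent with the presence
#'   mask).
#' @param params a [dynsbm_params()].
#' @return a scalar, possibly `-Inf`.
#' @export
complete_log_likelihood <- function(net, z, params) {
  check_compatible(net, params)
  z <- as.matrix(z)
  if (!all((z > 0L) == (net$presence == 1L)))
    stop("z must be nonzero exactly at present node-steps")
  n <- net$n_nodes; t_steps <- net$n_steps
  la <- log(params$alpha); lp <- log(params$pi)
  total <- 0
  for (i in seq_len(n)) {
    steps <- which(net$presence[i, ] == 1L)
    if (length(steps) == 0L) next
    total <- total + la[z[i, steps[1L]]]
    if (length(steps) > 1L) {
      zz <- z[i, steps]
      total <- total + sum(lp[cbind(zz[-length(zz)], zz[-1L])])
    }
  }
  lf <- logf_array(params)
  for (t in seq_len(t_steps)) {
    pres <- which(net$presence[, t] == 1L)
    if (length(pres) >= 2L) {
      pairs <- which(
        if (net$directed) {
          outer(seq_along(pres), seq_along(pres), "!=")
        } else {
          upper.tri(diag(length(pres)))
        }, arr.ind = TRUE)
      ii <- pres[pairs[, 1L]]; jj <- pres[pairs[, 2L]]
      total <- total + sum(lf[cbind(z[cbind(ii, t)], z[cbind(jj, t)],
                                    net$values[cbind(ii, jj, t)] + 1L, t)])
    }
    if (net$self_loops && length(pres) >= 1L) {
      zi <- z[cbind(pres, t)]
      total <- total + sum(lf[cbind(zi, zi,
                                    net$values[cbind(pres, pres, t)] + 1L, t)])
    }
  }
  total
}

#' Exact log marginal likelihood by enumeration
#'
#' `log sum_Z exp(complete_log_likelihood)` over every membership
#' configuration of the present node-steps, log-sum-exp stabilised. Only
#' feasible on tiny instances; serves as the independent bound oracle for
#' the variational fit.
#'
#' @param net a [dynamic_network()].
#' @param params a [dynsbm_params()].
#' @param max_configs guard on the enumeration size.
#' @return a scalar.
#' @export
exact_log_marginal <- function(net, params, max_configs = 2^20) {
  check_compatible(net, params)
  q <- params$q_groups
  ns <- sum(net$presence)
  if (q^ns > max_configs)
    stop("instance too large for exhaustive enumeration: Q^", ns,
         " configurations")
  n_conf <- as.integer(round(q^ns))
  # column k of cfg enumerates the k-th present node-step
  idx <- which(net$presence == 1L, arr.ind = TRUE)  # (node, step) rows
  cfg <- matrix(0L, n_conf, ns)
  for (k in seq_len(ns))
    cfg[, k] <- rep(rep(seq_len(q), each = q^(k - 1L)),
                    length.out = n_conf)
  col_of <- matrix(NA_integer_, net$n_nodes, net$n_steps)
  col_of[idx] <- seq_len(ns)

  ll <- numeric(n_conf)
  la <- log(params$alpha); lp_vec <- as.vector(log(params$pi))
  for (i in seq_len(net$n_nodes)) {
    steps <- which(net$presence[i, ] == 1L)
    if (length(steps) == 0L) next
    ll <- ll + la[cfg[, col_of[i, steps[1L]]]]
    if (length(steps) > 1L) {
      for (k in seq_len(length(steps) - 1L)) {
        zp <- cfg[, col_of[i, steps[k]]]
        zn <- cfg[, col_of[i, steps[k + 1L]]]
        ll <- ll + lp_vec[zp + q * (zn - 1L)]
      }
    }
  }
  lf <- logf_array(params)
  for (t in seq_len(net$n_steps)) {
    pres <- which(net$presence[, t] == 1L)
    dyads <- if (net$directed) {
      subset(expand.grid(i = pres, j = pres), i != j)
    } else {
      subset(expand.grid(i = pres, j = pres), i < j)
    }
    if (net$self_loops) dyads <- rbind(dyads, data.frame(i = pres, j = pres))
    for (r in seq_len(nrow(dyads))) {
      i <- dyads$i[r]; j <- dyads$j[r]
      lfm <- as.vector(lf[, , net$values[i, j, t] + 1L, t])
      zi <- cfg[, col_of[i, t]]
      zj <- cfg[, col_of[j, t]]
      ll <- ll + lfm[zi + q * (zj - 1L)]
    }
  }
  m <- max(ll)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(ll - m)))
}

# ---------------------------------------------------------------------------
# fitting

#' Fit a dynamic SBM by variational EM
#'
#' Alternates [e_step()] and [m_step()] until the relative change in the
#' ELBO falls below `tol` or `max_iter` iterations, for `n_init`
#' initialisations: the first clusters nodes by k-means on the rows of the
#' time-aggregated adjacency (columns appended for directed networks), the
#' rest are random hard memberships. The run with the highest final ELBO
#' is returned; MAP membership trajectories are decoded per node by
#' Viterbi on its posterior chain, with ties broken toward the lowest
#' group index and group 0 marking absent node-steps.
#'
#' @param net a [dynamic_network()].
#' @param q_groups (maximal) number of groups `Q`; groups may be empty at
#'   some or all steps.
#' @param n_init number of initialisations.
#' @param max_iter maximum EM iterations per initialisation.
#' @param tol relative ELBO convergence tolerance.
#' @param max_inner,inner_tol E-step sweep schedule, see [e_step()].
#' @param seed integer seed controlling all randomness of the fit.
#' @return a `dynsbm_fit`: list with `params`, `state`, `map_memberships`,
#'   `elbo_trace` (best run), `all_traces` (one trace per initialisation),
#'   `elbo`, `converged`, `n_iterations`, `seed_used`, `q_groups`.
#' @export
fit_dynsbm <- function(net, q_groups, n_init = 5L, max_iter = 100L,
                       tol = 1e-6, max_inner = 5L, inner_tol = 1e-4,
                       seed = 1L) {
  q_groups <- as.integer(q_groups)
  if (q_groups < 1L) stop("q_groups must be >= 1")
  if (q_groups > sum(net$presence))
    stop("q_groups exceeds the number of present node-steps")
  best <- NULL
  all_traces <- vector("list", max(1L, n_init))
  for (r in seq_len(max(1L, n_init))) {
    z0 <- if (r == 1L) init_spectral(net, q_groups, derive_seed(seed, 100L))
          else init_random(net, q_groups, derive_seed(seed, 100L + r))
    run <- vem_run(net, z0, q_groups, max_iter, tol, max_inner, inner_tol)
    all_traces[[r]] <- run$trace
    if (is.null(best) || run$elbo > best$elbo) best <- run
  }
  z_map <- viterbi_memberships(net, best$state, best$params)
  rownames(z_map) <- net$node_labels
  structure(list(
    params = best$params, state = best$state, map_memberships = z_map,
    elbo_trace = best$trace, all_traces = all_traces,
    elbo = best$elbo, converged = best$converged,
    n_iterations = length(best$trace), seed_used = as.integer(seed),
    q_groups = q_groups
  ), class = "dynsbm_fit")
}

vem_run <- function(net, z0, q, max_iter, tol, max_inner, inner_tol) {
  state <- state_from_memberships(net, z0, q)
  params <- m_step(net, state)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    state <- e_step(net, params, state, max_inner, inner_tol)
    stats <- dyad_stats(net, state$tau)
    params <- m_step_internal(net, state, stats)
    el <- expected_cll(net, state, params, stats) + chain_entropy(net, state)
    trace <- c(trace, el)
    if (is.finite(prev) && abs(el - prev) <= tol * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- el
  }
  list(state = state, params = params, trace = trace,
       elbo = trace[length(trace)], converged = converged)
}

init_spectral <- function(net, q, seed) {
  n <- net$n_nodes
  agg <- matrix(0, n, n)
  for (t in seq_len(net$n_steps)) agg <- agg + net$values[, , t]
  feats <- if (net$directed) cbind(agg, t(agg)) else agg
  z_node <- with_local_seed(seed, {
    km <- tryCatch(stats::kmeans(feats, centers = q, nstart = 5L),
                   error = function(e) NULL)
    if (is.null(km)) sample.int(q, n, replace = TRUE) else km$cluster
  })
  z <- matrix(0L, n, net$n_steps)
  for (i in seq_len(n))
    z[i, net$presence[i, ] == 1L] <- as.integer(z_node[i])
  z
}

init_random <- function(net, q, seed) {
  with_local_seed(seed, {
    z <- matrix(0L, net$n_nodes, net$n_steps)
    pres <- which(net$presence == 1L)
    z[pres] <- sample.int(q, length(pres), replace = TRUE)
    z
  })
}

viterbi_memberships <- function(net, state, params) {
  n <- net$n_nodes; t_steps <- net$n_steps; q <- params$q_groups
  la <- log(params$alpha); lp <- log(params$pi)
  z <- matrix(0L, n, t_steps)
  for (i in seq_len(n)) {
    steps <- which(net$presence[i, ] == 1L)
    k_len <- length(steps)
    if (k_len == 0L) next
    rho <- matrix(state$logrho[i, steps, ], k_len, q)
    delta <- matrix(-Inf, k_len, q)
    back <- matrix(0L, k_len, q)
    delta[1L, ] <- la + rho[1L, ]
    if (k_len > 1L) {
      for (k in 2:k_len) for (g in seq_len(q)) {
        cand <- delta[k - 1L, ] + lp[, g]
        back[k, g] <- which.max(cand)     # ties -> lowest index
        delta[k, g] <- cand[back[k, g]] + rho[k, g]
      }
    }
    g <- which.max(delta[k_len, ])
    z[i, steps[k_len]] <- g
    if (k_len > 1L) {
      for (k in k_len:2) {
        g <- back[k, g]
        z[i, steps[k - 1L]] <- g
      }
    }
  }
  z
}

#' @export
print.dynsbm_fit <- function(x, ...) {
  cat(sprintf(
    "<dynsbm_fit> Q = %d, ELBO = %.4f after %d iterations (%s)\n",
    x$q_groups, x$elbo, x$n_iterations,
    if (x$converged) "converged" else "max_iter reached"))
  tab <- table(factor(x$map_memberships[x$map_memberships > 0],
                      levels = seq_len(x$q_groups)))
  cat("  group occupancy (node-steps):",
      paste(sprintf("%d:%d", seq_len(x$q_groups), tab), collapse = "  "),
      "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# label alignment (for comparing a fit against known memberships)

#' Align estimated groups with reference memberships
#'
#' Searches all permutations of the `Q` group labels and returns the
#' relabelled estimate maximising agreement with the reference over
#' present node-steps. Useful for parameter-recovery experiments where
#' labels are only identified up to permutation.
#'
#' @param z_est,z_ref membership matrices (0 = absent).
#' @param q_groups number of groups.
#' @return list with `z` (relabelled estimate), `perm` (perm[old] = new),
#'   `agreement` (fraction of matching present node-steps).
#' @export
align_groups <- function(z_est, z_ref, q_groups) {
  perms <- all_permutations(q_groups)
  mask <- z_ref > 0L & z_est > 0L
  best <- NULL
  for (p in perms) {
    z_new <- z_est
    z_new[mask] <- p[z_est[mask]]
    agr <- mean(z_new[mask] == z_ref[mask])
    if (is.null(best) || agr > best$agreement)
      best <- list(z = z_new, perm = p, agreement = agr)
  }
  best
}

all_permutations <- function(q) {
  if (q == 1L) return(list(1L))
  out <- list()
  for (g in seq_len(q)) {
    sub <- all_permutations(q - 1L)
    for (s in sub) {
      rest <- seq_len(q)[-g]
      p <- integer(q)
      p[g] <- 1L
      p[rest] <- s + 1L
      out <- c(out, list(p))
    }
  }
  out
}
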