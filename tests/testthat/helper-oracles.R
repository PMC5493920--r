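# Independent oracles and small-instance generators shared by the tests.
# The complete-likelihood oracle below is a deliberately naive scalar
# term-by-term summation, kept structurally different from the package's
# vectorised implementation.

oracle_cll <- function(net, z, params) {
  log_emit <- function(q, l, t, y) {
    b <- params$beta[q, l, t]
    if (y == 0) return(log(1 - b))
    if (params$n_categories == 1L) log(b)
    else log(b) + log(params$gamma[q, l, t, y])
  }
  total <- 0
  for (i in seq_len(net$n_nodes)) {
    steps <- which(net$presence[i, ] == 1L)
    if (length(steps) == 0L) next
    total <- total + log(params$alpha[z[i, steps[1L]]])
    if (length(steps) > 1L) {
      for (k in 2:length(steps))
        total <- total + log(params$pi[z[i, steps[k - 1L]], z[i, steps[k]]])
    }
  }
  for (t in seq_len(net$n_steps)) {
    for (i in seq_len(net$n_nodes)) {
      for (j in seq_len(net$n_nodes)) {
        if (net$presence[i, t] == 0L || net$presence[j, t] == 0L) next
        if (i == j) {
          if (net$self_loops)
            total <- total + log_emit(z[i, t], z[i, t], t, net$values[i, i, t])
          next
        }
        if (!net$directed && i > j) next
        total <- total + log_emit(z[i, t], z[j, t], t, net$values[i, j, t])
      }
    }
  }
  total
}

# random tiny instance: N in 3..4, T in 1..3, Q = 2, enumerable chains
random_tiny_instance <- function(seed, m = 1L, directed = FALSE,
                                 self_loops = FALSE, with_absence = TRUE) {
  withr::with_seed(seed, {
    n <- sample(3:4, 1L)
    t_steps <- sample(1:3, 1L)
    q <- 2L
    alpha <- as.vector(stats::runif(q, 0.2, 1))
    alpha <- alpha / sum(alpha)
    pim <- matrix(stats::runif(q * q, 0.1, 1), q, q)
    pim <- pim / rowSums(pim)
    beta <- array(stats::runif(q * q * t_steps, 0.15, 0.85),
                  c(q, q, t_steps))
    for (g in seq_len(q)) beta[g, g, ] <- beta[g, g, 1L]
    if (!directed) for (t in seq_len(t_steps))
      beta[, , t] <- (beta[, , t] + t(beta[, , t])) / 2
    gamma <- NULL
    if (m > 1L) {
      gamma <- array(stats::runif(q * q * t_steps * m, 0.2, 1),
                     c(q, q, t_steps, m))
      for (g in seq_len(q)) for (mm in seq_len(m))
        gamma[g, g, , mm] <- gamma[g, g, 1L, mm]
      if (!directed) for (t in seq_len(t_steps)) for (mm in seq_len(m))
        gamma[, , t, mm] <- (gamma[, , t, mm] + t(gamma[, , t, mm])) / 2
      sums <- apply(gamma, 1:3, sum)
      for (mm in seq_len(m))
        gamma[, , , mm] <- array(gamma[, , , mm], dim(sums)) / sums
    }
    params <- dynsbm_params(alpha, pim, beta, gamma, directed = directed,
                            self_loops = self_loops)
    presence <- matrix(1L, n, t_steps)
    if (with_absence && t_steps > 1L) {
      presence[sample.int(n, 1L), sample.int(t_steps, 1L)] <- 0L
    }
    z <- simulate_memberships(params, presence, sample.int(1e6, 1L))
    net <- simulate_network(params, z, sample.int(1e6, 1L))
    list(net = net, z = z, params = params)
  })
}

elbo_trace_monotone <- function(trace, rel_tol = 1e-8) {
  if (length(trace) < 2L) return(TRUE)
  all(diff(trace) >= -rel_tol * abs(trace[-length(trace)]))
}

mean_present_ari <- function(z_est, z_true) {
  t_steps <- ncol(z_true)
  mean(vapply(seq_len(t_steps), function(t) {
    keep <- z_true[, t] > 0L
    mclust::adjustedRandIndex(z_est[keep, t], z_true[keep, t])
  }, numeric(1)))
}

# six-node toy with hand-enumerable summaries (see test-summaries.R)
summary_toy <- function() {
  z <- rbind(c(1L, 1L), c(1L, 1L), c(1L, 2L),
             c(2L, 2L), c(2L, 0L), c(2L, 2L))
  presence <- matrix(1L, 6, 2)
  presence[5, 2] <- 0L
  v <- array(0L, c(6, 6, 2))
  set_edge <- function(t, i, j, val) {
    v[i, j, t] <<- val
    v[j, i, t] <<- val
  }
  set_edge(1, 1, 2, 1); set_edge(1, 1, 3, 2); set_edge(1, 2, 3, 3)
  set_edge(1, 4, 5, 2); set_edge(1, 5, 6, 1)
  set_edge(1, 1, 4, 1); set_edge(1, 3, 6, 3)
  set_edge(2, 1, 2, 2)
  set_edge(2, 3, 4, 1); set_edge(2, 4, 6, 2)
  set_edge(2, 1, 3, 3); set_edge(2, 2, 4, 1)
  net <- dynamic_network(v, presence, directed = FALSE, self_loops = FALSE,
                         n_categories = 3L)
  rownames(z) <- net$node_labels
  list(net = net, z = z)
}
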