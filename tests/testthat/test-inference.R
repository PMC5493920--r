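test_that("complete log-likelihood matches hand values", {
  # single dyad, one group: log P = log alpha (=0) + log beta
  p <- dynsbm_params(1, matrix(1), matrix(0.5, 1, 1), n_steps = 1)
  v <- array(0L, c(2, 2, 1)); v[1, 2, 1] <- v[2, 1, 1] <- 1L
  net <- dynamic_network(v)
  expect_equal(complete_log_likelihood(net, matrix(1L, 2, 1), p), log(0.5))

  # impossible transition under an identity chain
  p2 <- dynsbm_params(c(0.5, 0.5), diag(2), matrix(0.5, 2, 2), n_steps = 2)
  v <- array(0L, c(2, 2, 2))
  net2 <- dynamic_network(v)
  z_switch <- rbind(c(1L, 2L), c(1L, 1L))
  expect_identical(complete_log_likelihood(net2, z_switch, p2), -Inf)
})

test_that("complete log-likelihood equals the term-enumeration oracle", {
  cases <- expand.grid(m = c(1L, 3L), directed = c(FALSE, TRUE))
  for (r in seq_len(nrow(cases))) {
    for (seed in 1:6) {
      inst <- random_tiny_instance(100 * r + seed, m = cases$m[r],
                                   directed = cases$directed[r],
                                   self_loops = cases$directed[r])
      got <- complete_log_likelihood(inst$net, inst$z, inst$params)
      expect_equal(got, oracle_cll(inst$net, inst$z, inst$params),
                   tolerance = 1e-12)
    }
  }
})

test_that("exact log marginal agrees with direct enumeration", {
  # Q = 1: a single configuration
  p <- dynsbm_params(1, matrix(1), matrix(0.3, 1, 1), n_steps = 2)
  inst <- random_tiny_instance(3, m = 1L)
  p1 <- dynsbm_params(1, matrix(1), matrix(0.3, 1, 1),
                      n_steps = inst$net$n_steps)
  z1 <- matrix(as.integer(inst$net$presence), inst$net$n_nodes,
               inst$net$n_steps)
  expect_equal(exact_log_marginal(inst$net, p1),
               complete_log_likelihood(inst$net, z1, p1), tolerance = 1e-12)

  # N = 2, T = 1, Q = 2: four configurations, summed by hand
  b <- matrix(c(0.7, 0.2, 0.2, 0.7), 2, 2)
  p2 <- dynsbm_params(c(0.6, 0.4), matrix(0.5, 2, 2), b, n_steps = 1)
  v <- array(0L, c(2, 2, 1)); v[1, 2, 1] <- v[2, 1, 1] <- 1L
  net <- dynamic_network(v)
  hand <- log(0.6 * 0.6 * 0.7 + 0.6 * 0.4 * 0.2 +
              0.4 * 0.6 * 0.2 + 0.4 * 0.4 * 0.7)
  expect_equal(exact_log_marginal(net, p2), hand, tolerance = 1e-12)

  expect_error(
    exact_log_marginal(make_fixture("foodweb_like", 1)$net,
                       dynblock:::fixture_params("foodweb_like")),
    "too large")
})

test_that("E-step degenerates correctly and preserves symmetry", {
  inst <- random_tiny_instance(11, m = 1L)
  p1 <- dynsbm_params(1, matrix(1), matrix(0.4, 1, 1),
                      n_steps = inst$net$n_steps)
  st <- e_step(inst$net, p1)
  pres <- inst$net$presence == 1L
  expect_true(all(st$tau[, , 1][pres] == 1))

  # fully exchangeable parameters + uniform start leave tau uniform
  pex <- dynsbm_params(c(0.5, 0.5), matrix(0.5, 2, 2),
                       matrix(0.4, 2, 2), n_steps = inst$net$n_steps)
  st2 <- e_step(inst$net, pex)
  expect_equal(st2$tau[, , 1][pres], st2$tau[, , 2][pres], tolerance = 1e-12)
})

test_that("one Gauss-Seidel update equals the exact conditional posterior", {
  for (m in c(1L, 3L)) {
    inst <- random_tiny_instance(20 + m, m = m, with_absence = FALSE)
    net <- inst$net; params <- inst$params; z <- inst$z
    q <- 2L
    # others pinned at their true groups; node 1 starts uniform
    st0 <- dynblock:::state_from_memberships(net, z, q)
    st0$tau[1, , ] <- 1 / q
    st1 <- e_step(net, params, st0, max_inner = 1, tol = 0)

    # enumeration oracle: P(z_1 | z_-1, Y) over node 1's chain
    t_steps <- net$n_steps
    configs <- as.matrix(expand.grid(rep(list(1:q), t_steps)))
    w <- apply(configs, 1L, function(z1) {
      zz <- z; zz[1, ] <- z1
      exp(oracle_cll(net, zz, params))
    })
    w <- w / sum(w)
    for (t in seq_len(t_steps)) {
      marg <- vapply(1:q, function(g) sum(w[configs[, t] == g]), numeric(1))
      expect_equal(st1$tau[1, t, ], marg, tolerance = 1e-8)
    }
  }
})

test_that("M-step recovers frequencies from hard memberships", {
  # transition counts with smoothing: 4 stay, 1 switch out of 5 from group 1
  v <- array(0L, c(5, 5, 2))
  net <- dynamic_network(v, n_categories = 1L)
  z <- cbind(rep(1L, 5), c(1L, 1L, 1L, 1L, 2L))
  st <- dynblock:::state_from_memberships(net, z, 2L)
  par <- m_step(net, st)
  eps <- 1e-6
  expect_equal(par$pi[1, ], c((4 + eps) / (5 + 2 * eps),
                              (1 + eps) / (5 + 2 * eps)), tolerance = 1e-12)

  # block densities from one-hot, constant memberships
  inst <- random_tiny_instance(31, m = 1L, with_absence = FALSE)
  b <- matrix(c(0.7, 0.25, 0.25, 0.55), 2, 2)
  p <- dynsbm_params(c(0.5, 0.5), diag(2), b, n_steps = 3)
  z <- matrix(rep(rep(1:2, each = 10), 3), 20, 3)
  netb <- simulate_network(p, z, seed = 8)
  stb <- dynblock:::state_from_memberships(netb, z, 2L)
  parb <- m_step(netb, stb)
  for (t in 1:3) {
    cross <- netb$values[1:10, 11:20, t]
    expect_equal(parb$beta[1, 2, t], mean(cross > 0), tolerance = 1e-4)
  }
})

test_that("M-step output is a local maximiser of the expected likelihood", {
  inst <- random_tiny_instance(41, m = 3L, with_absence = FALSE)
  net <- inst$net
  st <- e_step(net, inst$params)
  stats <- dynblock:::dyad_stats(net, st$tau)
  hat <- dynblock:::m_step_internal(net, st, stats)
  base <- dynblock:::expected_cll(net, st, hat, stats)

  perturb <- function(par, what, delta) {
    p2 <- unclass(par)
    if (what == "alpha") {
      a <- pmax(p2$alpha + delta * stats::runif(length(p2$alpha), -1, 1),
                1e-9)
      p2$alpha <- a / sum(a)
    } else if (what == "pi") {
      pm <- pmax(p2$pi + delta * matrix(stats::runif(4, -1, 1), 2, 2), 1e-9)
      p2$pi <- pm / rowSums(pm)
    } else if (what == "beta") {
      b <- p2$beta
      d12 <- delta * stats::runif(dim(b)[3], -1, 1)
      b[1, 2, ] <- b[2, 1, ] <- pmin(pmax(b[1, 2, ] + d12, 1e-9), 1 - 1e-9)
      b[1, 1, ] <- pmin(pmax(b[1, 1, 1] + delta * stats::runif(1, -1, 1),
                             1e-9), 1 - 1e-9)
      p2$beta <- b
    } else {
      g <- p2$gamma
      for (t in seq_len(dim(g)[3])) {
        gg <- pmax(g[1, 2, t, ] + delta * stats::runif(3, -1, 1), 1e-9)
        g[1, 2, t, ] <- g[2, 1, t, ] <- gg / sum(gg)
      }
      p2$gamma <- g
    }
    class(p2) <- "dynsbm_params"
    p2
  }
  withr::with_seed(99, {
    blocks <- rep(c("alpha", "pi", "beta", "gamma"), length.out = 100)
    for (bk in blocks) {
      p_pert <- perturb(hat, bk, 0.01)
      expect_lte(dynblock:::expected_cll(net, st, p_pert, stats),
                 base + 1e-10)
    }
  })
})

test_that("fit with one group matches the exact marginal", {
  inst <- random_tiny_instance(51, m = 1L)
  f1 <- fit_dynsbm(inst$net, 1, n_init = 1, seed = 1)
  expect_equal(f1$elbo, exact_log_marginal(inst$net, f1$params),
               tolerance = 1e-10)
  # one-group beta is the pooled observed density (diagonal => time-pooled)
  obs <- 0; tot <- 0
  for (t in seq_len(inst$net$n_steps)) {
    pres <- inst$net$presence[, t] == 1L
    v <- inst$net$values[pres, pres, t]
    ut <- upper.tri(v)
    obs <- obs + sum(v[ut] > 0); tot <- tot + sum(ut)
  }
  expect_equal(f1$params$beta[1, 1, 1], (obs + 1e-6) / (tot + 2e-6),
               tolerance = 1e-12)
})

test_that("likelihood and ELBO are invariant under label permutation", {
  inst <- random_tiny_instance(61, m = 3L)
  net <- inst$net; p <- inst$params
  st <- e_step(net, p)
  sig <- c(2L, 1L)
  inv <- order(sig)
  p2 <- dynsbm_params(p$alpha[sig], p$pi[sig, sig], p$beta[sig, sig, ],
                      p$gamma[sig, sig, , ], directed = p$directed,
                      self_loops = p$self_loops)
  z2 <- inst$z
  z2[inst$z > 0L] <- inv[inst$z[inst$z > 0L]]
  expect_equal(complete_log_likelihood(net, z2, p2),
               complete_log_likelihood(net, inst$z, p), tolerance = 1e-12)
  st2 <- st
  st2$tau <- st$tau[, , sig, drop = FALSE]
  st2$xi <- st$xi[, , sig, sig, drop = FALSE]
  expect_equal(elbo(net, st2, p2), elbo(net, st, p), tolerance = 1e-10)
})

test_that("the ELBO never exceeds the exact marginal on tiny instances", {
  for (seed in 1:6) {
    inst <- random_tiny_instance(70 + seed, m = 1L)
    fit <- fit_dynsbm(inst$net, 2, n_init = 2, max_iter = 40, seed = seed)
    expect_lte(fit$elbo,
               exact_log_marginal(inst$net, fit$params) + 1e-8)
    for (tr in fit$all_traces) expect_true(elbo_trace_monotone(tr))
  }
})

test_that("MAP decoding breaks ties toward the lowest group", {
  # symmetric everything: every chain configuration is tied
  v <- array(0L, c(3, 3, 2))
  net <- dynamic_network(v, n_categories = 1L)
  p <- dynsbm_params(c(0.5, 0.5), matrix(0.5, 2, 2), matrix(0.5, 2, 2),
                     n_steps = 2)
  st <- e_step(net, p)
  z <- dynblock:::viterbi_memberships(net, st, p)
  expect_true(all(z == 1L))
})
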