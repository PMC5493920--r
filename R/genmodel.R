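# Generative dynamic SBM: parameter container and simulator.
#
# Each node follows a hidden Markov chain over Q groups (initial law
# alpha, common transition matrix pi). Conditional on the endpoint groups
# (q, l) at step t, a dyad is present with probability beta[q, l, t] and,
# if present and M > 1, its category is drawn from gamma[q, l, t, ].
# Within-group (diagonal) emission parameters are held constant over time:
# with time-varying memberships the group labels are only anchored across
# steps by a time-stable intra-group signature.

#' Construct a dynamic SBM parameter set
#'
#' @param alpha length-`Q` initial group distribution.
#' @param pi `Q x Q` Markov transition matrix (rows sum to 1); entry
#'   `[q, l]` is the probability of moving from group `q` to group `l`
#'   between consecutive present steps.
#' @param beta `Q x Q x T` array of edge-presence probabilities; a `Q x Q`
#'   matrix is accepted and recycled over `n_steps` steps. Diagonal entries
#'   must be constant in `t` (identifiability constraint).
#' @param gamma `Q x Q x T x M` array of category distributions for present
#'   edges, or `NULL` for a binary model (`M = 1`). A `Q x Q x M` array is
#'   recycled over steps. Diagonal entries must be constant in `t`.
#' @param directed,self_loops network flags; for undirected networks
#'   `beta` and `gamma` must be symmetric in `(q, l)`.
#' @param n_steps number of steps `T`, needed only when `beta` is a matrix.
#' @return an object of class `dynsbm_params`.
#' @export
dynsbm_params <- function(alpha, pi, beta, gamma = NULL, directed = FALSE,
                          self_loops = FALSE, n_steps = NULL) {
  q <- length(alpha)
  pi <- as.matrix(pi)
  if (is.matrix(beta)) {
    if (is.null(n_steps)) stop("n_steps is required when beta is a matrix")
    beta <- array(beta, c(q, q, n_steps))
  }
  t_steps <- dim(beta)[3L]
  if (!is.null(gamma) && length(dim(gamma)) == 3L)
    gamma <- aperm(array(gamma, c(q, q, dim(gamma)[3L], t_steps)),
                   c(1L, 2L, 4L, 3L))
  m <- if (is.null(gamma)) 1L else dim(gamma)[4L]
  x <- structure(list(
    alpha = as.numeric(alpha), pi = pi, beta = beta, gamma = gamma,
    q_groups = q, n_steps = t_steps, n_categories = as.integer(m),
    directed = isTRUE(directed), self_loops = isTRUE(self_loops)
  ), class = "dynsbm_params")
  validate_dynsbm_params(x)
  x
}

#' @keywords internal
validate_dynsbm_params <- function(p, tol = 1e-8) {
  q <- p$q_groups
  if (q < 1L) stop("Q must be >= 1", call. = FALSE)
  if (any(p$alpha < 0) || abs(sum(p$alpha) - 1) > tol)
    stop("alpha must be a probability vector", call. = FALSE)
  if (!all(dim(p$pi) == c(q, q)))
    stop("pi must be Q x Q", call. = FALSE)
  if (any(p$pi < 0) || any(abs(rowSums(p$pi) - 1) > 1e-12))
    stop("rows of pi must sum to 1 (tolerance 1e-12)", call. = FALSE)
  if (!all(dim(p$beta)[1:2] == q) || length(dim(p$beta)) != 3L)
    stop("beta must be Q x Q x T", call. = FALSE)
  if (any(p$beta < 0 | p$beta > 1))
    stop("beta entries must lie in [0, 1]", call. = FALSE)
  t_steps <- p$n_steps
  for (g in seq_len(q)) {
    if (max(p$beta[g, g, ]) - min(p$beta[g, g, ]) > tol)
      stop("diagonal beta[", g, ", ", g, ", ] must be constant over time",
           call. = FALSE)
  }
  if (!p$directed) {
    for (t in seq_len(t_steps))
      if (max(abs(p$beta[, , t] - t(p$beta[, , t]))) > tol)
        stop("undirected model requires symmetric beta", call. = FALSE)
  }
  if (!is.null(p$gamma)) {
    if (!all(dim(p$gamma)[1:3] == c(q, q, t_steps)))
      stop("gamma must be Q x Q x T x M", call. = FALSE)
    if (any(p$gamma < 0))
      stop("gamma entries must be non-negative", call. = FALSE)
    s <- apply(p$gamma, 1:3, sum)
    if (any(abs(s - 1) > tol))
      stop("each gamma[q, l, t, ] must sum to 1", call. = FALSE)
    for (g in seq_len(q)) {
      d <- p$gamma[g, g, , , drop = FALSE]
      if (t_steps > 1L && max(apply(d, 4L, function(v) max(v) - min(v))) > tol)
        stop("diagonal gamma[", g, ", ", g, ", , ] must be constant over time",
             call. = FALSE)
    }
    if (!p$directed) {
      for (t in seq_len(t_steps)) for (mm in seq_len(p$n_categories))
        if (max(abs(p$gamma[, , t, mm] - t(p$gamma[, , t, mm]))) > tol)
          stop("undirected model requires symmetric gamma", call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.dynsbm_params <- function(x, ...) {
  cat(sprintf(
    "<dynsbm_params> Q = %d groups, T = %d steps, M = %d categories (%s%s)\n",
    x$q_groups, x$n_steps, x$n_categories,
    if (x$directed) "directed" else "undirected",
    if (x$self_loops) ", self-loops" else ""))
  invisible(x)
}

# run expr with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483399) + 1L
}

#' Simulate group membership trajectories
#'
#' Each node's trajectory is an independent realisation of the common
#' Markov chain: the group at the node's first present step is drawn from
#' `alpha` and each pair of consecutive present steps is bridged by one
#' application of `pi`, whatever the gap length. Absent node-steps get the
#' reporting group 0.
#'
#' @param params a [dynsbm_params()].
#' @param presence `N x T` binary presence mask (each node present at
#'   least once).
#' @param seed integer RNG seed.
#' @return integer `N x T` matrix `Z` with `Z[i, t] = 0` iff absent.
#' @export
simulate_memberships <- function(params, presence, seed) {
  presence <- as_presence(as.matrix(presence),
                          nrow(as.matrix(presence)), ncol(as.matrix(presence)))
  if (any(rowSums(presence) == 0L))
    stop("every node needs at least one present step")
  t_steps <- ncol(presence)
  if (t_steps != params$n_steps) stop("presence and params disagree on T")
  q <- params$q_groups
  n <- nrow(presence)
  with_local_seed(seed, {
    z <- matrix(0L, n, t_steps)
    for (i in seq_len(n)) {
      steps <- which(presence[i, ] == 1L)
      g <- sample.int(q, 1L, prob = params$alpha)
      z[i, steps[1L]] <- g
      for (s in steps[-1L]) {
        g <- sample.int(q, 1L, prob = params$pi[g, ])
        z[i, s] <- g
      }
    }
    z
  })
}

#' Simulate a dynamic network given memberships
#'
#' For every observable dyad (both endpoints present; ordered pairs when
#' directed; `i = j` included iff self-loops are allowed) an edge is drawn
#' with probability `beta[q, l, t]` and, when present and `M > 1`, a
#' category from `gamma[q, l, t, ]`. Self-loops use the diagonal block of
#' the node's own group. Dyads with an absent endpoint are 0.
#'
#' @param params a [dynsbm_params()].
#' @param z membership matrix from [simulate_memberships()].
#' @param seed integer RNG seed.
#' @param node_labels,step_labels passed to [dynamic_network()].
#' @return a [dynamic_network()].
#' @export
simulate_network <- function(params, z, seed, node_labels = NULL,
                             step_labels = NULL) {
  z <- as.matrix(z)
  n <- nrow(z)
  t_steps <- ncol(z)
  if (t_steps != params$n_steps) stop("z and params disagree on T")
  if (max(z) > params$q_groups) stop("z has groups beyond Q")
  q <- params$q_groups
  m <- params$n_categories
  presence <- matrix(as.integer(z > 0L), n, t_steps)
  with_local_seed(seed, {
    values <- array(0L, c(n, n, t_steps))
    for (t in seq_len(t_steps)) {
      pres <- which(presence[, t] == 1L)
      if (length(pres) < 1L) next
      zt <- z[pres, t]
      # ordered index pairs into `pres`
      if (params$directed) {
        pr <- expand.grid(a = seq_along(pres), b = seq_along(pres))
        pr <- pr[pr$a != pr$b | params$self_loops, , drop = FALSE]
      } else {
        pr <- expand.grid(a = seq_along(pres), b = seq_along(pres))
        pr <- pr[pr$a < pr$b | (pr$a == pr$b & params$self_loops), ,
                 drop = FALSE]
      }
      if (nrow(pr) == 0L) next
      qa <- zt[pr$a]; ql <- zt[pr$b]
      bet <- params$beta[cbind(qa, ql, t)]
      edge <- stats::runif(nrow(pr)) < bet
      cat_val <- integer(nrow(pr))
      if (any(edge)) {
        if (m == 1L) {
          cat_val[edge] <- 1L
        } else {
          u <- stats::runif(sum(edge))
          cum <- rep(0, sum(edge))
          res <- rep(m, sum(edge))
          done <- rep(FALSE, sum(edge))
          for (mm in seq_len(m - 1L)) {
            cum <- cum + params$gamma[cbind(qa[edge], ql[edge],
                                            rep(t, sum(edge)), mm)]
            hit <- !done & u < cum
            res[hit] <- mm
            done <- done | hit
          }
          cat_val[edge] <- res
        }
      }
      ia <- pres[pr$a]; jb <- pres[pr$b]
      values[cbind(ia, jb, rep(t, nrow(pr)))] <- cat_val
      if (!params$directed)
        values[cbind(jb, ia, rep(t, nrow(pr)))] <- cat_val
    }
    dynamic_network(values, presence, directed = params$directed,
                    self_loops = params$self_loops, n_categories = m,
                    node_labels = node_labels, step_labels = step_labels)
  })
}

#' Built-in simulation scenarios
#'
#' Returns a simulated `(network, memberships, params)` triple with
#' well-separated blocks, at the scale of the systems the model targets.
#'
#' Scenarios:
#' \describe{
#'   \item{`ants_like`}{N = 152 individuals over T = 10 daily snapshots,
#'     undirected, weights binned into M = 3 intensity categories, Q = 3
#'     groups: two cohesive groups (one with high-intensity contacts), a
#'     third group weakly tied to the second — the structure of a colony
#'     contact network.}
#'   \item{`foodweb_like`}{N = 26 species over T = 6 seasonal snapshots,
#'     directed binary feeding links with self-loops (cannibalism), Q = 4
#'     trophic groups (peripheral species, common prey, intermediate and
#'     top predators), about 20\% absent node-steps and a drop in link
#'     density in the later seasons.}
#'   \item{`bernoulli_recovery`}{N = 100, T = 10, Q = 3, binary undirected,
#'     within-group density 0.4, between-group 0.05, transition matrix with
#'     0.9 on the diagonal — an assortative benchmark for membership and
#'     parameter recovery.}
#'   \item{`multinomial_recovery`}{N = 180, T = 5, Q = 3, undirected,
#'     M = 3 categories with a distinct intensity profile per block pair,
#'     within-group density 0.6, between-group 0.25.}
#' }
#'
#' @param scenario one of `"ants_like"`, `"foodweb_like"`,
#'   `"bernoulli_recovery"`, `"multinomial_recovery"`.
#' @param seed integer RNG seed.
#' @return list with elements `net`, `z`, `params`.
#' @export
make_fixture <- function(scenario, seed) {
  params <- fixture_params(scenario)
  n <- switch(scenario, ants_like = 152L, foodweb_like = 26L,
              bernoulli_recovery = 100L, multinomial_recovery = 180L)
  t_steps <- params$n_steps
  presence <- matrix(1L, n, t_steps)
  if (scenario == "foodweb_like") {
    presence <- with_local_seed(derive_seed(seed, 1L), {
      p <- matrix(as.integer(stats::runif(n * t_steps) > 0.2), n, t_steps)
      for (i in which(rowSums(p) == 0L)) p[i, sample.int(t_steps, 1L)] <- 1L
      p
    })
  }
  z <- simulate_memberships(params, presence, derive_seed(seed, 2L))
  net <- simulate_network(params, z, derive_seed(seed, 3L))
  list(net = net, z = z, params = params)
}

fixture_params <- function(scenario) {
  switch(
    scenario,
    ants_like = {
      t_steps <- 10L
      beta <- array(0, c(3, 3, t_steps))
      for (t in seq_len(t_steps)) {
        b <- matrix(c(0.85, 0.55, 0.45,
                      0.55, 0.85, 0.10,
                      0.45, 0.10, 0.55), 3, 3, byrow = TRUE)
        # mild seasonal wobble on between-group densities only
        w <- 0.08 * sin(2 * base::pi * (t - 1) / t_steps)
        b[1, 2] <- b[2, 1] <- b[1, 2] + w
        b[1, 3] <- b[3, 1] <- b[1, 3] - w
        beta[, , t] <- b
      }
      g <- array(0, c(3, 3, 3))
      g[1, 1, ] <- c(0.40, 0.35, 0.25)
      g[2, 2, ] <- c(0.10, 0.25, 0.65)
      g[3, 3, ] <- c(0.55, 0.30, 0.15)
      g[1, 2, ] <- g[2, 1, ] <- c(0.30, 0.40, 0.30)
      g[1, 3, ] <- g[3, 1, ] <- c(0.35, 0.35, 0.30)
      g[2, 3, ] <- g[3, 2, ] <- c(0.70, 0.20, 0.10)
      gamma <- array(0, c(3, 3, t_steps, 3))
      for (t in seq_len(t_steps)) gamma[, , t, ] <- g
      dynsbm_params(
        alpha = rep(1 / 3, 3),
        pi = matrix(c(0.90, 0.05, 0.05,
                      0.05, 0.90, 0.05,
                      0.05, 0.05, 0.90), 3, 3, byrow = TRUE),
        beta = beta, gamma = gamma, directed = FALSE, self_loops = FALSE)
    },
    foodweb_like = {
      t_steps <- 6L
      # row q = consumer group, column l = resource group
      b <- matrix(c(0.03, 0.05, 0.02, 0.02,
                    0.05, 0.04, 0.02, 0.02,
                    0.40, 0.80, 0.50, 0.05,
                    0.50, 0.80, 0.70, 0.60), 4, 4, byrow = TRUE)
      beta <- array(0, c(4, 4, t_steps))
      for (t in seq_len(t_steps)) {
        bt <- b
        if (t >= 4L) {         # seasonal thinning of off-diagonal links
          off <- !diag(4)
          bt[off] <- 0.6 * bt[off]
        }
        beta[, , t] <- bt
      }
      dynsbm_params(
        alpha = c(0.35, 0.30, 0.20, 0.15),
        pi = matrix(c(0.85, 0.05, 0.05, 0.05,
                      0.05, 0.85, 0.05, 0.05,
                      0.05, 0.05, 0.85, 0.05,
                      0.05, 0.05, 0.05, 0.85), 4, 4, byrow = TRUE),
        beta = beta, gamma = NULL, directed = TRUE, self_loops = TRUE)
    },
    bernoulli_recovery = {
      t_steps <- 10L
      b <- matrix(0.05, 3, 3); diag(b) <- 0.4
      dynsbm_params(
        alpha = rep(1 / 3, 3),
        pi = matrix(c(0.90, 0.05, 0.05,
                      0.05, 0.90, 0.05,
                      0.05, 0.05, 0.90), 3, 3, byrow = TRUE),
        beta = b, gamma = NULL, directed = FALSE, self_loops = FALSE,
        n_steps = t_steps)
    },
    multinomial_recovery = {
      t_steps <- 5L
      b <- matrix(0.25, 3, 3); diag(b) <- 0.6
      g <- array(0, c(3, 3, 3))
      g[1, 1, ] <- c(0.70, 0.20, 0.10)
      g[2, 2, ] <- c(0.20, 0.60, 0.20)
      g[3, 3, ] <- c(0.10, 0.20, 0.70)
      g[1, 2, ] <- g[2, 1, ] <- c(0.50, 0.30, 0.20)
      g[1, 3, ] <- g[3, 1, ] <- c(0.30, 0.40, 0.30)
      g[2, 3, ] <- g[3, 2, ] <- c(0.20, 0.30, 0.50)
      dynsbm_params(
        alpha = rep(1 / 3, 3),
        pi = matrix(c(0.90, 0.05, 0.05,
                      0.05, 0.90, 0.05,
                      0.05, 0.05, 0.90), 3, 3, byrow = TRUE),
        beta = array(b, c(3, 3, t_steps)),
        gamma = g, # Q x Q x M, recycled over steps by the constructor
        directed = FALSE, self_loops = FALSE, n_steps = t_steps)
    },
    stop("unknown scenario: ", scenario)
  )
}

# ---------------------------------------------------------------------------
# parameter (de)serialisation

#' Write fitted or simulation parameters to JSON
#'
#' @param params a [dynsbm_params()].
#' @param path output file.
#' @export
params_to_json <- function(params, path) {
  doc <- list(
    q_groups = params$q_groups, n_steps = params$n_steps,
    n_categories = params$n_categories,
    directed = params$directed, self_loops = params$self_loops,
    alpha = params$alpha, pi = params$pi, beta = params$beta,
    gamma = params$gamma
  )
  tmp <- paste0(path, ".tmp", Sys.getpid())
  jsonlite::write_json(doc, tmp, digits = NA, auto_unbox = TRUE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Read parameters written by [params_to_json()]
#'
#' @param path JSON file.
#' @return a [dynsbm_params()].
#' @export
params_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  q <- doc$q_groups; t_steps <- doc$n_steps; m <- doc$n_categories
  gamma <- if (length(doc$gamma) == 0L) NULL else
    array(unlist(doc$gamma), c(q, q, t_steps, m))
  dynsbm_params(
    alpha = doc$alpha,
    pi = matrix(unlist(doc$pi), q, q),
    beta = array(unlist(doc$beta), c(q, q, t_steps)),
    gamma = gamma,
    directed = doc$directed, self_loops = doc$self_loops)
}
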