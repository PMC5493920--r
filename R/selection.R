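# Choosing the number of groups: ICL and the elbow heuristic.

#' Integrated classification likelihood of a fit
#'
#' Penalised completed likelihood: the complete-data log-likelihood at the
#' MAP memberships and fitted parameters, minus half of `log(sample size)`
#' per free parameter, blockwise:
#' \itemize{
#'   \item initial law: `(Q - 1)` parameters penalised by `log N`;
#'   \item Markov transitions: `Q (Q - 1)` parameters penalised by
#'     `log(N (T - 1))` (the transition count scale);
#'   \item emissions: between-group parameters are per step
#'     (`Q (Q - 1) T (1 + (M - 1))`, halved when undirected), within-group
#'     parameters are pooled over time (`Q (1 + (M - 1))`), penalised by
#'     `log D` with `D` the number of observable dyad-step observations.
#' }
#' Blocks with no free parameters (`Q = 1`, or `T = 1` for transitions)
#' contribute no penalty.
#'
#' @param fit a `dynsbm_fit`.
#' @param net the [dynamic_network()] that was fitted.
#' @return a scalar; larger is better.
#' @export
icl <- function(fit, net) {
  q <- fit$q_groups
  n <- net$n_nodes
  t_steps <- net$n_steps
  m <- net$n_categories
  cll <- complete_log_likelihood(net, fit$map_memberships, fit$params)
  d <- n_observable_dyads(net)
  k_off <- q * (q - 1L) * t_steps * (1L + (m - 1L)) /
    (if (net$directed) 1L else 2L)
  k_diag <- q * (1L + (m - 1L))
  pen <- 0.5 * (k_off + k_diag) * log(d)
  if (q > 1L) {
    pen <- pen + 0.5 * (q - 1L) * log(n)
    if (t_steps > 1L)
      pen <- pen + 0.5 * q * (q - 1L) * log(n * (t_steps - 1L))
  }
  cll - pen
}

n_observable_dyads <- function(net) {
  total <- 0
  for (t in seq_len(net$n_steps)) {
    nt <- sum(net$presence[, t])
    total <- total +
      (if (net$directed) nt * (nt - 1L) else nt * (nt - 1L) / 2) +
      (if (net$self_loops) nt else 0L)
  }
  total
}

#' Elbow selection on a log-likelihood sequence
#'
#' Formalises "the point where the slope of the log-likelihood
#' significantly decreases" as the point of maximum discrete curvature:
#' the interior `Q` maximising
#' `(ll[k] - ll[k-1]) - (ll[k+1] - ll[k])`, ties going to the smallest
#' `Q`. Invariant to adding a constant to all values.
#'
#' @param q_values increasing integer vector (at least 3 values).
#' @param loglik matching log-likelihood (or ELBO) values.
#' @return the selected element of `q_values`.
#' @export
select_elbow <- function(q_values, loglik) {
  if (length(q_values) < 3L) stop("elbow selection needs at least 3 points")
  if (length(loglik) != length(q_values))
    stop("q_values and loglik lengths differ")
  k <- 2:(length(q_values) - 1L)
  curv <- (loglik[k] - loglik[k - 1L]) - (loglik[k + 1L] - loglik[k])
  q_values[k[which.max(curv)]]   # which.max takes the first tie
}

#' Fit a range of group counts and score each model
#'
#' Runs [fit_dynsbm()] for every `Q` in `q_min..q_max` with shared
#' settings and per-`Q` seeds derived from `seed`, and records the final
#' ELBO and [icl()] of each fit.
#'
#' @param net a [dynamic_network()].
#' @param q_min,q_max scan range.
#' @param seed integer master seed.
#' @inheritParams fit_dynsbm
#' @return a `dynsbm_scan`: list with `q_values`, `fits`, `elbo`, `icl`,
#'   `best_icl` and (when the scan has 3+ points) `best_elbow`.
#' @export
scan_q <- function(net, q_min, q_max, n_init = 5L, max_iter = 100L,
                   tol = 1e-6, max_inner = 5L, inner_tol = 1e-4, seed = 1L) {
  q_min <- as.integer(q_min); q_max <- as.integer(q_max)
  if (q_min < 1L || q_min > q_max) stop("need 1 <= q_min <= q_max")
  q_values <- q_min:q_max
  fits <- lapply(q_values, function(q)
    fit_dynsbm(net, q, n_init = n_init, max_iter = max_iter, tol = tol,
               max_inner = max_inner, inner_tol = inner_tol,
               seed = derive_seed(seed, 1000L + q)))
  elbos <- vapply(fits, function(f) f$elbo, numeric(1))
  icls <- vapply(fits, function(f) icl(f, net), numeric(1))
  structure(list(
    q_values = q_values, fits = fits, elbo = elbos, icl = icls,
    best_icl = q_values[which.max(icls)],
    best_elbow = if (length(q_values) >= 3L)
      select_elbow(q_values, elbos) else NA_integer_
  ), class = "dynsbm_scan")
}

#' @export
print.dynsbm_scan <- function(x, ...) {
  df <- data.frame(Q = x$q_values, elbo = x$elbo, icl = x$icl,
                   icl_best = x$q_values == x$best_icl,
                   elbow_best = !is.na(x$best_elbow) &
                     x$q_values == x$best_elbow)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a scan summary as CSV
#'
#' Columns: `Q, elbo, icl, icl_selected, elbow_selected`.
#'
#' @param scan a `dynsbm_scan`.
#' @param path output file.
#' @export
write_scan_csv <- function(scan, path) {
  df <- data.frame(
    Q = scan$q_values, elbo = scan$elbo, icl = scan$icl,
    icl_selected = as.integer(scan$q_values == scan$best_icl),
    elbow_selected = as.integer(!is.na(scan$best_elbow) &
                                  scan$q_values == scan$best_elbow))
  tmp <- paste0(path, ".tmp", Sys.getpid())
  utils::write.csv(df, tmp, row.names = FALSE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
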