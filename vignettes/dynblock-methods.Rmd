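---
title: "Dynamic stochastic block models in dynblock: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic stochastic block models in dynblock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynblock)
```

## The model

A dynamic network is a sequence of $T$ snapshots of the same system: a
colony contact network aggregated by day, a food web sampled by season,
or any sequence indexed by a one-dimensional gradient. `dynblock` fits a
dynamic stochastic block model (dynSBM) to such data. Its two layers are:

**Membership chains.** Each of the $N$ nodes carries a latent group
$Z_{it} \in \{1, \dots, Q\}$ that evolves as a Markov chain, i.i.d.
across nodes: the group at a node's first observed step is drawn from an
initial law $\alpha$, and consecutive observed steps are linked by a
common $Q \times Q$ transition matrix $\Pi$,
$\Pr(Z_{it} = l \mid Z_{i,t-1} = q) = \Pi_{ql}$. Because of this chain,
the groups estimated at one step borrow strength from all the other
steps — the model is not a per-snapshot clustering glued together
afterwards.

**Zero-inflated block emissions.** Conditional on the endpoint groups,
each observable dyad is drawn independently:
$$\Pr(Y_{ijt} = 0) = 1 - \beta_{qlt}, \qquad
  \Pr(Y_{ijt} = m) = \beta_{qlt}\,\gamma_{qlt}(m), \quad m = 1, \dots, M,$$
with $(q, l) = (Z_{it}, Z_{jt})$. The point mass at zero (edge absent)
makes sparsity $\beta$ and intensity $\gamma$ separately interpretable
and separately estimable; with $M = 1$ the emission reduces to a
Bernoulli for binary networks. Directed networks use ordered pairs
($\beta_{qlt} \ne \beta_{lqt}$ in general) and self-loops, when enabled,
use the diagonal block of the node's own group.

**Arrivals and departures.** A binary presence mask $R_{it}$ records
which nodes are part of the network at which steps. Absent node-steps
emit nothing, contribute nothing to any likelihood quantity, and are
reported as the special group 0. Two consecutive *present* steps of a
node are bridged by a single application of $\Pi$ regardless of the gap
length. This is a deliberate contract: the alternative readings (a power
of $\Pi$ per skipped step, or a fresh draw from $\alpha$ at each return)
require a model of what the entity did while unobserved, which the data
cannot inform at the scales this package targets; the single-step rule is
the simplest exchangeable choice and is what the simulator implements, so
inference and simulation agree exactly.

**Identifiability.** With time-varying memberships and fully
time-varying emissions, group labels could be permuted independently at
every step. The model is anchored by holding the *within-group*
parameters $\beta_{qq}$ and $\gamma_{qq}(\cdot)$ constant over time while
between-group parameters may vary freely with $t$: a group is defined by
its stable internal signature, and changes over time are expressed
through memberships and between-group mixing. We apply the constraint to
both $\beta$ and $\gamma$ — for a weighted network a group whose internal
contact *intensity* drifts freely would be as unidentifiable as one
whose internal density drifts. The simulator enforces the same
constraint, so recovery experiments are well posed.

## Variational EM

The exact likelihood sums over $Q^{\sum_{it} R_{it}}$ membership
configurations, so we maximise an evidence lower bound (ELBO) instead.
The variational family is a product over nodes of Markov chains on each
node's present steps: the coupling *across* nodes is broken, while the
temporal dependence *within* a node is kept exact. The two alternating
steps are:

- **E-step.** Nodes are swept in index order (Gauss–Seidel). For node
  $i$, the emission message at step $t$ is
  $\log \rho_{itq} = \sum_{j \ne i} \sum_l \tau_{jtl} \log f(Y_{ijt};
  \Theta_{qlt})$ (both directions summed for directed networks, the
  self-loop adding its diagonal term), and an exact forward–backward
  pass along the node's present steps with initial law $\alpha$ and
  transitions $\Pi$ produces its new marginals $\tau_{i \cdot \cdot}$ and
  pairwise weights $\xi_i$. Each node update is an exact coordinate
  maximisation of the ELBO given all the other nodes, so sweeps can
  never decrease the objective; sweeping stops after `max_inner`
  passes or when $\max |\Delta\tau|$ falls below `tol`. The sweep order
  is fixed for bit-reproducibility.
- **M-step.** Closed forms: $\alpha$ from the marginals at first present
  steps, $\Pi$ from the summed pairwise weights, $\beta$ and $\gamma$
  from $\tau$-weighted dyad frequencies — per step for between-group
  entries, pooled over all steps for the within-group (diagonal) entries,
  which is exactly the maximiser under the identifiability constraint.

Every ratio in the M-step is smoothed with $\varepsilon = 10^{-6}$
(counts in the numerator, $K\varepsilon$ in the denominator for a
$K$-valued parameter). This serves one purpose: $Q$ is the *maximal*
number of groups and groups are allowed to empty out at some or all
steps, and an emptied group must keep valid parameters rather than
produce $0/0$ or $\log 0$. No group is ever deleted mid-run.

The ELBO is computed after each M-step as the expected complete
log-likelihood plus the entropy of the variational chains. Its trace is
stored per initialisation (`fit$all_traces`) so monotonicity is auditable
post hoc; a decrease beyond relative $10^{-8}$ is treated as a bug by the
test suite. MAP membership trajectories are decoded per node by Viterbi
on (log $\alpha$, log $\Pi$, converged messages) — decoding the chain
jointly rather than taking pointwise argmaxes of $\tau$, which could
produce a trajectory that is impossible under $\Pi$. Ties break toward
the lowest group index.

### Tunable parameters

| parameter | default | role |
|---|---|---|
| `q_groups` | — | maximal number of groups; select with `scan_q()` |
| `n_init` | 5 | restarts: 1 k-means on the time-aggregated adjacency + 4 random |
| `max_iter` | 100 | EM iterations per restart |
| `tol` | 1e-6 | relative ELBO convergence |
| `max_inner` | 5 | Gauss–Seidel sweeps per E-step |
| `inner_tol` | 1e-4 | sweep convergence on max change in tau |
| `seed` | 1 | controls every random draw of the fit |

The k-means initialisation clusters the rows of the adjacency summed
over time (rows and columns concatenated for directed networks):
aggregated structure is a strong and nearly free starting point, and the
random restarts guard against its failure modes (e.g. groups that exist
only at some steps and vanish in aggregation).

## Choosing the number of groups

`icl()` implements a penalised completed likelihood: the complete-data
log-likelihood at the MAP memberships minus $\tfrac12 k \log n$ per
parameter block, with each block penalised on its own sample-size scale —
$(Q-1)$ initial-law parameters against $\log N$, $Q(Q-1)$ transition
parameters against $\log(N(T-1))$ (the number of observed transitions),
and the emission parameters against $\log D$ with $D$ the number of
observable dyad-step observations. Between-group emissions count
$Q(Q-1)\,T\,M$ parameters (halved when undirected); within-group ones
are time-pooled, $Q\,M$. Blocks with no free parameters ($Q = 1$; the
transition block when $T = 1$) contribute nothing. The exact constants of
an ICL criterion vary between implementations in this literature; the
formula is kept in one function so the tested contract is the *selection
behaviour*, not the absolute value.

`select_elbow()` formalises the common elbow reading of a
log-likelihood-versus-$Q$ curve as the interior point of maximum discrete
curvature $(\ell_k - \ell_{k-1}) - (\ell_{k+1} - \ell_k)$, ties toward
the smaller $Q$. It is invariant to adding a constant to the curve.

## Weight binning

Raw interaction weights are discretised once for the whole dynamic
network: all positive weights, pooled across every dyad and step, are
split into $M$ equal-frequency bins; a weight equal to a bin threshold
goes to the lower bin, and zeros are untouched. Pooling over time (rather
than per step) keeps the meaning of "low/medium/high intensity"
comparable across snapshots, which is what makes the intensity panels of
`connectivity_summary()` readable as time series. Binning is
deterministic and order-independent; asking for more bins than there are
distinct positive weights is an error rather than a silent merge.

## What the simulator emulates — and what it does not

`make_fixture()` provides four documented scenarios:

- **`ants_like`** (N = 152, T = 10, undirected, M = 3, Q = 3): the scale
  of a tracked insect colony observed daily; two cohesive groups, one of
  them with high-intensity internal contacts, and a third group weakly
  tied to the second, with mild seasonal wobble on between-group
  densities. Transition matrix diagonal 0.9.
- **`foodweb_like`** (N = 26, T = 6, directed, self-loops, M = 1,
  Q = 4): the scale of a seasonal stream food web; trophic structure
  (peripheral species, common prey, intermediate and top predators,
  cannibalism on the diagonal), roughly 20% absent node-steps, and a
  thinning of between-group links in the later seasons.
- **`bernoulli_recovery`** (N = 100, T = 10, Q = 3): the assortative
  benchmark used by the recovery and model-selection experiments —
  within-group density 0.4, between-group 0.05, transition diagonal 0.9.
- **`multinomial_recovery`** (N = 180, T = 5, Q = 3, M = 3): distinct
  intensity profiles per block pair over a moderately dense graph. N is
  sized so that the binomial sampling error of a per-step between-group
  category proportion (~900 edges per block-step, s.e. ≈ 0.017) sits
  well below the ±0.05 band the recovery tests probe.

Passing tests on these fixtures show that the estimator recovers the
structure *of its own generative model* at realistic scales. They do not
show robustness to what real data add: overdispersion and day effects,
degree heterogeneity within groups, observation error in edge detection,
non-Markov membership dynamics, or informative absence (species that
disappear *because* of their trophic position). Those are model
misspecifications, not software properties, and should be assessed per
dataset.

## Numerical choices and degenerate inputs

- All chain computations (forward–backward, Viterbi, enumeration) are in
  log space with log-sum-exp stabilisation; a configuration with zero
  probability yields `-Inf`, never an exception, and `0 * log 0` is 0 by
  convention wherever an expectation is assembled.
- `exact_log_marginal()` enumerates every membership configuration
  (guarded at $Q^{\#\text{present node-steps}} \le 2^{20}$). It exists as
  the in-package oracle for the variational bound and is used by the test
  suite on tiny instances.
- A node absent at every step is legal input: it contributes nothing to
  any sum and is reported as group 0 throughout.
- Undirected dyads are stored symmetrically and counted once per
  unordered pair in every likelihood and every summary table; the
  within-group cell of a connectivity table counts $\binom{n_q}{2}$
  pairs plus $n_q$ self-loops when those are enabled, so proportions are
  reproducible bit-exactly.
- Ties — in Viterbi decoding, modal-group computation, elbow selection
  and weight binning — always resolve toward the lowest index/bin, so
  every output is a deterministic function of (data, settings, seed).

## Problem sizes in the test suite

The statistical experiments in the test suite run at the scales above:
50 enumeration-oracle instances ($N \le 4$, $T \le 3$), 10-seed recovery
and model-selection experiments on `bernoulli_recovery` and
`multinomial_recovery`, and one full `ants_like` fit. The complete suite
executes in under two minutes on a single core; the E-step sweep is
implemented in C++ (Rcpp), which is what makes 10-seed × 5-model scans
routine on a laptop.

## Known limitations

- Emission families are zero-inflated multinomial and Bernoulli only; no
  Gaussian or Poisson weights, no degree correction, no covariates.
- One transition matrix is shared by all nodes; there are no node- or
  group-level departure/return dynamics (absence is conditioned on, not
  modelled).
- Model selection refits the full model for every candidate $Q$; there is
  no path reuse between fits.
- No standard errors or posterior uncertainty on parameters; the
  variational marginals $\tau$ quantify membership uncertainty only up to
  the mean-field approximation.
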