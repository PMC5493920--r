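// Variational E-step for the dynamic SBM.
//
// Mean-field family: a product over nodes of Markov chains on each node's
// present steps. One sweep updates nodes in index order (Gauss-Seidel):
// for node i, emission messages are assembled from the current marginals
// of the other nodes, then an exact forward-backward pass along i's
// present steps yields its new marginals tau and pairwise weights xi.
// Each node update is an exact coordinate maximisation of the ELBO, so
// sweeps never decrease the objective.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t k = 1; k < v.size(); ++k) if (v[k] > m) m = v[k];
  if (!R_finite(m)) return m;
  double s = 0.0;
  for (size_t k = 0; k < v.size(); ++k) s += std::exp(v[k] - m);
  return m + std::log(s);
}

// y:        N*N*T ints in 0..M (dyad categories)
// presence: N x T ints
// tau_in:   N*T*Q doubles (index i + N*t + N*T*q)
// logf:     Q*Q*(M+1)*T doubles (index q + Q*l + Q*Q*c + Q*Q*(M+1)*t)
// logpi:    Q x Q, logalpha: Q
// xi out:   N*(T-1)*Q*Q (index i + N*k + N*(T-1)*q + N*(T-1)*Q*l), slot k
//           holds the joint weights for the k-th consecutive-present pair
// logrho out: N*T*Q emission messages as of each node's last update
// [[Rcpp::export]]
List estep_sweep_cpp(IntegerVector y, IntegerMatrix presence,
                     NumericVector tau_in, NumericVector logf,
                     NumericMatrix logpi, NumericVector logalpha,
                     bool directed, bool self_loops,
                     int max_inner, double tol) {
  const int N = presence.nrow(), T = presence.ncol();
  const R_xlen_t NT = (R_xlen_t)N * T;
  const int Q = logalpha.size();
  const int M1 = (int)(logf.size() / ((R_xlen_t)Q * Q * T)); // M + 1
  NumericVector tau = clone(tau_in);
  const int TP = T > 1 ? T - 1 : 1;
  NumericVector xi((R_xlen_t)N * TP * Q * Q);
  NumericVector logrho((R_xlen_t)N * T * Q);

  const int* yp = INTEGER(y);
  double* taup = REAL(tau);
  double* xip = REAL(xi);
  double* rhop = REAL(logrho);
  const double* lfp = REAL(logf);
  const R_xlen_t QQ = (R_xlen_t)Q * Q;
  const R_xlen_t QQM = QQ * M1;

  std::vector<int> steps(T);
  std::vector<double> rho((size_t)T * Q), la((size_t)T * Q),
      lb((size_t)T * Q), tmp(Q);

  int sweep = 0;
  double maxdiff = R_PosInf;
  for (sweep = 0; sweep < max_inner && maxdiff >= tol; ++sweep) {
    maxdiff = 0.0;
    for (int i = 0; i < N; ++i) {
      int K = 0;
      for (int t = 0; t < T; ++t) if (presence(i, t)) steps[K++] = t;
      if (K == 0) continue;

      // emission messages at each present step
      for (int k = 0; k < K; ++k) {
        const int t = steps[k];
        const double* lft = lfp + QQM * t;
        double* r = &rho[(size_t)k * Q];
        for (int q = 0; q < Q; ++q) r[q] = 0.0;
        if (self_loops) {
          const int c = yp[i + (R_xlen_t)N * i + (R_xlen_t)N * N * t];
          const double* lfc = lft + QQ * c;
          for (int q = 0; q < Q; ++q) r[q] += lfc[q + (R_xlen_t)Q * q];
        }
        for (int j = 0; j < N; ++j) {
          if (j == i || !presence(j, t)) continue;
          const int c = yp[i + (R_xlen_t)N * j + (R_xlen_t)N * N * t];
          const double* lfc = lft + QQ * c;
          const double* tj = taup + j + (R_xlen_t)N * t; // stride N*T over q
          for (int l = 0; l < Q; ++l) {
            const double tl = tj[NT * l];
            if (tl == 0.0) continue;
            const double* col = lfc + (R_xlen_t)Q * l;
            for (int q = 0; q < Q; ++q) r[q] += tl * col[q];
          }
          if (directed) {
            const int c2 = yp[j + (R_xlen_t)N * i + (R_xlen_t)N * N * t];
            const double* lfc2 = lft + QQ * c2;
            for (int l = 0; l < Q; ++l) {
              const double tl = tj[NT * l];
              if (tl == 0.0) continue;
              for (int q = 0; q < Q; ++q)
                r[q] += tl * lfc2[l + (R_xlen_t)Q * q];
            }
          }
        }
        for (int q = 0; q < Q; ++q)
          rhop[i + (R_xlen_t)N * t + NT * q] = r[q];
      }

      // forward pass (log alpha initial law, log pi between present steps)
      for (int q = 0; q < Q; ++q) la[q] = logalpha[q] + rho[q];
      for (int k = 1; k < K; ++k) {
        for (int q = 0; q < Q; ++q) {
          for (int l = 0; l < Q; ++l)
            tmp[l] = la[(size_t)(k - 1) * Q + l] + logpi(l, q);
          la[(size_t)k * Q + q] = rho[(size_t)k * Q + q] + logsumexp(tmp);
        }
      }
      // backward pass
      for (int q = 0; q < Q; ++q) lb[(size_t)(K - 1) * Q + q] = 0.0;
      for (int k = K - 2; k >= 0; --k) {
        for (int q = 0; q < Q; ++q) {
          for (int l = 0; l < Q; ++l)
            tmp[l] = logpi(q, l) + rho[(size_t)(k + 1) * Q + l] +
                     lb[(size_t)(k + 1) * Q + l];
          lb[(size_t)k * Q + q] = logsumexp(tmp);
        }
      }

      // marginals
      for (int k = 0; k < K; ++k) {
        const int t = steps[k];
        for (int q = 0; q < Q; ++q)
          tmp[q] = la[(size_t)k * Q + q] + lb[(size_t)k * Q + q];
        double mx = tmp[0];
        for (int q = 1; q < Q; ++q) if (tmp[q] > mx) mx = tmp[q];
        double s = 0.0;
        for (int q = 0; q < Q; ++q) {
          tmp[q] = R_finite(mx) ? std::exp(tmp[q] - mx) : 1.0;
          s += tmp[q];
        }
        for (int q = 0; q < Q; ++q) {
          const double nv = tmp[q] / s;
          double& tv = taup[i + (R_xlen_t)N * t + NT * q];
          const double d = std::fabs(nv - tv);
          if (d > maxdiff) maxdiff = d;
          tv = nv;
        }
      }
      // pairwise weights between consecutive present steps
      for (int k = 0; k + 1 < K; ++k) {
        std::vector<double> w((size_t)Q * Q);
        double mx = R_NegInf;
        for (int q = 0; q < Q; ++q) {
          for (int l = 0; l < Q; ++l) {
            const double v = la[(size_t)k * Q + q] + logpi(q, l) +
                             rho[(size_t)(k + 1) * Q + l] +
                             lb[(size_t)(k + 1) * Q + l];
            w[(size_t)q * Q + l] = v;
            if (v > mx) mx = v;
          }
        }
        double s = 0.0;
        for (size_t u = 0; u < w.size(); ++u) {
          w[u] = R_finite(mx) ? std::exp(w[u] - mx) : 1.0;
          s += w[u];
        }
        for (int q = 0; q < Q; ++q)
          for (int l = 0; l < Q; ++l)
            xip[i + (R_xlen_t)N * k + (R_xlen_t)N * TP * q +
                (R_xlen_t)N * TP * Q * l] = w[(size_t)q * Q + l] / s;
      }
    }
  }

  return List::create(_["tau"] = tau, _["xi"] = xi, _["logrho"] = logrho,
                      _["n_sweeps"] = sweep, _["max_change"] = maxdiff);
}
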