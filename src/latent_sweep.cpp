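// Compiled kernels for the Gibbs sampler's hot loops: the per-region
// latent scan (sequential over regions; participants are conditionally
// independent and drawn as a column) and the edge-residual passes.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One full latent scan: optional reflection Metropolis flips, then
// region-by-region normal draws for every participant, then the trait
// draws. Uses R's RNG so chains stay reproducible under set.seed().
// [[Rcpp::export(name = ".latent_sweep_cpp")]]
List latent_sweep_cpp(arma::mat Z, arma::vec theta, const arma::mat& B,
                      const arma::imat& pairs, const arma::mat& Q,
                      double inv_s2, const arma::vec& t_lin,
                      const arma::vec& n_items, double inv_t2,
                      const arma::mat& mask, bool all_obs, bool do_flips) {
  const int N = Z.n_rows, V = Z.n_cols, K = V + 1;
  const int M = pairs.n_rows;
  std::vector<std::vector<int>> cols(V), nbr(V);
  for (int m = 0; m < M; m++) {
    int u = pairs(m, 0) - 1, v = pairs(m, 1) - 1;
    cols[u].push_back(m); nbr[u].push_back(v);
    cols[v].push_back(m); nbr[v].push_back(u);
  }
  arma::vec Qcross = Q.submat(0, K - 1, V - 1, K - 1);
  if (do_flips) {
    arma::vec s = Z * Qcross;
    for (int i = 0; i < N; i++) {
      double logr = 2.0 * theta(i) * s(i);
      if (std::log(R::runif(0.0, 1.0)) < logr) Z.row(i) *= -1.0;
    }
  }
  arma::mat ZQ = Z * Q.submat(0, 0, V - 1, V - 1);
  arma::vec sumZ2 = arma::sum(Z % Z, 1);
  arma::vec dp(N), dl(N), prec(N), lin(N), znew(N), delta(N);
  for (int u = 0; u < V; u++) {
    const std::vector<int>& cu = cols[u];
    const std::vector<int>& nu = nbr[u];
    const int d = cu.size();
    dl.zeros();
    if (all_obs) {
      for (int j = 0; j < d; j++) {
        const double* b = B.colptr(cu[j]);
        const double* z = Z.colptr(nu[j]);
        for (int i = 0; i < N; i++) dl(i) += b[i] * z[i];
      }
      dp = sumZ2 - arma::square(Z.col(u));
    } else {
      dp.zeros();
      for (int j = 0; j < d; j++) {
        const double* b = B.colptr(cu[j]);
        const double* z = Z.colptr(nu[j]);
        const double* mk = mask.colptr(cu[j]);
        for (int i = 0; i < N; i++) {
          if (mk[i] > 0.0) {
            dp(i) += z[i] * z[i];
            dl(i) += b[i] * z[i];
          }
        }
      }
    }
    prec = dp * inv_s2 + Q(u, u);
    lin = dl * inv_s2 - (ZQ.col(u) - Z.col(u) * Q(u, u) + theta * Q(K - 1, u));
    for (int i = 0; i < N; i++) {
      znew(i) = lin(i) / prec(i) + R::rnorm(0.0, 1.0) / std::sqrt(prec(i));
    }
    delta = znew - Z.col(u);
    ZQ += delta * Q.submat(u, 0, u, V - 1);
    sumZ2 += arma::square(znew) - arma::square(Z.col(u));
    Z.col(u) = znew;
  }
  arma::vec zq_cross = Z * Qcross;
  for (int i = 0; i < N; i++) {
    double prec_t = n_items(i) * inv_t2 + Q(K - 1, K - 1);
    double lin_t = t_lin(i) * inv_t2 - zq_cross(i);
    theta(i) = lin_t / prec_t + R::rnorm(0.0, 1.0) / std::sqrt(prec_t);
  }
  return List::create(_["Z"] = Z, _["theta"] = theta);
}

// Single pass over the edge matrix: per-participant residual sums of
// (x - z_u z_v) over observed entries, and the residual sum of squares
// about the full mean (drift = w'beta + a).
// [[Rcpp::export(name = ".edge_resid_stats_cpp")]]
List edge_resid_stats_cpp(const arma::mat& edges, const arma::mat& zz,
                          const arma::vec& drift, const arma::mat& mask,
                          bool all_obs) {
  const int N = edges.n_rows, M = edges.n_cols;
  arma::vec rs(N, arma::fill::zeros);
  double sse = 0.0;
  for (int m = 0; m < M; m++) {
    const double* e = edges.colptr(m);
    const double* z = zz.colptr(m);
    const double* mk = all_obs ? nullptr : mask.colptr(m);
    for (int i = 0; i < N; i++) {
      if (all_obs || mk[i] > 0.0) {
        double b = e[i] - z[i];
        rs(i) += b;
        double r = b - drift(i);
        sse += r * r;
      }
    }
  }
  return List::create(_["row_sums"] = rs, _["sse"] = sse);
}
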