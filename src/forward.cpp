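// Reduced-state HMM forward algorithm with factored sparse transitions and
// emission pruning. States are (e*, per-channel surviving counts) plus one
// absorbing DETACHED state; transition factors are applied in the order
// detachment, Edman, per-channel dye loss, matching the simulator.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double normpdf(double x, double mean, double sd) {
  double z = (x - mean) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.50662827463100050242);
}

// [[Rcpp::export]]
arma::vec hmm_forward_cpp(const arma::sp_mat& detach,
                          const arma::sp_mat& edman,
                          const List& dye_loss,
                          const arma::vec& init,
                          const arma::imat& ell,
                          const arma::mat& Y,   // n_reads x (T*C), time-major
                          const arma::vec& mu,
                          const arma::vec& sigma,
                          const arma::vec& sigma_bg,
                          double cutoff) {
  const int ns = init.n_elem;
  const int C = ell.n_cols;
  const int n_reads = Y.n_rows;
  const int T = Y.n_cols / C;

  std::vector<arma::sp_mat> loss(C);
  for (int c = 0; c < C; ++c) loss[c] = as<arma::sp_mat>(dye_loss[c]);

  arma::ivec n_max(C);
  for (int c = 0; c < C; ++c) n_max(c) = ell.col(c).max();

  arma::vec out(n_reads);
  arma::vec f(ns), w(ns);
  // per-channel per-count emission densities (pruned counts set to zero)
  std::vector<arma::vec> dens(C);
  for (int c = 0; c < C; ++c) dens[c].set_size(n_max(c) + 1);

  for (int r = 0; r < n_reads; ++r) {
    f = init;
    double logscale = 0.0;
    bool dead = false;
    for (int t = 0; t < T; ++t) {
      if (t > 0) {
        double s = arma::accu(f);
        if (s <= 0) { dead = true; break; }
        logscale += std::log(s);
        f /= s;
        f = detach * f;
        f = edman * f;
        for (int c = 0; c < C; ++c) f = loss[c] * f;
      }
      for (int c = 0; c < C; ++c) {
        const double y = Y(r, t * C + c);
        int lo = 0, hi = n_max(c);
        if (std::isfinite(cutoff)) {
          lo = -1; hi = -1;
          for (int l = 0; l <= n_max(c); ++l) {
            double sd = std::sqrt(sigma_bg(c) * sigma_bg(c) +
                                  l * sigma(c) * sigma(c));
            if (std::fabs(y - l * mu(c)) <= cutoff * sd) {
              if (lo < 0) lo = l;
              hi = l;
            }
          }
          if (lo < 0) {  // fallback: nearest count, never an empty kept set
            double best = std::numeric_limits<double>::infinity();
            for (int l = 0; l <= n_max(c); ++l) {
              double dist = std::fabs(y - l * mu(c));
              if (dist < best) { best = dist; lo = l; }
            }
            hi = lo;
          }
        }
        for (int l = 0; l <= n_max(c); ++l) {
          if (l < lo || l > hi) {
            dens[c](l) = 0.0;
          } else {
            double sd = std::sqrt(sigma_bg(c) * sigma_bg(c) +
                                  l * sigma(c) * sigma(c));
            dens[c](l) = normpdf(y, l * mu(c), sd);
          }
        }
      }
      for (int i = 0; i < ns; ++i) {
        double wi = 1.0;
        for (int c = 0; c < C; ++c) wi *= dens[c](ell(i, c));
        f(i) *= wi;
      }
    }
    if (dead) {
      out(r) = -arma::datum::inf;
    } else {
      double s = arma::accu(f);
      out(r) = (s <= 0) ? -arma::datum::inf : logscale + std::log(s);
    }
  }
  return out;
}
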