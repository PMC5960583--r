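// Metropolis-within-Gibbs core for the hierarchical hurdle-exponential
// model.  Only the positive part of the hurdle is handled here: the
// occurrence probabilities have a closed-form Beta conditional (the
// occurrence indicators are fully observed) and are drawn on the R side.
//
// Positive-wall likelihood: x_i ~ Exponential with mean
//   m_i = mu[type_i] + b_boat[boat_i] + b_net[net_i],
// proposals that drive any active m_i (or mu itself) nonpositive are
// rejected.  Priors: mu ~ U(0, mu_upper); b ~ N(0, sigma^2);
// sigma ~ U(0, sigma_upper).  Gaussian random-walk proposals with
// per-parameter step sizes adapted during burn-in only.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

inline double pos_ll(double x, double m) { return -std::log(m) - x / m; }

// delta log-likelihood over one index set for a shift of the group mean
inline bool shift_delta(const std::vector<int>& idx, const NumericVector& x,
                        const std::vector<double>& m, double shift,
                        double& dll) {
  dll = 0.0;
  for (int i : idx) {
    double mn = m[i] + shift;
    if (mn <= 0.0) return false;
    dll += pos_ll(x[i], mn) - pos_ll(x[i], m[i]);
  }
  return true;
}

inline void apply_shift(const std::vector<int>& idx, std::vector<double>& m,
                        double shift) {
  for (int i : idx) m[i] += shift;
}

struct Adapter {
  std::vector<int> acc, tries;
  Adapter(int n) : acc(n, 0), tries(n, 0) {}
  void hit(int p, bool accepted) { tries[p]++; if (accepted) acc[p]++; }
  void adapt(NumericVector& step) {
    for (size_t p = 0; p < acc.size(); ++p) {
      if (tries[p] == 0) continue;
      double rate = double(acc[p]) / tries[p];
      step[p] *= std::exp(rate - 0.44);
      if (step[p] < 1e-10) step[p] = 1e-10;
      if (step[p] > 1e8) step[p] = 1e8;
      acc[p] = 0; tries[p] = 0;
    }
  }
};

} // namespace

// [[Rcpp::export]]
NumericMatrix run_hurdle_chain(NumericVector x, IntegerVector type,
                               IntegerVector boat, IntegerVector net,
                               int n_type, int n_boat, int n_net,
                               NumericVector mu0, NumericVector b_boat0,
                               NumericVector b_net0, double sigma_boat0,
                               double sigma_net0, double mu_upper,
                               double sigma_boat_upper,
                               double sigma_net_upper,
                               bool update_sigma_boat, bool update_sigma_net,
                               NumericVector step, int burn, int thin,
                               int n_keep) {
  const int n = x.size();
  const int n_par = n_type + n_boat + n_net + 2;
  std::vector<std::vector<int>> by_type(n_type), by_boat(n_boat),
      by_net(n_net);
  for (int i = 0; i < n; ++i) {
    by_type[type[i]].push_back(i);
    by_boat[boat[i]].push_back(i);
    by_net[net[i]].push_back(i);
  }

  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> bb(b_boat0.begin(), b_boat0.end());
  std::vector<double> bn(b_net0.begin(), b_net0.end());
  double sb = sigma_boat0, sn = sigma_net0;

  std::vector<double> m(n);
  for (int i = 0; i < n; ++i)
    m[i] = mu[type[i]] + bb[boat[i]] + bn[net[i]];

  NumericVector st = clone(step);
  Adapter ad(n_par);
  NumericMatrix out(n_keep, n_par);
  const int total = burn + thin * n_keep;
  int kept = 0;

  for (int it = 0; it < total; ++it) {
    // --- fixed gear-type means -------------------------------------
    for (int t = 0; t < n_type; ++t) {
      double prop = mu[t] + norm_rand() * st[t];
      bool ok = prop > 0.0 && prop < mu_upper;
      double dll = 0.0;
      if (ok) ok = shift_delta(by_type[t], x, m, prop - mu[t], dll);
      bool accept = ok && std::log(unif_rand()) < dll;
      if (accept) { apply_shift(by_type[t], m, prop - mu[t]); mu[t] = prop; }
      if (it < burn) ad.hit(t, accept);
    }
    // --- boat random effects ---------------------------------------
    if (!(sb == 0.0 && !update_sigma_boat)) {
      for (int j = 0; j < n_boat; ++j) {
        int p = n_type + j;
        double prop = bb[j] + norm_rand() * st[p];
        double dll = 0.0;
        bool ok = shift_delta(by_boat[j], x, m, prop - bb[j], dll);
        if (ok && sb > 0.0)
          dll += -0.5 * (prop * prop - bb[j] * bb[j]) / (sb * sb);
        else if (sb <= 0.0)
          ok = false;
        bool accept = ok && std::log(unif_rand()) < dll;
        if (accept) { apply_shift(by_boat[j], m, prop - bb[j]); bb[j] = prop; }
        if (it < burn) ad.hit(p, accept);
      }
    }
    // --- net random effects ----------------------------------------
    if (!(sn == 0.0 && !update_sigma_net)) {
      for (int k = 0; k < n_net; ++k) {
        int p = n_type + n_boat + k;
        double prop = bn[k] + norm_rand() * st[p];
        double dll = 0.0;
        bool ok = shift_delta(by_net[k], x, m, prop - bn[k], dll);
        if (ok && sn > 0.0)
          dll += -0.5 * (prop * prop - bn[k] * bn[k]) / (sn * sn);
        else if (sn <= 0.0)
          ok = false;
        bool accept = ok && std::log(unif_rand()) < dll;
        if (accept) { apply_shift(by_net[k], m, prop - bn[k]); bn[k] = prop; }
        if (it < burn) ad.hit(p, accept);
      }
    }
    // --- random-effect scales --------------------------------------
    if (update_sigma_boat) {
      int p = n_type + n_boat + n_net;
      double prop = sb + norm_rand() * st[p];
      bool ok = prop > 0.0 && prop < sigma_boat_upper;
      double dll = 0.0;
      if (ok) {
        double ss = 0.0;
        for (double b : bb) ss += b * b;
        dll = -n_boat * (std::log(prop) - std::log(sb)) -
              0.5 * ss * (1.0 / (prop * prop) - 1.0 / (sb * sb));
      }
      bool accept = ok && std::log(unif_rand()) < dll;
      if (accept) sb = prop;
      if (it < burn) ad.hit(p, accept);
    }
    if (update_sigma_net) {
      int p = n_type + n_boat + n_net + 1;
      double prop = sn + norm_rand() * st[p];
      bool ok = prop > 0.0 && prop < sigma_net_upper;
      double dll = 0.0;
      if (ok) {
        double ss = 0.0;
        for (double b : bn) ss += b * b;
        dll = -n_net * (std::log(prop) - std::log(sn)) -
              0.5 * ss * (1.0 / (prop * prop) - 1.0 / (sn * sn));
      }
      bool accept = ok && std::log(unif_rand()) < dll;
      if (accept) sn = prop;
      if (it < burn) ad.hit(p, accept);
    }

    if (it < burn) {
      if ((it + 1) % 50 == 0) ad.adapt(st);
    } else if ((it - burn + 1) % thin == 0) {
      int c = 0;
      for (int t = 0; t < n_type; ++t) out(kept, c++) = mu[t];
      for (int j = 0; j < n_boat; ++j) out(kept, c++) = bb[j];
      for (int k = 0; k < n_net; ++k) out(kept, c++) = bn[k];
      out(kept, c++) = sb;
      out(kept, c) = sn;
      ++kept;
      if (kept == n_keep) break;
    }
  }
  return out;
}
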