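// Core MCMC loop for the hierarchical Bernoulli RSF.
// Updates per iteration:
//   - per individual: blocked random-walk Metropolis on the coefficient
//     vector (proposal shaped by the penalized Fisher information), then
//     a scalar Metropolis sweep over single coefficients;
//   - group level: joint translation moves (mu_k and all beta_ik shifted
//     together), conjugate Gaussian update of mu, slice sampling of each
//     sigma_k on the log scale (half-normal prior).
// Linear predictors eta and exp(eta) are cached and updated
// incrementally; single-covariate moves touch only the rows where the
// covariate is non-zero, so sparse 0/1 presence layers are cheap.

#include <Rcpp.h>
using namespace Rcpp;

// stable log(1 + exp(eta)) from cached E = exp(eta)
static inline double softp(double E, double eta) {
  return (std::isfinite(E) && E < 1e300) ? log1p(E) : eta;
}

// one univariate slice-sampling update with stepping out (Neal 2003)
template <class F>
static double slice1(double x0, F logf, double w, int max_steps) {
  double f0 = logf(x0);
  double z = f0 - R::rexp(1.0);
  double u = R::runif(0.0, 1.0);
  double L = x0 - w * u, Rr = L + w;
  int j = (int)std::floor(R::runif(0.0, 1.0) * max_steps);
  int k = max_steps - 1 - j;
  while (j > 0 && logf(L) > z) { L -= w; --j; }
  while (k > 0 && logf(Rr) > z) { Rr += w; --k; }
  for (;;) {
    double x1 = R::runif(L, Rr);
    if (logf(x1) >= z) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
    if (Rr - L < 1e-12) return x0;
  }
}

struct IndData {
  NumericMatrix X, L;
  NumericVector y, m;
  std::vector<std::vector<int> > nzidx;     // per covariate: non-zero rows
  std::vector<std::vector<double> > nzval;  // values at those rows
  std::vector<bool> binary;                 // all non-zero values == 1?
  std::vector<double> eta, E;
  double ll;
};

static void recompute(IndData &D, const NumericMatrix &B, int i, int p) {
  const int n = D.X.nrow();
  D.ll = 0.0;
  for (int r = 0; r < n; ++r) {
    double e = 0.0;
    for (int k = 0; k < p; ++k) e += D.X(r, k) * B(i, k);
    D.eta[r] = e;
    D.E[r] = std::exp(e);
    D.ll += D.y[r] * e - D.m[r] * softp(D.E[r], e);
  }
}

// delta log-likelihood of shifting covariate k by dlt; applies the shift
// when apply = true
static double shift_cov(IndData &D, int k, double dlt, bool apply) {
  const std::vector<int> &idx = D.nzidx[k];
  const std::vector<double> &val = D.nzval[k];
  const bool bin = D.binary[k];
  const double ed = std::exp(dlt);
  double dll = 0.0;
  const int nnz = idx.size();
  for (int j = 0; j < nnz; ++j) {
    const int r = idx[j];
    const double x = val[j];
    const double e_new = D.eta[r] + dlt * x;
    const double E_new = bin ? D.E[r] * ed : std::exp(e_new);
    if (apply) {
      D.eta[r] = e_new;
      D.E[r] = E_new;
    } else {
      dll += D.y[r] * dlt * x -
        D.m[r] * (softp(E_new, e_new) - softp(D.E[r], D.eta[r]));
    }
  }
  return dll;
}

// [[Rcpp::export]]
List run_rsf_chain_cpp(List Xs, List ys, List ms, List Ls,
                       NumericMatrix B_init, NumericVector mu_init,
                       NumericVector sigma_init, bool hierarchical,
                       double mean_sd, double sigma_sd,
                       int iter, int warmup) {
  const int n_ind = Xs.size();
  const int p = mu_init.size();
  RNGScope scope;

  std::vector<IndData> D(n_ind);
  for (int i = 0; i < n_ind; ++i) {
    D[i].X = as<NumericMatrix>(Xs[i]);
    D[i].y = as<NumericVector>(ys[i]);
    D[i].m = as<NumericVector>(ms[i]);
    D[i].L = as<NumericMatrix>(Ls[i]);
    const int n = D[i].X.nrow();
    D[i].eta.resize(n);
    D[i].E.resize(n);
    D[i].nzidx.resize(p);
    D[i].nzval.resize(p);
    D[i].binary.resize(p);
    for (int k = 0; k < p; ++k) {
      bool bin = true;
      for (int r = 0; r < n; ++r) {
        const double x = D[i].X(r, k);
        if (x != 0.0) {
          D[i].nzidx[k].push_back(r);
          D[i].nzval[k].push_back(x);
          if (x != 1.0) bin = false;
        }
      }
      D[i].binary[k] = bin;
    }
  }

  NumericMatrix B = clone(B_init);
  NumericVector mu = clone(mu_init), sigma = clone(sigma_init);
  for (int i = 0; i < n_ind; ++i) recompute(D[i], B, i, p);

  std::vector<double> s_ind(n_ind, 2.38 / std::sqrt((double)p));
  NumericMatrix s_sc(n_ind, p);
  std::fill(s_sc.begin(), s_sc.end(), 0.3);
  std::vector<double> s_tr(p, 0.25);
  std::vector<double> s_sg(p, 0.3);
  std::vector<double> acc_ind(n_ind, 0.0);

  NumericMatrix keep_mu(iter, p);
  NumericMatrix keep_sigma(hierarchical ? iter : 1, hierarchical ? p : 1);
  NumericVector keep_B(Dimension(iter, n_ind, p));

  std::vector<double> prop(p), eta_p, E_p;
  const double tau0 = mean_sd;
  const int total = warmup + iter;

  for (int t = 1; t <= total; ++t) {
    if (t % 256 == 0) {
      Rcpp::checkUserInterrupt();
      for (int i = 0; i < n_ind; ++i) recompute(D[i], B, i, p);
    }
    for (int i = 0; i < n_ind; ++i) {
      const int n = D[i].X.nrow();
      // blocked RWM with Fisher-shaped proposal: prop = B_i + s * z^T U
      std::vector<double> z(p);
      for (int k = 0; k < p; ++k) z[k] = R::rnorm(0.0, 1.0);
      for (int k = 0; k < p; ++k) {
        double d = 0.0;
        for (int j = 0; j <= k; ++j) d += z[j] * D[i].L(j, k);
        prop[k] = B(i, k) + s_ind[i] * d;
      }
      eta_p.resize(n); E_p.resize(n);
      double llp = 0.0;
      for (int r = 0; r < n; ++r) {
        double e = 0.0;
        for (int k = 0; k < p; ++k) e += D[i].X(r, k) * prop[k];
        eta_p[r] = e;
        E_p[r] = std::exp(e);
        llp += D[i].y[r] * e - D[i].m[r] * softp(E_p[r], e);
      }
      double lpr = 0.0;
      for (int k = 0; k < p; ++k) {
        const double mk = hierarchical ? mu[k] : 0.0;
        const double sk = hierarchical ? sigma[k] : mean_sd;
        lpr += R::dnorm(prop[k], mk, sk, 1) - R::dnorm(B(i, k), mk, sk, 1);
      }
      const double a = llp - D[i].ll + lpr;
      if (std::isfinite(a) && std::log(R::runif(0.0, 1.0)) < a) {
        for (int k = 0; k < p; ++k) B(i, k) = prop[k];
        D[i].ll = llp;
        D[i].eta.swap(eta_p);
        D[i].E.swap(E_p);
        acc_ind[i] += 1.0;
      }
      if (t <= warmup) {
        const double ar = std::isfinite(a) ? std::min(1.0, std::exp(a)) : 0.0;
        s_ind[i] *= std::exp((ar - 0.234) / std::sqrt((double)t));
      }

      // scalar sweep over single coefficients
      for (int k = 0; k < p; ++k) {
        const double dlt = R::rnorm(0.0, s_sc(i, k));
        const double dll = shift_cov(D[i], k, dlt, false);
        const double bk = B(i, k) + dlt;
        const double mk = hierarchical ? mu[k] : 0.0;
        const double sk = hierarchical ? sigma[k] : mean_sd;
        const double a2 = dll +
          R::dnorm(bk, mk, sk, 1) - R::dnorm(B(i, k), mk, sk, 1);
        if (std::isfinite(a2) && std::log(R::runif(0.0, 1.0)) < a2) {
          shift_cov(D[i], k, dlt, true);
          B(i, k) = bk;
          D[i].ll += dll;
        }
        if (t <= warmup) {
          const double ar = std::isfinite(a2) ? std::min(1.0, std::exp(a2)) : 0.0;
          s_sc(i, k) *= std::exp((ar - 0.44) / std::sqrt((double)t));
        }
      }
    }

    if (hierarchical) {
      // joint translation of (mu_k, beta_.k): deviations unchanged
      for (int k = 0; k < p; ++k) {
        const double dlt = R::rnorm(0.0, s_tr[k]);
        std::vector<double> dlli(n_ind);
        double dll = 0.0;
        for (int i = 0; i < n_ind; ++i) {
          dlli[i] = shift_cov(D[i], k, dlt, false);
          dll += dlli[i];
        }
        const double a = dll + R::dnorm(mu[k] + dlt, 0.0, tau0, 1) -
          R::dnorm(mu[k], 0.0, tau0, 1);
        if (std::isfinite(a) && std::log(R::runif(0.0, 1.0)) < a) {
          mu[k] += dlt;
          for (int i = 0; i < n_ind; ++i) {
            shift_cov(D[i], k, dlt, true);
            B(i, k) += dlt;
            D[i].ll += dlli[i];
          }
        }
        if (t <= warmup) {
          const double ar = std::isfinite(a) ? std::min(1.0, std::exp(a)) : 0.0;
          s_tr[k] *= std::exp((ar - 0.44) / std::sqrt((double)t));
        }
      }

      // scale move: rescale sigma_k and all deviations beta_ik - mu_k by
      // a common factor c (parameter expansion; Jacobian and group
      // density collapse to a single log c term), improving exploration
      // of the heavy upper tail of weakly identified group sds
      for (int k = 0; k < p; ++k) {
        const double c = std::exp(R::rnorm(0.0, s_sg[k]));
        std::vector<double> dlti(n_ind), dlli(n_ind);
        double dll = 0.0;
        for (int i = 0; i < n_ind; ++i) {
          dlti[i] = (c - 1.0) * (B(i, k) - mu[k]);
          dlli[i] = shift_cov(D[i], k, dlti[i], false);
          dll += dlli[i];
        }
        const double a = dll +
          R::dnorm(c * sigma[k], 0.0, sigma_sd, 1) -
          R::dnorm(sigma[k], 0.0, sigma_sd, 1) + std::log(c);
        if (std::isfinite(a) && std::log(R::runif(0.0, 1.0)) < a) {
          sigma[k] *= c;
          for (int i = 0; i < n_ind; ++i) {
            shift_cov(D[i], k, dlti[i], true);
            B(i, k) += dlti[i];
            D[i].ll += dlli[i];
          }
        }
        if (t <= warmup) {
          const double ar = std::isfinite(a) ? std::min(1.0, std::exp(a)) : 0.0;
          s_sg[k] *= std::exp((ar - 0.44) / std::sqrt((double)t));
        }
      }

      // conjugate update of mu, slice update of sigma
      for (int k = 0; k < p; ++k) {
        double sb = 0.0;
        for (int i = 0; i < n_ind; ++i) sb += B(i, k);
        const double prec = n_ind / (sigma[k] * sigma[k]) + 1.0 / (tau0 * tau0);
        const double mhat = (sb / (sigma[k] * sigma[k])) / prec;
        mu[k] = R::rnorm(mhat, std::sqrt(1.0 / prec));

        const double muk = mu[k];
        const NumericMatrix &Bref = B;
        auto logf = [&Bref, k, muk, n_ind, sigma_sd](double ls) {
          const double s = std::exp(ls);
          double v = 0.0;
          for (int i = 0; i < n_ind; ++i)
            v += R::dnorm(Bref(i, k), muk, s, 1);
          return v + R::dnorm(s, 0.0, sigma_sd, 1) + ls;
        };
        sigma[k] = std::exp(slice1(std::log(sigma[k]), logf, 1.0, 50));
      }
    } else {
      for (int k = 0; k < p; ++k) {
        double sb = 0.0;
        for (int i = 0; i < n_ind; ++i) sb += B(i, k);
        mu[k] = sb / n_ind;
      }
    }

    if (t > warmup) {
      const int j = t - warmup - 1;
      for (int k = 0; k < p; ++k) {
        keep_mu(j, k) = mu[k];
        if (hierarchical) keep_sigma(j, k) = sigma[k];
        for (int i = 0; i < n_ind; ++i)
          keep_B[j + iter * (i + n_ind * k)] = B(i, k);
      }
    }
  }

  for (int i = 0; i < n_ind; ++i) acc_ind[i] /= total;
  return List::create(_["mu"] = keep_mu,
                      _["sigma"] = hierarchical ? SEXP(keep_sigma) : R_NilValue,
                      _["B"] = keep_B,
                      _["accept_ind"] = wrap(acc_ind));
}
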