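// Adaptive random-walk Metropolis-within-Gibbs samplers for the Beta mixture
// item response model, the attentive-only Beta IRM, and the normal mixture
// CFA baseline.  The careless class indicator is never sampled: the mixture
// is evaluated in its marginal form per response cell, via log-sum-exp.
// All randomness comes from R's RNG so chains are reproducible via set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// half-Cauchy(0, s) log-density for x > 0
static inline double hc_lpdf(double x, double s) {
  return std::log(2.0 / (M_PI * s)) - std::log1p((x / s) * (x / s));
}

static inline double logit(double p) { return std::log(p) - std::log1p(-p); }
static inline double inv_logit(double x) {
  if (x > 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

// proposal-scale adaptation (Robbins-Monro toward 44% acceptance)
struct Adapt {
  std::vector<double> scale;
  std::vector<int> acc, att;
  explicit Adapt(int n, double s0) : scale(n, s0), acc(n, 0), att(n, 0) {}
  void tune() {
    for (size_t k = 0; k < scale.size(); ++k) {
      if (att[k] == 0) continue;
      double rate = double(acc[k]) / att[k];
      scale[k] *= std::exp(0.66 * (rate - 0.44));
      if (scale[k] < 1e-4) scale[k] = 1e-4;
      if (scale[k] > 20.0) scale[k] = 20.0;
      acc[k] = 0; att[k] = 0;
    }
  }
};

// in-place lower Cholesky; returns false if not positive definite
static bool chol_lower(const std::vector<double>& A, int D,
                       std::vector<double>& L) {
  L.assign(D * D, 0.0);
  for (int i = 0; i < D; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * D + j];
      for (int k = 0; k < j; ++k) s -= L[i * D + k] * L[j * D + k];
      if (i == j) {
        if (s <= 1e-12) return false;
        L[i * D + i] = std::sqrt(s);
      } else {
        L[i * D + j] = s / L[j * D + j];
      }
    }
  }
  return true;
}

// ---------------------------------------------------------------------------
// Beta mixture IRM / Beta IRM sampler
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".mixture_chain_cpp")]]
NumericMatrix mixture_chain_cpp(NumericMatrix y, IntegerVector wording,
                                IntegerVector dimj, int D, List prior,
                                List init, int n_iter, int n_burnin, int thin,
                                bool mixture) {
  const int N = y.nrow(), J = y.ncol();
  const double item_sd = prior["item_prior_sd"];
  const double sig_scale = prior["trait_sd_scale"];
  const double lkj_eta = prior["lkj_shape"];
  const double mn_scale = prior["careless_shape_scale"];
  const double conc_scale = prior["concentration_scale"];

  // --- state ---
  std::vector<double> b = as<std::vector<double> >(init["difficulty"]);
  std::vector<double> al = as<std::vector<double> >(init["dispersion"]);
  NumericMatrix th0 = init["theta"];
  std::vector<double> th(N * D);  // person-major: th[i*D + d]
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < D; ++d) th[i * D + d] = th0(i, d);
  std::vector<double> lsig = as<std::vector<double> >(init["log_sigma"]);
  NumericMatrix R0 = init["corr"];
  std::vector<double> Rc(D * D);
  for (int d = 0; d < D; ++d)
    for (int e = 0; e < D; ++e) Rc[d * D + e] = R0(d, e);
  double lm = std::log(as<double>(init["m"]));
  double ln = std::log(as<double>(init["n"]));
  double lpi = logit(as<double>(init["pi"]));
  double lom = std::log(as<double>(init["omega"]));
  std::vector<double> lpii(N);
  NumericVector pii0 = init["person_prob"];
  for (int i = 0; i < N; ++i) lpii[i] = logit(pii0[i]);

  std::vector<double> L(D * D);
  chol_lower(Rc, D, L);

  // --- caches ---
  std::vector<bool> obs(N * J);
  std::vector<double> ly(N * J), l1y(N * J);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < J; ++j) {
      double v = y(i, j);
      bool ok = R_finite(v);
      obs[i * J + j] = ok;
      ly[i * J + j] = ok ? std::log(v) : 0.0;
      l1y[i * J + j] = ok ? std::log1p(-v) : 0.0;
    }

  std::vector<double> lfA(N * J, 0.0), lfC(N * J, 0.0), propcol(N), proprow(J);
  std::vector<double> lw1(N), lw0(N);
  double S_lp = 0.0, S_l1p = 0.0;  // sums of log(pi_i), log(1-pi_i)

  double m = std::exp(lm), n = std::exp(ln), ppi = inv_logit(lpi),
         om = std::exp(lom);

  // Beta log-density via cached log(y), log(1-y): the sampler's hot path
  auto att_ld = [&](int i, int j, double thid, double bj, double alj) {
    double eta = wording[j] * thid - bj;
    double a = std::exp(0.5 * (eta + alj));
    double bb = std::exp(-0.5 * (eta - alj));
    return (a - 1.0) * ly[i * J + j] + (bb - 1.0) * l1y[i * J + j] +
           std::lgamma(a + bb) - std::lgamma(a) - std::lgamma(bb);
  };
  auto care_ld = [&](int i, int j, double mm, double nn, double lb) {
    return (mm - 1.0) * ly[i * J + j] + (nn - 1.0) * l1y[i * J + j] - lb;
  };

  double lbet = R::lbeta(m, n);
  for (int i = 0; i < N; ++i) {
    double p = inv_logit(lpii[i]);
    lw1[i] = std::log(p); lw0[i] = std::log1p(-p);
    S_lp += lw1[i]; S_l1p += lw0[i];
    for (int j = 0; j < J; ++j) {
      if (!obs[i * J + j]) continue;
      lfA[i * J + j] = att_ld(i, j, th[i * D + dimj[j]], b[j], al[j]);
      lfC[i * J + j] = care_ld(i, j, m, n, lbet);
    }
  }

  auto cell_ll = [&](int i, double la, double lc) {
    return mixture ? lse2(lw1[i] + la, lw0[i] + lc) : la;
  };

  // multivariate-normal log-density of one person's trait vector
  std::vector<double> zbuf(D);
  auto mvn_lp = [&](const double* t) {
    double q = 0.0, ld = 0.0;
    for (int d = 0; d < D; ++d) {
      double sg = std::exp(lsig[d]);
      double v = t[d] / sg;
      for (int e = 0; e < d; ++e) v -= L[d * D + e] * zbuf[e];
      zbuf[d] = v / L[d * D + d];
      q += zbuf[d] * zbuf[d];
      ld += std::log(L[d * D + d]) + lsig[d];
    }
    return -0.5 * q - ld - 0.5 * D * std::log(2.0 * M_PI);
  };
  auto theta_prior_sum = [&]() {
    double s = 0.0;
    for (int i = 0; i < N; ++i) s += mvn_lp(&th[i * D]);
    return s;
  };

  // --- adaptation blocks ---
  Adapt ad_b(J, 0.3), ad_al(J, 0.3), ad_th(N, 0.5), ad_pii(N, 1.0);
  Adapt ad_sig(D, 0.3), ad_glob(5, 0.4);  // m, n, (m,n) joint, pi, omega
  int npair = D * (D - 1) / 2;
  Adapt ad_R(npair > 0 ? npair : 1, 0.1);

  // --- output ---
  int n_kept = 0;
  for (int it = n_burnin; it < n_iter; it += thin) ++n_kept;
  int ncol_glob = mixture ? 4 : 0;
  int ncol = 2 * J + D + npair + ncol_glob + N * D + (mixture ? N : 0);
  NumericMatrix out(n_kept, ncol);
  int keep_row = 0;

  std::vector<double> thprop(D);

  for (int it = 0; it < n_iter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();

    // -- item difficulties and dispersions --
    for (int j = 0; j < J; ++j) {
      for (int par = 0; par < 2; ++par) {
        Adapt& ad = par == 0 ? ad_b : ad_al;
        double cur = par == 0 ? b[j] : al[j];
        double prop = cur + ad.scale[j] * R::norm_rand();
        double bp = par == 0 ? prop : b[j];
        double ap = par == 0 ? al[j] : prop;
        double dll = (R::dnorm(prop, 0.0, item_sd, 1) -
                      R::dnorm(cur, 0.0, item_sd, 1));
        for (int i = 0; i < N; ++i) {
          if (!obs[i * J + j]) { propcol[i] = 0.0; continue; }
          propcol[i] = att_ld(i, j, th[i * D + dimj[j]], bp, ap);
          dll += cell_ll(i, propcol[i], lfC[i * J + j]) -
                 cell_ll(i, lfA[i * J + j], lfC[i * J + j]);
        }
        ad.att[j]++;
        if (std::log(R::unif_rand()) < dll) {
          ad.acc[j]++;
          if (par == 0) b[j] = prop; else al[j] = prop;
          for (int i = 0; i < N; ++i)
            if (obs[i * J + j]) lfA[i * J + j] = propcol[i];
        }
      }
    }

    // -- person traits --
    for (int i = 0; i < N; ++i) {
      for (int d = 0; d < D; ++d)
        thprop[d] = th[i * D + d] + ad_th.scale[i] * R::norm_rand();
      double dll = mvn_lp(&thprop[0]) - mvn_lp(&th[i * D]);
      for (int j = 0; j < J; ++j) {
        if (!obs[i * J + j]) { proprow[j] = 0.0; continue; }
        proprow[j] = att_ld(i, j, thprop[dimj[j]], b[j], al[j]);
        dll += cell_ll(i, proprow[j], lfC[i * J + j]) -
               cell_ll(i, lfA[i * J + j], lfC[i * J + j]);
      }
      ad_th.att[i]++;
      if (std::log(R::unif_rand()) < dll) {
        ad_th.acc[i]++;
        for (int d = 0; d < D; ++d) th[i * D + d] = thprop[d];
        for (int j = 0; j < J; ++j)
          if (obs[i * J + j]) lfA[i * J + j] = proprow[j];
      }
    }

    // -- trait scale (and correlations when multidimensional) --
    for (int d = 0; d < D; ++d) {
      double cur = lsig[d];
      double prop = cur + ad_sig.scale[d] * R::norm_rand();
      double base = theta_prior_sum() + hc_lpdf(std::exp(cur), sig_scale) + cur;
      lsig[d] = prop;
      double cand = theta_prior_sum() + hc_lpdf(std::exp(prop), sig_scale) + prop;
      ad_sig.att[d]++;
      if (std::log(R::unif_rand()) < cand - base) ad_sig.acc[d]++;
      else lsig[d] = cur;
    }
    if (D > 1) {
      int k = 0;
      for (int d = 0; d < D; ++d) for (int e = d + 1; e < D; ++e, ++k) {
        double cur = Rc[d * D + e];
        double prop = cur + ad_R.scale[k] * R::norm_rand();
        ad_R.att[k]++;
        if (prop <= -1.0 || prop >= 1.0) continue;
        std::vector<double> Rp(Rc), Lp;
        Rp[d * D + e] = Rp[e * D + d] = prop;
        if (!chol_lower(Rp, D, Lp)) continue;
        double ldet_old = 0.0, ldet_new = 0.0;
        for (int q = 0; q < D; ++q) {
          ldet_old += 2.0 * std::log(L[q * D + q]);
          ldet_new += 2.0 * std::log(Lp[q * D + q]);
        }
        double base = theta_prior_sum() + (lkj_eta - 1.0) * ldet_old;
        std::vector<double> Lold(L);
        L = Lp;
        double cand = theta_prior_sum() + (lkj_eta - 1.0) * ldet_new;
        if (std::log(R::unif_rand()) < cand - base) {
          ad_R.acc[k]++;
          Rc = Rp;
        } else {
          L = Lold;
        }
      }
    }

    if (mixture) {
      // -- individual attentiveness probabilities (logit scale) --
      double a_hyp = om * ppi, b_hyp = om * (1.0 - ppi);
      for (int i = 0; i < N; ++i) {
        double cur = lpii[i];
        double prop = cur + ad_pii.scale[i] * R::norm_rand();
        double p1 = inv_logit(prop);
        double nl1 = std::log(p1), nl0 = std::log1p(-p1);
        // Beta prior plus logit Jacobian: a*log(p) + b*log(1-p) - lbeta(a,b)
        double dll = a_hyp * (nl1 - lw1[i]) + b_hyp * (nl0 - lw0[i]);
        for (int j = 0; j < J; ++j) {
          if (!obs[i * J + j]) continue;
          dll += lse2(nl1 + lfA[i * J + j], nl0 + lfC[i * J + j]) -
                 lse2(lw1[i] + lfA[i * J + j], lw0[i] + lfC[i * J + j]);
        }
        ad_pii.att[i]++;
        if (std::log(R::unif_rand()) < dll) {
          ad_pii.acc[i]++;
          lpii[i] = prop;
          S_lp += nl1 - lw1[i]; S_l1p += nl0 - lw0[i];
          lw1[i] = nl1; lw0[i] = nl0;
        }
      }

      // -- careless Beta shapes m, n: single-parameter moves plus a joint
      //    move along the posterior's correlated (concentration) direction --
      for (int par = 0; par < 3; ++par) {
        double step = ad_glob.scale[par] * R::norm_rand();
        double lmp = (par == 1) ? lm : lm + step;
        double lnp = (par == 0) ? ln : ln + step;
        double mp = std::exp(lmp), np = std::exp(lnp);
        double lbp = R::lbeta(mp, np);
        double dll = hc_lpdf(mp, mn_scale) + lmp + hc_lpdf(np, mn_scale) + lnp -
                     (hc_lpdf(m, mn_scale) + lm + hc_lpdf(n, mn_scale) + ln);
        for (int i = 0; i < N; ++i)
          for (int j = 0; j < J; ++j) {
            if (!obs[i * J + j]) continue;
            double lcp = care_ld(i, j, mp, np, lbp);
            dll += lse2(lw1[i] + lfA[i * J + j], lw0[i] + lcp) -
                   lse2(lw1[i] + lfA[i * J + j], lw0[i] + lfC[i * J + j]);
          }
        ad_glob.att[par]++;
        if (std::log(R::unif_rand()) < dll) {
          ad_glob.acc[par]++;
          lm = lmp; ln = lnp; m = mp; n = np;
          for (int i = 0; i < N; ++i)
            for (int j = 0; j < J; ++j)
              if (obs[i * J + j]) lfC[i * J + j] = care_ld(i, j, m, n, lbp);
        }
      }

      // -- population attentive proportion pi (flat Dirichlet(1,1) prior) --
      {
        double cur = lpi;
        double prop = cur + ad_glob.scale[3] * R::norm_rand();
        double pp = inv_logit(prop);
        double a0 = om * ppi, b0 = om * (1.0 - ppi);
        double a1 = om * pp, b1 = om * (1.0 - pp);
        // flat prior on pi plus logit Jacobian log(p(1-p))
        double dll = std::log(pp) + std::log1p(-pp) -
                     (std::log(ppi) + std::log1p(-ppi));
        dll += (a1 - a0) * S_lp + (b1 - b0) * S_l1p -
               N * (R::lbeta(a1, b1) - R::lbeta(a0, b0));
        ad_glob.att[3]++;
        if (std::log(R::unif_rand()) < dll) {
          ad_glob.acc[3]++; lpi = prop; ppi = pp;
        }
      }

      // -- Dirichlet concentration omega --
      {
        double cur = lom;
        double prop = cur + ad_glob.scale[4] * R::norm_rand();
        double omp = std::exp(prop);
        double a0 = om * ppi, b0 = om * (1.0 - ppi);
        double a1 = omp * ppi, b1 = omp * (1.0 - ppi);
        double dll = hc_lpdf(omp, conc_scale) + prop -
                     (hc_lpdf(om, conc_scale) + cur);
        dll += (a1 - a0) * S_lp + (b1 - b0) * S_l1p -
               N * (R::lbeta(a1, b1) - R::lbeta(a0, b0));
        ad_glob.att[4]++;
        if (std::log(R::unif_rand()) < dll) {
          ad_glob.acc[4]++; lom = prop; om = omp;
        }
      }
    }

    // -- adaptation during burn-in --
    if (it < n_burnin && (it + 1) % 25 == 0) {
      ad_b.tune(); ad_al.tune(); ad_th.tune(); ad_sig.tune();
      if (D > 1) ad_R.tune();
      if (mixture) { ad_pii.tune(); ad_glob.tune(); }
    }

    // -- store --
    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      int c = 0;
      for (int j = 0; j < J; ++j) out(keep_row, c++) = b[j];
      for (int j = 0; j < J; ++j) out(keep_row, c++) = al[j];
      for (int d = 0; d < D; ++d) out(keep_row, c++) = std::exp(lsig[d]);
      for (int d = 0; d < D; ++d)
        for (int e = d + 1; e < D; ++e) out(keep_row, c++) = Rc[d * D + e];
      if (mixture) {
        out(keep_row, c++) = m;
        out(keep_row, c++) = n;
        out(keep_row, c++) = ppi;
        out(keep_row, c++) = om;
      }
      for (int i = 0; i < N; ++i)
        for (int d = 0; d < D; ++d) out(keep_row, c++) = th[i * D + d];
      if (mixture)
        for (int i = 0; i < N; ++i) out(keep_row, c++) = inv_logit(lpii[i]);
      ++keep_row;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Normal mixture CFA baseline (unidimensional trait, variance fixed to 1)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cfa_chain_cpp")]]
NumericMatrix cfa_chain_cpp(NumericMatrix y, IntegerVector wording,
                            List prior, List init, int n_iter, int n_burnin,
                            int thin) {
  const int N = y.nrow(), J = y.ncol();
  const double item_sd = prior["item_prior_sd"];
  const double sig_scale = prior["trait_sd_scale"];
  const double conc_scale = prior["concentration_scale"];

  std::vector<double> nu = as<std::vector<double> >(init["intercept"]);
  std::vector<double> llam(J);
  NumericVector lam0 = init["loading"];
  for (int j = 0; j < J; ++j) llam[j] = std::log(std::fabs(lam0[j]));
  std::vector<double> lsigj = as<std::vector<double> >(init["log_sigma_item"]);
  NumericVector th0 = init["theta"];
  std::vector<double> th = as<std::vector<double> >(th0);
  double mu_c = init["careless_mean"];
  double lsig_c = std::log(as<double>(init["careless_sd"]));
  double lpi = logit(as<double>(init["pi"]));
  double lom = std::log(as<double>(init["omega"]));
  std::vector<double> lpii(N);
  NumericVector pii0 = init["person_prob"];
  for (int i = 0; i < N; ++i) lpii[i] = logit(pii0[i]);

  std::vector<bool> obs(N * J);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < J; ++j) obs[i * J + j] = R_finite(y(i, j));

  std::vector<double> lfA(N * J, 0.0), lfC(N * J, 0.0), propcol(N), proprow(J);
  std::vector<double> lw1(N), lw0(N);
  double S_lp = 0.0, S_l1p = 0.0;
  double ppi = inv_logit(lpi), om = std::exp(lom);

  auto att_ld = [&](int i, int j, double nuj, double lamj, double sj) {
    return R::dnorm(y(i, j), nuj + lamj * th[i], sj, 1);
  };
  auto att_ld_th = [&](int i, int j, double t) {
    return R::dnorm(y(i, j),
                    nu[j] + wording[j] * std::exp(llam[j]) * t,
                    std::exp(lsigj[j]), 1);
  };

  for (int i = 0; i < N; ++i) {
    double p = inv_logit(lpii[i]);
    lw1[i] = std::log(p); lw0[i] = std::log1p(-p);
    S_lp += lw1[i]; S_l1p += lw0[i];
    for (int j = 0; j < J; ++j) {
      if (!obs[i * J + j]) continue;
      lfA[i * J + j] = att_ld(i, j, nu[j], wording[j] * std::exp(llam[j]),
                              std::exp(lsigj[j]));
      lfC[i * J + j] = R::dnorm(y(i, j), mu_c, std::exp(lsig_c), 1);
    }
  }

  Adapt ad_nu(J, 0.3), ad_lam(J, 0.3), ad_sj(J, 0.3), ad_th(N, 0.5),
        ad_pii(N, 1.0), ad_glob(4, 0.4);  // mu_c, sig_c, pi, omega

  int n_kept = 0;
  for (int it = n_burnin; it < n_iter; it += thin) ++n_kept;
  NumericMatrix out(n_kept, 3 * J + 4 + N + N);
  int keep_row = 0;

  for (int it = 0; it < n_iter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();

    // item blocks: intercept, log-loading-magnitude, log residual sd
    for (int j = 0; j < J; ++j) {
      for (int par = 0; par < 3; ++par) {
        Adapt& ad = par == 0 ? ad_nu : (par == 1 ? ad_lam : ad_sj);
        double cur = par == 0 ? nu[j] : (par == 1 ? llam[j] : lsigj[j]);
        double prop = cur + ad.scale[j] * R::norm_rand();
        double nuj = par == 0 ? prop : nu[j];
        double lamj = wording[j] * std::exp(par == 1 ? prop : llam[j]);
        double sj = std::exp(par == 2 ? prop : lsigj[j]);
        double dll;
        if (par == 0)
          dll = R::dnorm(prop, 0.0, item_sd, 1) -
                R::dnorm(cur, 0.0, item_sd, 1);
        else if (par == 1)
          // half-normal(0, item_sd) on |lambda| with log-scale Jacobian
          dll = R::dnorm(std::exp(prop), 0.0, item_sd, 1) + prop -
                (R::dnorm(std::exp(cur), 0.0, item_sd, 1) + cur);
        else
          dll = hc_lpdf(std::exp(prop), sig_scale) + prop -
                (hc_lpdf(std::exp(cur), sig_scale) + cur);
        for (int i = 0; i < N; ++i) {
          if (!obs[i * J + j]) { propcol[i] = 0.0; continue; }
          propcol[i] = att_ld(i, j, nuj, lamj, sj);
          dll += lse2(lw1[i] + propcol[i], lw0[i] + lfC[i * J + j]) -
                 lse2(lw1[i] + lfA[i * J + j], lw0[i] + lfC[i * J + j]);
        }
        ad.att[j]++;
        if (std::log(R::unif_rand()) < dll) {
          ad.acc[j]++;
          if (par == 0) nu[j] = prop;
          else if (par == 1) llam[j] = prop;
          else lsigj[j] = prop;
          for (int i = 0; i < N; ++i)
            if (obs[i * J + j]) lfA[i * J + j] = propcol[i];
        }
      }
    }

    // traits, standard-normal prior (variance fixed at 1 for identification)
    for (int i = 0; i < N; ++i) {
      double cur = th[i];
      double prop = cur + ad_th.scale[i] * R::norm_rand();
      double dll = R::dnorm(prop, 0.0, 1.0, 1) - R::dnorm(cur, 0.0, 1.0, 1);
      for (int j = 0; j < J; ++j) {
        if (!obs[i * J + j]) { proprow[j] = 0.0; continue; }
        proprow[j] = att_ld_th(i, j, prop);
        dll += lse2(lw1[i] + proprow[j], lw0[i] + lfC[i * J + j]) -
               lse2(lw1[i] + lfA[i * J + j], lw0[i] + lfC[i * J + j]);
      }
      ad_th.att[i]++;
      if (std::log(R::unif_rand()) < dll) {
        ad_th.acc[i]++;
        th[i] = prop;
        for (int j = 0; j < J; ++j)
          if (obs[i * J + j]) lfA[i * J + j] = proprow[j];
      }
    }

    // careless normal parameters
    for (int par = 0; par < 2; ++par) {
      double cur = par == 0 ? mu_c : lsig_c;
      double prop = cur + ad_glob.scale[par] * R::norm_rand();
      double mup = par == 0 ? prop : mu_c;
      double scp = std::exp(par == 0 ? lsig_c : prop);
      double dll;
      if (par == 0)
        dll = R::dnorm(prop, 0.0, item_sd, 1) - R::dnorm(cur, 0.0, item_sd, 1);
      else
        dll = hc_lpdf(std::exp(prop), sig_scale) + prop -
              (hc_lpdf(std::exp(cur), sig_scale) + cur);
      double acc_dll = dll;
      for (int i = 0; i < N; ++i)
        for (int j = 0; j < J; ++j) {
          if (!obs[i * J + j]) continue;
          double lcp = R::dnorm(y(i, j), mup, scp, 1);
          acc_dll += lse2(lw1[i] + lfA[i * J + j], lw0[i] + lcp) -
                     lse2(lw1[i] + lfA[i * J + j], lw0[i] + lfC[i * J + j]);
        }
      ad_glob.att[par]++;
      if (std::log(R::unif_rand()) < acc_dll) {
        ad_glob.acc[par]++;
        if (par == 0) mu_c = prop; else lsig_c = prop;
        double sc = std::exp(lsig_c);
        for (int i = 0; i < N; ++i)
          for (int j = 0; j < J; ++j)
            if (obs[i * J + j])
              lfC[i * J + j] = R::dnorm(y(i, j), mu_c, sc, 1);
      }
    }

    // attentiveness probabilities and hyperparameters (same as Beta mixture)
    double a_hyp = om * ppi, b_hyp = om * (1.0 - ppi);
    for (int i = 0; i < N; ++i) {
      double cur = lpii[i];
      double prop = cur + ad_pii.scale[i] * R::norm_rand();
      double p1 = inv_logit(prop);
      double nl1 = std::log(p1), nl0 = std::log1p(-p1);
      double dll = a_hyp * (nl1 - lw1[i]) + b_hyp * (nl0 - lw0[i]);
      for (int j = 0; j < J; ++j) {
        if (!obs[i * J + j]) continue;
        dll += lse2(nl1 + lfA[i * J + j], nl0 + lfC[i * J + j]) -
               lse2(lw1[i] + lfA[i * J + j], lw0[i] + lfC[i * J + j]);
      }
      ad_pii.att[i]++;
      if (std::log(R::unif_rand()) < dll) {
        ad_pii.acc[i]++;
        lpii[i] = prop;
        S_lp += nl1 - lw1[i]; S_l1p += nl0 - lw0[i];
        lw1[i] = nl1; lw0[i] = nl0;
      }
    }
    {
      double cur = lpi;
      double prop = cur + ad_glob.scale[2] * R::norm_rand();
      double pp = inv_logit(prop);
      double a0 = om * ppi, b0 = om * (1.0 - ppi);
      double a1 = om * pp, b1 = om * (1.0 - pp);
      double dll = std::log(pp) + std::log1p(-pp) -
                   (std::log(ppi) + std::log1p(-ppi));
      dll += (a1 - a0) * S_lp + (b1 - b0) * S_l1p -
             N * (R::lbeta(a1, b1) - R::lbeta(a0, b0));
      ad_glob.att[2]++;
      if (std::log(R::unif_rand()) < dll) {
        ad_glob.acc[2]++; lpi = prop; ppi = pp;
      }
    }
    {
      double cur = lom;
      double prop = cur + ad_glob.scale[3] * R::norm_rand();
      double omp = std::exp(prop);
      double a0 = om * ppi, b0 = om * (1.0 - ppi);
      double a1 = omp * ppi, b1 = omp * (1.0 - ppi);
      double dll = hc_lpdf(omp, conc_scale) + prop -
                   (hc_lpdf(om, conc_scale) + cur);
      dll += (a1 - a0) * S_lp + (b1 - b0) * S_l1p -
             N * (R::lbeta(a1, b1) - R::lbeta(a0, b0));
      ad_glob.att[3]++;
      if (std::log(R::unif_rand()) < dll) {
        ad_glob.acc[3]++; lom = prop; om = omp;
      }
    }

    if (it < n_burnin && (it + 1) % 25 == 0) {
      ad_nu.tune(); ad_lam.tune(); ad_sj.tune(); ad_th.tune();
      ad_pii.tune(); ad_glob.tune();
    }

    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      int c = 0;
      for (int j = 0; j < J; ++j) out(keep_row, c++) = nu[j];
      for (int j = 0; j < J; ++j)
        out(keep_row, c++) = wording[j] * std::exp(llam[j]);
      for (int j = 0; j < J; ++j) out(keep_row, c++) = std::exp(lsigj[j]);
      out(keep_row, c++) = mu_c;
      out(keep_row, c++) = std::exp(lsig_c);
      out(keep_row, c++) = ppi;
      out(keep_row, c++) = om;
      for (int i = 0; i < N; ++i) out(keep_row, c++) = th[i];
      for (int i = 0; i < N; ++i) out(keep_row, c++) = inv_logit(lpii[i]);
      ++keep_row;
    }
  }
  return out;
}
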