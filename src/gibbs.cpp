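// Blocked Gibbs sampler for the Bayesian Finlay-Wilkinson reaction-norm model
//
//   y_ijk = mu + g_i + h_j + b_i * h_j + e_ijk,  e ~ N(0, var_e)
//   g ~ N(0, A var_g), b ~ N(0, A var_b), h ~ N(0, H var_h)
//   variances ~ scaled-inverse-chi-square(df, S2); flat prior on mu
//
// One cycle scans mu, g (block), b (block), h (block), then var_e, var_g,
// var_b, var_h. Records with missing y contribute to no likelihood sum.
// All randomness goes through R's RNG so set.seed() on the R side makes a
// chain bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Draw from N(P^{-1} rhs, P^{-1}) for symmetric positive-definite precision P.
static arma::vec rmvnorm_prec(const arma::vec& rhs, const arma::mat& P) {
  arma::mat L = arma::chol(P, "lower");
  arma::vec m = arma::solve(arma::trimatu(L.t()),
                            arma::solve(arma::trimatl(L), rhs));
  arma::vec z(P.n_rows);
  for (arma::uword i = 0; i < z.n_elem; ++i) z[i] = R::norm_rand();
  return m + arma::solve(arma::trimatu(L.t()), z);
}

// Scaled-inverse-chi-square draw with numerator df*S2 + quadratic form.
static double rscaled_inv_chisq(double df, double numerator) {
  return numerator / R::rchisq(df);
}

// [[Rcpp::export]]
List fw_gibbs_chain_cpp(const arma::vec& y,
                        const arma::ivec& vi,       // 0-based variety index per record
                        const arma::ivec& ei,       // 0-based environment index per record
                        const arma::uvec& obs,      // 0-based indices of observed records
                        const arma::mat& Ainv, bool a_diag, const arma::vec& adiag,
                        const arma::mat& Hinv, bool h_diag, const arma::vec& hdiag,
                        const arma::vec& hyper,     // df_e,S2_e,df_g,S2_g,df_b,S2_b,df_h,S2_h
                        int n_iter, int burn_in, int thin,
                        double mu0, const arma::vec& g0, const arma::vec& b0,
                        const arma::vec& h0, const arma::vec& var0,
                        const arma::ivec& mon_var,  // 0-based variety indices whose g,b draws are kept
                        const arma::ivec& mon_env,  // 0-based environment indices whose h draws are kept
                        const LogicalVector& update // mu,g,b,h,var_e,var_g,var_b,var_h
) {
  const int nrec = y.n_elem;
  const int nV = g0.n_elem, nE = h0.n_elem;
  const int nobs = obs.n_elem;
  const double df_e = hyper[0], S2_e = hyper[1];
  const double df_g = hyper[2], S2_g = hyper[3];
  const double df_b = hyper[4], S2_b = hyper[5];
  const double df_h = hyper[6], S2_h = hyper[7];

  double mu = mu0;
  arma::vec g = g0, b = b0, h = h0;
  double ve = var0[0], vg = var0[1], vb = var0[2], vh = var0[3];

  // records per line / environment among observed records (fixed)
  arma::vec Dg(nV, arma::fill::zeros);
  for (int k = 0; k < nobs; ++k) Dg[vi[obs[k]]] += 1.0;

  const int n_keep = (n_iter > burn_in) ? (n_iter - burn_in) / thin : 0;
  const int n_mon = 5 + 2 * mon_var.n_elem + mon_env.n_elem;
  arma::mat samples(n_keep, n_mon, arma::fill::zeros);

  // accumulators for posterior means / SDs from thinned post-burn-in draws
  double mu_s = 0, mu_s2 = 0;
  arma::vec g_s(nV, arma::fill::zeros), g_s2(nV, arma::fill::zeros);
  arma::vec b_s(nV, arma::fill::zeros), b_s2(nV, arma::fill::zeros);
  arma::vec h_s(nE, arma::fill::zeros), h_s2(nE, arma::fill::zeros);
  arma::vec yh_s(nrec, arma::fill::zeros), yh_s2(nrec, arma::fill::zeros);
  arma::vec v_s(4, arma::fill::zeros), v_s2(4, arma::fill::zeros);

  arma::vec r(std::max(nV, nE));
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- mu | . (flat prior) ---
    if (update[0] && nobs > 0) {
      double acc = 0;
      for (int k = 0; k < nobs; ++k) {
        int t = obs[k];
        acc += y[t] - g[vi[t]] - (1.0 + b[vi[t]]) * h[ei[t]];
      }
      mu = acc / nobs + R::norm_rand() * std::sqrt(ve / nobs);
    }

    // --- g | . ---
    if (update[1]) {
      arma::vec rg(nV, arma::fill::zeros);
      for (int k = 0; k < nobs; ++k) {
        int t = obs[k];
        rg[vi[t]] += y[t] - mu - (1.0 + b[vi[t]]) * h[ei[t]];
      }
      if (a_diag) {
        for (int i = 0; i < nV; ++i) {
          double p = Dg[i] / ve + adiag[i] / vg;
          g[i] = (rg[i] / ve) / p + R::norm_rand() / std::sqrt(p);
        }
      } else {
        arma::mat P = Ainv / vg;
        P.diag() += Dg / ve;
        g = rmvnorm_prec(rg / ve, P);
      }
    }

    // --- b | . (covariate h_j within line) ---
    if (update[2]) {
      arma::vec Db(nV, arma::fill::zeros), rb(nV, arma::fill::zeros);
      for (int k = 0; k < nobs; ++k) {
        int t = obs[k];
        double hh = h[ei[t]];
        Db[vi[t]] += hh * hh;
        rb[vi[t]] += hh * (y[t] - mu - g[vi[t]] - hh);
      }
      if (a_diag) {
        for (int i = 0; i < nV; ++i) {
          double p = Db[i] / ve + adiag[i] / vb;
          b[i] = (rb[i] / ve) / p + R::norm_rand() / std::sqrt(p);
        }
      } else {
        arma::mat P = Ainv / vb;
        P.diag() += Db / ve;
        b = rmvnorm_prec(rb / ve, P);
      }
    }

    // --- h | . (covariate 1 + b_i within environment) ---
    if (update[3]) {
      arma::vec Dh(nE, arma::fill::zeros), rh(nE, arma::fill::zeros);
      for (int k = 0; k < nobs; ++k) {
        int t = obs[k];
        double s = 1.0 + b[vi[t]];
        Dh[ei[t]] += s * s;
        rh[ei[t]] += s * (y[t] - mu - g[vi[t]]);
      }
      if (h_diag) {
        for (int j = 0; j < nE; ++j) {
          double p = Dh[j] / ve + hdiag[j] / vh;
          h[j] = (rh[j] / ve) / p + R::norm_rand() / std::sqrt(p);
        }
      } else {
        arma::mat P = Hinv / vh;
        P.diag() += Dh / ve;
        h = rmvnorm_prec(rh / ve, P);
      }
    }

    // --- var_e | . ---
    if (update[4] && nobs > 0) {
      double rss = 0;
      for (int k = 0; k < nobs; ++k) {
        int t = obs[k];
        double e = y[t] - mu - g[vi[t]] - (1.0 + b[vi[t]]) * h[ei[t]];
        rss += e * e;
      }
      ve = rscaled_inv_chisq(df_e + nobs, rss + df_e * S2_e);
    }

    // --- var_g, var_b, var_h | . ---
    if (update[5]) {
      double q = a_diag ? arma::dot(g % g, adiag)
                        : arma::as_scalar(g.t() * Ainv * g);
      vg = rscaled_inv_chisq(df_g + nV, q + df_g * S2_g);
    }
    if (update[6]) {
      double q = a_diag ? arma::dot(b % b, adiag)
                        : arma::as_scalar(b.t() * Ainv * b);
      vb = rscaled_inv_chisq(df_b + nV, q + df_b * S2_b);
    }
    if (update[7]) {
      double q = h_diag ? arma::dot(h % h, hdiag)
                        : arma::as_scalar(h.t() * Hinv * h);
      vh = rscaled_inv_chisq(df_h + nE, q + df_h * S2_h);
    }

    if (!std::isfinite(mu) || !std::isfinite(ve) || !std::isfinite(vg) ||
        !std::isfinite(vb) || !std::isfinite(vh) || !g.is_finite() ||
        !b.is_finite() || !h.is_finite())
      stop("non-finite value in Gibbs draw at cycle %d", iter);

    // --- record thinned post-burn-in draw ---
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      mu_s += mu; mu_s2 += mu * mu;
      g_s += g; g_s2 += g % g;
      b_s += b; b_s2 += b % b;
      h_s += h; h_s2 += h % h;
      v_s[0] += ve; v_s2[0] += ve * ve;
      v_s[1] += vg; v_s2[1] += vg * vg;
      v_s[2] += vb; v_s2[2] += vb * vb;
      v_s[3] += vh; v_s2[3] += vh * vh;
      for (int t = 0; t < nrec; ++t) {
        double p = mu + g[vi[t]] + (1.0 + b[vi[t]]) * h[ei[t]];
        yh_s[t] += p; yh_s2[t] += p * p;
      }
      samples(kept, 0) = ve; samples(kept, 1) = vg;
      samples(kept, 2) = vb; samples(kept, 3) = vh;
      samples(kept, 4) = mu;
      int c = 5;
      for (arma::uword m = 0; m < mon_var.n_elem; ++m) samples(kept, c++) = g[mon_var[m]];
      for (arma::uword m = 0; m < mon_var.n_elem; ++m) samples(kept, c++) = b[mon_var[m]];
      for (arma::uword m = 0; m < mon_env.n_elem; ++m) samples(kept, c++) = h[mon_env[m]];
      ++kept;
    }

    if (iter % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  auto sd_of = [&](double s, double s2, int n) {
    if (n < 2) return NA_REAL;
    double v = (s2 - s * s / n) / (n - 1);
    return v > 0 ? std::sqrt(v) : 0.0;
  };
  auto vec_mean = [&](const arma::vec& s) { return s / std::max(kept, 1); };
  auto vec_sd = [&](const arma::vec& s, const arma::vec& s2) {
    arma::vec out(s.n_elem);
    for (arma::uword i = 0; i < s.n_elem; ++i) out[i] = sd_of(s[i], s2[i], kept);
    return out;
  };

  return List::create(
      _["mu"] = mu_s / std::max(kept, 1), _["SD.mu"] = sd_of(mu_s, mu_s2, kept),
      _["g"] = vec_mean(g_s), _["SD.g"] = vec_sd(g_s, g_s2),
      _["b"] = vec_mean(b_s), _["SD.b"] = vec_sd(b_s, b_s2),
      _["h"] = vec_mean(h_s), _["SD.h"] = vec_sd(h_s, h_s2),
      _["yhat"] = vec_mean(yh_s), _["SD.yhat"] = vec_sd(yh_s, yh_s2),
      _["var"] = vec_mean(v_s), _["SD.var"] = vec_sd(v_s, v_s2),
      _["samples"] = samples, _["n_keep"] = kept);
}
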