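#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Truncated-normal draw by inverse-CDF, bounds may be +-Inf.
static double rtruncnorm1(double mu, double sd, double lo, double hi) {
  double plo = R_finite(lo) ? R::pnorm(lo, mu, sd, 1, 0) : 0.0;
  double phi = R_finite(hi) ? R::pnorm(hi, mu, sd, 1, 0) : 1.0;
  if (phi - plo < 1e-14) {
    // numerically degenerate window: return the nearest feasible point
    double mid = R_finite(lo) ? (R_finite(hi) ? 0.5 * (lo + hi) : lo) : hi;
    return mid;
  }
  double u = plo + unif_rand() * (phi - plo);
  double z = R::qnorm(u, mu, sd, 1, 0);
  if (R_finite(lo) && z < lo) z = lo;
  if (R_finite(hi) && z > hi) z = hi;
  return z;
}

// Single-site Gibbs sampler for the mixed model
//   y = W theta + e,  theta = (b, h, a),
//   h ~ N(0, I vh), a ~ N(0, K va), e ~ N(0, I ve),
// with scaled-inverse-chi-square variance updates, operating on the sparse
// design W (dgCMatrix) and the sparse prior precision Kinv of the animal
// block. For threshold traits, y holds latent liabilities augmented each
// round from truncated normals between the current category thresholds.
//
// Update order per round: liabilities -> b -> h -> a -> thresholds ->
// variances. Uses R's RNG stream so runs are reproducible via set.seed().
// [[Rcpp::export]]
List gibbs_mixed(NumericVector y_in,
                 IntegerVector ycat,
                 S4 W, S4 Kinv,
                 int n_fixed, int n_flock, int n_animal,
                 int n_iter, int burn_in, int thin,
                 NumericVector prior_df, NumericVector prior_S,
                 bool fix_var, NumericVector fixed_var,
                 int n_cat, NumericVector thr_init,
                 bool store_effects,
                 NumericVector start_var) {
  const IntegerVector wi = W.slot("i");
  const IntegerVector wp = W.slot("p");
  const NumericVector wx = W.slot("x");
  const IntegerVector wdim = W.slot("Dim");
  const int n = wdim[0], p = wdim[1];
  const IntegerVector ki = Kinv.slot("i");
  const IntegerVector kp = Kinv.slot("p");
  const NumericVector kx = Kinv.slot("x");

  const bool threshold = n_cat >= 2;
  const int n_thr = threshold ? (n_cat - 1) : 0;
  // thresholds t_1..t_{C-1}; t_1 = 0 fixed, t_2 = 1 fixed when C >= 3,
  // t_3.. sampled (C >= 4); residual variance sampled only when C >= 3
  const int first_free_thr = 2;           // 0-based index into thr
  const bool sample_ve = !threshold || n_cat >= 3;

  std::vector<double> theta(p, 0.0);
  NumericVector liab = clone(y_in);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = liab[i];

  std::vector<double> wtw(p, 0.0);
  for (int j = 0; j < p; ++j)
    for (int idx = wp[j]; idx < wp[j + 1]; ++idx)
      wtw[j] += wx[idx] * wx[idx];

  double va = start_var[0], vh = start_var[1], ve = start_var[2];
  if (fix_var) { va = fixed_var[0]; vh = fixed_var[1]; ve = fixed_var[2]; }
  std::vector<double> thr(n_thr);
  for (int k = 0; k < n_thr; ++k) thr[k] = thr_init[k];

  const int n_store = (n_iter - burn_in) / thin;
  const int n_thr_free = std::max(0, n_thr - first_free_thr);
  NumericMatrix var_draws(n_store, 3 + n_thr_free);
  NumericMatrix eff_draws(store_effects ? n_store : 1,
                          store_effects ? p : 1);
  std::vector<double> th_sum(p, 0.0), th_sumsq(p, 0.0);

  GetRNGstate();
  int stored = 0;
  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- latent liabilities ---
    if (threshold) {
      double sde = std::sqrt(ve);
      for (int i = 0; i < n; ++i) {
        int c = ycat[i];                       // 1..C
        double lo = (c == 1) ? R_NegInf : thr[c - 2];
        double hi = (c == n_cat) ? R_PosInf : thr[c - 1];
        double mu = liab[i] - e[i];
        double lnew = rtruncnorm1(mu, sde, lo, hi);
        e[i] += lnew - liab[i];
        liab[i] = lnew;
      }
    }

    // --- location effects: fixed, flock, animal (ascending column order) ---
    for (int j = 0; j < p; ++j) {
      double rhs = wtw[j] * theta[j];
      for (int idx = wp[j]; idx < wp[j + 1]; ++idx)
        rhs += wx[idx] * e[wi[idx]];
      double alpha = 0.0, prior_diag = 0.0, prior_off = 0.0;
      if (j >= n_fixed + n_flock) {           // animal block
        alpha = ve / va;
        int k = j - n_fixed - n_flock;
        for (int idx = kp[k]; idx < kp[k + 1]; ++idx) {
          int l = ki[idx];
          if (l == k) prior_diag += kx[idx];
          else prior_off += kx[idx] * theta[n_fixed + n_flock + l];
        }
      } else if (j >= n_fixed) {              // flock block (iid)
        alpha = ve / vh;
        prior_diag = 1.0;
      }
      double denom = wtw[j] + alpha * prior_diag;
      if (denom <= 0.0) continue;             // empty fixed column
      double mean = (rhs - alpha * prior_off) / denom;
      double nv = R::rnorm(mean, std::sqrt(ve / denom));
      double delta = nv - theta[j];
      if (delta != 0.0)
        for (int idx = wp[j]; idx < wp[j + 1]; ++idx)
          e[wi[idx]] -= wx[idx] * delta;
      theta[j] = nv;
    }

    // --- free thresholds (C >= 4) ---
    if (threshold && n_thr_free > 0) {
      for (int k = first_free_thr; k < n_thr; ++k) {
        // t_{k+1} separates categories k+1 and k+2 (1-based categories)
        double lo = R_NegInf, hi = R_PosInf;
        for (int i = 0; i < n; ++i) {
          if (ycat[i] == k + 1 && liab[i] > lo) lo = liab[i];
          if (ycat[i] == k + 2 && liab[i] < hi) hi = liab[i];
        }
        if (!R_finite(lo)) lo = thr[k - 1];
        if (!R_finite(hi)) hi = lo + 1.0;
        if (lo < thr[k - 1]) lo = thr[k - 1];
        if (k + 1 < n_thr && hi > thr[k + 1]) hi = thr[k + 1];
        thr[k] = lo + unif_rand() * (hi - lo);
      }
    }

    // --- variances ---
    if (!fix_var) {
      if (n_flock > 0) {
        double ss = 0.0;
        for (int j = n_fixed; j < n_fixed + n_flock; ++j)
          ss += theta[j] * theta[j];
        vh = (ss + prior_df[1] * prior_S[1]) / R::rchisq(n_flock + prior_df[1]);
      }
      {
        // quadratic form a' Kinv a
        double qf = 0.0;
        for (int k = 0; k < n_animal; ++k) {
          double ak = theta[n_fixed + n_flock + k];
          if (ak == 0.0) continue;
          double acc = 0.0;
          for (int idx = kp[k]; idx < kp[k + 1]; ++idx)
            acc += kx[idx] * theta[n_fixed + n_flock + ki[idx]];
          qf += ak * acc;
        }
        if (qf < 0.0) qf = 0.0;
        va = (qf + prior_df[0] * prior_S[0]) / R::rchisq(n_animal + prior_df[0]);
      }
      if (sample_ve) {
        double sse = 0.0;
        for (int i = 0; i < n; ++i) sse += e[i] * e[i];
        ve = (sse + prior_df[2] * prior_S[2]) / R::rchisq(n + prior_df[2]);
      }
    }

    // --- storage ---
    if (iter > burn_in && (iter - burn_in) % thin == 0 && stored < n_store) {
      var_draws(stored, 0) = va;
      var_draws(stored, 1) = vh;
      var_draws(stored, 2) = ve;
      for (int k = 0; k < n_thr_free; ++k)
        var_draws(stored, 3 + k) = thr[first_free_thr + k];
      for (int j = 0; j < p; ++j) {
        th_sum[j] += theta[j];
        th_sumsq[j] += theta[j] * theta[j];
        if (store_effects) eff_draws(stored, j) = theta[j];
      }
      ++stored;
    }
  }
  PutRNGstate();

  NumericVector pm(p), psd(p);
  for (int j = 0; j < p; ++j) {
    pm[j] = th_sum[j] / n_store;
    double v = th_sumsq[j] / n_store - pm[j] * pm[j];
    psd[j] = std::sqrt(std::max(0.0, v * n_store / std::max(1, n_store - 1)));
  }
  return List::create(_["var_draws"] = var_draws,
                      _["effect_mean"] = pm,
                      _["effect_sd"] = psd,
                      _["effect_draws"] = eff_draws,
                      _["n_store"] = n_store);
}
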