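#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the animal-level model
//   y = mu + u (+ v) + e,  V(u) = G sigmaA2, V(v) = D sigmaD2,
//   V(e) = diag(1/w) sigmaE2,
// parameterized through the mixed-model equations: location effects are
// updated one at a time from their scalar normal full conditionals (the
// off-diagonal coupling of u_i enters through the precision Ginv/sigmaA2),
// variance components from their scaled inverse chi-square conditionals
// under flat priors.  Uses R's RNG, so results are reproducible with
// set.seed() on the R side.
// [[Rcpp::export(name = ".gibbs_animal_cpp")]]
List gibbs_animal_cpp(NumericVector y, NumericVector w,
                      NumericMatrix Ginv, NumericMatrix Dinv,
                      bool dominance,
                      int n_iter, int burn_in, int thin,
                      double sigmaA2, double sigmaD2, double sigmaE2,
                      double floor_val) {
  int n = y.size();
  NumericVector u(n), v(n);
  double mu = mean(y);
  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix samples(n_keep, dominance ? 4 : 3); // mu, sigmaA2, (sigmaD2), sigmaE2
  NumericVector u_mean(n), v_mean(n);
  int kept = 0;
  int floor_hits = 0;
  // residual vector e = y - mu - u - v maintained incrementally
  NumericVector e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  for (int it = 1; it <= n_iter; ++it) {
    double lamE = 1.0 / sigmaE2;
    // overall mean (flat prior)
    {
      double sw = 0.0, swr = 0.0;
      for (int i = 0; i < n; ++i) { sw += w[i]; swr += w[i] * (e[i] + mu); }
      double prec = sw * lamE;
      double mu_new = swr * lamE / prec + R::rnorm(0.0, std::sqrt(1.0 / prec));
      for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
      mu = mu_new;
    }
    // additive effects u_i; Ginv is symmetric so row i is read as the
    // contiguous column i
    {
      double lamA = 1.0 / sigmaA2;
      const double *G = Ginv.begin();
      for (int i = 0; i < n; ++i) {
        const double *gi = G + (std::size_t)i * n;
        double gdot = 0.0;
        for (int j = 0; j < n; ++j) gdot += gi[j] * u[j];
        gdot -= gi[i] * u[i];
        double prec = w[i] * lamE + gi[i] * lamA;
        double rhs = w[i] * lamE * (e[i] + u[i]) - lamA * gdot;
        double u_new = rhs / prec + R::rnorm(0.0, std::sqrt(1.0 / prec));
        e[i] += u[i] - u_new;
        u[i] = u_new;
      }
      double quad = 0.0;
      for (int i = 0; i < n; ++i) {
        const double *gi = G + (std::size_t)i * n;
        double acc = 0.0;
        for (int j = 0; j < n; ++j) acc += gi[j] * u[j];
        quad += u[i] * acc;
      }
      sigmaA2 = quad / R::rchisq(n - 2.0);
      if (sigmaA2 < floor_val) { sigmaA2 = floor_val; ++floor_hits; }
    }
    // dominance effects v_i
    if (dominance) {
      double lamD = 1.0 / sigmaD2;
      const double *Dv = Dinv.begin();
      for (int i = 0; i < n; ++i) {
        const double *di = Dv + (std::size_t)i * n;
        double ddot = 0.0;
        for (int j = 0; j < n; ++j) ddot += di[j] * v[j];
        ddot -= di[i] * v[i];
        double prec = w[i] * lamE + di[i] * lamD;
        double rhs = w[i] * lamE * (e[i] + v[i]) - lamD * ddot;
        double v_new = rhs / prec + R::rnorm(0.0, std::sqrt(1.0 / prec));
        e[i] += v[i] - v_new;
        v[i] = v_new;
      }
      double quad = 0.0;
      for (int i = 0; i < n; ++i) {
        const double *di = Dv + (std::size_t)i * n;
        double acc = 0.0;
        for (int j = 0; j < n; ++j) acc += di[j] * v[j];
        quad += v[i] * acc;
      }
      sigmaD2 = quad / R::rchisq(n - 2.0);
      if (sigmaD2 < floor_val) { sigmaD2 = floor_val; ++floor_hits; }
    }
    // residual variance
    {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += w[i] * e[i] * e[i];
      sigmaE2 = sse / R::rchisq(n - 2.0);
      if (sigmaE2 < floor_val) { sigmaE2 = floor_val; ++floor_hits; }
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      samples(kept, 0) = mu;
      samples(kept, 1) = sigmaA2;
      if (dominance) { samples(kept, 2) = sigmaD2; samples(kept, 3) = sigmaE2; }
      else samples(kept, 2) = sigmaE2;
      for (int i = 0; i < n; ++i) { u_mean[i] += u[i]; if (dominance) v_mean[i] += v[i]; }
      ++kept;
    }
  }
  if (kept > 0) {
    for (int i = 0; i < n; ++i) { u_mean[i] /= kept; v_mean[i] /= kept; }
  }
  return List::create(_["samples"] = samples, _["u_mean"] = u_mean,
                      _["v_mean"] = v_mean, _["floor_hits"] = floor_hits);
}

// Single-site Gibbs sampler for the marker-level model
//   y = mu + T a + X d + e,  V(a) = I sigma_a2, V(d) = I sigma_d2,
//   V(e) = diag(1/w) sigmaE2,
// with T coded {-1, 0, 1} and X coded {0, 1, 0}.  Sampling order per
// iteration: mu, all additive effects, all dominance effects, variances.
// When update_variances is false all three variances stay fixed (BLUP-SNP).
// [[Rcpp::export(name = ".gibbs_snp_cpp")]]
List gibbs_snp_cpp(NumericVector y, NumericVector w,
                   NumericMatrix T, NumericMatrix X,
                   int n_iter, int burn_in, int thin,
                   double sigma_a2, double sigma_d2, double sigmaE2,
                   bool update_variances, double floor_val) {
  int n = y.size(), m = T.ncol();
  NumericVector a(m), d(m);
  double mu = mean(y);
  NumericVector e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  // precomputed weighted diagonal cross products
  NumericVector twt(m), xwx(m);
  for (int k = 0; k < m; ++k) {
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      s1 += w[i] * T(i, k) * T(i, k);
      s2 += w[i] * X(i, k) * X(i, k);
    }
    twt[k] = s1; xwx[k] = s2;
  }
  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix samples(n_keep, 4); // mu, sigma_a2, sigma_d2, sigmaE2
  NumericVector a_mean(m), d_mean(m);
  int kept = 0, floor_hits = 0;

  for (int it = 1; it <= n_iter; ++it) {
    double lamE = 1.0 / sigmaE2;
    {
      double sw = 0.0, swr = 0.0;
      for (int i = 0; i < n; ++i) { sw += w[i]; swr += w[i] * (e[i] + mu); }
      double prec = sw * lamE;
      double mu_new = swr * lamE / prec + R::rnorm(0.0, std::sqrt(1.0 / prec));
      for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
      mu = mu_new;
    }
    double lamA = 1.0 / sigma_a2;
    for (int k = 0; k < m; ++k) {
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += w[i] * T(i, k) * e[i];
      rhs = lamE * (rhs + twt[k] * a[k]);
      double prec = twt[k] * lamE + lamA;
      double a_new = rhs / prec + R::rnorm(0.0, std::sqrt(1.0 / prec));
      double delta = a[k] - a_new;
      if (delta != 0.0) for (int i = 0; i < n; ++i) e[i] += T(i, k) * delta;
      a[k] = a_new;
    }
    double lamD = 1.0 / sigma_d2;
    for (int k = 0; k < m; ++k) {
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += w[i] * X(i, k) * e[i];
      rhs = lamE * (rhs + xwx[k] * d[k]);
      double prec = xwx[k] * lamE + lamD;
      double d_new = rhs / prec + R::rnorm(0.0, std::sqrt(1.0 / prec));
      double delta = d[k] - d_new;
      if (delta != 0.0) for (int i = 0; i < n; ++i) e[i] += X(i, k) * delta;
      d[k] = d_new;
    }
    if (update_variances) {
      double ssa = 0.0, ssd = 0.0, sse = 0.0;
      for (int k = 0; k < m; ++k) { ssa += a[k] * a[k]; ssd += d[k] * d[k]; }
      for (int i = 0; i < n; ++i) sse += w[i] * e[i] * e[i];
      sigma_a2 = ssa / R::rchisq(m - 2.0);
      sigma_d2 = ssd / R::rchisq(m - 2.0);
      sigmaE2 = sse / R::rchisq(n - 2.0);
      if (sigma_a2 < floor_val) { sigma_a2 = floor_val; ++floor_hits; }
      if (sigma_d2 < floor_val) { sigma_d2 = floor_val; ++floor_hits; }
      if (sigmaE2 < floor_val) { sigmaE2 = floor_val; ++floor_hits; }
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      samples(kept, 0) = mu;
      samples(kept, 1) = sigma_a2;
      samples(kept, 2) = sigma_d2;
      samples(kept, 3) = sigmaE2;
      for (int k = 0; k < m; ++k) { a_mean[k] += a[k]; d_mean[k] += d[k]; }
      ++kept;
    }
  }
  if (kept > 0) for (int k = 0; k < m; ++k) { a_mean[k] /= kept; d_mean[k] /= kept; }
  return List::create(_["samples"] = samples, _["a_mean"] = a_mean,
                      _["d_mean"] = d_mean, _["floor_hits"] = floor_hits);
}
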