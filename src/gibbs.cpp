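#include <Rcpp.h>
using namespace Rcpp;

// Collapsed conjugate Gibbs sampler for the ontology-structured hierarchy
//   y_z ~ N(mu_z, s_z^2), mu_z ~ N(beta_d, tau_d^2)  =>  (mu_z integrated)
//   y_z ~ N(beta_{d(z)}, s_z^2 + tau_{d(z)}^2)
//   beta_d ~ N(gamma_{c(d)}, sigma_{c(d)}^2)
//   gamma_c ~ N(alpha, zeta^2)
//   alpha ~ N(0, loc_sd^2);  zeta, sigma_c, tau_d ~ halfN(0, scale_sd^2)
//
// Each sweep draws (alpha, gamma, beta) jointly from their exact Gaussian
// conditional given the scales — one upward message pass to alpha, then
// ancestral sampling back down the tree — and then slice-samples each scale
// on the log scale against the collapsed likelihood. Integrating the
// trial-level means out removes the funnel coupling between tau_d and the
// per-trial deviations, so the chain mixes fast even for single-trial drugs.

static inline double sq(double x) { return x * x; }

// generic slice sampler on x with log-density lp (Neal 2003, stepping out)
template <class F>
static double slice1(double x0, F lp) {
  const double w = 1.0;
  const int m = 60;
  double logy = lp(x0) + std::log(R::unif_rand());
  double L = x0 - w * R::unif_rand();
  double Rr = L + w;
  int j = (int)std::floor(m * R::unif_rand());
  int kk = m - 1 - j;
  while (j-- > 0 && lp(L) > logy) L -= w;
  while (kk-- > 0 && lp(Rr) > logy) Rr += w;
  for (;;) {
    double x1 = L + R::unif_rand() * (Rr - L);
    if (lp(x1) >= logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
}

// half-normal(0, ps2) prior on exp(x), plus the log-scale Jacobian
static inline double log_prior_scale(double x, double ps2) {
  return -0.5 * std::exp(2.0 * x) / ps2 + x;
}

// scale governing k normal deviations with sum of squares ss
static inline double lp_scale_ss(double x, double k, double ss, double ps2) {
  if (x < -12.0 || x > 8.0) return -1e300;
  return -k * x - 0.5 * ss * std::exp(-2.0 * x) + log_prior_scale(x, ps2);
}

static inline double rnorm_pm(double mean, double prec) {
  return mean + R::norm_rand() / std::sqrt(prec);
}

// [[Rcpp::export(name = ".gibbs_full")]]
List gibbs_full_cpp(NumericVector y, NumericVector s,
                    IntegerVector drug_of_trial,   // 0-based, length n
                    IntegerVector class_of_drug,   // 0-based, length D
                    int n_class,
                    double loc_prior_sd, double scale_prior_sd,
                    int n_keep, int n_burn, int n_chain, int thin,
                    bool fix_scales,
                    NumericVector fixed_tau, NumericVector fixed_sigma,
                    double fixed_zeta) {
  int n = y.size();
  int D = class_of_drug.size();
  int C = n_class;
  double loc_prec = 1.0 / sq(loc_prior_sd);
  double ps2 = sq(scale_prior_sd);

  std::vector<int> k_class(C, 0);  // drugs per class
  for (int d = 0; d < D; d++) k_class[class_of_drug[d]]++;
  // trials grouped by drug for the per-drug likelihood loops
  std::vector<std::vector<int>> trials_of(D);
  for (int z = 0; z < n; z++) trials_of[drug_of_trial[z]].push_back(z);

  NumericVector draw_alpha(n_keep * n_chain), draw_zeta(n_keep * n_chain);
  NumericVector draw_beta(n_keep * D * n_chain);
  NumericVector draw_gamma(n_keep * C * n_chain);
  NumericVector draw_tau(n_keep * D * n_chain);
  NumericVector draw_sigma(n_keep * C * n_chain);

  for (int ch = 0; ch < n_chain; ch++) {
    std::vector<double> beta(D), gamma(C), tau(D), sigma(C);
    double alpha = 0.0, zeta = 1.0;
    if (fix_scales) {
      for (int d = 0; d < D; d++) tau[d] = fixed_tau[d];
      for (int c = 0; c < C; c++) sigma[c] = fixed_sigma[c];
      zeta = fixed_zeta;
    } else {  // overdispersed scale starts
      for (int d = 0; d < D; d++)
        tau[d] = scale_prior_sd * std::exp(0.5 * R::norm_rand());
      for (int c = 0; c < C; c++)
        sigma[c] = scale_prior_sd * std::exp(0.5 * R::norm_rand());
      zeta = scale_prior_sd * std::exp(0.5 * R::norm_rand());
    }

    int total = n_burn + n_keep * thin;
    int kept = 0;
    for (int it = 0; it < total; it++) {
      // ---- joint draw of (alpha, gamma, beta) given scales ----
      // upward pass: precision-weighted data summaries per drug and class
      std::vector<double> P_drug(D), num_drug(D);
      for (int d = 0; d < D; d++) {
        double P = 0.0, num = 0.0;
        double t2 = sq(tau[d]);
        for (int z : trials_of[d]) {
          double w = 1.0 / (sq(s[z]) + t2);
          P += w;
          num += w * y[z];
        }
        P_drug[d] = P;
        num_drug[d] = num;
      }
      std::vector<double> P_class(C, 0.0), num_class(C, 0.0);
      for (int d = 0; d < D; d++) {
        int c = class_of_drug[d];
        double w = 1.0 / (sq(sigma[c]) + 1.0 / P_drug[d]);
        P_class[c] += w;
        num_class[c] += w * (num_drug[d] / P_drug[d]);
      }
      double P_a = loc_prec, num_a = 0.0;
      double z2 = sq(zeta);
      for (int c = 0; c < C; c++) {
        double w = 1.0 / (z2 + 1.0 / P_class[c]);
        P_a += w;
        num_a += w * (num_class[c] / P_class[c]);
      }
      // downward ancestral sampling
      alpha = rnorm_pm(num_a / P_a, P_a);
      for (int c = 0; c < C; c++) {
        double prec = 1.0 / z2 + P_class[c];
        gamma[c] = rnorm_pm((alpha / z2 + num_class[c]) / prec, prec);
      }
      for (int d = 0; d < D; d++) {
        double s2c = sq(sigma[class_of_drug[d]]);
        double prec = 1.0 / s2c + P_drug[d];
        beta[d] = rnorm_pm((gamma[class_of_drug[d]] / s2c + num_drug[d]) / prec,
                           prec);
      }

      if (!fix_scales) {
        // tau_d against the collapsed likelihood prod N(y_z; beta_d, s^2+tau^2)
        for (int d = 0; d < D; d++) {
          double b = beta[d];
          const std::vector<int>& tz = trials_of[d];
          auto lp = [&](double x) {
            if (x < -12.0 || x > 8.0) return -1e300;
            double t2 = std::exp(2.0 * x);
            double ll = 0.0;
            for (int z : tz) {
              double v = sq(s[z]) + t2;
              ll += -0.5 * std::log(v) - 0.5 * sq(y[z] - b) / v;
            }
            return ll + log_prior_scale(x, ps2);
          };
          tau[d] = std::exp(slice1(std::log(tau[d]), lp));
        }
        // sigma_c from the beta-gamma deviations in its class
        std::vector<double> ss_class(C, 0.0);
        for (int d = 0; d < D; d++)
          ss_class[class_of_drug[d]] += sq(beta[d] - gamma[class_of_drug[d]]);
        for (int c = 0; c < C; c++) {
          double k = k_class[c], ss = ss_class[c];
          sigma[c] = std::exp(slice1(std::log(sigma[c]),
            [&](double x) { return lp_scale_ss(x, k, ss, ps2); }));
        }
        // zeta from the gamma-alpha deviations
        double ss_z = 0.0;
        for (int c = 0; c < C; c++) ss_z += sq(gamma[c] - alpha);
        double kC = C;
        zeta = std::exp(slice1(std::log(zeta),
          [&](double x) { return lp_scale_ss(x, kC, ss_z, ps2); }));
      }

      if (it >= n_burn && ((it - n_burn) % thin) == 0) {
        int i = kept++;
        draw_alpha[ch * n_keep + i] = alpha;
        draw_zeta[ch * n_keep + i] = zeta;
        for (int d = 0; d < D; d++) {
          draw_beta[ch * n_keep * D + d * n_keep + i] = beta[d];
          draw_tau[ch * n_keep * D + d * n_keep + i] = tau[d];
        }
        for (int c = 0; c < C; c++) {
          draw_gamma[ch * n_keep * C + c * n_keep + i] = gamma[c];
          draw_sigma[ch * n_keep * C + c * n_keep + i] = sigma[c];
        }
      }
    }
  }

  draw_alpha.attr("dim") = IntegerVector::create(n_keep, n_chain);
  draw_zeta.attr("dim") = IntegerVector::create(n_keep, n_chain);
  draw_beta.attr("dim") = IntegerVector::create(n_keep, D, n_chain);
  draw_gamma.attr("dim") = IntegerVector::create(n_keep, C, n_chain);
  draw_tau.attr("dim") = IntegerVector::create(n_keep, D, n_chain);
  draw_sigma.attr("dim") = IntegerVector::create(n_keep, C, n_chain);

  return List::create(
    Named("alpha") = draw_alpha, Named("zeta") = draw_zeta,
    Named("beta") = draw_beta, Named("gamma") = draw_gamma,
    Named("tau") = draw_tau, Named("sigma") = draw_sigma);
}

// Two-level single-drug model, trial means likewise integrated out:
//   y_z ~ N(beta, s_z^2 + tau^2); beta ~ N(0, loc_sd^2);
//   tau ~ halfN(0, scale_sd^2)
// [[Rcpp::export(name = ".gibbs_single")]]
List gibbs_single_cpp(NumericVector y, NumericVector s,
                      double loc_prior_sd, double scale_prior_sd,
                      int n_keep, int n_burn, int n_chain, int thin) {
  int n = y.size();
  double loc_prec = 1.0 / sq(loc_prior_sd);
  double ps2 = sq(scale_prior_sd);

  NumericVector draw_beta(n_keep * n_chain), draw_tau(n_keep * n_chain);

  for (int ch = 0; ch < n_chain; ch++) {
    double beta = 0.0;
    double tau = scale_prior_sd * std::exp(0.5 * R::norm_rand());

    int total = n_burn + n_keep * thin;
    int kept = 0;
    for (int it = 0; it < total; it++) {
      double t2 = sq(tau);
      double P = loc_prec, num = 0.0;
      for (int z = 0; z < n; z++) {
        double w = 1.0 / (sq(s[z]) + t2);
        P += w;
        num += w * y[z];
      }
      beta = rnorm_pm(num / P, P);
      auto lp = [&](double x) {
        if (x < -12.0 || x > 8.0) return -1e300;
        double tt = std::exp(2.0 * x);
        double ll = 0.0;
        for (int z = 0; z < n; z++) {
          double v = sq(s[z]) + tt;
          ll += -0.5 * std::log(v) - 0.5 * sq(y[z] - beta) / v;
        }
        return ll + log_prior_scale(x, ps2);
      };
      tau = std::exp(slice1(std::log(tau), lp));

      if (it >= n_burn && ((it - n_burn) % thin) == 0) {
        int i = kept++;
        draw_beta[ch * n_keep + i] = beta;
        draw_tau[ch * n_keep + i] = tau;
      }
    }
  }
  draw_beta.attr("dim") = IntegerVector::create(n_keep, n_chain);
  draw_tau.attr("dim") = IntegerVector::create(n_keep, n_chain);
  return List::create(Named("beta") = draw_beta, Named("tau") = draw_tau);
}
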