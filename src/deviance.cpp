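// Profiled marginal (-2 log) likelihood of the polynomial random-coefficient
// model, evaluated from per-patient sufficient statistics.
//
// Model per patient i:  y_i = Z_i alpha + Z_i b_i + e_i,
//   b_i ~ N(0, G), e_i ~ N(0, sigma2 I).
// Parameterisation: G = sigma2 * Lambda Lambda', Lambda lower-triangular with
// log-scale diagonal (theta packs Lambda column-major, lower triangle).
// alpha (GLS) and sigma2 are profiled out analytically; the optimiser only
// sees theta. Woodbury/determinant-lemma identities keep every solve at
// q x q (q = degree + 1 <= 4), so cost is O(n_patients * q^3) per call.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static mat theta_to_lambda(const vec& theta, int q) {
  mat L(q, q, fill::zeros);
  int k = 0;
  for (int j = 0; j < q; ++j) {
    for (int i = j; i < q; ++i) {
      L(i, j) = (i == j) ? std::exp(theta(k)) : theta(k);
      ++k;
    }
  }
  return L;
}

// [[Rcpp::export(name = ".cpp_profiled_deviance")]]
Rcpp::List cpp_profiled_deviance(const arma::vec& theta,
                                 const Rcpp::List& szz,
                                 const Rcpp::List& szy,
                                 const arma::vec& syy,
                                 const arma::ivec& nobs,
                                 const bool reml) {
  const int m = szz.size();
  const int q = Rcpp::as<arma::mat>(szz[0]).n_rows;
  const double big = 1e10;
  // refuse absurd parameter regions before they overflow the algebra
  if (abs(theta).max() > 40.0) {
    return Rcpp::List::create(Rcpp::Named("deviance") = big,
                              Rcpp::Named("ok") = false);
  }
  const mat L = theta_to_lambda(theta, q);

  mat A(q, q, fill::zeros);   // sum Z' V*^-1 Z   (V* = I + Z G* Z')
  vec b(q, fill::zeros);      // sum Z' V*^-1 y
  double c = 0.0;             // sum y' V*^-1 y
  double logdet_sum = 0.0;
  double N = 0.0;

  for (int i = 0; i < m; ++i) {
    const mat Szz = Rcpp::as<arma::mat>(szz[i]);
    const vec Szy = Rcpp::as<arma::vec>(szy[i]);
    const mat SL = Szz * L;              // q x q
    mat C = symmatu(L.t() * SL);         // L' Szz L (symmetrised)
    C.diag() += 1.0;                     // I + L' Szz L
    mat R;
    if (!chol(R, C)) {
      return Rcpp::List::create(Rcpp::Named("deviance") = big,
                                Rcpp::Named("ok") = false);
    }
    logdet_sum += 2.0 * sum(log(R.diag()));
    const vec u = L.t() * Szy;           // q
    // plain back-substitution; skip arma's rcond check + refinement,
    // which warn loudly at the extreme thetas BFGS probes
    const mat Ci_Lt_Szz = solve(trimatu(R),
                                solve(trimatl(R.t()), SL.t(),
                                      solve_opts::fast),
                                solve_opts::fast);
    const vec Ci_u = solve(trimatu(R),
                           solve(trimatl(R.t()), u, solve_opts::fast),
                           solve_opts::fast);
    A += Szz - SL * Ci_Lt_Szz;
    b += Szy - SL * Ci_u;
    c += syy(i) - dot(u, Ci_u);
    N += nobs(i);
  }

  // quiet SPD solve; a failed factorisation (boundary theta where the
  // whole-cohort information matrix underflows) just reports a bad value
  mat RA;
  if (!chol(RA, symmatu(A))) {
    return Rcpp::List::create(Rcpp::Named("deviance") = big,
                              Rcpp::Named("ok") = false);
  }
  const vec alpha = solve(trimatu(RA),
                          solve(trimatl(RA.t()), b, solve_opts::fast),
                          solve_opts::fast);
  double rss = c - dot(b, alpha);
  if (rss < 1e-300) rss = 1e-300;

  const double denom = reml ? (N - q) : N;
  double sigma2 = rss / denom;
  if (sigma2 < 1e-12) sigma2 = 1e-12;   // guard for noiseless degenerate fits

  double dev = denom * std::log(2.0 * M_PI * sigma2) + logdet_sum + denom;
  if (reml) {
    dev += 2.0 * sum(log(RA.diag()));
  }
  if (!std::isfinite(dev)) {
    return Rcpp::List::create(Rcpp::Named("deviance") = big,
                              Rcpp::Named("ok") = false);
  }

  return Rcpp::List::create(
      Rcpp::Named("deviance") = dev,
      Rcpp::Named("alpha") = alpha,
      Rcpp::Named("sigma2") = sigma2,
      Rcpp::Named("lambda") = L,
      Rcpp::Named("ok") = true);
}
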