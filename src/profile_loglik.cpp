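// Profiled Gaussian log-likelihood of the block pedigree model
//   Omega_f = pg * 2Phi_f + pc * H_f + (1 - pg - pc) * I
// scaled by a total variance s2 that, like the fixed effects beta, has a
// closed-form maximiser given the variance proportions.  Families are
// independent blocks: only per-family factorisations are ever formed, so
// memory scales with the largest family, not the cohort.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".cpp_profile_loglik")]]
Rcpp::List cpp_profile_loglik(const Rcpp::List& Klist,
                              const Rcpp::List& Xlist,
                              const Rcpp::List& ylist,
                              double pg, double pc, bool household) {
  const int F = Klist.size();
  double pe = 1.0 - pg - (household ? pc : 0.0);
  if (pg < 0.0 || pc < 0.0 || pe <= 0.0) {
    return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf);
  }
  int p = Rcpp::as<Rcpp::NumericMatrix>(Xlist[0]).ncol();
  mat XtX(p, p, fill::zeros);
  vec Xty(p, fill::zeros);
  double yty = 0.0, logdet = 0.0;
  long n = 0;
  for (int f = 0; f < F; ++f) {
    mat K = Rcpp::as<mat>(Klist[f]);
    mat X = Rcpp::as<mat>(Xlist[f]);
    vec y = Rcpp::as<vec>(ylist[f]);
    const uword k = K.n_rows;
    mat R = pg * K;
    R.diag() += pe;
    if (household && pc > 0.0) R += pc * ones<mat>(k, k);
    mat L;
    if (!chol(L, R, "lower")) {
      return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf);
    }
    mat Xs = solve(trimatl(L), X);
    vec ys = solve(trimatl(L), y);
    XtX += Xs.t() * Xs;
    Xty += Xs.t() * ys;
    yty += dot(ys, ys);
    logdet += 2.0 * accu(log(L.diag()));
    n += k;
  }
  vec beta;
  if (!solve(beta, XtX, Xty, solve_opts::no_approx)) {
    beta = pinv(XtX) * Xty;
  }
  double rss = yty - dot(Xty, beta);
  if (rss < 1e-12) rss = 1e-12;
  double s2 = rss / n;
  double ll = -0.5 * (n * (std::log(2.0 * M_PI) + std::log(s2) + 1.0)
                      + logdet);
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("beta") = beta,
                            Rcpp::Named("sigma2_total") = s2,
                            Rcpp::Named("n") = (double) n);
}
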