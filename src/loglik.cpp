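#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Core of the profiled GLS log-likelihood of the split-plot isoform
// model, computed from per-condition sufficient statistics so cost does
// not grow with the number of samples:
//
//   Sigma : L x L within-sample covariance
//   X     : J design blocks (L x p), one per condition
//   Ybar  : L x J matrix of condition mean vectors
//   S     : L x L x J within-condition scatter, sum_k (Y - Ybar)(Y - Ybar)'
//   K     : per-condition sample counts
//
// logLik = -1/2 sum_jk [ L log 2pi + log|Sigma| + r'Sigma^-1 r ] at the
// GLS estimate beta = (sum K_j X_j' W X_j)^-1 sum K_j X_j' W Ybar_j,
// with W = Sigma^-1.
static bool profile_core(const mat& Sigma, const std::vector<mat>& X,
                         const mat& Ybar, const cube& S, const vec& K,
                         double& ll, vec& beta, mat& A) {
  const uword L = Sigma.n_rows;
  const uword J = K.n_elem;

  mat R;
  if (!chol(R, Sigma)) return false;
  const double logdet = 2.0 * accu(log(R.diag()));

  mat W;
  if (!inv_sympd(W, Sigma)) return false;

  const uword p = X[0].n_cols;
  A.zeros(p, p);
  vec b(p, fill::zeros);
  double trace_term = 0.0;
  const double N = accu(K);

  for (uword j = 0; j < J; ++j) {
    const mat WX = W * X[j];
    A += K(j) * (X[j].t() * WX);
    b += K(j) * (WX.t() * Ybar.col(j));
    trace_term += accu(W % S.slice(j));
  }

  if (!solve(beta, A, b, solve_opts::likely_sympd + solve_opts::no_approx))
    return false;

  double quad = trace_term;
  for (uword j = 0; j < J; ++j) {
    const vec d = Ybar.col(j) - X[j] * beta;
    quad += K(j) * as_scalar(d.t() * W * d);
  }

  ll = -0.5 * (N * L * std::log(2.0 * M_PI) + N * logdet + quad);
  return std::isfinite(ll);
}

static std::vector<mat> as_blocks(const Rcpp::List& X) {
  std::vector<mat> out;
  out.reserve(X.size());
  for (int j = 0; j < X.size(); ++j) out.push_back(Rcpp::as<mat>(X[j]));
  return out;
}

// [[Rcpp::export(name = ".glsProfileCpp")]]
Rcpp::List glsProfile(const arma::mat& Sigma, const Rcpp::List& X,
                      const arma::mat& Ybar, const arma::cube& S,
                      const arma::vec& K, const bool wantBeta) {
  const std::vector<mat> Xb = as_blocks(X);
  double ll;
  vec beta;
  mat A;
  if (!profile_core(Sigma, Xb, Ybar, S, K, ll, beta, A))
    return Rcpp::List::create(Rcpp::Named("logLik") = R_NegInf);
  if (!wantBeta)
    return Rcpp::List::create(Rcpp::Named("logLik") = ll);
  mat Ainv;
  if (!inv_sympd(Ainv, A))
    return Rcpp::List::create(Rcpp::Named("logLik") = R_NegInf);
  return Rcpp::List::create(Rcpp::Named("logLik") = ll,
                            Rcpp::Named("beta") = beta,
                            Rcpp::Named("vcov") = Ainv);
}

// Negative profiled log-likelihood as a function of the unconstrained
// optimizer parameterization theta (variances logged; unstructured uses
// the log-Cholesky with the column-wise lower triangle). structCode:
// 1 = compound symmetry, 2 = unequal variance, 3 = unstructured.
// Returns 1e10 on any numerical failure so optim() can keep going.
// [[Rcpp::export(name = ".negProfileLoglikCpp")]]
double negProfileLoglik(const arma::vec& theta, const int structCode,
                        const Rcpp::List& X, const arma::mat& Ybar,
                        const arma::cube& S, const arma::vec& K) {
  const uword L = Ybar.n_rows;
  mat Sigma(L, L);
  if (structCode == 1) {
    const double rho = std::exp(theta(1));
    Sigma.fill(rho);
    Sigma.diag() += std::exp(theta(0));
  } else if (structCode == 2) {
    const double rho = std::exp(theta(L));
    Sigma.fill(rho);
    for (uword l = 0; l < L; ++l) Sigma(l, l) += std::exp(theta(l));
  } else {
    mat C(L, L, fill::zeros);
    uword idx = 0;
    for (uword c = 0; c < L; ++c)
      for (uword r = c; r < L; ++r) {
        const double v = theta(idx++);
        C(r, c) = (r == c) ? std::exp(v) : v;
      }
    Sigma = C * C.t();
  }
  if (!Sigma.is_finite()) return 1e10;

  const std::vector<mat> Xb = as_blocks(X);
  double ll;
  vec beta;
  mat A;
  if (!profile_core(Sigma, Xb, Ybar, S, K, ll, beta, A)) return 1e10;
  return -ll;
}
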