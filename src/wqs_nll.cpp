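#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Parameter packing for the subset-level weighted-index GLM.
//   par = [alpha, b, delta (k), theta (m-1)]
//   weights w = softmax(c(theta, 0))  (simplex without explicit constraint)
//   beta1   = b                if dir == 0 (unconstrained)
//           = dir * exp(b)     if dir == +1 / -1 (sign-constrained)
//   eta     = alpha + beta1 * (Q w) + X delta
// family: 0 = binomial (logit), 1 = gaussian (unit variance; profile later)

static void wqs_unpack(const arma::vec& par, const arma::mat& Q,
                       const arma::mat& X, int dir,
                       double& alpha, double& beta1, arma::vec& delta,
                       arma::vec& w, arma::vec& z, arma::vec& eta) {
  const arma::uword m = Q.n_cols, k = X.n_cols;
  alpha = par(0);
  beta1 = (dir == 0) ? par(1) : dir * std::exp(std::min(par(1), 50.0));
  arma::vec theta(m, arma::fill::zeros);
  for (arma::uword i = 0; i + 1 < m; ++i) theta(i) = par(2 + k + i);
  theta -= theta.max();
  w = arma::exp(theta);
  w /= arma::accu(w);
  z = Q * w;
  eta = alpha + beta1 * z;
  if (k > 0) {
    delta = par.subvec(2, 1 + k);
    eta += X * delta;
  } else {
    delta.reset();
  }
}

// [[Rcpp::export]]
double wqs_nll_cpp(const arma::vec& par, const arma::mat& Q,
                   const arma::mat& X, const arma::vec& y,
                   int dir, int family) {
  double alpha, beta1;
  arma::vec delta, w, z, eta;
  wqs_unpack(par, Q, X, dir, alpha, beta1, delta, w, z, eta);
  double ll = 0.0;
  if (family == 0) {
    for (arma::uword i = 0; i < eta.n_elem; ++i) {
      const double e = eta(i);
      const double lse = (e > 0) ? e + std::log1p(std::exp(-e))
                                 : std::log1p(std::exp(e));
      ll += y(i) * e - lse;
    }
  } else {
    const arma::vec r = y - eta;
    ll = -0.5 * arma::dot(r, r);
  }
  return -ll;
}

// [[Rcpp::export]]
arma::vec wqs_nll_grad_cpp(const arma::vec& par, const arma::mat& Q,
                           const arma::mat& X, const arma::vec& y,
                           int dir, int family) {
  const arma::uword m = Q.n_cols, k = X.n_cols;
  double alpha, beta1;
  arma::vec delta, w, z, eta;
  wqs_unpack(par, Q, X, dir, alpha, beta1, delta, w, z, eta);

  arma::vec r(eta.n_elem);  // d loglik / d eta
  if (family == 0) {
    for (arma::uword i = 0; i < eta.n_elem; ++i)
      r(i) = y(i) - 1.0 / (1.0 + std::exp(-eta(i)));
  } else {
    r = y - eta;
  }

  arma::vec g(par.n_elem, arma::fill::zeros);
  g(0) = arma::accu(r);
  const double dz = arma::dot(r, z);
  g(1) = (dir == 0) ? dz : beta1 * dz;  // chain through exp for constrained
  if (k > 0) g.subvec(2, 1 + k) = X.t() * r;
  if (m > 1) {
    const arma::vec gw = beta1 * (Q.t() * r);   // d loglik / d w
    const double wg = arma::dot(w, gw);
    for (arma::uword i = 0; i + 1 < m; ++i)
      g(2 + k + i) = w(i) * (gw(i) - wg);       // softmax Jacobian
  }
  return -g;
}
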