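// Gibbs sampler for a phylogenetic threshold (probit) mixed model:
//   z_i = x_i' b + u_i + e_i,  e_i ~ N(0, 1) fixed,
//   y_i = 1{z_i > 0},          u ~ N(0, sigma2 * C),
// with N(0, b_var) priors on the fixed effects and an inverse-gamma
// (shape, scale) prior on the phylogenetic variance sigma2.
// Latent z are sampled by truncated-normal data augmentation (Albert-Chib),
// (b, u) jointly from their conditional Gaussian, sigma2 from its conjugate
// inverse-gamma. Uses R's RNG, so runs are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Standard normal truncated to (a, Inf): rejection sampling with Robert's
// exponential proposal in the far tail.
static double rtnorm_lower(double a) {
  if (a < 0.45) {
    for (;;) {
      double x = R::norm_rand();
      if (x > a) return x;
    }
  }
  const double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a + R::exp_rand() / alpha;
    double d = x - alpha;
    if (R::unif_rand() <= std::exp(-0.5 * d * d)) return x;
  }
}

// N(mu, 1) truncated to be positive (positive = true) or negative.
static double rtnorm_sign(double mu, bool positive) {
  if (positive) return mu + rtnorm_lower(-mu);
  return mu - rtnorm_lower(mu);
}

// [[Rcpp::export]]
arma::mat probit_gibbs_cpp(const arma::ivec& y, const arma::mat& X,
                           const arma::mat& Cinv, double prior_shape,
                           double prior_scale, double b_var, int n_iter,
                           int burnin, int thin) {
  const int n = X.n_rows, p = X.n_cols, q = p + n;
  const arma::mat Xt = X.t();
  const arma::mat XtX = Xt * X;

  arma::vec b(p, arma::fill::zeros);
  arma::vec u(n, arma::fill::zeros);
  arma::vec z(n, arma::fill::zeros);
  double sigma2 = 1.0;

  const int n_keep = (n_iter - burnin + thin - 1) / thin;
  arma::mat out(n_keep, p + 1);
  int kept = 0;

  arma::mat M(q, q);
  arma::vec rhs(q), mean(q), v(q), draw(q);

  for (int it = 0; it < n_iter; ++it) {
    // latent liabilities
    arma::vec mu = X * b + u;
    for (int i = 0; i < n; ++i) z(i) = rtnorm_sign(mu(i), y(i) == 1);

    // joint (b, u)
    M.submat(0, 0, p - 1, p - 1) = XtX + arma::eye(p, p) / b_var;
    M.submat(0, p, p - 1, q - 1) = Xt;
    M.submat(p, 0, q - 1, p - 1) = X;
    M.submat(p, p, q - 1, q - 1) = arma::eye(n, n) + Cinv / sigma2;
    rhs.head(p) = Xt * z;
    rhs.tail(n) = z;

    arma::mat R = arma::chol(M); // upper: R'R = M
    mean = arma::solve(arma::trimatu(R),
                       arma::solve(arma::trimatl(R.t()), rhs));
    for (int i = 0; i < q; ++i) v(i) = R::norm_rand();
    draw = mean + arma::solve(arma::trimatu(R), v);
    b = draw.head(p);
    u = draw.tail(n);

    // phylogenetic variance
    double ss = arma::as_scalar(u.t() * Cinv * u);
    double shape_post = prior_shape + 0.5 * n;
    double rate_post = prior_scale + 0.5 * ss;
    sigma2 = 1.0 / R::rgamma(shape_post, 1.0 / rate_post);
    if (sigma2 < 1e-10) sigma2 = 1e-10;

    if (it >= burnin && (it - burnin) % thin == 0) {
      for (int j = 0; j < p; ++j) out(kept, j) = b(j);
      out(kept, p) = sigma2;
      ++kept;
    }
  }
  return out.rows(0, kept - 1);
}
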