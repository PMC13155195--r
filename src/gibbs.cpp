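#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gibbs kernels for the logistic-tree normal samplers. All randomness goes
// through R's RNG (norm_rand / unif_rand / R::rgamma) so that set.seed()
// controls every draw.

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z[i] = R::norm_rand();
  return z;
}

// Sample psi_i | rest ~ MVN( P^{-1} h_i, P^{-1} ) with P = Omega + diag(w_i)
// and h_i = Omega mu + kappa_i, independently across the n rows.
// [[Rcpp::export(name = ".psi_update_dense")]]
arma::mat psi_update_dense(const arma::mat& Omega, const arma::vec& mu,
                           const arma::mat& kappa, const arma::mat& w) {
  int n = kappa.n_rows, d = kappa.n_cols;
  arma::mat psi(n, d);
  arma::vec om = Omega * mu;
  for (int i = 0; i < n; ++i) {
    arma::mat P = Omega;
    P.diag() += w.row(i).t();
    arma::vec h = om + kappa.row(i).t();
    arma::mat R = arma::chol(P);  // upper: P = R'R
    // mean: solve P m = h; draw: m + R^{-1} z
    arma::vec m = arma::solve(arma::trimatl(R.t()), h);
    m = arma::solve(arma::trimatu(R), m);
    arma::vec z = rnorm_vec(d);
    psi.row(i) = (m + arma::solve(arma::trimatu(R), z)).t();
  }
  return psi;
}

// One full column sweep of the blocked Gibbs sampler for the Bayesian
// graphical lasso: double-exponential(lambda) off-diagonals with latent
// scales Tau, exponential(lambda/2) diagonals. S is the d x d scatter matrix
// of the ns centred Gaussian vectors. Positive definiteness is maintained by
// construction (gamma > 0 added to the Schur complement).
// [[Rcpp::export(name = ".glasso_sweep")]]
arma::mat glasso_sweep(arma::mat Omega, const arma::mat& S,
                       const arma::mat& Tau, double lambda, int ns) {
  int d = Omega.n_rows;
  if (d == 1) {
    double g = R::rgamma(ns / 2.0 + 1.0, 2.0 / (S(0, 0) + lambda));
    Omega(0, 0) = g;
    return Omega;
  }
  arma::uvec all = arma::regspace<arma::uvec>(0, d - 1);
  for (int j = 0; j < d; ++j) {
    arma::uvec notj = arma::find(all != (unsigned)j);
    arma::mat O11 = Omega.submat(notj, notj);
    arma::mat O11inv = arma::inv_sympd(O11);
    double s22 = S(j, j);
    arma::vec s12 = S.col(j);
    s12 = s12.elem(notj);
    arma::vec tau12 = Tau.col(j);
    tau12 = tau12.elem(notj);
    arma::mat Cinv = (s22 + lambda) * O11inv;
    Cinv.diag() += 1.0 / tau12;
    arma::mat R = arma::chol(Cinv);
    arma::vec mtmp = arma::solve(arma::trimatl(R.t()), -s12);
    arma::vec mean = arma::solve(arma::trimatu(R), mtmp);
    arma::vec beta = mean + arma::solve(arma::trimatu(R), rnorm_vec(d - 1));
    double gam = R::rgamma(ns / 2.0 + 1.0, 2.0 / (s22 + lambda));
    for (int k = 0; k < d - 1; ++k) {
      Omega(notj[k], j) = beta[k];
      Omega(j, notj[k]) = beta[k];
    }
    arma::vec ob = O11inv * beta;
    Omega(j, j) = gam + arma::dot(beta, ob);
  }
  return Omega;
}

static double rinvgauss1(double mu, double lam) {
  double y = R::norm_rand();
  y = y * y;
  double x = mu + 0.5 * mu * mu * y / lam -
             0.5 * mu / lam * std::sqrt(4.0 * mu * lam * y + mu * mu * y * y);
  if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
  return x;
}

// Latent scale update for the graphical lasso: 1/tau_jk | omega_jk follows an
// inverse Gaussian with mean sqrt(lambda^2 / omega_jk^2) and shape lambda^2.
// [[Rcpp::export(name = ".glasso_tau_update")]]
arma::mat glasso_tau_update(const arma::mat& Omega, double lambda) {
  int d = Omega.n_rows;
  arma::mat Tau(d, d, arma::fill::ones);
  for (int j = 0; j < d - 1; ++j) {
    for (int k = j + 1; k < d; ++k) {
      double w = std::fabs(Omega(j, k));
      double mu = (w < 1e-12) ? 1e12 : lambda / w;
      double u = rinvgauss1(mu, lambda * lambda);
      if (u < 1e-12) u = 1e-12;
      double tau = 1.0 / u;
      Tau(j, k) = tau;
      Tau(k, j) = tau;
    }
  }
  return Tau;
}

// Random-effect update for the mixed-effects sampler: for each subject g,
// gamma_g | rest ~ MVN( P^{-1} h_g, P^{-1} ), P = Omega_re + n_g * D,
// D = diag(1/sigma2), h_g = D * (column sums of that subject's residuals).
// [[Rcpp::export(name = ".gamma_update")]]
arma::mat gamma_update(const arma::mat& Omega_re, const arma::vec& sigma2,
                       const arma::mat& rsum, const arma::ivec& ng) {
  int G = rsum.n_rows, d = rsum.n_cols;
  arma::vec dprec = 1.0 / sigma2;
  arma::mat out(G, d);
  for (int g = 0; g < G; ++g) {
    arma::mat P = Omega_re;
    P.diag() += ng[g] * dprec;
    arma::vec h = rsum.row(g).t() % dprec;
    arma::mat R = arma::chol(P);
    arma::vec m = arma::solve(arma::trimatl(R.t()), h);
    m = arma::solve(arma::trimatu(R), m);
    out.row(g) = (m + arma::solve(arma::trimatu(R), rnorm_vec(d))).t();
  }
  return out;
}
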