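#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Exact Polya-Gamma PG(1, z) sampling via the alternating-series (Devroye-type)
// method of Polson, Scott & Windle. A PG(1, z) variate is J*(1, z/2)/4 where
// J* is sampled by rejection from a mixture of a truncated inverse-Gaussian
// (left of t = 0.64) and a truncated exponential (right of t), with the
// Jacobi-density partial sums as the squeeze. No truncation approximation:
// the accept/reject loop terminates with an exact draw.

static const double PG_TRUNC = 0.64;

// n-th coefficient of the alternating series for the J*(1,0) density at x.
static double pg_a(int n, double x) {
  double np5 = n + 0.5;
  if (x > PG_TRUNC) {
    return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * x * 0.5);
  }
  return M_PI * np5 * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np5 * np5 / x);
}

// Probability that the proposal falls in the truncated-exponential component.
static double pg_mass_texpon(double z) {
  double t  = PG_TRUNC;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double b  = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a  = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// Inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, t).
static double pg_rtigauss(double z, double t) {
  z = std::fabs(z);
  double x = t + 1.0;
  if (z < 1.0 / t) {  // mean beyond the truncation point: chi-type rejection
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = R::norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

static double rpg1(double zin) {
  if (!std::isfinite(zin)) Rcpp::stop("non-finite tilt in PG(1, z) sampler");
  double z  = std::fabs(zin) * 0.5;
  double fz = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double ptex = pg_mass_texpon(z);
  while (true) {
    double x;
    if (R::unif_rand() < ptex) {
      x = PG_TRUNC + R::exp_rand() / fz;
    } else {
      x = pg_rtigauss(z, PG_TRUNC);
    }
    double s = pg_a(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    while (true) {
      ++n;
      if (n % 2 == 1) {
        s -= pg_a(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += pg_a(n, x);
        if (y > s) break;  // reject, redraw proposal
      }
    }
  }
}

//' @noRd
// [[Rcpp::export]]
Rcpp::NumericVector rpg_cpp(int n, Rcpp::NumericVector z) {
  Rcpp::NumericVector out(n);
  int m = z.size();
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i % m]);
  return out;
}

// One systematic Gibbs sweep chain for the multinomial logistic model with a
// Polya-Gamma expansion. Categories q = 1..Q-1 are updated in turn against the
// current competing-category offset C_iq = log(sum_{r != q} exp(psi_ir)) with
// psi_iQ = 0; conditionally the update for beta_q is multivariate normal with
// precision X' Omega X + B0^-1.
//
// X:     n x p design; cat: 1-based category index per subject (1..Q)
// b0:    p x (Q-1) prior means; B0inv: p x p x (Q-1) prior precisions
// Returns a p x (Q-1) x iter cube of retained draws (burnin discarded).
//' @noRd
// [[Rcpp::export]]
arma::cube gibbs_mlr_cpp(const arma::mat& X, const arma::ivec& cat, int Q,
                         const arma::mat& b0, const arma::cube& B0inv,
                         int iter, int burnin, const arma::mat& beta_init) {
  const int n = X.n_rows, p = X.n_cols, Qm1 = Q - 1;
  arma::mat beta = beta_init;            // p x (Q-1)
  arma::mat psi  = X * beta;             // n x (Q-1)
  arma::cube draws(p, Qm1, iter);
  arma::vec Cq(n), omega(n), kappa(n);

  // prior contribution to the full-conditional mean, fixed across sweeps
  arma::mat prior_rhs(p, Qm1);
  for (int q = 0; q < Qm1; ++q) prior_rhs.col(q) = B0inv.slice(q) * b0.col(q);

  for (int it = 0; it < iter + burnin; ++it) {
    for (int q = 0; q < Qm1; ++q) {
      // offset of competing categories (reference included as exp(0) = 1)
      for (int i = 0; i < n; ++i) {
        double m = 0.0;
        for (int r = 0; r < Qm1; ++r)
          if (r != q && psi(i, r) > m) m = psi(i, r);
        double s = std::exp(-m);
        for (int r = 0; r < Qm1; ++r)
          if (r != q) s += std::exp(psi(i, r) - m);
        Cq[i] = m + std::log(s);
        omega[i] = rpg1(psi(i, q) - Cq[i]);
        kappa[i] = (cat[i] == q + 1 ? 0.5 : -0.5);
      }
      arma::mat Xw = X.each_col() % omega;
      arma::mat prec = X.t() * Xw + B0inv.slice(q);
      arma::vec rhs  = X.t() * (kappa + omega % Cq) + prior_rhs.col(q);
      arma::mat L;
      if (!arma::chol(L, prec, "lower"))
        Rcpp::stop("singular posterior precision for response category %d", q + 1);
      arma::vec mu = arma::solve(arma::trimatu(L.t()),
                                 arma::solve(arma::trimatl(L), rhs));
      arma::vec zdraw(p);
      for (int j = 0; j < p; ++j) zdraw[j] = R::norm_rand();
      arma::vec bq = mu + arma::solve(arma::trimatu(L.t()), zdraw);
      if (!bq.is_finite())
        Rcpp::stop("divergent linear predictor in category %d", q + 1);
      beta.col(q) = bq;
      psi.col(q)  = X * bq;
    }
    if (it >= burnin) draws.slice(it - burnin) = beta;
  }
  return draws;
}
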