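#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Generalized inverse Gaussian sampler
//
// Target density: f(x) propto x^(lambda-1) exp(-(rho*x + chi/x)/2), x > 0.
// chi = 0 (lambda > 0) degenerates to Gamma(shape = lambda, rate = rho/2).
// Otherwise we sample the two-parameter form GIG(lambda, omega),
// omega = sqrt(rho*chi), by Devroye-type rejection from a three-piece
// log-concave envelope, then rescale by sqrt(chi/rho). Uses R's RNG so
// draws are reproducible under set.seed().
// ---------------------------------------------------------------------------

static inline double gig_psi(double x, double alpha, double lam) {
  return -alpha * (std::cosh(x) - 1.0) - lam * (std::exp(x) - x - 1.0);
}

static inline double gig_dpsi(double x, double alpha, double lam) {
  return -alpha * std::sinh(x) - lam * (std::exp(x) - 1.0);
}

static double gig_one(double lambda, double rho, double chi) {
  if (!(rho > 0.0)) stop("sampleGIG: rho must be > 0");
  if (chi < 0.0) stop("sampleGIG: chi must be >= 0");
  if (chi == 0.0) {
    if (!(lambda > 0.0)) stop("sampleGIG: chi = 0 requires lambda > 0");
    return R::rgamma(lambda, 2.0 / rho);  // shape, scale
  }

  double lam = lambda;
  bool swap = false;
  if (lam < 0.0) { lam = -lam; swap = true; }

  const double omega = std::sqrt(rho * chi);
  const double alpha = std::sqrt(omega * omega + lam * lam) - lam;

  // right and left envelope cut points t, s
  double x = -gig_psi(1.0, alpha, lam);
  double t;
  if (x >= 0.5 && x <= 2.0) t = 1.0;
  else if (x > 2.0) t = std::sqrt(2.0 / (alpha + lam));
  else t = std::log(4.0 / (alpha + 2.0 * lam));

  x = -gig_psi(-1.0, alpha, lam);
  double s;
  if (x >= 0.5 && x <= 2.0) s = 1.0;
  else if (x > 2.0) s = std::sqrt(4.0 / (alpha * std::cosh(1.0) + lam));
  else {
    double s1 = std::log(1.0 + 1.0 / alpha +
                         std::sqrt(1.0 / (alpha * alpha) + 2.0 / alpha));
    s = (lam > 0.0) ? std::min(1.0 / lam, s1) : s1;
  }

  const double eta = -gig_psi(t, alpha, lam);
  const double zeta = -gig_dpsi(t, alpha, lam);
  const double theta = -gig_psi(-s, alpha, lam);
  const double xi = gig_dpsi(-s, alpha, lam);
  const double pp = 1.0 / xi;
  const double rr = 1.0 / zeta;
  const double td = t - rr * eta;
  const double sd = s - pp * theta;
  const double q = td + sd;

  double rnd = 0.0;
  for (;;) {
    const double U = unif_rand();
    const double V = unif_rand();
    const double W = unif_rand();
    if (U < q / (pp + q + rr)) rnd = -sd + q * V;
    else if (U < (q + rr) / (pp + q + rr)) rnd = td - rr * std::log(V);
    else rnd = -sd + pp * std::log(V);

    double g;
    if (rnd >= -sd && rnd <= td) g = 1.0;
    else if (rnd > td) g = std::exp(-eta - zeta * (rnd - t));
    else g = std::exp(-theta + xi * (rnd + s));

    if (W * g <= std::exp(gig_psi(rnd, alpha, lam))) break;
  }

  double out = std::exp(rnd) *
    (lam / omega + std::sqrt(1.0 + (lam / omega) * (lam / omega)));
  if (swap) out = 1.0 / out;
  return out * std::sqrt(chi / rho);
}

//' @noRd
// [[Rcpp::export(name = ".gig_draws")]]
NumericVector gig_draws(int n, double lambda, double rho, double chi) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = gig_one(lambda, rho, chi);
  return out;
}

// ---------------------------------------------------------------------------
// Block beta update: draw beta_blk ~ N(A^-1 bhat, (sigma2/n) A^-1) with
// A = D + diag(1/psi), via lower Cholesky A = L L'. On factorization
// failure add jitter eps = 1e-6 * trace(A)/dim to the diagonal, doubling
// up to 6 times.
// ---------------------------------------------------------------------------

static arma::mat chol_with_jitter(const arma::mat& A, int block_id,
                                  arma::mat& A_used) {
  arma::mat L;
  if (arma::chol(L, A, "lower")) { A_used = A; return L; }
  double eps = 1e-6 * arma::trace(A) / A.n_rows;
  for (int k = 0; k < 6; ++k) {
    arma::mat Aj = A;
    Aj.diag() += eps;
    if (arma::chol(L, Aj, "lower")) { A_used = Aj; return L; }
    eps *= 2.0;
  }
  stop("Cholesky factorization failed in LD block %d after maximum jitter",
       block_id);
}

static arma::vec draw_beta_block(const arma::mat& D, const arma::vec& bhat,
                                 const arma::vec& psi, double sigma2,
                                 double n_gwas, int block_id, double& quad) {
  arma::mat A = D;
  A.diag() += 1.0 / psi;
  arma::mat A_used;
  arma::mat L = chol_with_jitter(A, block_id, A_used);
  arma::vec tmp = arma::solve(arma::trimatl(L), bhat);
  const double sdv = std::sqrt(sigma2 / n_gwas);
  for (arma::uword j = 0; j < tmp.n_elem; ++j) tmp[j] += sdv * norm_rand();
  arma::vec beta = arma::solve(arma::trimatu(L.t()), tmp);
  quad = arma::as_scalar(beta.t() * A_used * beta);
  return beta;
}

//' @noRd
// [[Rcpp::export(name = ".beta_block_draws")]]
arma::mat beta_block_draws(const arma::mat& D, const arma::vec& bhat,
                           const arma::vec& psi, double sigma2,
                           double n_gwas, int ndraws) {
  arma::mat out(ndraws, bhat.n_elem);
  double quad = 0.0;
  for (int i = 0; i < ndraws; ++i) {
    out.row(i) = draw_beta_block(D, bhat, psi, sigma2, n_gwas, 1, quad).t();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Full chain. Fixed scan per the package contract:
//   beta (per block) -> psi, delta -> phi (auto mode) -> sigma2.
// Running means accumulated over retained draws; optional full beta trace.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cs_gibbs_chain")]]
List cs_gibbs_chain(List block_idx, List block_D, arma::vec beta_hat,
                    double n_gwas, double a, double b, double phi_init,
                    bool phi_auto, int n_iter, int n_burnin, int thin,
                    bool update_psi, bool update_sigma2, arma::vec psi_init,
                    double sigma2_init, bool keep_trace) {
  const int p = beta_hat.n_elem;
  const int n_blk = block_idx.size();
  if (n_burnin >= n_iter) stop("n_burnin must be < n_iter");
  if (thin < 1) stop("thin must be >= 1");

  arma::vec beta(p, arma::fill::zeros);
  arma::vec psi = psi_init;
  double phi = phi_init;
  double sigma2 = sigma2_init;
  // delta initialized at its conditional mean under psi = 1
  arma::vec delta(p);
  delta.fill((a + b) / (1.0 + phi_init));

  std::vector<arma::uvec> idx(n_blk);
  std::vector<arma::mat> Dm(n_blk);
  for (int k = 0; k < n_blk; ++k) {
    IntegerVector iv = block_idx[k];
    arma::uvec u(iv.size());
    for (int j = 0; j < iv.size(); ++j) u[j] = iv[j] - 1;  // 1-based in
    idx[k] = u;
    Dm[k] = as<arma::mat>(block_D[k]);
    if (Dm[k].n_rows != u.n_elem)
      stop("block %d: D dimension does not match SNP count", k + 1);
  }

  const int n_kept = (n_iter - n_burnin) / thin;
  arma::vec beta_sum(p, arma::fill::zeros), beta_sumsq(p, arma::fill::zeros);
  arma::vec psi_sum(p, arma::fill::zeros);
  arma::vec phi_trace(n_kept), sigma2_trace(n_kept);
  arma::mat beta_trace;
  if (keep_trace) beta_trace.set_size(n_kept, p);

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // -- beta, block by block
    double quad = 0.0;
    for (int k = 0; k < n_blk; ++k) {
      double q = 0.0;
      beta.elem(idx[k]) = draw_beta_block(
        Dm[k], beta_hat.elem(idx[k]), psi.elem(idx[k]), sigma2, n_gwas,
        k + 1, q);
      quad += q;
    }
    if (!beta.is_finite())
      stop("non-finite beta draw at iteration %d; aborting chain", it);

    // -- psi, delta
    if (update_psi) {
      for (int j = 0; j < p; ++j) {
        double chi = n_gwas * beta[j] * beta[j] / sigma2;
        double ps = gig_one(a - 0.5, 2.0 * delta[j], chi);
        if (ps > 1.0) ps = 1.0;
        psi[j] = ps;
        delta[j] = R::rgamma(a + b, 1.0 / (psi[j] + phi));
      }
    }

    // -- phi (auto)
    if (phi_auto) {
      double w = R::rgamma(1.0, 1.0 / (phi + 1.0));
      phi = R::rgamma(p * b + 0.5, 1.0 / (arma::accu(delta) + w));
    }

    // -- sigma2
    if (update_sigma2) {
      double e1 = (n_gwas / 2.0) *
        (1.0 - 2.0 * arma::dot(beta, beta_hat) + quad);
      double e2 = (n_gwas / 2.0) * arma::accu(arma::square(beta) / psi);
      double e = std::max(e1, e2);
      if (!std::isfinite(e))
        stop("non-finite residual-variance rate at iteration %d", it);
      sigma2 = 1.0 / R::rgamma((n_gwas + p) / 2.0, 1.0 / e);
    }

    if (it > n_burnin && (it - n_burnin) % thin == 0) {
      beta_sum += beta;
      beta_sumsq += arma::square(beta);
      psi_sum += psi;
      phi_trace[kept] = phi;
      sigma2_trace[kept] = sigma2;
      if (keep_trace) beta_trace.row(kept) = beta.t();
      ++kept;
    }
  }

  arma::vec beta_mean = beta_sum / kept;
  arma::vec beta_var =
    (beta_sumsq - kept * arma::square(beta_mean)) / std::max(kept - 1, 1);

  List out = List::create(
    _["beta_mean"] = beta_mean, _["beta_var"] = beta_var,
    _["psi_mean"] = psi_sum / kept, _["phi_mean"] = arma::mean(phi_trace),
    _["sigma2_mean"] = arma::mean(sigma2_trace),
    _["phi_trace"] = phi_trace, _["sigma2_trace"] = sigma2_trace,
    _["n_kept"] = kept);
  if (keep_trace) out["beta_trace"] = beta_trace;
  return out;
}
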