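// Fast kernel for the 2003 Phi minimum-information-bipartition search.
// The R functions in R/phi2003.R define the semantics; this kernel must
// agree with them exactly (a test enforces it).  Row-vector dynamics
// F <- F * CON + c * R throughout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG_2PIE = std::log(2.0 * M_PI * std::exp(1.0));

// 0.5 * log det of a symmetric positive definite matrix via Cholesky
static double half_logdet(const arma::mat& s) {
  arma::mat ch;
  if (!arma::chol(ch, s)) {
    stop("covariance not positive definite in Phi kernel");
  }
  return arma::accu(arma::log(ch.diag()));
}

// Gaussian entropy of the block of `cov` indexed by `idx`
static double block_entropy(const arma::mat& cov, const arma::uvec& idx) {
  arma::mat s = cov.submat(idx, idx);
  return 0.5 * (double)idx.n_elem * LOG_2PIE + half_logdet(s);
}

// stationary covariance, reference (fixed-point) mode:
// COV = t(Q) diag(noise^2) Q with Q = inv(I - CON)
static arma::mat cov_reference(const arma::mat& q, const arma::vec& noise) {
  arma::mat sq = q;
  for (arma::uword i = 0; i < sq.n_rows; ++i) sq.row(i) *= noise(i);
  return sq.t() * sq;
}

// stationary covariance, corrected (discrete Lyapunov) mode:
// S = M S t(M) + diag(noise^2), M = t(CON)
static arma::mat cov_corrected(const arma::mat& con, const arma::vec& noise) {
  arma::uword k = con.n_rows;
  arma::mat m = con.t();
  arma::mat v = arma::diagmat(arma::square(noise));
  arma::mat lhs = arma::eye(k * k, k * k) - arma::kron(m, m);
  arma::vec s = arma::solve(lhs, arma::vectorise(v));
  arma::mat out(s.memptr(), k, k);
  return 0.5 * (out + out.t());
}

// MI(A:B) under the noise assignment (cp on A, ci on B), i.e. EI(A->B)
static double ei_directional(const arma::mat& con, const arma::mat& q,
                             const arma::uvec& a, const arma::uvec& b,
                             double cp, double ci, bool corrected) {
  arma::uword k = con.n_rows;
  arma::vec noise(k);
  noise.fill(ci);
  noise.elem(a).fill(cp);
  arma::mat cov = corrected ? cov_corrected(con, noise)
                            : cov_reference(q, noise);
  arma::uvec ab = arma::join_cols(a, b);
  return block_entropy(cov, a) + block_entropy(cov, b)
       - block_entropy(cov, ab);
}

// Minimum information bipartition of the induced subsystem `cons`
// (k x k).  Returns unnormalized EI, normalized EI, and a 0/1 mask of
// part A at the minimizing cut (first minimum in mask order).
// [[Rcpp::export(name = "phi_mib_cpp")]]
List phi_mib_cpp(const arma::mat& cons, double cp, double ci,
                 bool corrected) {
  arma::uword k = cons.n_rows;
  if (k < 2 || cons.n_cols != k) stop("need a square matrix of order >= 2");
  if (k > 25) stop("bipartition enumeration refused for k > 25");

  arma::mat q;
  if (!corrected) {
    arma::mat imc = arma::eye(k, k) - cons;
    if (!arma::inv(q, imc)) stop("(I - CON) singular in Phi kernel");
  }

  const double hmax1 = 0.5 * std::log(2.0 * M_PI * std::exp(1.0) * cp * cp);
  double best_norm = arma::datum::inf, best_ei = 0.0;
  unsigned long best_mask = 0;

  unsigned long n_bi = (1UL << (k - 1)) - 1UL;  // part A always holds node 0
  for (unsigned long t = 0; t < n_bi; ++t) {
    unsigned long mask = (t << 1) | 1UL;
    arma::uvec a(k), b(k);
    arma::uword na = 0, nb = 0;
    for (arma::uword i = 0; i < k; ++i) {
      if (mask & (1UL << i)) a(na++) = i; else b(nb++) = i;
    }
    a.resize(na); b.resize(nb);
    double ei = ei_directional(cons, q, a, b, cp, ci, corrected)
              + ei_directional(cons, q, b, a, cp, ci, corrected);
    double norm = ei / (std::min(na, nb) * hmax1);
    if (norm < best_norm) {
      best_norm = norm;
      best_ei = ei;
      best_mask = mask;
    }
  }

  IntegerVector a_mask(k);
  for (arma::uword i = 0; i < k; ++i) {
    a_mask[i] = (best_mask & (1UL << i)) ? 1 : 0;
  }
  return List::create(_["ei"] = best_ei, _["ei_norm"] = best_norm,
                      _["a_mask"] = a_mask);
}
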