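// EM core for probabilistic PCA with missing entries.
// The R wrapper validates inputs, initialises parameters and owns the RNG;
// this routine only iterates the E/M updates over the observed cells.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".ppca_em_cpp")]]
Rcpp::List ppca_em_cpp(const arma::mat& x, const arma::umat& obs,
                       arma::mat W, arma::vec mu, double s2,
                       double tol, int max_iter) {
  const uword n = x.n_rows, d = x.n_cols, k = W.n_cols;
  const double log2pi = std::log(2.0 * M_PI);

  // per-row observed / missing index sets
  std::vector<uvec> olist(n), mlist(n);
  for (uword i = 0; i < n; ++i) {
    olist[i] = find(obs.row(i).t() == 1);
    mlist[i] = find(obs.row(i).t() == 0);
  }

  vec ll_trace(max_iter, fill::zeros);
  bool converged = false;
  int used = 0;
  mat Ik = eye(k, k);

  for (int iter = 0; iter < max_iter; ++iter) {
    mat Szz(k, k, fill::zeros), Sxz(d, k, fill::zeros);
    vec Sz(k, fill::zeros), Sx(d, fill::zeros);
    double sxx = 0.0, ll = 0.0;

    for (uword i = 0; i < n; ++i) {
      const uvec& o = olist[i];
      const uvec& m = mlist[i];
      const uword no = o.n_elem;
      mat Wo = W.rows(o);
      mat M = Wo.t() * Wo + s2 * Ik;
      mat Minv = inv_sympd(M);
      vec xo = x.row(i).t();
      xo = xo(o);
      vec xc = xo - mu(o);
      vec xw = Wo.t() * xc;
      vec Ez = Minv * xw;
      mat Vz = s2 * Minv;

      Szz += Ez * Ez.t() + Vz;
      Sz += Ez;
      Sxz.rows(o) += xo * Ez.t();
      Sx(o) += xo;
      sxx += dot(xo, xo);
      double quad = (dot(xc, xc) - dot(Ez, xw)) / s2;
      double ldM, sign;
      log_det(ldM, sign, M);
      ll += -0.5 * (no * log2pi + (double)(no - k) * std::log(s2) + ldM +
                    quad);
      if (m.n_elem > 0) {
        mat Wm = W.rows(m);
        vec Exm = Wm * Ez + mu(m);
        mat WmV = Wm * Vz;
        Sxz.rows(m) += Exm * Ez.t() + WmV;
        Sx(m) += Exm;
        sxx += dot(Exm, Exm) + trace(WmV * Wm.t()) + m.n_elem * s2;
      }
    }
    ll_trace(iter) = ll;
    used = iter + 1;
    if (iter > 0) {
      double rel = std::abs(ll - ll_trace(iter - 1)) /
        (std::abs(ll_trace(iter - 1)) + datum::eps);
      if (rel < tol) { converged = true; break; }
    }
    // M-step on the augmented design [z; 1]
    mat Aug(k + 1, k + 1);
    Aug.submat(0, 0, k - 1, k - 1) = Szz;
    Aug.submat(0, k, k - 1, k) = Sz;
    Aug.submat(k, 0, k, k - 1) = Sz.t();
    Aug(k, k) = (double)n;
    mat RHS = join_rows(Sxz, Sx);              // d x (k+1)
    mat Wmu = solve(Aug, RHS.t(), solve_opts::likely_sympd).t();
    W = Wmu.cols(0, k - 1);
    mu = Wmu.col(k);
    s2 = std::max((sxx - accu(Wmu % RHS)) / (double)(n * d), 1e-12);
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("mu") = mu,
    Rcpp::Named("sigma2") = s2,
    Rcpp::Named("loglik_trace") = ll_trace.head(used),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("n_iter") = used);
}
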