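// Data-augmentation kernel for multivariate normal imputation.
// The I-step/P-step iteration runs thousands of times per replicate, so it
// lives in C++; all randomness flows through R's RNG so runs are
// reproducible from set.seed() alone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Wishart(df, S) draw by Bartlett decomposition, using R's RNG.
static arma::mat rwishart(double df, const arma::mat& S) {
  const arma::uword d = S.n_cols;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(d, d, arma::fill::zeros);
  for (arma::uword i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

static arma::mat rnorm_mat(arma::uword n, arma::uword m) {
  arma::mat out(n, m);
  for (arma::uword j = 0; j < m; ++j)
    for (arma::uword i = 0; i < n; ++i) out(i, j) = R::norm_rand();
  return out;
}

// One data-augmentation chain. z holds the data with missing cells already
// filled by the starting imputation; `patterns` lists, per missingness
// pattern, the 1-based row indices and observed/missing coordinate sets.
// Snapshots of the completed matrix are taken at the (1-based) iteration
// numbers in take_at.
// [[Rcpp::export]]
List da_chain_cpp(const arma::mat& z_in, const List& patterns,
                  const arma::vec& mu0, const arma::mat& sigma0,
                  const IntegerVector& take_at) {
  arma::mat z = z_in;
  const arma::uword n = z.n_rows, d = z.n_cols;
  arma::vec mu = mu0;
  arma::mat sigma = sigma0;

  const int npat = patterns.size();
  std::vector<arma::uvec> rows(npat), obs(npat), mis(npat);
  for (int p = 0; p < npat; ++p) {
    List pat = patterns[p];
    rows[p] = as<arma::uvec>(pat["rows"]) - 1;
    obs[p] = as<arma::uvec>(pat["obs"]) - 1;
    mis[p] = as<arma::uvec>(pat["mis"]) - 1;
  }

  int total = 0;
  for (int i = 0; i < take_at.size(); ++i) total = std::max(total, take_at[i]);
  List out(take_at.size());
  int slot = 0;

  for (int it = 1; it <= total; ++it) {
    // I-step: draw missing coordinates from their conditional normal
    for (int p = 0; p < npat; ++p) {
      const arma::uvec& o = obs[p];
      const arma::uvec& m = mis[p];
      const arma::uvec& r = rows[p];
      if (o.n_elem == 0) { // fully missing rows: draw from the marginal
        arma::mat ch0 = arma::chol(sigma.submat(m, m), "upper");
        arma::mat draw = rnorm_mat(r.n_elem, m.n_elem) * ch0;
        draw.each_row() += mu.elem(m).t();
        z.submat(r, m) = draw;
        continue;
      }
      arma::mat soo = sigma.submat(o, o);
      arma::mat smo = sigma.submat(m, o);
      arma::mat B = arma::solve(soo, smo.t(), arma::solve_opts::likely_sympd).t();
      arma::mat cc = sigma.submat(m, m) - B * smo.t();
      arma::mat ch = arma::chol(arma::symmatu(cc), "upper");
      arma::mat zo = z.submat(r, o);
      zo.each_row() -= mu.elem(o).t();
      arma::mat cmu = zo * B.t();
      cmu.each_row() += mu.elem(m).t();
      z.submat(r, m) = cmu + rnorm_mat(r.n_elem, m.n_elem) * ch;
    }
    // P-step: (mu, Sigma) from the normal-inverse-Wishart posterior
    // under the Jeffreys prior given the completed data
    arma::rowvec zbar = arma::mean(z, 0);
    arma::mat zc = z.each_row() - zbar;
    arma::mat S = zc.t() * zc;
    arma::mat W = rwishart(double(n - 1), arma::inv_sympd(S));
    sigma = arma::inv_sympd(W);
    arma::vec zn = rnorm_mat(d, 1).col(0);
    mu = zbar.t() + (arma::chol(sigma, "lower") * zn) / std::sqrt(double(n));

    if (slot < take_at.size() && it == take_at[slot]) {
      out[slot] = wrap(z);
      ++slot;
    }
  }
  return out;
}
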