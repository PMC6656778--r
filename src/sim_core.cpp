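// Genotype-level simulation core for the multi- vs single-gene MR study.
// Genotypes are s ~ Binomial(2, q), standardized with the generating q;
// all randomness comes from R's RNG so set.seed() governs reproducibility.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void fill_genotypes(arma::mat& Z, const arma::vec& q) {
  const int n = Z.n_rows, m = Z.n_cols;
  for (int j = 0; j < m; ++j) {
    const double qj = q[j];
    const double p0 = (1.0 - qj) * (1.0 - qj);
    const double p1 = p0 + 2.0 * qj * (1.0 - qj);
    const double mu = 2.0 * qj, sd = std::sqrt(2.0 * qj * (1.0 - qj));
    double* col = Z.colptr(j);
    for (int i = 0; i < n; ++i) {
      const double u = unif_rand();
      const double s = (u > p0) + (u > p1);
      col[i] = (s - mu) / sd;
    }
  }
}

// per-SNP simple-regression summaries of columns of Y on columns of Z
static void marginal_ols(const arma::mat& Z, const arma::mat& Y,
                         arma::mat& beta, arma::mat& se) {
  const int n = Z.n_rows, m = Z.n_cols, k = Y.n_cols;
  const arma::rowvec zmean = arma::mean(Z, 0);
  const arma::rowvec zss = arma::sum(arma::square(Z), 0);
  const arma::rowvec ymean = arma::mean(Y, 0);
  const arma::rowvec yss = arma::sum(arma::square(Y), 0);
  const arma::mat ZtY = Z.t() * Y;
  for (int g = 0; g < k; ++g) {
    const double Syy = yss[g] - n * ymean[g] * ymean[g];
    for (int j = 0; j < m; ++j) {
      const double Sxx = zss[j] - n * zmean[j] * zmean[j];
      const double Sxy = ZtY(j, g) - n * zmean[j] * ymean[g];
      const double b = Sxy / Sxx;
      beta(j, g) = b;
      se(j, g) = std::sqrt((Syy - b * Sxy) / (n - 2) / Sxx);
    }
  }
}

// Full generative cohort: expression per Eq.-4-type model and, optionally,
// the trait. Returns marginal summary statistics and (optionally) the
// individual-level data and the genotype correlation matrix.
// [[Rcpp::export(name = ".sim_cohort_cpp")]]
List sim_cohort_cpp(int n, arma::vec q, arma::mat B, arma::vec alpha,
                    double gamma_e, double gamma_t,
                    arma::vec sig2_e, double sig2_t,
                    bool want_trait, bool want_ld, bool keep) {
  const int m = q.n_elem, k = B.n_cols;
  RNGScope scope;
  arma::mat Z(n, m);
  fill_genotypes(Z, q);
  arma::vec conf(n);
  for (int i = 0; i < n; ++i) conf[i] = norm_rand();
  arma::mat E = Z * B;
  for (int j = 0; j < k; ++j) {
    const double sd = std::sqrt(sig2_e[j]);
    double* col = E.colptr(j);
    for (int i = 0; i < n; ++i) col[i] += gamma_e * conf[i] + sd * norm_rand();
  }
  arma::mat betaE(m, k), seE(m, k);
  marginal_ols(Z, E, betaE, seE);
  List out = List::create(_["beta_eqtl"] = betaE, _["se_eqtl"] = seE);
  if (want_trait) {
    arma::vec trait = E * alpha;
    const double sd = std::sqrt(sig2_t);
    for (int i = 0; i < n; ++i) trait[i] += gamma_t * norm_rand() + sd * norm_rand();
    arma::mat betaG(m, 1), seG(m, 1);
    marginal_ols(Z, arma::mat(trait), betaG, seG);
    out["beta_gwas"] = arma::vec(betaG.col(0));
    out["se_gwas"] = arma::vec(seG.col(0));
    if (keep) out["trait"] = trait;
  }
  if (want_ld) out["C"] = wrap(arma::cor(Z));
  if (keep) { out["Z"] = Z; out["E"] = E; }
  return out;
}

// Summary-only trait cohort: the trait given genotypes is Gaussian with
// mean Z %*% (B alpha) and a noise SD that absorbs the latent expression
// residuals and confounders -- distributionally identical to the full
// generative path, at a fraction of the RNG cost.
// [[Rcpp::export(name = ".sim_trait_summary_cpp")]]
List sim_trait_summary_cpp(int n, arma::vec q, arma::vec b_direct,
                           double noise_sd) {
  const int m = q.n_elem;
  RNGScope scope;
  arma::mat Z(n, m);
  fill_genotypes(Z, q);
  arma::vec trait = Z * b_direct;
  for (int i = 0; i < n; ++i) trait[i] += noise_sd * norm_rand();
  arma::mat betaG(m, 1), seG(m, 1);
  marginal_ols(Z, arma::mat(trait), betaG, seG);
  return List::create(_["beta_gwas"] = arma::vec(betaG.col(0)),
                      _["se_gwas"] = arma::vec(seG.col(0)));
}
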