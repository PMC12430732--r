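#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Cox partial likelihood with Efron handling of tied event times.
// All routines require rows sorted by increasing follow-up time; tied
// times must be adjacent (sorting guarantees this).

// Partial log-likelihood, score vector and observed information at beta.
// [[Rcpp::export]]
List cox_loglik_deriv(const arma::vec& time,
                      const arma::ivec& status,
                      const arma::mat& X,
                      const arma::vec& beta) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec eta = X * beta;
  const double shift = eta.max();          // guards exp() overflow
  arma::vec w = arma::exp(eta - shift);

  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);
  double loglik = 0.0;
  arma::vec U(p, arma::fill::zeros);
  arma::mat I(p, p, arma::fill::zeros);

  arma::sword i = n - 1;
  while (i >= 0) {
    const double t = time[i];
    // accumulate the tied-time block [j+1 .. i]
    double S0d = 0.0, etad = 0.0;
    arma::vec S1d(p, arma::fill::zeros), xd(p, arma::fill::zeros);
    arma::mat S2d(p, p, arma::fill::zeros);
    int d = 0;
    arma::sword j = i;
    while (j >= 0 && time[j] == t) {
      const double wi = w[j];
      const arma::vec xi = X.row(j).t();
      S0 += wi;
      S1 += wi * xi;
      S2 += wi * (xi * xi.t());
      if (status[j] == 1) {
        ++d;
        xd += xi;
        etad += eta[j];
        S0d += wi;
        S1d += wi * xi;
        S2d += wi * (xi * xi.t());
      }
      --j;
    }
    if (d > 0) {
      loglik += etad;
      U += xd;
      for (int l = 0; l < d; ++l) {
        const double f = static_cast<double>(l) / d;
        const double s0 = S0 - f * S0d;
        const arma::vec s1 = S1 - f * S1d;
        const arma::mat s2 = S2 - f * S2d;
        const arma::vec xbar = s1 / s0;
        loglik -= std::log(s0) + shift;
        U -= xbar;
        I += s2 / s0 - xbar * xbar.t();
      }
    }
    i = j;
  }
  return List::create(_["loglik"] = loglik,
                      _["score"] = U,
                      _["imat"] = I);
}

// Schoenfeld residuals plus the extended score/information used by the
// proportional-hazards score test: columns X are augmented (implicitly)
// by X * g(t) with coefficient 0, where g is an already-centred transform
// of time supplied per row.
// [[Rcpp::export]]
List cox_zph_quant(const arma::vec& time,
                   const arma::ivec& status,
                   const arma::mat& X,
                   const arma::vec& beta,
                   const arma::vec& g) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec eta = X * beta;
  const double shift = eta.max();
  arma::vec w = arma::exp(eta - shift);

  const arma::uword ndeath = arma::accu(status == 1);
  arma::mat sch(ndeath, p, arma::fill::zeros);
  arma::vec sch_time(ndeath, arma::fill::zeros);
  arma::vec sch_g(ndeath, arma::fill::zeros);

  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);
  arma::vec u2(p, arma::fill::zeros);
  arma::mat I11(p, p, arma::fill::zeros);
  arma::mat I12(p, p, arma::fill::zeros);
  arma::mat I22(p, p, arma::fill::zeros);

  arma::sword row = ndeath - 1;   // fill residuals from largest time down
  arma::sword i = n - 1;
  while (i >= 0) {
    const double t = time[i];
    double S0d = 0.0;
    arma::vec S1d(p, arma::fill::zeros), xd(p, arma::fill::zeros);
    arma::mat S2d(p, p, arma::fill::zeros);
    int d = 0;
    double gt = 0.0;
    arma::sword j = i;
    while (j >= 0 && time[j] == t) {
      const double wi = w[j];
      const arma::vec xi = X.row(j).t();
      S0 += wi;
      S1 += wi * xi;
      S2 += wi * (xi * xi.t());
      if (status[j] == 1) {
        ++d;
        xd += xi;
        gt = g[j];
        S0d += wi;
        S1d += wi * xi;
        S2d += wi * (xi * xi.t());
      }
      --j;
    }
    if (d > 0) {
      arma::vec xbar_sum(p, arma::fill::zeros);
      arma::mat V_sum(p, p, arma::fill::zeros);
      for (int l = 0; l < d; ++l) {
        const double f = static_cast<double>(l) / d;
        const double s0 = S0 - f * S0d;
        const arma::vec s1 = S1 - f * S1d;
        const arma::mat s2 = S2 - f * S2d;
        const arma::vec xbar = s1 / s0;
        xbar_sum += xbar;
        V_sum += s2 / s0 - xbar * xbar.t();
      }
      const arma::vec xbar_avg = xbar_sum / d;
      for (arma::sword k = i; k > j; --k) {
        if (status[k] == 1) {
          sch.row(row) = (X.row(k) - xbar_avg.t());
          sch_time[row] = t;
          sch_g[row] = gt;
          --row;
        }
      }
      u2 += gt * (xd - xbar_sum);
      I11 += V_sum;
      I12 += gt * V_sum;
      I22 += gt * gt * V_sum;
    }
    i = j;
  }
  return List::create(_["u2"] = u2,
                      _["imat11"] = I11,
                      _["imat12"] = I12,
                      _["imat22"] = I22,
                      _["schoenfeld"] = sch,
                      _["sch_time"] = sch_time,
                      _["sch_g"] = sch_g);
}
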