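// R-facing wrappers around the GRN kinetics kernel (right-hand side and
// analytic Jacobians); the integrators live in grn_integrate.cpp.

#include <RcppArmadillo.h>
#include "grn_kernel.h"
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector grn_rhs_cpp(int G, IntegerVector tg, IntegerVector rg,
                          IntegerVector sg, NumericVector theta,
                          NumericVector dm, NumericVector basal,
                          NumericVector x) {
  GrnNet net{G, (int)tg.size(), (int)theta.size(),
             tg.begin(), rg.begin(), sg.begin()};
  NumericVector f(2 * G);
  grn_f(net, theta.begin(), dm.begin(), basal.begin(), x.begin(), f.begin());
  return f;
}

// [[Rcpp::export]]
List grn_jac_cpp(int G, IntegerVector tg, IntegerVector rg, IntegerVector sg,
                 NumericVector theta, NumericVector dm, NumericVector basal,
                 NumericVector x) {
  GrnNet net{G, (int)tg.size(), (int)theta.size(),
             tg.begin(), rg.begin(), sg.begin()};
  arma::mat J, F;
  grn_jac(net, theta.begin(), dm.begin(), x.begin(), J, &F);
  return List::create(_["jac_state"] = J, _["jac_theta"] = F);
}
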