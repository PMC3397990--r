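// Adaptive integrators for the GRN system with forward sensitivities:
//  method 0: Rosenbrock(2,3), L-stable (stiff; ode23s-type coefficients)
//  method 1: Dormand-Prince 5(4) explicit pair (fast on mildly stiff runs)
// Step-error control covers the states; sensitivity columns are excluded
// from the error norm by default (err_sens), as in CVODES' default.

#include <RcppArmadillo.h>
#include "grn_kernel.h"
using namespace Rcpp;

// [[Rcpp::export]]
List grn_integrate_cpp(int G, IntegerVector tg, IntegerVector rg,
                       IntegerVector sg, NumericVector theta,
                       NumericVector dm, NumericVector basal,
                       NumericVector x0, NumericVector times,
                       double rtol, double atol, bool sens,
                       double hmax, int maxsteps, int method,
                       bool err_sens) {
  const int n = 2 * G, I = tg.size(), P = theta.size();
  GrnNet net{G, I, P, tg.begin(), rg.begin(), sg.begin()};
  const double *th = theta.begin(), *dmv = dm.begin(), *bas = basal.begin();
  const int nt = times.size();
  const double ln10 = std::log(10.0);

  arma::mat states(n, nt, arma::fill::zeros);
  arma::cube S_out;
  if (sens) S_out.zeros(n, P, nt);

  const int ncol = sens ? P + 1 : 1;
  const int nerr = err_sens ? ncol : 1;
  arma::mat X(n, ncol, arma::fill::zeros);
  X.col(0) = arma::vec(x0.begin(), n);

  arma::mat J(n, n), Fth;
  auto aug_rhs = [&](const arma::mat &Xc, arma::mat &out, arma::mat &Jout) {
    grn_f(net, th, dmv, bas, Xc.colptr(0), out.colptr(0));
    if (sens) {
      grn_jac(net, th, dmv, Xc.colptr(0), Jout, &Fth);
      out.cols(1, P) = Jout * Xc.cols(1, P);
      for (int k = 0; k < P; ++k)
        out.col(k + 1) += (ln10 * th[k]) * Fth.col(k);
    } else if (method == 0) {
      grn_jac(net, th, dmv, Xc.colptr(0), Jout, nullptr);
    }
  };

  double t = 0.0;
  int it = 0;
  while (it < nt && times[it] <= t + 1e-14) {
    states.col(it) = X.col(0);
    ++it;
  }
  bool ok = true;
  double tfail = NA_REAL;
  long nsteps = 0;

  auto errnorm_of = [&](const arma::mat &E, const arma::mat &X0,
                        const arma::mat &X1) {
    double en = 0.0;
    for (int c = 0; c < nerr; ++c)
      for (int i = 0; i < n; ++i) {
        const double sc = atol + rtol * std::max(std::abs(X0(i, c)),
                                                 std::abs(X1(i, c)));
        en = std::max(en, std::abs(E(i, c)) / sc);
      }
    return en;
  };

  if (it < nt) {
    const double tend = times[nt - 1];
    double h = std::min(hmax, (tend - t) * 1e-3);

    if (method == 0) {  // Rosenbrock(2,3)
      const double d = 1.0 / (2.0 + std::sqrt(2.0));
      const double e32 = 6.0 + std::sqrt(2.0);
      arma::mat f0(n, ncol), fmid(n, ncol), f2(n, ncol);
      arma::mat k1(n, ncol), k2(n, ncol), k3(n, ncol), Xmid(n, ncol),
          X1(n, ncol), W(n, n), Jmid(n, n), J1(n, n), E(n, ncol);
      aug_rhs(X, f0, J);
      while (t < tend) {
        if (++nsteps > maxsteps ||
            h < 16.0 * std::numeric_limits<double>::epsilon() *
                    std::max(std::abs(t), 1.0)) {
          ok = false; tfail = t; break;
        }
        const double hfull = h;
        bool hit_output = false;
        if (t + h >= times[it] - 1e-14) { h = times[it] - t; hit_output = true; }
        W = -(h * d) * J;
        W.diag() += 1.0;
        arma::mat LU_L, LU_U, LU_P;
        if (!arma::lu(LU_L, LU_U, LU_P, W)) { h = 0.5 * hfull; continue; }
        auto wsolve = [&](const arma::mat &B, arma::mat &out_) {
          out_ = arma::solve(arma::trimatu(LU_U),
                             arma::solve(arma::trimatl(LU_L), LU_P * B));
          return out_.is_finite();
        };
        if (!wsolve(f0, k1)) { h = 0.5 * hfull; continue; }
        Xmid = X + (0.5 * h) * k1;
        if (!Xmid.col(0).is_finite()) { h = 0.5 * hfull; continue; }
        aug_rhs(Xmid, fmid, Jmid);
        if (!wsolve(fmid - k1, k2)) { h = 0.5 * hfull; continue; }
        k2 += k1;
        X1 = X + h * k2;
        if (!X1.is_finite()) { h = 0.5 * hfull; continue; }
        aug_rhs(X1, f2, J1);
        if (!wsolve(f2 - e32 * (k2 - fmid) - 2.0 * (k1 - f0), k3)) {
          h = 0.5 * hfull; continue;
        }
        E = (h / 6.0) * (k1 - 2.0 * k2 + k3);
        const double en = errnorm_of(E, X, X1);
        if (std::isfinite(en) && en <= 1.0) {
          t += h; X = X1; f0 = f2; J = J1;
          if (hit_output) {
            while (it < nt && times[it] <= t + 1e-12) {
              states.col(it) = X.col(0);
              if (sens) S_out.slice(it) = X.cols(1, P);
              ++it;
            }
          }
          double hnew = h * std::min(5.0, std::max(0.2,
              0.8 * std::pow(std::max(en, 1e-10), -1.0 / 3.0)));
          if (hit_output) hnew = std::max(hnew, hfull);
          h = std::min(hmax, hnew);
        } else if (!std::isfinite(en)) {
          h = 0.5 * hfull;
        } else {
          h = h * std::max(0.2, 0.8 * std::pow(en, -1.0 / 3.0));
        }
      }
    } else {  // Dormand-Prince 5(4)
      static const double
        a21 = 1.0 / 5,
        a31 = 3.0 / 40, a32 = 9.0 / 40,
        a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9,
        a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
        a54 = -212.0 / 729,
        a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
        a64 = 49.0 / 176, a65 = -5103.0 / 18656,
        b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
        b5 = -2187.0 / 6784, b6 = 11.0 / 84,
        e1 = b1 - 5179.0 / 57600, e3 = b3 - 7571.0 / 16695,
        e4 = b4 - 393.0 / 640, e5 = b5 + 92097.0 / 339200,
        e6 = b6 - 187.0 / 2100, e7 = -1.0 / 40;
      arma::mat k1(n, ncol), k2(n, ncol), k3(n, ncol), k4(n, ncol),
          k5(n, ncol), k6(n, ncol), k7(n, ncol), Xs(n, ncol), X1(n, ncol),
          E(n, ncol), Jdummy;
      aug_rhs(X, k1, Jdummy);
      while (t < tend) {
        if (++nsteps > maxsteps ||
            h < 16.0 * std::numeric_limits<double>::epsilon() *
                    std::max(std::abs(t), 1.0)) {
          ok = false; tfail = t; break;
        }
        const double hfull = h;
        bool hit_output = false;
        if (t + h >= times[it] - 1e-14) { h = times[it] - t; hit_output = true; }
        Xs = X + h * (a21 * k1);
        aug_rhs(Xs, k2, Jdummy);
        Xs = X + h * (a31 * k1 + a32 * k2);
        aug_rhs(Xs, k3, Jdummy);
        Xs = X + h * (a41 * k1 + a42 * k2 + a43 * k3);
        aug_rhs(Xs, k4, Jdummy);
        Xs = X + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4);
        aug_rhs(Xs, k5, Jdummy);
        Xs = X + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5);
        aug_rhs(Xs, k6, Jdummy);
        X1 = X + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
        if (!X1.is_finite()) { h = 0.25 * hfull; continue; }
        aug_rhs(X1, k7, Jdummy);
        E = h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);
        const double en = errnorm_of(E, X, X1);
        if (std::isfinite(en) && en <= 1.0) {
          t += h; X = X1; k1 = k7;  // FSAL
          if (hit_output) {
            while (it < nt && times[it] <= t + 1e-12) {
              states.col(it) = X.col(0);
              if (sens) S_out.slice(it) = X.cols(1, P);
              ++it;
            }
          }
          double hnew = h * std::min(10.0, std::max(0.2,
              0.9 * std::pow(std::max(en, 1e-12), -1.0 / 5.0)));
          if (hit_output) hnew = std::max(hnew, hfull);
          h = std::min(hmax, hnew);
        } else if (!std::isfinite(en)) {
          h = 0.25 * hfull;
        } else {
          h = h * std::max(0.1, 0.9 * std::pow(en, -1.0 / 5.0));
        }
      }
    }
  }

  List out = List::create(
      _["times"] = times, _["states"] = states, _["success"] = ok,
      _["t_fail"] = tfail, _["n_steps"] = (double)nsteps);
  if (sens) out["sens"] = S_out;
  return out;
}
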