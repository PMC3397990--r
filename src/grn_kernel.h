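// Shared GRN kinetics kernel: Hill regulation terms, the ODE right-hand
// side, and analytic state/parameter Jacobians.
//
// State layout: x = (mRNA_1..mRNA_G, protein_1..protein_G).
// Parameter layout (linear scale): pro_1..pro_G, rbs_1..rbs_G, delta_p,
// then (h_j, Kd_j) per interaction. mRNA degradation rates dm and basal
// transcription rates are carried separately (fixed, not estimated).
#ifndef GRN_KERNEL_H
#define GRN_KERNEL_H

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

struct GrnNet {
  int G, I, P;
  const int *tg, *rg, *sg;  // 0-based target gene, regulator gene, sign
};

// Hill term and derivatives at regulator level x >= 0.
// activation: H = u/(1+u), repression: H = 1/(1+u), u = (x/Kd)^h
inline void hill_terms(double x, double h, double Kd, int sign,
                       double &H, double &dH_dx, double &dH_dh,
                       double &dH_dKd) {
  if (x < 0.0) x = 0.0;
  if (x == 0.0) {
    if (sign > 0) {
      H = 0.0;
      dH_dx = (h == 1.0) ? 1.0 / Kd : 0.0;  // h > 1: zero slope at origin
    } else {
      H = 1.0;
      dH_dx = (h == 1.0) ? -1.0 / Kd : 0.0;
    }
    dH_dh = 0.0; dH_dKd = 0.0;
    return;
  }
  const double r = x / Kd;
  const double lr = std::log(r);
  double u = std::exp(std::min(h * lr, 700.0));  // overflow guard
  const double denom = 1.0 + u;
  const double w = u / (denom * denom);
  if (sign > 0) {
    H = u / denom;
    dH_dx = h * w / x;
    dH_dh = lr * w;
    dH_dKd = -h * w / Kd;
  } else {
    H = 1.0 / denom;
    dH_dx = -h * w / x;
    dH_dh = -lr * w;
    dH_dKd = h * w / Kd;
  }
}

// f(x): dm_g/dt = basal_g + pro_g * hsum_g - dm_g * m_g  (hsum = 1 if
// unregulated); dp_g/dt = rbs_g * m_g - delta_p * p_g
inline void grn_f(const GrnNet &net, const double *th, const double *dm,
                  const double *basal, const double *x, double *f) {
  const int G = net.G;
  const double *pro = th, *rbs = th + G;
  const double dp = th[2 * G];
  std::vector<double> hsum(G, -1.0);  // -1 marks "no regulator seen"
  for (int j = 0; j < net.I; ++j) {
    const int g = net.tg[j];
    double H, d1, d2, d3;
    hill_terms(x[G + net.rg[j]], th[2 * G + 1 + 2 * j],
               th[2 * G + 2 + 2 * j], net.sg[j], H, d1, d2, d3);
    if (hsum[g] < 0.0) hsum[g] = 0.0;
    hsum[g] += H;
  }
  for (int g = 0; g < G; ++g) {
    const double hs = (hsum[g] < 0.0) ? 1.0 : hsum[g];
    f[g] = basal[g] + pro[g] * hs - dm[g] * x[g];
    f[G + g] = rbs[g] * x[g] - dp * x[G + g];
  }
}

// State Jacobian J = df/dx (2G x 2G) and optionally the linear-scale
// parameter Jacobian F = df/dtheta (2G x P).
inline void grn_jac(const GrnNet &net, const double *th, const double *dm,
                    const double *x, arma::mat &J, arma::mat *F) {
  const int G = net.G, n = 2 * G;
  const double *pro = th, *rbs = th + G;
  const double dp = th[2 * G];
  J.zeros(n, n);
  if (F) F->zeros(n, net.P);
  std::vector<double> hsum(G, -1.0);
  for (int j = 0; j < net.I; ++j) {
    const int g = net.tg[j], r = net.rg[j];
    double H, dHx, dHh, dHK;
    hill_terms(x[G + r], th[2 * G + 1 + 2 * j], th[2 * G + 2 + 2 * j],
               net.sg[j], H, dHx, dHh, dHK);
    if (hsum[g] < 0.0) hsum[g] = 0.0;
    hsum[g] += H;
    J(g, G + r) += pro[g] * dHx;
    if (F) {
      (*F)(g, 2 * G + 1 + 2 * j) = pro[g] * dHh;
      (*F)(g, 2 * G + 2 + 2 * j) = pro[g] * dHK;
    }
  }
  for (int g = 0; g < G; ++g) {
    J(g, g) -= dm[g];
    J(G + g, g) = rbs[g];
    J(G + g, G + g) = -dp;
    if (F) {
      (*F)(g, g) = (hsum[g] < 0.0) ? 1.0 : hsum[g];  // d/dpro_g
      (*F)(G + g, G + g) = x[g];                     // d/drbs_g
      (*F)(G + g, 2 * G) = -x[G + g];                // d/ddelta_p
    }
  }
}

#endif
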