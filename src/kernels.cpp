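// Compiled pair-interaction kernels: 12-6 Lennard-Jones + Coulomb over
// the exclusion-filtered pair list, and the generalized-Born term
// (Hawkins-Cramer-Truhlar pairwise descreening) over all atom pairs,
// both with analytic gradients. Pure bookkeeping lives in R; only these
// O(n^2) loops are compiled.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".nb_kernel")]]
List nb_kernel(NumericMatrix X, IntegerVector ii, IntegerVector jj,
               NumericVector sig, NumericVector eps, NumericVector qq,
               LogicalVector is14, double s14lj, double s14el,
               double cutoff, bool do_lj, bool do_el) {
  const int m = ii.size(), n = X.nrow();
  NumericMatrix G(n, 3);
  double elj = 0.0, eel = 0.0;
  int bad = -1;
  for (int p = 0; p < m; ++p) {
    const int a = ii[p] - 1, b = jj[p] - 1;
    const double dx = X(a, 0) - X(b, 0);
    const double dy = X(a, 1) - X(b, 1);
    const double dz = X(a, 2) - X(b, 2);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1e-12) { bad = p; break; }
    const double r = std::sqrt(r2);
    if (cutoff > 0 && r > cutoff) continue;
    double dEdr = 0.0;
    if (do_lj) {
      const double sc = is14[p] ? s14lj : 1.0;
      const double sr2 = sig[p] * sig[p] / r2;
      const double s6 = sr2 * sr2 * sr2;
      elj += 4.0 * eps[p] * (s6 * s6 - s6) * sc;
      dEdr += 4.0 * eps[p] * (-12.0 * s6 * s6 + 6.0 * s6) / r * sc;
    }
    if (do_el) {
      const double sc = is14[p] ? s14el : 1.0;
      const double q = qq[p] * sc;
      eel += q / r;
      dEdr += -q / r2;
    }
    const double w = dEdr / r;
    G(a, 0) += w * dx; G(a, 1) += w * dy; G(a, 2) += w * dz;
    G(b, 0) -= w * dx; G(b, 1) -= w * dy; G(b, 2) -= w * dz;
  }
  return List::create(_["lj"] = elj, _["elec"] = eel, _["gradient"] = G,
                      _["bad"] = bad + 1);
}

// HCT descreening integral H(r; ri, sj) and dH/dr
static inline void hct_term(double ri, double sj, double r,
                            double &H, double &dH) {
  if (ri >= r + sj) { H = 0.0; dH = 0.0; return; }
  const double U = r + sj;
  const double d = r - sj;
  const double ad = std::fabs(d);
  const double L = (ad > ri) ? ad : ri;
  const double iU = 1.0 / U, iL = 1.0 / L, ir = 1.0 / r;
  const double iU2 = iU * iU, iL2 = iL * iL;
  const double lg = std::log(L * iU);
  const double s2 = sj * sj;
  H = iL - iU + 0.25 * r * (iU2 - iL2) + 0.5 * ir * lg +
      0.25 * s2 * ir * (iL2 - iU2);
  const double dLdr = (ad > ri) ? ((d > 0) ? 1.0 : -1.0) : 0.0;
  const double dHdU = iU2 - 0.5 * r * iU2 * iU - 0.5 * ir * iU +
                      0.5 * s2 * ir * iU2 * iU;
  const double dHdL = -iL2 + 0.5 * r * iL2 * iL + 0.5 * ir * iL -
                      0.5 * s2 * ir * iL2 * iL;
  const double dHdr = 0.25 * (iU2 - iL2) - 0.5 * ir * ir * lg -
                      0.25 * s2 * ir * ir * (iL2 - iU2);
  dH = dHdr + dHdU + dHdL * dLdr;
}

// [[Rcpp::export(name = ".gb_kernel")]]
List gb_kernel(NumericMatrix X, IntegerVector ii, IntegerVector jj,
               NumericVector rho, NumericVector scr, NumericVector q,
               double fac, double rmax) {
  const int m = ii.size(), n = X.nrow();
  std::vector<double> sumH(n, 0.0);
  std::vector<double> dHij(m), dHji(m), rr(m);
  for (int p = 0; p < m; ++p) {
    const int a = ii[p] - 1, b = jj[p] - 1;
    const double dx = X(a, 0) - X(b, 0);
    const double dy = X(a, 1) - X(b, 1);
    const double dz = X(a, 2) - X(b, 2);
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    rr[p] = r;
    double H, dH;
    hct_term(rho[a], scr[b] * rho[b], r, H, dH);
    sumH[a] += H; dHij[p] = dH;
    hct_term(rho[b], scr[a] * rho[a], r, H, dH);
    sumH[b] += H; dHji[p] = dH;
  }
  std::vector<double> R(n);
  std::vector<bool> clamped(n);
  double energy = 0.0;
  std::vector<double> dEdR(n);
  for (int k = 0; k < n; ++k) {
    double invR = 1.0 / rho[k] - 0.5 * sumH[k];
    clamped[k] = invR <= 1.0 / rmax;
    if (clamped[k]) invR = 1.0 / rmax;
    R[k] = 1.0 / invR;
    energy += fac * q[k] * q[k] / R[k];
    dEdR[k] = -fac * q[k] * q[k] / (R[k] * R[k]);
  }
  // pair pass 1: energy and dE/dR accumulation
  std::vector<double> dEdf(m), dfdr(m);
  for (int p = 0; p < m; ++p) {
    const int a = ii[p] - 1, b = jj[p] - 1;
    const double r = rr[p], r2 = r * r;
    const double RR = R[a] * R[b];
    const double ex = std::exp(-r2 / (4.0 * RR));
    const double f = std::sqrt(r2 + RR * ex);
    const double qab = q[a] * q[b];
    energy += 2.0 * fac * qab / f;
    const double dedf = -2.0 * fac * qab / (f * f);
    dEdf[p] = dedf;
    dfdr[p] = r * (1.0 - 0.25 * ex) / f;
    dEdR[a] += dedf * ex * (R[b] + r2 / (4.0 * R[a])) / (2.0 * f);
    dEdR[b] += dedf * ex * (R[a] + r2 / (4.0 * R[b])) / (2.0 * f);
  }
  // pair pass 2: chain rule through the Born radii
  NumericMatrix G(n, 3);
  for (int p = 0; p < m; ++p) {
    const int a = ii[p] - 1, b = jj[p] - 1;
    const double r = rr[p];
    double dEdr = dEdf[p] * dfdr[p];
    if (!clamped[a]) dEdr += dEdR[a] * 0.5 * R[a] * R[a] * dHij[p];
    if (!clamped[b]) dEdr += dEdR[b] * 0.5 * R[b] * R[b] * dHji[p];
    const double w = dEdr / r;
    const double dx = X(a, 0) - X(b, 0);
    const double dy = X(a, 1) - X(b, 1);
    const double dz = X(a, 2) - X(b, 2);
    G(a, 0) += w * dx; G(a, 1) += w * dy; G(a, 2) += w * dz;
    G(b, 0) -= w * dx; G(b, 1) -= w * dy; G(b, 2) -= w * dz;
  }
  return List::create(_["energy"] = energy, _["gradient"] = G);
}

// [[Rcpp::export(name = ".bonded_kernel")]]
List bonded_kernel(NumericMatrix X,
                   IntegerMatrix bonds, NumericVector bk, NumericVector br0,
                   IntegerMatrix angles, NumericVector ak, NumericVector at0,
                   IntegerMatrix tors, NumericVector tk, IntegerVector tn,
                   NumericVector tg) {
  const int n = X.nrow();
  NumericMatrix G(n, 3);
  double e_bond = 0.0, e_angle = 0.0, e_tor = 0.0;
  for (int p = 0; p < bonds.nrow(); ++p) {
    const int a = bonds(p, 0) - 1, b = bonds(p, 1) - 1;
    double d[3];
    for (int c = 0; c < 3; ++c) d[c] = X(a, c) - X(b, c);
    const double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    const double dev = r - br0[p];
    e_bond += bk[p] * dev * dev;
    const double w = 2.0 * bk[p] * dev / r;
    for (int c = 0; c < 3; ++c) { G(a, c) += w * d[c]; G(b, c) -= w * d[c]; }
  }
  for (int p = 0; p < angles.nrow(); ++p) {
    const int i = angles(p, 0) - 1, j = angles(p, 1) - 1,
              k = angles(p, 2) - 1;
    double u[3], v[3];
    for (int c = 0; c < 3; ++c) { u[c] = X(i, c) - X(j, c);
                                  v[c] = X(k, c) - X(j, c); }
    const double nu = std::sqrt(u[0]*u[0]+u[1]*u[1]+u[2]*u[2]);
    const double nv = std::sqrt(v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
    double cth = (u[0]*v[0]+u[1]*v[1]+u[2]*v[2]) / (nu * nv);
    if (cth > 1.0) cth = 1.0; if (cth < -1.0) cth = -1.0;
    double sth = std::sqrt(1.0 - cth * cth);
    if (sth < 1e-10) sth = 1e-10;
    const double theta = std::acos(cth);
    const double dev = theta - at0[p];
    e_angle += ak[p] * dev * dev;
    const double w = 2.0 * ak[p] * dev;
    for (int c = 0; c < 3; ++c) {
      const double gi = (u[c] * (cth / nu) - v[c] / nv) / (nu * sth);
      const double gk = (v[c] * (cth / nv) - u[c] / nu) / (nv * sth);
      G(i, c) += w * gi;
      G(k, c) += w * gk;
      G(j, c) -= w * (gi + gk);
    }
  }
  for (int p = 0; p < tors.nrow(); ++p) {
    const int i = tors(p, 0) - 1, j = tors(p, 1) - 1,
              k = tors(p, 2) - 1, l = tors(p, 3) - 1;
    double b1[3], b2[3], b3[3];
    for (int c = 0; c < 3; ++c) {
      b1[c] = X(j, c) - X(i, c);
      b2[c] = X(k, c) - X(j, c);
      b3[c] = X(l, c) - X(k, c);
    }
    double n1[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                     b1[0]*b2[1]-b1[1]*b2[0] };
    double n2[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                     b2[0]*b3[1]-b2[1]*b3[0] };
    const double nb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    double cx[3] = { n1[1]*n2[2]-n1[2]*n2[1], n1[2]*n2[0]-n1[0]*n2[2],
                     n1[0]*n2[1]-n1[1]*n2[0] };
    const double y = (cx[0]*b2[0]+cx[1]*b2[1]+cx[2]*b2[2]) / nb2;
    const double x = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    const double phi = std::atan2(y, x);
    const double arg = tn[p] * phi - tg[p];
    e_tor += tk[p] * (1.0 + std::cos(arg));
    const double w = -tk[p] * tn[p] * std::sin(arg);
    double sq1 = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
    double sq2 = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
    if (sq1 < 1e-18) sq1 = 1e-18;
    if (sq2 < 1e-18) sq2 = 1e-18;
    const double c12 = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (nb2*nb2);
    const double c32 = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (nb2*nb2);
    for (int c = 0; c < 3; ++c) {
      const double gi = -n1[c] * (nb2 / sq1);
      const double gl = n2[c] * (nb2 / sq2);
      const double gj = -gi * (1.0 + c12) + gl * c32;
      const double gk = gi * c12 - gl * (1.0 + c32);
      G(i, c) += w * gi; G(j, c) += w * gj;
      G(k, c) += w * gk; G(l, c) += w * gl;
    }
  }
  return List::create(_["bond"] = e_bond, _["angle"] = e_angle,
                      _["torsion"] = e_tor, _["gradient"] = G);
}
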