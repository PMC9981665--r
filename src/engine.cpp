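#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// minimum-image component for an orthorhombic box
static inline double mimg(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// Pairwise forces and energy for the toy bead forcefield:
// WCA repulsion (uniform epsilon/sigma) plus screened Coulomb
// U_c = kC * qi * qj * exp(-r/lambda) / r, truncated at `cutoff` and
// (optionally) shifted so the pair energy is zero at the cutoff.
// lambda <= 0 means unscreened (plain 1/r); cutoff <= 0 means no cutoff.
// [[Rcpp::export]]
List pair_forces_cpp(NumericMatrix pos, NumericVector box,
                     NumericVector charges, double eps, double sigma,
                     double lambda, double cutoff, double kC, bool shift) {
  const int n = pos.nrow();
  NumericMatrix forces(n, 3);
  double e_wca = 0.0, e_coul = 0.0;
  const double rw = sigma * std::pow(2.0, 1.0 / 6.0);
  const double rw2 = rw * rw;
  const bool have_cut = cutoff > 0.0;
  const double cut2 = have_cut ? cutoff * cutoff : 0.0;
  const bool screened = lambda > 0.0;
  double ushift = 0.0;  // shape factor at the cutoff, per unit kC*qi*qj
  if (shift && have_cut)
    ushift = (screened ? std::exp(-cutoff / lambda) : 1.0) / cutoff;
  const double Lx = box[0], Ly = box[1], Lz = box[2];

  for (int i = 0; i < n - 1; ++i) {
    const double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2);
    const double qi = charges[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = mimg(pos(j, 0) - xi, Lx);
      double dy = mimg(pos(j, 1) - yi, Ly);
      double dz = mimg(pos(j, 2) - zi, Lz);
      double r2 = dx * dx + dy * dy + dz * dz;
      double fod = 0.0;  // (dU/dr)/r, so force on j is -fod * rij
      bool touched = false;
      if (eps > 0.0 && r2 < rw2) {
        if (r2 < 1e-12)
          stop("coincident beads (pair %d, %d): r < 1e-6 A", i + 1, j + 1);
        double s2 = sigma * sigma / r2;
        double s6 = s2 * s2 * s2;
        double s12 = s6 * s6;
        e_wca += 4.0 * eps * (s12 - s6) + eps;
        fod += -24.0 * eps * (2.0 * s12 - s6) / r2;
        touched = true;
      }
      const double qq = qi * charges[j];
      if (qq != 0.0 && (!have_cut || r2 < cut2)) {
        double r = std::sqrt(r2);
        if (r < 1e-6)
          stop("coincident beads (pair %d, %d): r < 1e-6 A", i + 1, j + 1);
        double pref = kC * qq;
        double ex = screened ? std::exp(-r / lambda) : 1.0;
        e_coul += pref * (ex / r - ushift);
        double dudr = -pref * ex / r2 - (screened ? pref * ex / (lambda * r) : 0.0);
        fod += dudr / r;
        touched = true;
      }
      if (touched) {
        // force on j along +rij is -dU/dr * rij/r  =>  Fj = -fod * rij
        double fx = -fod * dx, fy = -fod * dy, fz = -fod * dz;
        forces(j, 0) += fx; forces(j, 1) += fy; forces(j, 2) += fz;
        forces(i, 0) -= fx; forces(i, 1) -= fy; forces(i, 2) -= fz;
      }
    }
  }
  return List::create(_["forces"] = forces, _["e_wca"] = e_wca,
                      _["e_coulomb"] = e_coul);
}

// All (i, j) pairs between two point sets with minimum-image distance
// strictly below rmax. Returns a 3-column matrix (i, j, dist), 1-based.
// [[Rcpp::export]]
NumericMatrix cross_pairs_cpp(NumericMatrix a, NumericMatrix b,
                              NumericVector box, double rmax) {
  const int na = a.nrow(), nb = b.nrow();
  const double r2max = rmax * rmax;
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  std::vector<double> out;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double dx = mimg(b(j, 0) - a(i, 0), Lx);
      double dy = mimg(b(j, 1) - a(i, 1), Ly);
      double dz = mimg(b(j, 2) - a(i, 2), Lz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < r2max) {
        out.push_back(i + 1); out.push_back(j + 1);
        out.push_back(std::sqrt(r2));
      }
    }
  }
  const int m = out.size() / 3;
  NumericMatrix res(m, 3);
  for (int k = 0; k < m; ++k) {
    res(k, 0) = out[3 * k]; res(k, 1) = out[3 * k + 1];
    res(k, 2) = out[3 * k + 2];
  }
  return res;
}

// All unordered pairs (i < j) within one point set with minimum-image
// distance strictly below rmax. Returns (i, j, dist), 1-based.
// [[Rcpp::export]]
NumericMatrix self_pairs_cpp(NumericMatrix a, NumericVector box,
                             double rmax) {
  const int n = a.nrow();
  const double r2max = rmax * rmax;
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  std::vector<double> out;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = mimg(a(j, 0) - a(i, 0), Lx);
      double dy = mimg(a(j, 1) - a(i, 1), Ly);
      double dz = mimg(a(j, 2) - a(i, 2), Lz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < r2max) {
        out.push_back(i + 1); out.push_back(j + 1);
        out.push_back(std::sqrt(r2));
      }
    }
  }
  const int m = out.size() / 3;
  NumericMatrix res(m, 3);
  for (int k = 0; k < m; ++k) {
    res(k, 0) = out[3 * k]; res(k, 1) = out[3 * k + 1];
    res(k, 2) = out[3 * k + 2];
  }
  return res;
}
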