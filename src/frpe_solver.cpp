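// Axisymmetric displacement/pore-pressure finite elements for the
// fibril-reinforced poroelastic material, total-Lagrangian finite
// deformation, backward-Euler time stepping, monolithic Newton with
// numerically differentiated element tangents, banded LAPACK solve.
//
// Units are SI throughout (m, s, Pa, N, m^4/(N s)).
//
// Element: 4-node bilinear quad, equal-order u/p, with a
// Bochev-Dohrmann-type pressure-projection stabilisation controlled by
// mat[7] (0 disables it).
//
// Nodal dof ordering: [u_r, u_z, p] per node, nodes in mesh order.

#include <Rcpp.h>
#define USE_FC_LEN_T
#include <Rconfig.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Material {
  double Ef0, Efeps, Enf, k0, M, nu, e0, stab;
  double K, G;  // derived bulk/shear moduli of the non-fibrillar matrix
};

// Gauss points (2x2) and bilinear shape data on the reference square.
const double GP = 0.577350269189625764509148780502;
const double gp_xi[4]  = {-GP,  GP,  GP, -GP};
const double gp_eta[4] = {-GP, -GP,  GP,  GP};
const double nd_xi[4]  = {-1.0,  1.0, 1.0, -1.0};
const double nd_eta[4] = {-1.0, -1.0, 1.0,  1.0};

// Element residual. xc, zc: reference node coords; x: local dofs (12),
// xn: previous-step dofs; fib: n_fib x 4 rows (n_r, n_z, n_theta, weight).
// Returns false if an element inverts (J <= 0).
bool elementResidual(const double* xc, const double* zc,
                     const double* x, const double* xn,
                     double dt, const Material& mat,
                     const double* fib, int nfib,
                     double* res) {
  for (int i = 0; i < 12; ++i) res[i] = 0.0;

  // Per-Gauss-point storage for the stabilisation pass.
  double w_gp[4], p_gp[4], pn_gp[4], N_gp[4][4];

  for (int g = 0; g < 4; ++g) {
    double xi = gp_xi[g], eta = gp_eta[g];
    double N[4], dNxi[4], dNeta[4];
    for (int a = 0; a < 4; ++a) {
      N[a]    = 0.25 * (1.0 + xi * nd_xi[a]) * (1.0 + eta * nd_eta[a]);
      dNxi[a] = 0.25 * nd_xi[a] * (1.0 + eta * nd_eta[a]);
      dNeta[a]= 0.25 * nd_eta[a] * (1.0 + xi * nd_xi[a]);
    }
    double j11 = 0, j12 = 0, j21 = 0, j22 = 0, r = 0;
    for (int a = 0; a < 4; ++a) {
      j11 += dNxi[a] * xc[a];  j12 += dNxi[a] * zc[a];
      j21 += dNeta[a] * xc[a]; j22 += dNeta[a] * zc[a];
      r   += N[a] * xc[a];
    }
    double detJm = j11 * j22 - j12 * j21;
    if (detJm <= 0.0 || r <= 0.0) return false;
    double dNr[4], dNz[4];
    for (int a = 0; a < 4; ++a) {
      dNr[a] = ( j22 * dNxi[a] - j12 * dNeta[a]) / detJm;
      dNz[a] = (-j21 * dNxi[a] + j11 * dNeta[a]) / detJm;
    }
    double w = 2.0 * M_PI * r * detJm;  // unit Gauss weights

    // Field values and gradients (current and previous step).
    double ur = 0, durr = 0, durz = 0, duzr = 0, duzz = 0, p = 0, pr = 0, pz = 0;
    double urn = 0, durrn = 0, durzn = 0, duzrn = 0, duzzn = 0, pn = 0;
    for (int a = 0; a < 4; ++a) {
      double u1 = x[3 * a], u2 = x[3 * a + 1], pp = x[3 * a + 2];
      ur += N[a] * u1;
      durr += dNr[a] * u1; durz += dNz[a] * u1;
      duzr += dNr[a] * u2; duzz += dNz[a] * u2;
      p += N[a] * pp; pr += dNr[a] * pp; pz += dNz[a] * pp;
      double v1 = xn[3 * a], v2 = xn[3 * a + 1];
      urn += N[a] * v1;
      durrn += dNr[a] * v1; durzn += dNz[a] * v1;
      duzrn += dNr[a] * v2; duzzn += dNz[a] * v2;
      pn += N[a] * xn[3 * a + 2];
    }

    double Frr = 1.0 + durr, Frz = durz, Fzr = duzr, Fzz = 1.0 + duzz;
    double Ftt = 1.0 + ur / r;
    double detF2 = Frr * Fzz - Frz * Fzr;
    double J = detF2 * Ftt;
    if (J <= 0.0 || detF2 <= 0.0 || Ftt <= 0.0) return false;

    double Fttn = 1.0 + urn / r;
    double Jn = ((1.0 + durrn) * (1.0 + duzzn) - durzn * duzrn) * Fttn;

    // Neo-Hookean non-fibrillar Cauchy stress.
    double Brr = Frr * Frr + Frz * Frz;
    double Brz = Frr * Fzr + Frz * Fzz;
    double Bzz = Fzr * Fzr + Fzz * Fzz;
    double Btt = Ftt * Ftt;
    double J23 = std::pow(J, 2.0 / 3.0);
    double c1 = 0.5 * mat.K * (J - 1.0) / J;
    double c2 = mat.G / J;
    double srr = c1 + c2 * (Brr - J23);
    double srz =      c2 * Brz;
    double szz = c1 + c2 * (Bzz - J23);
    double stt = c1 + c2 * (Btt - J23);

    // Tension-only fibril network: convected directions, logarithmic fibre
    // strain, rank-one Cauchy contributions. In-plane/hoop shear components
    // cancel over the symmetric direction set and are not tracked.
    for (int f = 0; f < nfib; ++f) {
      double nr = fib[4 * f], nz = fib[4 * f + 1], nt = fib[4 * f + 2];
      double wt = fib[4 * f + 3];
      double vr = Frr * nr + Frz * nz;
      double vz = Fzr * nr + Fzz * nz;
      double vt = Ftt * nt;
      double lam2 = vr * vr + vz * vz + vt * vt;
      double eps = 0.5 * std::log(lam2);
      if (eps > 0.0) {
        double s = (0.5 * mat.Efeps * eps + mat.Ef0) * eps;
        double fac = wt * s / lam2;
        srr += fac * vr * vr;
        srz += fac * vr * vz;
        szz += fac * vz * vz;
        stt += fac * vt * vt;
      }
    }

    // Total stress (effective minus pore pressure).
    srr -= p; szz -= p; stt -= p;

    // First Piola-Kirchhoff P = J sigma F^{-T}.
    double iT11 =  Fzz / detF2, iT12 = -Fzr / detF2;
    double iT21 = -Frz / detF2, iT22 =  Frr / detF2;
    double Prr = J * (srr * iT11 + srz * iT21);
    double Prz = J * (srr * iT12 + srz * iT22);
    double Pzr = J * (srz * iT11 + szz * iT21);
    double Pzz = J * (srz * iT12 + szz * iT22);
    double Ptt = J * stt / Ftt;

    // Darcy flux pulled back to the reference configuration:
    // q0 = -k J C^{-1} grad0 p, with k = k0 J^M (void-ratio power law,
    // (1+e)/(1+e0) = J for incompressible constituents).
    double k_sp = mat.k0 * std::pow(J, mat.M);
    double Crr = Frr * Frr + Fzr * Fzr;
    double Crz = Frr * Frz + Fzr * Fzz;
    double Czz = Frz * Frz + Fzz * Fzz;
    double detC2 = detF2 * detF2;
    double kJ = k_sp * J / detC2;
    double Kxx =  kJ * Czz, Kxz = -kJ * Crz, Kzz = kJ * Crr;
    double qr = Kxx * pr + Kxz * pz;
    double qz = Kxz * pr + Kzz * pz;

    for (int a = 0; a < 4; ++a) {
      res[3 * a]     += w * (Prr * dNr[a] + Prz * dNz[a] + Ptt * N[a] / r);
      res[3 * a + 1] += w * (Pzr * dNr[a] + Pzz * dNz[a]);
      res[3 * a + 2] += w * (N[a] * (J - Jn) / dt + dNr[a] * qr + dNz[a] * qz);
    }

    w_gp[g] = w; p_gp[g] = p; pn_gp[g] = pn;
    for (int a = 0; a < 4; ++a) N_gp[g][a] = N[a];
  }

  // Pressure-projection stabilisation (equal-order u/p).
  if (mat.stab > 0.0) {
    double vol = 0, pbar = 0, pnbar = 0, Nbar[4] = {0, 0, 0, 0};
    for (int g = 0; g < 4; ++g) {
      vol += w_gp[g];
      pbar += w_gp[g] * p_gp[g];
      pnbar += w_gp[g] * pn_gp[g];
      for (int a = 0; a < 4; ++a) Nbar[a] += w_gp[g] * N_gp[g][a];
    }
    pbar /= vol; pnbar /= vol;
    for (int a = 0; a < 4; ++a) Nbar[a] /= vol;
    double cst = mat.stab / ((mat.K + 4.0 * mat.G / 3.0) * dt);
    for (int g = 0; g < 4; ++g) {
      double dp = (p_gp[g] - pbar) - (pn_gp[g] - pnbar);
      for (int a = 0; a < 4; ++a)
        res[3 * a + 2] += cst * w_gp[g] * dp * (N_gp[g][a] - Nbar[a]);
    }
  }
  return true;
}

}  // namespace

// Internal residual of the assembled system (momentum + mass balance) at
// state U given previous state Un. Returns the full residual vector, or
// NaNs if any element inverts.
// [[Rcpp::export]]
NumericVector cpp_frpe_residual(NumericMatrix coords, IntegerMatrix conn,
                                NumericVector U, NumericVector Un,
                                double dt, NumericVector matv,
                                NumericMatrix fibdirs) {
  int nn = coords.nrow(), ne = conn.nrow();
  Material mat = {matv[0], matv[1], matv[2], matv[3], matv[4], matv[5],
                  matv[6], matv[7], 0, 0};
  mat.K = mat.Enf / (3.0 * (1.0 - 2.0 * mat.nu));
  mat.G = mat.Enf / (2.0 * (1.0 + mat.nu));
  int nfib = fibdirs.nrow();
  std::vector<double> fib(fibdirs.begin(), fibdirs.end());
  // column-major to row-major
  std::vector<double> fibr(4 * nfib);
  for (int f = 0; f < nfib; ++f)
    for (int c = 0; c < 4; ++c) fibr[4 * f + c] = fibdirs(f, c);

  NumericVector R(3 * nn);
  double xc[4], zc[4], xl[12], xnl[12], res[12];
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 4; ++a) {
      int nd = conn(e, a) - 1;
      xc[a] = coords(nd, 0); zc[a] = coords(nd, 1);
      for (int c = 0; c < 3; ++c) {
        xl[3 * a + c] = U[3 * nd + c];
        xnl[3 * a + c] = Un[3 * nd + c];
      }
    }
    if (!elementResidual(xc, zc, xl, xnl, dt, mat, fibr.data(), nfib, res)) {
      std::fill(R.begin(), R.end(), NA_REAL);
      return R;
    }
    for (int a = 0; a < 4; ++a) {
      int nd = conn(e, a) - 1;
      for (int c = 0; c < 3; ++c) R[3 * nd + c] += res[3 * a + c];
    }
  }
  return R;
}

// One backward-Euler step of the coupled system, Newton iterations with
// central-difference element tangents and a banded LU solve (dgbsv).
// dirIdx: 1-based dof indices with prescribed values dirVal.
// Returns list(U, residual, converged, iters, err).
// [[Rcpp::export]]
List cpp_frpe_step(NumericMatrix coords, IntegerMatrix conn,
                   NumericVector U0, NumericVector Un,
                   double dt, NumericVector matv, NumericMatrix fibdirs,
                   IntegerVector dirIdx, NumericVector dirVal,
                   NumericVector fext, List control) {
  int nn = coords.nrow(), ne = conn.nrow(), n = 3 * nn;
  Material mat = {matv[0], matv[1], matv[2], matv[3], matv[4], matv[5],
                  matv[6], matv[7], 0, 0};
  mat.K = mat.Enf / (3.0 * (1.0 - 2.0 * mat.nu));
  mat.G = mat.Enf / (2.0 * (1.0 + mat.nu));
  int nfib = fibdirs.nrow();
  std::vector<double> fibr(4 * nfib);
  for (int f = 0; f < nfib; ++f)
    for (int c = 0; c < 4; ++c) fibr[4 * f + c] = fibdirs(f, c);

  int maxIter = as<int>(control["max_iter"]);
  double tolRel = as<double>(control["tol_rel"]);
  double absU = as<double>(control["abs_u"]);
  double absP = as<double>(control["abs_p"]);
  double hU = as<double>(control["h_u"]);
  double hP = as<double>(control["h_p"]);

  std::vector<double> U(U0.begin(), U0.end());
  std::vector<char> isDir(n, 0);
  for (int i = 0; i < dirIdx.size(); ++i) {
    int d = dirIdx[i] - 1;
    isDir[d] = 1;
    U[d] = dirVal[i];
  }

  // Half bandwidth from connectivity.
  int kd = 0;
  for (int e = 0; e < ne; ++e) {
    int lo = conn(e, 0), hi = conn(e, 0);
    for (int a = 1; a < 4; ++a) {
      if (conn(e, a) < lo) lo = conn(e, a);
      if (conn(e, a) > hi) hi = conn(e, a);
    }
    int b = 3 * (hi - lo) + 2;
    if (b > kd) kd = b;
  }
  int kl = kd, ku = kd, ldab = 2 * kl + ku + 1;
  std::vector<double> AB((size_t)ldab * n);
  std::vector<double> R(n), rhs(n);
  std::vector<int> ipiv(n);
  double xc[4], zc[4], xl[12], xnl[12], res[12], resp[12], resm[12];
  std::vector<double> Ke(12 * 12);

  auto assembleR = [&](std::vector<double>& Rout) -> bool {
    std::fill(Rout.begin(), Rout.end(), 0.0);
    for (int e = 0; e < ne; ++e) {
      for (int a = 0; a < 4; ++a) {
        int nd = conn(e, a) - 1;
        xc[a] = coords(nd, 0); zc[a] = coords(nd, 1);
        for (int c = 0; c < 3; ++c) {
          xl[3 * a + c] = U[3 * nd + c];
          xnl[3 * a + c] = Un[3 * nd + c];
        }
      }
      if (!elementResidual(xc, zc, xl, xnl, dt, mat, fibr.data(), nfib, res))
        return false;
      for (int a = 0; a < 4; ++a) {
        int nd = conn(e, a) - 1;
        for (int c = 0; c < 3; ++c) Rout[3 * nd + c] += res[3 * a + c];
      }
    }
    return true;
  };

  // Assemble the banded tangent (central differences on element residuals),
  // apply Dirichlet rows/columns, factorise with dgbtrf. Returns false on
  // element inversion or singular factorisation.
  auto assembleFactorise = [&]() -> bool {
    std::fill(AB.begin(), AB.end(), 0.0);
    for (int e = 0; e < ne; ++e) {
      int nds[4];
      for (int a = 0; a < 4; ++a) {
        int nd = conn(e, a) - 1;
        nds[a] = nd;
        xc[a] = coords(nd, 0); zc[a] = coords(nd, 1);
        for (int c = 0; c < 3; ++c) {
          xl[3 * a + c] = U[3 * nd + c];
          xnl[3 * a + c] = Un[3 * nd + c];
        }
      }
      for (int l = 0; l < 12; ++l) {
        double h = (l % 3 == 2) ? hP : hU;
        double sav = xl[l];
        xl[l] = sav + h;
        bool ok = elementResidual(xc, zc, xl, xnl, dt, mat, fibr.data(), nfib, resp);
        xl[l] = sav - h;
        ok = ok && elementResidual(xc, zc, xl, xnl, dt, mat, fibr.data(), nfib, resm);
        xl[l] = sav;
        if (!ok) return false;
        for (int i = 0; i < 12; ++i) Ke[12 * l + i] = (resp[i] - resm[i]) / (2 * h);
      }
      for (int l = 0; l < 12; ++l) {
        int gj = 3 * nds[l / 3] + l % 3;
        for (int i = 0; i < 12; ++i) {
          int gi = 3 * nds[i / 3] + i % 3;
          AB[(size_t)(kl + ku + gi - gj) + (size_t)ldab * gj] += Ke[12 * l + i];
        }
      }
    }
    for (int d = 0; d < n; ++d) {
      if (!isDir[d]) continue;
      for (int j = std::max(0, d - kd); j <= std::min(n - 1, d + kd); ++j)
        AB[(size_t)(kl + ku + d - j) + (size_t)ldab * j] = 0.0;
      for (int i = std::max(0, d - kd); i <= std::min(n - 1, d + kd); ++i)
        AB[(size_t)(kl + ku + i - d) + (size_t)ldab * d] = 0.0;
      AB[(size_t)(kl + ku) + (size_t)ldab * d] = 1.0;
    }
    int info = 0;
    F77_CALL(dgbtrf)(&n, &n, &kl, &ku, AB.data(), &ldab, ipiv.data(), &info);
    return info == 0;
  };

  bool converged = false;
  int iter = 0;
  double nu0 = -1, np0 = -1, prevNorm = R_PosInf;
  bool haveFactors = false;
  int staleUses = 0;
  std::string err = "";

  for (iter = 0; iter < maxIter; ++iter) {
    if (!assembleR(R)) { err = "element inversion"; break; }
    for (int i = 0; i < n; ++i) R[i] -= fext[i];

    double nu = 0, np = 0;
    for (int i = 0; i < n; ++i) {
      if (isDir[i]) continue;
      if (i % 3 == 2) np += R[i] * R[i]; else nu += R[i] * R[i];
    }
    nu = std::sqrt(nu); np = std::sqrt(np);
    if (nu0 < 0) { nu0 = nu; np0 = np; }
    if (nu <= std::max(tolRel * nu0, absU) &&
        np <= std::max(tolRel * np0, absP)) {
      converged = true;
      break;
    }

    // Modified Newton: reuse the factorised tangent while the residual
    // keeps contracting well; refresh otherwise (and periodically).
    double norm = nu / std::max(nu0, 1e-300) + np / std::max(np0, 1e-300);
    bool refresh = !haveFactors || staleUses >= 6 || norm > 0.4 * prevNorm;
    if (refresh) {
      if (!assembleFactorise()) { err = "element inversion or singular tangent"; break; }
      haveFactors = true;
      staleUses = 0;
    } else {
      ++staleUses;
    }
    prevNorm = norm;

    for (int i = 0; i < n; ++i) rhs[i] = isDir[i] ? 0.0 : -R[i];
    int nrhs = 1, info = 0;
    F77_CALL(dgbtrs)("N", &n, &kl, &ku, &nrhs, AB.data(), &ldab, ipiv.data(),
                     rhs.data(), &n, &info FCONE);
    if (info != 0) { err = "banded solve failed"; break; }
    for (int i = 0; i < n; ++i) U[i] += rhs[i];
  }
  if (!converged && err.empty()) err = "Newton did not converge";

  // Final internal residual (reactions at constrained dofs).
  std::vector<double> Rint(n, NA_REAL);
  assembleR(Rint);

  return List::create(_["U"] = NumericVector(U.begin(), U.end()),
                      _["residual"] = NumericVector(Rint.begin(), Rint.end()),
                      _["converged"] = converged,
                      _["iters"] = iter,
                      _["err"] = err);
}

// Integral of J over the reference domain (current volume) and the
// reference volume, for mass-conservation checks.
// [[Rcpp::export]]
NumericVector cpp_volume_integrals(NumericMatrix coords, IntegerMatrix conn,
                                   NumericVector U) {
  int ne = conn.nrow();
  double vcur = 0, vref = 0;
  for (int e = 0; e < ne; ++e) {
    double xc[4], zc[4], xl[12];
    for (int a = 0; a < 4; ++a) {
      int nd = conn(e, a) - 1;
      xc[a] = coords(nd, 0); zc[a] = coords(nd, 1);
      for (int c = 0; c < 3; ++c) xl[3 * a + c] = U[3 * nd + c];
    }
    for (int g = 0; g < 4; ++g) {
      double xi = gp_xi[g], eta = gp_eta[g];
      double N[4], dNxi[4], dNeta[4];
      for (int a = 0; a < 4; ++a) {
        N[a]    = 0.25 * (1.0 + xi * nd_xi[a]) * (1.0 + eta * nd_eta[a]);
        dNxi[a] = 0.25 * nd_xi[a] * (1.0 + eta * nd_eta[a]);
        dNeta[a]= 0.25 * nd_eta[a] * (1.0 + xi * nd_xi[a]);
      }
      double j11 = 0, j12 = 0, j21 = 0, j22 = 0, r = 0;
      for (int a = 0; a < 4; ++a) {
        j11 += dNxi[a] * xc[a];  j12 += dNxi[a] * zc[a];
        j21 += dNeta[a] * xc[a]; j22 += dNeta[a] * zc[a];
        r   += N[a] * xc[a];
      }
      double detJm = j11 * j22 - j12 * j21;
      double ur = 0, durr = 0, durz = 0, duzr = 0, duzz = 0;
      for (int a = 0; a < 4; ++a) {
        ur += N[a] * xl[3 * a];
        durr += ((j22 * dNxi[a] - j12 * dNeta[a]) / detJm) * xl[3 * a];
        durz += ((-j21 * dNxi[a] + j11 * dNeta[a]) / detJm) * xl[3 * a];
        duzr += ((j22 * dNxi[a] - j12 * dNeta[a]) / detJm) * xl[3 * a + 1];
        duzz += ((-j21 * dNxi[a] + j11 * dNeta[a]) / detJm) * xl[3 * a + 1];
      }
      double J = ((1 + durr) * (1 + duzz) - durz * duzr) * (1 + ur / r);
      double w = 2.0 * M_PI * r * detJm;
      vcur += w * J;
      vref += w;
    }
  }
  return NumericVector::create(_["current"] = vcur, _["reference"] = vref);
}

// Minimum reference-element Jacobian over all Gauss points (mesh validity).
// [[Rcpp::export]]
double cpp_min_jacobian(NumericMatrix coords, IntegerMatrix conn) {
  int ne = conn.nrow();
  double mn = R_PosInf;
  for (int e = 0; e < ne; ++e) {
    double xc[4], zc[4];
    for (int a = 0; a < 4; ++a) {
      int nd = conn(e, a) - 1;
      xc[a] = coords(nd, 0); zc[a] = coords(nd, 1);
    }
    for (int g = 0; g < 4; ++g) {
      double xi = gp_xi[g], eta = gp_eta[g];
      double dNxi[4], dNeta[4];
      for (int a = 0; a < 4; ++a) {
        dNxi[a] = 0.25 * nd_xi[a] * (1.0 + eta * nd_eta[a]);
        dNeta[a]= 0.25 * nd_eta[a] * (1.0 + xi * nd_xi[a]);
      }
      double j11 = 0, j12 = 0, j21 = 0, j22 = 0;
      for (int a = 0; a < 4; ++a) {
        j11 += dNxi[a] * xc[a];  j12 += dNxi[a] * zc[a];
        j21 += dNeta[a] * xc[a]; j22 += dNeta[a] * zc[a];
      }
      double d = j11 * j22 - j12 * j21;
      if (d < mn) mn = d;
    }
  }
  return mn;
}
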