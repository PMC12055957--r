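// D3Q19 lattice-Boltzmann engine with immersed-boundary coupling for
// compound viscoelastic capsules.
//
// - BGK collision with Guo forcing; local relaxation time from a truncated
//   power-law viscosity evaluated at the local shear rate (reconstructed
//   from non-equilibrium moments).
// - Bouzidi linear interpolated bounce-back on curved walls (reduces to
//   mid-link bounce-back at q = 1/2); optional moving plane walls via the
//   momentum-corrected mid-link rule (used for Couette benchmarks).
// - Pressure (density) boundaries by the non-equilibrium extrapolation rule.
// - Immersed boundary: 4-point Peskin kernel for force spreading and
//   velocity interpolation (exact partition of unity and first moment).
// - Front-tracking indicator per capsule from a Poisson solve
//   laplace(I) = div(G), G the spread outward surface-normal field,
//   warm-started SOR; carries the cytoplasm / nucleus viscosity contrast.

#include <Rcpp.h>
#include "capsule_core.h"
#include <cmath>
#include <cstring>
#include <stdexcept>

using namespace Rcpp;

namespace {

const int NQ = 19;
const int CX[NQ] = {0, 1, -1, 0, 0, 0, 0, 1, -1, 1, -1, 1, -1, 1, -1, 0, 0, 0, 0};
const int CY[NQ] = {0, 0, 0, 1, -1, 0, 0, 1, -1, -1, 1, 0, 0, 0, 0, 1, -1, 1, -1};
const int CZ[NQ] = {0, 0, 0, 0, 0, 1, -1, 0, 0, 0, 0, 1, -1, -1, 1, 1, -1, -1, 1};
const int OPP[NQ] = {0, 2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12, 11, 14, 13, 16, 15, 18, 17};
const double WQ[NQ] = {1.0 / 3,
                       1.0 / 18, 1.0 / 18, 1.0 / 18, 1.0 / 18, 1.0 / 18, 1.0 / 18,
                       1.0 / 36, 1.0 / 36, 1.0 / 36, 1.0 / 36, 1.0 / 36, 1.0 / 36,
                       1.0 / 36, 1.0 / 36, 1.0 / 36, 1.0 / 36, 1.0 / 36, 1.0 / 36};

enum NodeFlag { SOLID = 0, FLUID = 1, MOVING_WALL = 255 };
// flags >= 2 and < 255: pressure plane id = flag - 2

// 4-point Peskin kernel (the piecewise square-root kernel; satisfies
// partition of unity and zero first moment exactly)
inline double phi4(double r) {
  double a = std::fabs(r);
  if (a < 1.0) return 0.125 * (3.0 - 2.0 * a + std::sqrt(1.0 + 4.0 * a - 4.0 * a * a));
  if (a < 2.0) return 0.125 * (5.0 - 2.0 * a - std::sqrt(-7.0 + 12.0 * a - 4.0 * a * a));
  return 0.0;
}

struct PressurePlane {
  int axis;     // 0,1,2
  int side;     // 0 = min face, 1 = max face
  double rho;   // target density (lattice)
};

struct Capsule {
  capsule::MeshTopo topo;
  std::vector<capsule::RefElem> ref;
  std::vector<double> X;     // lattice coords
  std::vector<double> Vel;   // lattice units per step
  std::vector<double> Vf;    // low-pass filtered velocities (viscous stress)
  double Gs, Cc, mus, musd, kc, c0;  // lattice units
  double lambda;             // interior viscosity ratio mu_int / mu0
  std::vector<double> fmem;  // total nodal force, lattice units
  std::vector<double> fbend; // cached bending forces
  std::vector<double> indicator;  // per lattice node
  double Eb;
};

struct Sim {
  int nx, ny, nz;
  size_t nc;
  // physical scales
  double dx, dt, rho0;
  // fluid
  double K, alpha, gamma0, gmin, gmax, mu0, tau_max;
  double wall_u[3];  // moving-wall velocity (lattice)
  double body_force[3];  // constant body force density (lattice)
  std::vector<unsigned char> flag;
  std::vector<float> qlink;
  std::vector<double> f, fpost;
  std::vector<double> rho, ux, uy, uz, tau;
  std::vector<double> fx, fy, fz;
  std::vector<double> gsr;  // local shear rate (lattice units)
  std::vector<PressurePlane> planes;
  std::vector<Capsule> caps;
  int bending_every, indicator_every, visc_every;
  double filter_beta;
  int sor_max, sor_min;
  double sor_tol, sor_omega;
  long step_count;
  bool newtonian;  // skip shear-rate viscosity update (fixed tau)
  double tau_fixed;
  bool periodic[3];

  inline size_t idx(int x, int y, int z) const {
    return (static_cast<size_t>(z) * ny + y) * nx + x;
  }
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
  // wrap coordinates on periodic axes; returns false if off-domain
  inline bool wrap(int& x, int& y, int& z) const {
    if (periodic[0]) x = (x + nx) % nx;
    if (periodic[1]) y = (y + ny) % ny;
    if (periodic[2]) z = (z + nz) % nz;
    return inside(x, y, z);
  }
};

inline double feq(int i, double rho, double ux, double uy, double uz) {
  double cu = CX[i] * ux + CY[i] * uy + CZ[i] * uz;
  double u2 = ux * ux + uy * uy + uz * uz;
  return WQ[i] * rho * (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * u2);
}

// physical truncated power-law viscosity (Pa s)
inline double mu_powerlaw(const Sim& S, double gd_phys) {
  double g = gd_phys;
  if (g < S.gmin) g = S.gmin;
  if (g > S.gmax) g = S.gmax;
  return S.K * std::pow(g / S.gamma0, S.alpha - 1.0);
}

void collide(Sim& S) {
  const double dt_dx2 = S.dt / (S.dx * S.dx);
  const size_t nc = S.nc;
  for (size_t n = 0; n < nc; ++n) {
    unsigned char fl = S.flag[n];
    if (fl == SOLID || fl == MOVING_WALL) continue;
    double* fn = &S.f[n * NQ];
    double r = 0, jx = 0, jy = 0, jz = 0;
    for (int i = 0; i < NQ; ++i) {
      r += fn[i];
      jx += fn[i] * CX[i];
      jy += fn[i] * CY[i];
      jz += fn[i] * CZ[i];
    }
    double Fx = S.fx[n] + S.body_force[0];
    double Fy = S.fy[n] + S.body_force[1];
    double Fz = S.fz[n] + S.body_force[2];
    double vx = (jx + 0.5 * Fx) / r;
    double vy = (jy + 0.5 * Fy) / r;
    double vz = (jz + 0.5 * Fz) / r;
    S.rho[n] = r;
    S.ux[n] = vx;
    S.uy[n] = vy;
    S.uz[n] = vz;
    double fe[NQ];
    for (int i = 0; i < NQ; ++i) fe[i] = feq(i, r, vx, vy, vz);
    double tau_n = S.tau[n];
    bool update_visc = !S.newtonian && (S.step_count % S.visc_every == 0);
    if (update_visc) {
      // strain rate from non-equilibrium moments (with forcing correction)
      double pxx = 0, pyy = 0, pzz = 0, pxy = 0, pxz = 0, pyz = 0;
      for (int i = 0; i < NQ; ++i) {
        double fneq = fn[i] - fe[i];
        pxx += fneq * CX[i] * CX[i];
        pyy += fneq * CY[i] * CY[i];
        pzz += fneq * CZ[i] * CZ[i];
        pxy += fneq * CX[i] * CY[i];
        pxz += fneq * CX[i] * CZ[i];
        pyz += fneq * CY[i] * CZ[i];
      }
      pxx += 0.5 * 2.0 * vx * Fx;
      pyy += 0.5 * 2.0 * vy * Fy;
      pzz += 0.5 * 2.0 * vz * Fz;
      pxy += 0.5 * (vx * Fy + vy * Fx);
      pxz += 0.5 * (vx * Fz + vz * Fx);
      pyz += 0.5 * (vy * Fz + vz * Fy);
      double coef = -1.5 / (tau_n * r);
      double sxx = coef * pxx, syy = coef * pyy, szz = coef * pzz;
      double sxy = coef * pxy, sxz = coef * pxz, syz = coef * pyz;
      double gd_lat = std::sqrt(2.0 * (sxx * sxx + syy * syy + szz * szz +
                                       2.0 * (sxy * sxy + sxz * sxz + syz * syz)));
      S.gsr[n] = gd_lat;
      double gd_phys = gd_lat / S.dt;
      double mu_ext = mu_powerlaw(S, gd_phys);
      double mu_phys = mu_ext;
      if (!S.caps.empty()) {
        double Iout = 1.0;
        double mu_in = 0.0;
        // capsule 0 = cell, capsule 1 = nucleus (nested)
        double I0 = S.caps[0].indicator.empty() ? 0.0 : S.caps[0].indicator[n];
        double I1 = (S.caps.size() > 1 && !S.caps[1].indicator.empty())
                        ? S.caps[1].indicator[n] : 0.0;
        if (I1 > I0) I1 = I0;
        Iout = 1.0 - I0;
        mu_in = S.caps[0].lambda * S.mu0 * (I0 - I1);
        if (S.caps.size() > 1) mu_in += S.caps[1].lambda * S.mu0 * I1;
        else mu_in += 0.0;
        mu_phys = mu_ext * Iout + mu_in;
      }
      double nu_lat = (mu_phys / S.rho0) * dt_dx2;
      tau_n = 3.0 * nu_lat + 0.5;
      if (tau_n > S.tau_max) tau_n = S.tau_max;
      if (tau_n < 0.505) tau_n = 0.505;
      S.tau[n] = tau_n;
    }
    double omega = 1.0 / tau_n;
    double* fp = &S.fpost[n * NQ];
    if (Fx == 0.0 && Fy == 0.0 && Fz == 0.0) {
      for (int i = 0; i < NQ; ++i)
        fp[i] = fn[i] - omega * (fn[i] - fe[i]);
    } else {
      double fcoef = 1.0 - 0.5 * omega;
      double uF = vx * Fx + vy * Fy + vz * Fz;
      for (int i = 0; i < NQ; ++i) {
        double cu = CX[i] * vx + CY[i] * vy + CZ[i] * vz;
        double cF = CX[i] * Fx + CY[i] * Fy + CZ[i] * Fz;
        double forcing = fcoef * WQ[i] * (3.0 * (cF - uF) + 9.0 * cu * cF);
        fp[i] = fn[i] - omega * (fn[i] - fe[i]) + forcing;
      }
    }
  }
}

void stream(Sim& S) {
  const int nx = S.nx, ny = S.ny, nz = S.nz;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t n = S.idx(x, y, z);
        unsigned char fl = S.flag[n];
        if (fl == SOLID || fl == MOVING_WALL) continue;
        const double* fp = &S.fpost[n * NQ];
        S.f[n * NQ] = fp[0];
        for (int i = 1; i < NQ; ++i) {
          int xm = x + CX[i], ym = y + CY[i], zm = z + CZ[i];
          bool open = S.wrap(xm, ym, zm);
          unsigned char flm = open ? S.flag[S.idx(xm, ym, zm)] : SOLID;
          if (open && flm != SOLID && flm != MOVING_WALL) {
            S.f[S.idx(xm, ym, zm) * NQ + i] = fp[i];
          } else {
            // wall link: bounce the population back into direction opp(i)
            int io = OPP[i];
            if (flm == MOVING_WALL) {
              double cu = CX[io] * S.wall_u[0] + CY[io] * S.wall_u[1] +
                          CZ[io] * S.wall_u[2];
              S.f[n * NQ + io] = fp[i] + 6.0 * WQ[i] * S.rho[n] * cu;
            } else {
              float qf = S.qlink[n * NQ + i];
              double q = (qf >= 0.0f) ? qf : 0.5;
              int xb = x - CX[i], yb = y - CY[i], zb = z - CZ[i];
              bool hb = S.wrap(xb, yb, zb) &&
                        S.flag[S.idx(xb, yb, zb)] != SOLID &&
                        S.flag[S.idx(xb, yb, zb)] != MOVING_WALL;
              if (q < 0.5 && hb) {
                const double* fb = &S.fpost[S.idx(xb, yb, zb) * NQ];
                S.f[n * NQ + io] = 2.0 * q * fp[i] + (1.0 - 2.0 * q) * fb[i];
              } else if (q >= 0.5) {
                S.f[n * NQ + io] =
                    fp[i] / (2.0 * q) + (1.0 - 1.0 / (2.0 * q)) * fp[io];
              } else {
                S.f[n * NQ + io] = fp[i];  // plain bounce-back fallback
              }
            }
          }
        }
      }
}

void apply_pressure_bc(Sim& S) {
  if (S.planes.empty()) return;
  const int nx = S.nx, ny = S.ny, nz = S.nz;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t n = S.idx(x, y, z);
        unsigned char fl = S.flag[n];
        if (fl < 2 || fl == MOVING_WALL) continue;
        const PressurePlane& P = S.planes[fl - 2];
        int xn = x, yn = y, zn = z;
        int dir = (P.side == 0) ? 1 : -1;
        if (P.axis == 0) xn += dir;
        else if (P.axis == 1) yn += dir;
        else zn += dir;
        if (!S.inside(xn, yn, zn)) continue;
        size_t m = S.idx(xn, yn, zn);
        if (S.flag[m] == SOLID) continue;
        const double* fm = &S.f[m * NQ];
        double r = 0, jx = 0, jy = 0, jz = 0;
        for (int i = 0; i < NQ; ++i) {
          r += fm[i];
          jx += fm[i] * CX[i];
          jy += fm[i] * CY[i];
          jz += fm[i] * CZ[i];
        }
        double vx = jx / r, vy = jy / r, vz = jz / r;
        double* fn = &S.f[n * NQ];
        for (int i = 0; i < NQ; ++i) {
          double fe_b = feq(i, P.rho, vx, vy, vz);
          double fe_n = feq(i, r, vx, vy, vz);
          fn[i] = fe_b + (fm[i] - fe_n);
        }
        S.rho[n] = P.rho;
        S.ux[n] = vx;
        S.uy[n] = vy;
        S.uz[n] = vz;
      }
}

// ---- immersed boundary ---------------------------------------------------

void spread_point(Sim& S, const double* xp, const double* fv) {
  int i0 = static_cast<int>(std::floor(xp[0] - 0.5)) - 1;
  int j0 = static_cast<int>(std::floor(xp[1] - 0.5)) - 1;
  int k0 = static_cast<int>(std::floor(xp[2] - 0.5)) - 1;
  for (int k = 0; k < 4; ++k) {
    int zr = k0 + k;
    double wz = phi4(xp[2] - (zr + 0.5));
    if (wz == 0.0) continue;
    int z = zr;
    if (S.periodic[2]) z = ((z % S.nz) + S.nz) % S.nz;
    else if (z < 0 || z >= S.nz) continue;
    for (int j = 0; j < 4; ++j) {
      int yr = j0 + j;
      double wy = phi4(xp[1] - (yr + 0.5));
      if (wy == 0.0) continue;
      int y = yr;
      if (S.periodic[1]) y = ((y % S.ny) + S.ny) % S.ny;
      else if (y < 0 || y >= S.ny) continue;
      double wyz = wy * wz;
      for (int i = 0; i < 4; ++i) {
        int xr = i0 + i;
        double w = phi4(xp[0] - (xr + 0.5)) * wyz;
        if (w == 0.0) continue;
        int x = xr;
        if (S.periodic[0]) x = ((x % S.nx) + S.nx) % S.nx;
        else if (x < 0 || x >= S.nx) continue;
        size_t n = S.idx(x, y, z);
        S.fx[n] += w * fv[0];
        S.fy[n] += w * fv[1];
        S.fz[n] += w * fv[2];
      }
    }
  }
}

void interp_point(const Sim& S, const double* xp, double* uv) {
  uv[0] = uv[1] = uv[2] = 0.0;
  int i0 = static_cast<int>(std::floor(xp[0] - 0.5)) - 1;
  int j0 = static_cast<int>(std::floor(xp[1] - 0.5)) - 1;
  int k0 = static_cast<int>(std::floor(xp[2] - 0.5)) - 1;
  for (int k = 0; k < 4; ++k) {
    int zr = k0 + k;
    double wz = phi4(xp[2] - (zr + 0.5));
    if (wz == 0.0) continue;
    int z = zr;
    if (S.periodic[2]) z = ((z % S.nz) + S.nz) % S.nz;
    else if (z < 0 || z >= S.nz) continue;
    for (int j = 0; j < 4; ++j) {
      int yr = j0 + j;
      double wy = phi4(xp[1] - (yr + 0.5));
      if (wy == 0.0) continue;
      int y = yr;
      if (S.periodic[1]) y = ((y % S.ny) + S.ny) % S.ny;
      else if (y < 0 || y >= S.ny) continue;
      double wyz = wy * wz;
      for (int i = 0; i < 4; ++i) {
        int xr = i0 + i;
        double w = phi4(xp[0] - (xr + 0.5)) * wyz;
        if (w == 0.0) continue;
        int x = xr;
        if (S.periodic[0]) x = ((x % S.nx) + S.nx) % S.nx;
        else if (x < 0 || x >= S.nx) continue;
        size_t n = S.idx(x, y, z);
        uv[0] += w * S.ux[n];
        uv[1] += w * S.uy[n];
        uv[2] += w * S.uz[n];
      }
    }
  }
}

// ---- front-tracking indicator -------------------------------------------

void update_indicator(Sim& S, Capsule& C, bool first) {
  const size_t nc = S.nc;
  if (C.indicator.empty()) {
    C.indicator.assign(nc, 0.0);
    first = true;
  }
  // bounding box of the capsule plus kernel + decay margin
  double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
  for (int v = 0; v < C.topo.nv; ++v)
    for (int d = 0; d < 3; ++d) {
      if (C.X[3 * v + d] < lo[d]) lo[d] = C.X[3 * v + d];
      if (C.X[3 * v + d] > hi[d]) hi[d] = C.X[3 * v + d];
    }
  int b0[3], b1[3];
  const int dims[3] = {S.nx, S.ny, S.nz};
  for (int d = 0; d < 3; ++d) {
    b0[d] = std::max(1, static_cast<int>(std::floor(lo[d] - 8.0)));
    b1[d] = std::min(dims[d] - 2, static_cast<int>(std::ceil(hi[d] + 8.0)));
    if (first) {
      b0[d] = 1;
      b1[d] = dims[d] - 2;
    }
  }
  std::vector<double> Gx(nc, 0.0), Gy(nc, 0.0), Gz(nc, 0.0);
  // spread outward normal * area from element centroids
  std::vector<double> sx(nc, 0.0);
  for (int t = 0; t < C.topo.nf; ++t) {
    const int* T = &C.topo.tri[3 * t];
    const double* a = &C.X[3 * T[0]];
    const double* b = &C.X[3 * T[1]];
    const double* c = &C.X[3 * T[2]];
    double cen[3] = {(a[0] + b[0] + c[0]) / 3.0, (a[1] + b[1] + c[1]) / 3.0,
                     (a[2] + b[2] + c[2]) / 3.0};
    double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
    double nA[3] = {0.5 * (e1[1] * e2[2] - e1[2] * e2[1]),
                    0.5 * (e1[2] * e2[0] - e1[0] * e2[2]),
                    0.5 * (e1[0] * e2[1] - e1[1] * e2[0])};
    // spread nA with the IB kernel
    int i0 = static_cast<int>(std::floor(cen[0] - 0.5)) - 1;
    int j0 = static_cast<int>(std::floor(cen[1] - 0.5)) - 1;
    int k0 = static_cast<int>(std::floor(cen[2] - 0.5)) - 1;
    for (int k = 0; k < 4; ++k) {
      int zr = k0 + k;
      double wz = phi4(cen[2] - (zr + 0.5));
      if (wz == 0.0) continue;
      int z = zr;
      if (S.periodic[2]) z = ((z % S.nz) + S.nz) % S.nz;
      else if (z < 0 || z >= S.nz) continue;
      for (int j = 0; j < 4; ++j) {
        int yr = j0 + j;
        double wy = phi4(cen[1] - (yr + 0.5));
        if (wy == 0.0) continue;
        int y = yr;
        if (S.periodic[1]) y = ((y % S.ny) + S.ny) % S.ny;
        else if (y < 0 || y >= S.ny) continue;
        double wyz = wy * wz;
        for (int i = 0; i < 4; ++i) {
          int xr = i0 + i;
          double w = phi4(cen[0] - (xr + 0.5)) * wyz;
          if (w == 0.0) continue;
          int x = xr;
          if (S.periodic[0]) x = ((x % S.nx) + S.nx) % S.nx;
          else if (x < 0 || x >= S.nx) continue;
          size_t n = S.idx(x, y, z);
          Gx[n] += w * nA[0];
          Gy[n] += w * nA[1];
          Gz[n] += w * nA[2];
        }
      }
    }
  }
  // rhs = div G (central differences, zero outside)
  std::vector<double> rhs(nc, 0.0);
  const int nx = S.nx, ny = S.ny, nz = S.nz;
  double rhs_norm = 0.0;
  for (int z = b0[2]; z <= b1[2]; ++z)
    for (int y = b0[1]; y <= b1[1]; ++y)
      for (int x = b0[0]; x <= b1[0]; ++x) {
        size_t n = S.idx(x, y, z);
        double d = 0.0;
        d += 0.5 * ((x + 1 < nx ? Gx[S.idx(x + 1, y, z)] : 0.0) -
                    (x - 1 >= 0 ? Gx[S.idx(x - 1, y, z)] : 0.0));
        d += 0.5 * ((y + 1 < ny ? Gy[S.idx(x, y + 1, z)] : 0.0) -
                    (y - 1 >= 0 ? Gy[S.idx(x, y - 1, z)] : 0.0));
        d += 0.5 * ((z + 1 < nz ? Gz[S.idx(x, y, z + 1)] : 0.0) -
                    (z - 1 >= 0 ? Gz[S.idx(x, y, z - 1)] : 0.0));
        rhs[n] = -d;  // I falls from 1 to 0 outward: grad I = -n delta
        rhs_norm += d * d;
      }
  rhs_norm = std::sqrt(rhs_norm);
  if (rhs_norm == 0.0) {
    std::fill(C.indicator.begin(), C.indicator.end(), 0.0);
    return;
  }
  // SOR over the local box, warm started from the previous indicator;
  // the box boundary keeps its previous (far-field) values, zero initially.
  std::vector<double>& I = C.indicator;
  int itmax = first ? S.sor_max : S.sor_min;
  double om = S.sor_omega;
  double tol = S.sor_tol * rhs_norm;
  for (int it = 0; it < itmax; ++it) {
    double res2 = 0.0;
    for (int rb = 0; rb < 2; ++rb)
      for (int z = b0[2]; z <= b1[2]; ++z)
        for (int y = b0[1]; y <= b1[1]; ++y)
          for (int x = b0[0]; x <= b1[0]; ++x) {
            if (((x + y + z) & 1) != rb) continue;
            size_t n = S.idx(x, y, z);
            double nb = I[S.idx(x + 1, y, z)] + I[S.idx(x - 1, y, z)] +
                        I[S.idx(x, y + 1, z)] + I[S.idx(x, y - 1, z)] +
                        I[S.idx(x, y, z + 1)] + I[S.idx(x, y, z - 1)];
            double r = (nb - rhs[n]) / 6.0 - I[n];
            I[n] += om * r;
            res2 += r * r;
          }
    if (it >= 2 && std::sqrt(res2) < tol) break;
  }
  for (size_t n = 0; n < nc; ++n) {
    if (I[n] < 0.0) I[n] = 0.0;
    if (I[n] > 1.0) I[n] = 1.0;
  }
}

void membrane_forces_caps(Sim& S) {
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  std::fill(S.fz.begin(), S.fz.end(), 0.0);
  for (size_t k = 0; k < S.caps.size(); ++k) {
    Capsule& C = S.caps[k];
    std::vector<double> fel, fv;
    capsule::elastic_forces(C.X, C.topo, C.ref, C.Gs, C.Cc, fel, NULL, NULL,
                            NULL, NULL);
    if (C.mus > 0.0 || C.musd > 0.0)
      capsule::viscous_forces(C.X, C.Vf, C.topo, C.mus, C.musd, fv, NULL,
                              NULL, NULL);
    if (C.kc > 0.0 &&
        (S.step_count % S.bending_every == 0 || C.fbend.empty()))
      C.Eb = capsule::bending_forces(C.X, C.topo, C.kc, C.c0, C.fbend);
    C.fmem.assign(3 * C.topo.nv, 0.0);
    for (int v = 0; v < C.topo.nv; ++v)
      for (int d = 0; d < 3; ++d) {
        double val = fel[3 * v + d];
        if (!fv.empty()) val += fv[3 * v + d];
        if (!C.fbend.empty()) val += C.fbend[3 * v + d];
        C.fmem[3 * v + d] = val;
      }
    for (int v = 0; v < C.topo.nv; ++v)
      spread_point(S, &C.X[3 * v], &C.fmem[3 * v]);
  }
}

void advect_caps(Sim& S) {
  for (size_t k = 0; k < S.caps.size(); ++k) {
    Capsule& C = S.caps[k];
    bool init = (S.step_count == 0);
    for (int v = 0; v < C.topo.nv; ++v) {
      double uv[3];
      interp_point(S, &C.X[3 * v], uv);
      for (int d = 0; d < 3; ++d) {
        C.Vel[3 * v + d] = uv[d];
        if (init) C.Vf[3 * v + d] = uv[d];
        else C.Vf[3 * v + d] += S.filter_beta * (uv[d] - C.Vf[3 * v + d]);
        C.X[3 * v + d] += uv[d];
      }
    }
  }
}

void sim_step_once(Sim& S) {
  if (!S.caps.empty()) {
    if (S.step_count % S.indicator_every == 0)
      for (size_t k = 0; k < S.caps.size(); ++k)
        update_indicator(S, S.caps[k], S.caps[k].indicator.empty());
    membrane_forces_caps(S);
  }
  collide(S);
  stream(S);
  apply_pressure_bc(S);
  if (!S.caps.empty()) advect_caps(S);
  S.step_count++;
}

Sim* get_sim(SEXP ptr) {
  Rcpp::XPtr<Sim> p(ptr);
  return p.get();
}

}  // namespace

// [[Rcpp::export]]
SEXP sim_create(IntegerVector dims, IntegerVector flag, NumericVector qlink,
                NumericMatrix planes, List phys, List control) {
  Sim* S = new Sim();
  S->nx = dims[0];
  S->ny = dims[1];
  S->nz = dims[2];
  S->nc = static_cast<size_t>(S->nx) * S->ny * S->nz;
  if (static_cast<size_t>(flag.size()) != S->nc)
    stop("flag length mismatch");
  S->dx = as<double>(phys["dx"]);
  S->dt = as<double>(phys["dt"]);
  S->rho0 = as<double>(phys["rho"]);
  S->K = as<double>(phys["K"]);
  S->alpha = as<double>(phys["alpha"]);
  S->gamma0 = as<double>(phys["gamma0"]);
  S->gmin = as<double>(phys["gamma_min"]);
  S->gmax = as<double>(phys["gamma_max"]);
  S->mu0 = as<double>(phys["mu0"]);
  S->tau_max = as<double>(control["tau_max"]);
  S->newtonian = as<bool>(control["newtonian"]);
  S->tau_fixed = as<double>(control["tau_fixed"]);
  S->bending_every = as<int>(control["bending_every"]);
  S->indicator_every = as<int>(control["indicator_every"]);
  S->visc_every = as<int>(control["visc_every"]);
  S->filter_beta = 1.0;
  S->sor_max = as<int>(control["sor_max"]);
  S->sor_min = as<int>(control["sor_min"]);
  S->sor_tol = as<double>(control["sor_tol"]);
  S->sor_omega = as<double>(control["sor_omega"]);
  NumericVector wu = control["wall_u"];
  for (int d = 0; d < 3; ++d) S->wall_u[d] = wu[d];
  LogicalVector per = control["periodic"];
  for (int d = 0; d < 3; ++d) S->periodic[d] = per[d];
  S->body_force[0] = S->body_force[1] = S->body_force[2] = 0.0;
  S->flag.resize(S->nc);
  for (size_t n = 0; n < S->nc; ++n)
    S->flag[n] = static_cast<unsigned char>(flag[n]);
  S->qlink.assign(S->nc * NQ, -1.0f);
  if (qlink.size() == static_cast<R_xlen_t>(S->nc * NQ))
    for (size_t n = 0; n < S->nc * NQ; ++n)
      S->qlink[n] = static_cast<float>(qlink[n]);
  S->planes.resize(planes.nrow());
  for (int p = 0; p < planes.nrow(); ++p) {
    S->planes[p].axis = static_cast<int>(planes(p, 0));
    S->planes[p].side = static_cast<int>(planes(p, 1));
    S->planes[p].rho = planes(p, 2);
  }
  S->f.assign(S->nc * NQ, 0.0);
  S->fpost.assign(S->nc * NQ, 0.0);
  S->rho.assign(S->nc, 1.0);
  S->ux.assign(S->nc, 0.0);
  S->uy.assign(S->nc, 0.0);
  S->uz.assign(S->nc, 0.0);
  double tau0 = S->newtonian
                    ? S->tau_fixed
                    : 3.0 * (S->mu0 / S->rho0) * S->dt / (S->dx * S->dx) + 0.5;
  S->tau.assign(S->nc, tau0);
  S->fx.assign(S->nc, 0.0);
  S->fy.assign(S->nc, 0.0);
  S->fz.assign(S->nc, 0.0);
  S->gsr.assign(S->nc, 0.0);
  for (size_t n = 0; n < S->nc; ++n)
    for (int i = 0; i < NQ; ++i) S->f[n * NQ + i] = feq(i, 1.0, 0, 0, 0);
  S->step_count = 0;
  Rcpp::XPtr<Sim> ptr(S, true);
  return ptr;
}

// [[Rcpp::export]]
List sim_get_state(SEXP ptr) {
  Sim* S = get_sim(ptr);
  return List::create(_["f"] = NumericVector(S->f.begin(), S->f.end()),
                      _["tau"] = NumericVector(S->tau.begin(), S->tau.end()),
                      _["step"] = static_cast<double>(S->step_count));
}

// [[Rcpp::export]]
void sim_set_state(SEXP ptr, List state) {
  Sim* S = get_sim(ptr);
  NumericVector f = state["f"], tau = state["tau"];
  if (static_cast<size_t>(f.size()) != S->f.size() ||
      static_cast<size_t>(tau.size()) != S->tau.size())
    stop("state size mismatch");
  std::copy(f.begin(), f.end(), S->f.begin());
  std::copy(tau.begin(), tau.end(), S->tau.begin());
  // refresh macroscopic fields
  for (size_t n = 0; n < S->nc; ++n) {
    if (S->flag[n] == SOLID || S->flag[n] == MOVING_WALL) continue;
    const double* fn = &S->f[n * NQ];
    double r = 0, jx = 0, jy = 0, jz = 0;
    for (int i = 0; i < NQ; ++i) {
      r += fn[i];
      jx += fn[i] * CX[i];
      jy += fn[i] * CY[i];
      jz += fn[i] * CZ[i];
    }
    S->rho[n] = r;
    S->ux[n] = jx / r;
    S->uy[n] = jy / r;
    S->uz[n] = jz / r;
  }
}

// [[Rcpp::export]]
void sim_set_uniform_velocity(SEXP ptr, NumericVector u_lat) {
  Sim* S = get_sim(ptr);
  for (size_t n = 0; n < S->nc; ++n) {
    for (int i = 0; i < NQ; ++i)
      S->f[n * NQ + i] = feq(i, 1.0, u_lat[0], u_lat[1], u_lat[2]);
    S->ux[n] = u_lat[0];
    S->uy[n] = u_lat[1];
    S->uz[n] = u_lat[2];
  }
}

// [[Rcpp::export]]
void sim_set_filter_beta(SEXP ptr, double beta) {
  Sim* S = get_sim(ptr);
  if (beta <= 0.0 || beta > 1.0) stop("beta must be in (0, 1]");
  S->filter_beta = beta;
}

// [[Rcpp::export]]
void sim_set_body_force(SEXP ptr, NumericVector g) {
  Sim* S = get_sim(ptr);
  for (int d = 0; d < 3; ++d) S->body_force[d] = g[d];
}

// [[Rcpp::export]]
void sim_set_plane_rho(SEXP ptr, int plane, double rho) {
  Sim* S = get_sim(ptr);
  if (plane < 1 || plane > static_cast<int>(S->planes.size()))
    stop("invalid plane index");
  S->planes[plane - 1].rho = rho;
}

// [[Rcpp::export]]
void sim_add_capsule(SEXP ptr, NumericMatrix X, IntegerMatrix Tri, double Gs,
                     double C, double mus, double musd, double kc, double c0,
                     double lambda) {
  Sim* S = get_sim(ptr);
  Capsule cap;
  int nv = X.nrow();
  std::vector<int> tri(Tri.nrow() * 3);
  for (int t = 0; t < Tri.nrow(); ++t)
    for (int d = 0; d < 3; ++d) tri[3 * t + d] = Tri(t, d) - 1;
  capsule::build_topo(tri, nv, cap.topo);
  cap.X.resize(3 * nv);
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) cap.X[3 * v + d] = X(v, d) / S->dx;
  capsule::build_ref_elems(cap.X, cap.topo, cap.ref);
  cap.Vel.assign(3 * nv, 0.0);
  cap.Vf.assign(3 * nv, 0.0);
  // convert moduli to lattice units
  double fdt = S->dt, fdx = S->dx, r0 = S->rho0;
  cap.Gs = Gs * fdt * fdt / (r0 * fdx * fdx * fdx);
  cap.Cc = C;
  cap.mus = mus * fdt / (r0 * fdx * fdx * fdx);
  cap.musd = musd * fdt / (r0 * fdx * fdx * fdx);
  cap.kc = kc * fdt * fdt / (r0 * fdx * fdx * fdx * fdx * fdx);
  cap.c0 = c0 * fdx;
  cap.lambda = lambda;
  cap.Eb = 0.0;
  S->caps.push_back(cap);
}

// [[Rcpp::export]]
void sim_run(SEXP ptr, int nsteps) {
  Sim* S = get_sim(ptr);
  for (int s = 0; s < nsteps; ++s) {
    sim_step_once(*S);
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
  }
}

// [[Rcpp::export]]
List sim_macroscopic(SEXP ptr) {
  Sim* S = get_sim(ptr);
  size_t nc = S->nc;
  NumericVector rho(nc), ux(nc), uy(nc), uz(nc), tau(nc), gsr(nc);
  double conv_u = S->dx / S->dt;
  for (size_t n = 0; n < nc; ++n) {
    rho[n] = S->rho[n];
    ux[n] = S->ux[n] * conv_u;
    uy[n] = S->uy[n] * conv_u;
    uz[n] = S->uz[n] * conv_u;
    tau[n] = S->tau[n];
    gsr[n] = S->gsr[n] / S->dt;
  }
  IntegerVector dim = IntegerVector::create(S->nx, S->ny, S->nz);
  rho.attr("dim") = dim;
  ux.attr("dim") = dim;
  uy.attr("dim") = dim;
  uz.attr("dim") = dim;
  tau.attr("dim") = dim;
  gsr.attr("dim") = dim;
  return List::create(_["rho"] = rho, _["ux"] = ux, _["uy"] = uy,
                      _["uz"] = uz, _["tau"] = tau, _["shear_rate"] = gsr,
                      _["step"] = static_cast<double>(S->step_count));
}

// [[Rcpp::export]]
double sim_mass(SEXP ptr) {
  Sim* S = get_sim(ptr);
  double m = 0.0;
  for (size_t n = 0; n < S->nc; ++n)
    if (S->flag[n] != SOLID && S->flag[n] != MOVING_WALL) {
      const double* fn = &S->f[n * NQ];
      for (int i = 0; i < NQ; ++i) m += fn[i];
    }
  return m;
}

// [[Rcpp::export]]
double sim_flow_rate(SEXP ptr, int axis, int index) {
  // physical volumetric flow rate through the lattice slab [index] (1-based)
  Sim* S = get_sim(ptr);
  double qsum = 0.0;
  int nx = S->nx, ny = S->ny, nz = S->nz;
  int i0 = index - 1;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if ((axis == 0 && x != i0) || (axis == 1 && y != i0) ||
            (axis == 2 && z != i0))
          continue;
        size_t n = S->idx(x, y, z);
        if (S->flag[n] == SOLID || S->flag[n] == MOVING_WALL) continue;
        qsum += (axis == 0) ? S->ux[n] : (axis == 1 ? S->uy[n] : S->uz[n]);
      }
  return qsum * S->dx * S->dx * (S->dx / S->dt);
}

// [[Rcpp::export]]
List sim_capsule_state(SEXP ptr, int k) {
  Sim* S = get_sim(ptr);
  if (k < 1 || k > static_cast<int>(S->caps.size())) stop("no such capsule");
  Capsule& C = S->caps[k - 1];
  int nv = C.topo.nv;
  NumericMatrix X(nv, 3), Vel(nv, 3), Fm(nv, 3);
  double cu = S->dx / S->dt;
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) {
      X(v, d) = C.X[3 * v + d] * S->dx;
      Vel(v, d) = C.Vel[3 * v + d] * cu;
      Fm(v, d) = C.fmem.empty() ? 0.0 : C.fmem[3 * v + d];
    }
  double area, vol;
  capsule::mesh_measures(C.X, C.topo, area, vol, NULL, NULL, NULL);
  return List::create(_["vertices"] = X, _["velocities"] = Vel,
                      _["forces_lattice"] = Fm,
                      _["area"] = area * S->dx * S->dx,
                      _["volume"] = vol * S->dx * S->dx * S->dx);
}

// [[Rcpp::export]]
NumericVector sim_indicator(SEXP ptr, int k) {
  Sim* S = get_sim(ptr);
  if (k < 1 || k > static_cast<int>(S->caps.size())) stop("no such capsule");
  Capsule& C = S->caps[k - 1];
  if (C.indicator.empty())
    update_indicator(*S, C, true);
  NumericVector I(C.indicator.begin(), C.indicator.end());
  I.attr("dim") = IntegerVector::create(S->nx, S->ny, S->nz);
  return I;
}

// [[Rcpp::export]]
void sim_refresh_indicator(SEXP ptr) {
  Sim* S = get_sim(ptr);
  for (size_t k = 0; k < S->caps.size(); ++k)
    update_indicator(*S, S->caps[k], S->caps[k].indicator.empty());
}

// ---- standalone IB kernel operations (module surface + tests) ------------

// [[Rcpp::export]]
NumericVector cpp_ib_kernel(NumericVector r) {
  NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i) out[i] = phi4(r[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ib_spread(NumericMatrix pos, NumericMatrix forces,
                            IntegerVector dims) {
  // positions in lattice coordinates (node p at (i+0.5)); returns force
  // density array dims[0] x dims[1] x dims[2] x 3
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nc = static_cast<size_t>(nx) * ny * nz;
  NumericVector out(nc * 3);
  for (int p = 0; p < pos.nrow(); ++p) {
    double xp[3] = {pos(p, 0), pos(p, 1), pos(p, 2)};
    int i0 = static_cast<int>(std::floor(xp[0] - 0.5)) - 1;
    int j0 = static_cast<int>(std::floor(xp[1] - 0.5)) - 1;
    int k0 = static_cast<int>(std::floor(xp[2] - 0.5)) - 1;
    for (int k = 0; k < 4; ++k) {
      int z = k0 + k;
      if (z < 0 || z >= nz) continue;
      double wz = phi4(xp[2] - (z + 0.5));
      for (int j = 0; j < 4; ++j) {
        int y = j0 + j;
        if (y < 0 || y >= ny) continue;
        double wyz = phi4(xp[1] - (y + 0.5)) * wz;
        for (int i = 0; i < 4; ++i) {
          int x = i0 + i;
          if (x < 0 || x >= nx) continue;
          double w = phi4(xp[0] - (x + 0.5)) * wyz;
          size_t n = (static_cast<size_t>(z) * ny + y) * nx + x;
          for (int d = 0; d < 3; ++d) out[n + d * nc] += w * forces(p, d);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ib_interp(NumericVector field, NumericMatrix pos,
                            IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nc = static_cast<size_t>(nx) * ny * nz;
  int ncomp = field.size() / nc;
  NumericMatrix out(pos.nrow(), ncomp);
  for (int p = 0; p < pos.nrow(); ++p) {
    double xp[3] = {pos(p, 0), pos(p, 1), pos(p, 2)};
    int i0 = static_cast<int>(std::floor(xp[0] - 0.5)) - 1;
    int j0 = static_cast<int>(std::floor(xp[1] - 0.5)) - 1;
    int k0 = static_cast<int>(std::floor(xp[2] - 0.5)) - 1;
    for (int k = 0; k < 4; ++k) {
      int z = k0 + k;
      if (z < 0 || z >= nz) continue;
      double wz = phi4(xp[2] - (z + 0.5));
      for (int j = 0; j < 4; ++j) {
        int y = j0 + j;
        if (y < 0 || y >= ny) continue;
        double wyz = phi4(xp[1] - (y + 0.5)) * wz;
        for (int i = 0; i < 4; ++i) {
          int x = i0 + i;
          if (x < 0 || x >= nx) continue;
          double w = phi4(xp[0] - (x + 0.5)) * wyz;
          size_t n = (static_cast<size_t>(z) * ny + y) * nx + x;
          for (int d = 0; d < ncomp; ++d) out(p, d) += w * field[n + d * nc];
        }
      }
    }
  }
  return out;
}
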