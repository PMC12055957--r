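// Membrane mechanics on triangulated surfaces.
//
// Elastic forces: each flat triangle carries a Skalak strain energy
// A_ref * W(F) where F is the 2x2 in-plane deformation gradient of the
// affine map from the reference triangle; nodal forces are the exact
// gradient of that energy (the energy depends on current edge lengths only,
// so the gradient is in-plane and element resultants/torques vanish).
//
// Viscous forces: the in-plane strain-rate tensor D is assembled from nodal
// velocities with linear shape functions on the current triangle; the
// surface stress tau_v = mu_s (2D - tr(D) P) + mu_s' tr(D) P is converted to
// nodal forces through the same virtual-work route.
//
// Bending: discrete Helfrich energy kc/2 sum_v (2H_v - c0)^2 A_v with
// cotangent-Laplacian mean curvature and barycentric vertex areas; nodal
// forces are the negative gradient of this energy, evaluated per vertex by
// complex-step differentiation of the energy restricted to the patch of
// triangles that the vertex position influences.

#include "capsule_core.h"
#include <cmath>
#include <algorithm>
#include <stdexcept>

namespace capsule {

void build_topo(const std::vector<int>& tri, int nv, MeshTopo& topo) {
  topo.nv = nv;
  topo.nf = static_cast<int>(tri.size() / 3);
  topo.tri = tri;
  const int nf = topo.nf;
  // vertex -> triangles
  topo.vt_ptr.assign(nv + 1, 0);
  for (int t = 0; t < 3 * nf; ++t) topo.vt_ptr[tri[t] + 1]++;
  for (int v = 0; v < nv; ++v) topo.vt_ptr[v + 1] += topo.vt_ptr[v];
  topo.vt_idx.assign(3 * nf, 0);
  {
    std::vector<int> fill(topo.vt_ptr.begin(), topo.vt_ptr.end() - 1);
    for (int f = 0; f < nf; ++f)
      for (int k = 0; k < 3; ++k) topo.vt_idx[fill[tri[3 * f + k]]++] = f;
  }
  // vertex -> neighbour vertices (unique)
  topo.vv_ptr.assign(nv + 1, 0);
  std::vector<std::vector<int> > nb(nv);
  for (int f = 0; f < nf; ++f) {
    const int* T = &tri[3 * f];
    for (int k = 0; k < 3; ++k) {
      int a = T[k], b = T[(k + 1) % 3];
      nb[a].push_back(b);
      nb[b].push_back(a);
    }
  }
  topo.vv_idx.clear();
  for (int v = 0; v < nv; ++v) {
    std::sort(nb[v].begin(), nb[v].end());
    nb[v].erase(std::unique(nb[v].begin(), nb[v].end()), nb[v].end());
    for (size_t i = 0; i < nb[v].size(); ++i) topo.vv_idx.push_back(nb[v][i]);
    topo.vv_ptr[v + 1] = static_cast<int>(topo.vv_idx.size());
  }
  // bending patch: triangles incident to the closed 1-ring of v
  topo.patch_ptr.assign(nv + 1, 0);
  topo.patch_idx.clear();
  std::vector<int> mark(nf, -1);
  for (int v = 0; v < nv; ++v) {
    std::vector<int> ring;
    ring.push_back(v);
    for (int i = topo.vv_ptr[v]; i < topo.vv_ptr[v + 1]; ++i)
      ring.push_back(topo.vv_idx[i]);
    for (size_t r = 0; r < ring.size(); ++r) {
      int u = ring[r];
      for (int i = topo.vt_ptr[u]; i < topo.vt_ptr[u + 1]; ++i) {
        int f = topo.vt_idx[i];
        if (mark[f] != v) {
          mark[f] = v;
          topo.patch_idx.push_back(f);
        }
      }
    }
    topo.patch_ptr[v + 1] = static_cast<int>(topo.patch_idx.size());
  }
}

static inline void local_frame(const double* x0, const double* x1,
                               const double* x2, double* t1, double* t2,
                               double* nrm, double& twoA) {
  double e1[3] = {x1[0] - x0[0], x1[1] - x0[1], x1[2] - x0[2]};
  double e2[3] = {x2[0] - x0[0], x2[1] - x0[1], x2[2] - x0[2]};
  double n[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                 e1[2] * e2[0] - e1[0] * e2[2],
                 e1[0] * e2[1] - e1[1] * e2[0]};
  twoA = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
  double le1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int k = 0; k < 3; ++k) t1[k] = e1[k] / le1;
  if (nrm) for (int k = 0; k < 3; ++k) nrm[k] = n[k] / twoA;
  double m[3] = {n[1] * t1[2] - n[2] * t1[1],
                 n[2] * t1[0] - n[0] * t1[2],
                 n[0] * t1[1] - n[1] * t1[0]};
  double lm = std::sqrt(m[0] * m[0] + m[1] * m[1] + m[2] * m[2]);
  for (int k = 0; k < 3; ++k) t2[k] = m[k] / lm;
}

// 2x2 shape matrix (columns = local coordinates of the two edge vectors)
static inline void shape_matrix(const double* x0, const double* x1,
                                const double* x2, const double* t1,
                                const double* t2, double* Ds) {
  double e1[3] = {x1[0] - x0[0], x1[1] - x0[1], x1[2] - x0[2]};
  double e2[3] = {x2[0] - x0[0], x2[1] - x0[1], x2[2] - x0[2]};
  Ds[0] = e1[0] * t1[0] + e1[1] * t1[1] + e1[2] * t1[2];
  Ds[2] = e2[0] * t1[0] + e2[1] * t1[1] + e2[2] * t1[2];
  Ds[1] = e1[0] * t2[0] + e1[1] * t2[1] + e1[2] * t2[2];
  Ds[3] = e2[0] * t2[0] + e2[1] * t2[1] + e2[2] * t2[2];
}

void build_ref_elems(const std::vector<double>& Vref, const MeshTopo& topo,
                     std::vector<RefElem>& ref) {
  const int nf = topo.nf;
  ref.resize(nf);
  for (int f = 0; f < nf; ++f) {
    const int* T = &topo.tri[3 * f];
    const double* x0 = &Vref[3 * T[0]];
    const double* x1 = &Vref[3 * T[1]];
    const double* x2 = &Vref[3 * T[2]];
    double t1[3], t2[3], twoA, Dm[4];
    local_frame(x0, x1, x2, t1, t2, NULL, twoA);
    if (twoA <= 0.0) throw std::runtime_error("degenerate reference element");
    shape_matrix(x0, x1, x2, t1, t2, Dm);
    double det = Dm[0] * Dm[3] - Dm[1] * Dm[2];
    RefElem& r = ref[f];
    r.Bm00 = Dm[3] / det;
    r.Bm01 = -Dm[2] / det;
    r.Bm10 = -Dm[1] / det;
    r.Bm11 = Dm[0] / det;
    r.Aref = 0.5 * std::fabs(det);
  }
}

void mesh_measures(const std::vector<double>& V, const MeshTopo& topo,
                   double& area, double& volume,
                   std::vector<double>* vert_area,
                   std::vector<double>* vert_normal,
                   std::vector<double>* vert_H) {
  const int nv = topo.nv, nf = topo.nf;
  area = 0.0;
  volume = 0.0;
  std::vector<double> va(nv, 0.0), vn(3 * nv, 0.0), mv(3 * nv, 0.0);
  for (int f = 0; f < nf; ++f) {
    const int* T = &topo.tri[3 * f];
    const double* a = &V[3 * T[0]];
    const double* b = &V[3 * T[1]];
    const double* c = &V[3 * T[2]];
    double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
    double n[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                   e1[2] * e2[0] - e1[0] * e2[2],
                   e1[0] * e2[1] - e1[1] * e2[0]};
    double twoA = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    double A = 0.5 * twoA;
    area += A;
    volume += (a[0] * (b[1] * c[2] - b[2] * c[1]) -
               a[1] * (b[0] * c[2] - b[2] * c[0]) +
               a[2] * (b[0] * c[1] - b[1] * c[0])) / 6.0;
    for (int k = 0; k < 3; ++k) {
      va[T[k]] += A / 3.0;
      vn[3 * T[k] + 0] += n[0] * 0.5;
      vn[3 * T[k] + 1] += n[1] * 0.5;
      vn[3 * T[k] + 2] += n[2] * 0.5;
    }
    // cotangent contributions: angle at vertex k weights edge (k+1, k+2)
    const double* P[3] = {a, b, c};
    for (int k = 0; k < 3; ++k) {
      const double* pk = P[k];
      const double* pi = P[(k + 1) % 3];
      const double* pj = P[(k + 2) % 3];
      double u[3] = {pi[0] - pk[0], pi[1] - pk[1], pi[2] - pk[2]};
      double w[3] = {pj[0] - pk[0], pj[1] - pk[1], pj[2] - pk[2]};
      double dot = u[0] * w[0] + u[1] * w[1] + u[2] * w[2];
      double cot = dot / twoA;  // |u x w| = 2A
      int vi = T[(k + 1) % 3], vj = T[(k + 2) % 3];
      for (int d = 0; d < 3; ++d) {
        double diff = V[3 * vi + d] - V[3 * vj + d];
        mv[3 * vi + d] += 0.5 * cot * diff;
        mv[3 * vj + d] -= 0.5 * cot * diff;
      }
    }
  }
  if (vert_area) *vert_area = va;
  if (vert_normal) {
    vert_normal->assign(3 * nv, 0.0);
    for (int v = 0; v < nv; ++v) {
      double l = std::sqrt(vn[3 * v] * vn[3 * v] + vn[3 * v + 1] * vn[3 * v + 1] +
                           vn[3 * v + 2] * vn[3 * v + 2]);
      if (l > 0)
        for (int d = 0; d < 3; ++d) (*vert_normal)[3 * v + d] = vn[3 * v + d] / l;
    }
  }
  if (vert_H) {
    vert_H->assign(nv, 0.0);
    for (int v = 0; v < nv; ++v) {
      double lm = std::sqrt(mv[3 * v] * mv[3 * v] + mv[3 * v + 1] * mv[3 * v + 1] +
                            mv[3 * v + 2] * mv[3 * v + 2]);
      double dot = mv[3 * v] * vn[3 * v] + mv[3 * v + 1] * vn[3 * v + 1] +
                   mv[3 * v + 2] * vn[3 * v + 2];
      double s = (dot >= 0) ? 1.0 : -1.0;
      (*vert_H)[v] = (va[v] > 0) ? s * lm / (2.0 * va[v]) : 0.0;
    }
  }
}

// dW/dF for the Skalak law, in terms of F (2x2, row-major)
static inline void sk_piola(const double* F, double Gs, double C, double* P) {
  double g11 = F[0] * F[0] + F[2] * F[2];
  double g22 = F[1] * F[1] + F[3] * F[3];
  double g12 = F[0] * F[1] + F[2] * F[3];
  double I1 = g11 + g22 - 2.0;
  double detG = g11 * g22 - g12 * g12;
  double I2 = detG - 1.0;
  double dW1 = 0.5 * Gs * (I1 + 1.0);
  double dW2 = 0.5 * Gs * (C * I2 - 1.0);
  // dI1/dF = 2F ; dI2/dF = 2 detG F^{-T}
  double detF = F[0] * F[3] - F[1] * F[2];
  // F^{-T} = adj(F)^T / detF ; detG = detF^2
  double FinvT[4] = {F[3] / detF, -F[2] / detF, -F[1] / detF, F[0] / detF};
  for (int k = 0; k < 4; ++k)
    P[k] = 2.0 * dW1 * F[k] + 2.0 * dW2 * detG * FinvT[k];
}

void elastic_forces(const std::vector<double>& V, const MeshTopo& topo,
                    const std::vector<RefElem>& ref, double Gs, double C,
                    std::vector<double>& force,
                    std::vector<double>* lam1, std::vector<double>* lam2,
                    std::vector<double>* tau1, std::vector<double>* tau2) {
  const int nf = topo.nf;
  force.assign(3 * topo.nv, 0.0);
  if (lam1) lam1->assign(nf, 0.0);
  if (lam2) lam2->assign(nf, 0.0);
  if (tau1) tau1->assign(nf, 0.0);
  if (tau2) tau2->assign(nf, 0.0);
  for (int f = 0; f < nf; ++f) {
    const int* T = &topo.tri[3 * f];
    const double* x0 = &V[3 * T[0]];
    const double* x1 = &V[3 * T[1]];
    const double* x2 = &V[3 * T[2]];
    double t1[3], t2[3], twoA, Ds[4];
    local_frame(x0, x1, x2, t1, t2, NULL, twoA);
    if (twoA <= 0.0) throw std::runtime_error("degenerate element");
    shape_matrix(x0, x1, x2, t1, t2, Ds);
    const RefElem& r = ref[f];
    double F[4] = {Ds[0] * r.Bm00 + Ds[2] * r.Bm10,
                   Ds[0] * r.Bm01 + Ds[2] * r.Bm11,
                   Ds[1] * r.Bm00 + Ds[3] * r.Bm10,
                   Ds[1] * r.Bm01 + Ds[3] * r.Bm11};
    double P[4];
    sk_piola(F, Gs, C, P);
    // H = Aref * P * Bm^T ; columns are minus the forces on nodes 1 and 2
    double H[4] = {r.Aref * (P[0] * r.Bm00 + P[1] * r.Bm01),
                   r.Aref * (P[0] * r.Bm10 + P[1] * r.Bm11),
                   r.Aref * (P[2] * r.Bm00 + P[3] * r.Bm01),
                   r.Aref * (P[2] * r.Bm10 + P[3] * r.Bm11)};
    double f1l[2] = {-H[0], -H[2]};
    double f2l[2] = {-H[1], -H[3]};
    for (int d = 0; d < 3; ++d) {
      double f1 = f1l[0] * t1[d] + f1l[1] * t2[d];
      double f2 = f2l[0] * t1[d] + f2l[1] * t2[d];
      force[3 * T[1] + d] += f1;
      force[3 * T[2] + d] += f2;
      force[3 * T[0] + d] -= f1 + f2;
    }
    if (lam1) {
      double g11 = F[0] * F[0] + F[2] * F[2];
      double g22 = F[1] * F[1] + F[3] * F[3];
      double g12 = F[0] * F[1] + F[2] * F[3];
      double tr = g11 + g22, det = g11 * g22 - g12 * g12;
      double disc = std::sqrt(std::max(0.0, tr * tr - 4.0 * det));
      double l1 = std::sqrt(0.5 * (tr + disc));
      double l2 = std::sqrt(std::max(0.0, 0.5 * (tr - disc)));
      (*lam1)[f] = l1;
      (*lam2)[f] = l2;
      if (tau1) {
        double I1 = l1 * l1 + l2 * l2 - 2.0;
        double I2 = (l1 * l2) * (l1 * l2) - 1.0;
        (*tau1)[f] = Gs * l1 / l2 * (I1 + 1.0 - l2 * l2) + C * Gs * I2 * l1 * l2;
        (*tau2)[f] = Gs * l2 / l1 * (I1 + 1.0 - l1 * l1) + C * Gs * I2 * l1 * l2;
      }
    }
  }
}

void viscous_forces(const std::vector<double>& V, const std::vector<double>& Vel,
                    const MeshTopo& topo, double mu_s, double mu_s_dil,
                    std::vector<double>& force,
                    std::vector<double>* D11, std::vector<double>* D22,
                    std::vector<double>* D12) {
  const int nf = topo.nf;
  force.assign(3 * topo.nv, 0.0);
  if (D11) D11->assign(nf, 0.0);
  if (D22) D22->assign(nf, 0.0);
  if (D12) D12->assign(nf, 0.0);
  for (int f = 0; f < nf; ++f) {
    const int* T = &topo.tri[3 * f];
    const double* x0 = &V[3 * T[0]];
    const double* x1 = &V[3 * T[1]];
    const double* x2 = &V[3 * T[2]];
    double t1[3], t2[3], twoA, Ds[4];
    local_frame(x0, x1, x2, t1, t2, NULL, twoA);
    shape_matrix(x0, x1, x2, t1, t2, Ds);
    double det = Ds[0] * Ds[3] - Ds[1] * Ds[2];
    double Bs[4] = {Ds[3] / det, -Ds[2] / det, -Ds[1] / det, Ds[0] / det};
    // local (in-plane) velocity differences
    double dv1[2], dv2[2];
    for (int c = 0; c < 2; ++c) {
      const double* tb = (c == 0) ? t1 : t2;
      dv1[c] = (Vel[3 * T[1]] - Vel[3 * T[0]]) * tb[0] +
               (Vel[3 * T[1] + 1] - Vel[3 * T[0] + 1]) * tb[1] +
               (Vel[3 * T[1] + 2] - Vel[3 * T[0] + 2]) * tb[2];
      dv2[c] = (Vel[3 * T[2]] - Vel[3 * T[0]]) * tb[0] +
               (Vel[3 * T[2] + 1] - Vel[3 * T[0] + 1]) * tb[1] +
               (Vel[3 * T[2] + 2] - Vel[3 * T[0] + 2]) * tb[2];
    }
    // velocity gradient L = [dv1 dv2] * Bs (2x2, row-major)
    double L[4] = {dv1[0] * Bs[0] + dv2[0] * Bs[2],
                   dv1[0] * Bs[1] + dv2[0] * Bs[3],
                   dv1[1] * Bs[0] + dv2[1] * Bs[2],
                   dv1[1] * Bs[1] + dv2[1] * Bs[3]};
    double d11 = L[0], d22 = L[3], d12 = 0.5 * (L[1] + L[2]);
    double trD = d11 + d22;
    double tau[4] = {mu_s * (2.0 * d11 - trD) + mu_s_dil * trD,
                     mu_s * 2.0 * d12,
                     mu_s * 2.0 * d12,
                     mu_s * (2.0 * d22 - trD) + mu_s_dil * trD};
    double A = 0.5 * std::fabs(det);
    // grad N1 = Bs row 0, grad N2 = Bs row 1 ; f_a = -A tau gradNa
    double f1l[2] = {-A * (tau[0] * Bs[0] + tau[1] * Bs[1]),
                     -A * (tau[2] * Bs[0] + tau[3] * Bs[1])};
    double f2l[2] = {-A * (tau[0] * Bs[2] + tau[1] * Bs[3]),
                     -A * (tau[2] * Bs[2] + tau[3] * Bs[3])};
    for (int d = 0; d < 3; ++d) {
      double f1 = f1l[0] * t1[d] + f1l[1] * t2[d];
      double f2 = f2l[0] * t1[d] + f2l[1] * t2[d];
      force[3 * T[1] + d] += f1;
      force[3 * T[2] + d] += f2;
      force[3 * T[0] + d] -= f1 + f2;
    }
    if (D11) (*D11)[f] = d11;
    if (D22) (*D22)[f] = d22;
    if (D12) (*D12)[f] = d12;
  }
}

// ---- bending -------------------------------------------------------------

typedef std::complex<double> cplx;

// energy of the vertex set {center + its 1-ring}, with the coordinates of
// vertex `pert` (or none when pert < 0) replaced by `xp`.
template <typename Real>
static Real patch_energy(const std::vector<double>& V, const MeshTopo& topo,
                         const std::vector<double>& sign_v, double kc, double c0,
                         int center, int pert, const Real* xp) {
  Real E = Real(0.0);
  // vertices whose energy terms we need
  int ring_start = topo.vv_ptr[center], ring_end = topo.vv_ptr[center + 1];
  for (int r = -1; r < ring_end - ring_start; ++r) {
    int u = (r < 0) ? center : topo.vv_idx[ring_start + r];
    Real Au = Real(0.0);
    Real mu[3] = {Real(0.0), Real(0.0), Real(0.0)};
    for (int i = topo.vt_ptr[u]; i < topo.vt_ptr[u + 1]; ++i) {
      int f = topo.vt_idx[i];
      const int* T = &topo.tri[3 * f];
      Real X[3][3];
      for (int k = 0; k < 3; ++k)
        for (int d = 0; d < 3; ++d)
          X[k][d] = (T[k] == pert) ? xp[d] : Real(V[3 * T[k] + d]);
      // orient so that X[0] is u
      int ku = (T[0] == u) ? 0 : (T[1] == u ? 1 : 2);
      int kp = (ku + 1) % 3, kq = (ku + 2) % 3;
      Real e1[3], e2[3];
      for (int d = 0; d < 3; ++d) {
        e1[d] = X[kp][d] - X[ku][d];
        e2[d] = X[kq][d] - X[ku][d];
      }
      Real n0 = e1[1] * e2[2] - e1[2] * e2[1];
      Real n1 = e1[2] * e2[0] - e1[0] * e2[2];
      Real n2 = e1[0] * e2[1] - e1[1] * e2[0];
      Real twoA = sqrt(n0 * n0 + n1 * n1 + n2 * n2);
      Au += twoA / Real(6.0);  // barycentric share
      // cot at p (opposite edge u-q): edges p->u = -e1, p->q = e2-e1
      Real dotp = Real(0.0), dotq = Real(0.0);
      for (int d = 0; d < 3; ++d) {
        Real pu = -e1[d], pq = e2[d] - e1[d];
        dotp += pu * pq;
        Real qu = -e2[d], qp = e1[d] - e2[d];
        dotq += qu * qp;
      }
      Real cotp = dotp / twoA, cotq = dotq / twoA;
      for (int d = 0; d < 3; ++d) {
        mu[d] += Real(0.5) * cotp * (X[ku][d] - X[kq][d]);
        mu[d] += Real(0.5) * cotq * (X[ku][d] - X[kp][d]);
      }
    }
    Real m2 = mu[0] * mu[0] + mu[1] * mu[1] + mu[2] * mu[2];
    if (c0 == 0.0) {
      // (2H)^2 A = |m|^2 / A ; no square root needed
      E += Real(0.5 * kc) * m2 / Au;
    } else {
      Real norm_m = sqrt(m2);
      Real twoH = Real(sign_v[u]) * norm_m / Au;
      Real dev = twoH - Real(c0);
      E += Real(0.5 * kc) * dev * dev * Au;
    }
  }
  return E;
}

static void curvature_signs(const std::vector<double>& V, const MeshTopo& topo,
                            std::vector<double>& sign_v) {
  std::vector<double> vh;
  double area, vol;
  mesh_measures(V, topo, area, vol, NULL, NULL, &vh);
  sign_v.resize(topo.nv);
  for (int v = 0; v < topo.nv; ++v) sign_v[v] = (vh[v] >= 0) ? 1.0 : -1.0;
}

double bending_energy(const std::vector<double>& V, const MeshTopo& topo,
                      double kc, double c0) {
  std::vector<double> va, vh;
  double area, vol;
  mesh_measures(V, topo, area, vol, &va, NULL, &vh);
  double E = 0.0;
  for (int v = 0; v < topo.nv; ++v) {
    double dev = 2.0 * vh[v] - c0;
    E += 0.5 * kc * dev * dev * va[v];
  }
  return E;
}

double bending_forces(const std::vector<double>& V, const MeshTopo& topo,
                      double kc, double c0, std::vector<double>& force) {
  force.assign(3 * topo.nv, 0.0);
  if (kc == 0.0) return 0.0;
  std::vector<double> sign_v;
  curvature_signs(V, topo, sign_v);
  const double h = 1e-20;
  for (int v = 0; v < topo.nv; ++v) {
    cplx xp[3];
    for (int d = 0; d < 3; ++d) xp[d] = cplx(V[3 * v + d], 0.0);
    for (int d = 0; d < 3; ++d) {
      xp[d] = cplx(V[3 * v + d], h);
      cplx E = patch_energy<cplx>(V, topo, sign_v, kc, c0, v, v, xp);
      force[3 * v + d] = -std::imag(E) / h;
      xp[d] = cplx(V[3 * v + d], 0.0);
    }
  }
  return bending_energy(V, topo, kc, c0);
}

}  // namespace capsule
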