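#include <Rcpp.h>
#include "capsule_core.h"
using namespace Rcpp;
using namespace capsule;

static std::vector<double> as_flat(const NumericMatrix& V) {
  std::vector<double> out(V.nrow() * 3);
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) out[3 * i + d] = V(i, d);
  return out;
}

static std::vector<int> as_tri(const IntegerMatrix& T) {
  std::vector<int> out(T.nrow() * 3);
  for (int i = 0; i < T.nrow(); ++i)
    for (int d = 0; d < 3; ++d) out[3 * i + d] = T(i, d) - 1;  // to 0-based
  return out;
}

static NumericMatrix to_mat(const std::vector<double>& x, int n) {
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = x[3 * i + d];
  return out;
}

// [[Rcpp::export]]
List cpp_mesh_measures(NumericMatrix V, IntegerMatrix Tri) {
  std::vector<double> Vf = as_flat(V);
  std::vector<int> tri = as_tri(Tri);
  MeshTopo topo;
  build_topo(tri, V.nrow(), topo);
  double area, vol;
  std::vector<double> va, vn, vh;
  mesh_measures(Vf, topo, area, vol, &va, &vn, &vh);
  return List::create(_["area"] = area, _["volume"] = vol,
                      _["vertex_area"] = NumericVector(va.begin(), va.end()),
                      _["vertex_normal"] = to_mat(vn, V.nrow()),
                      _["vertex_H"] = NumericVector(vh.begin(), vh.end()));
}

// [[Rcpp::export]]
List cpp_element_kinematics(NumericMatrix V, NumericMatrix Vref,
                            IntegerMatrix Tri, Nullable<NumericMatrix> Vprev,
                            double dt) {
  int nf = Tri.nrow();
  std::vector<double> Vf = as_flat(V), Vr = as_flat(Vref);
  std::vector<int> tri = as_tri(Tri);
  MeshTopo topo;
  build_topo(tri, V.nrow(), topo);
  std::vector<RefElem> ref;
  build_ref_elems(Vr, topo, ref);

  NumericVector lam1(nf), lam2(nf), I1v(nf), I2v(nf);
  NumericMatrix e1m(nf, 3), e2m(nf, 3);
  NumericVector d11(nf), d22(nf), d12(nf), trD(nf);
  bool have_prev = Vprev.isNotNull();
  std::vector<double> Vel;
  if (have_prev) {
    NumericMatrix Vp(Vprev);
    Vel.resize(3 * V.nrow());
    for (int i = 0; i < V.nrow(); ++i)
      for (int d = 0; d < 3; ++d)
        Vel[3 * i + d] = (V(i, d) - Vp(i, d)) / dt;
  }

  for (int f = 0; f < nf; ++f) {
    const int* T = &tri[3 * f];
    const double* x0 = &Vf[3 * T[0]];
    const double* x1 = &Vf[3 * T[1]];
    const double* x2 = &Vf[3 * T[2]];
    // local frame and shape matrix (duplicated small computation)
    double e1[3] = {x1[0] - x0[0], x1[1] - x0[1], x1[2] - x0[2]};
    double e2[3] = {x2[0] - x0[0], x2[1] - x0[1], x2[2] - x0[2]};
    double n[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                   e1[2] * e2[0] - e1[0] * e2[2],
                   e1[0] * e2[1] - e1[1] * e2[0]};
    double twoA = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    if (twoA <= 0) stop("degenerate element %d", f + 1);
    double le1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
    double t1[3] = {e1[0] / le1, e1[1] / le1, e1[2] / le1};
    double m[3] = {n[1] * t1[2] - n[2] * t1[1], n[2] * t1[0] - n[0] * t1[2],
                   n[0] * t1[1] - n[1] * t1[0]};
    double lm = std::sqrt(m[0] * m[0] + m[1] * m[1] + m[2] * m[2]);
    double t2[3] = {m[0] / lm, m[1] / lm, m[2] / lm};
    double Ds[4] = {e1[0] * t1[0] + e1[1] * t1[1] + e1[2] * t1[2],
                    e2[0] * t1[0] + e2[1] * t1[1] + e2[2] * t1[2],
                    e1[0] * t2[0] + e1[1] * t2[1] + e1[2] * t2[2],
                    e2[0] * t2[0] + e2[1] * t2[1] + e2[2] * t2[2]};
    const RefElem& r = ref[f];
    double F[4] = {Ds[0] * r.Bm00 + Ds[1] * r.Bm10,
                   Ds[0] * r.Bm01 + Ds[1] * r.Bm11,
                   Ds[2] * r.Bm00 + Ds[3] * r.Bm10,
                   Ds[2] * r.Bm01 + Ds[3] * r.Bm11};
    double g11 = F[0] * F[0] + F[2] * F[2];
    double g22 = F[1] * F[1] + F[3] * F[3];
    double g12 = F[0] * F[1] + F[2] * F[3];
    double tr = g11 + g22, det = g11 * g22 - g12 * g12;
    double disc = std::sqrt(std::max(0.0, tr * tr - 4.0 * det));
    double mu1 = 0.5 * (tr + disc), mu2 = std::max(0.0, 0.5 * (tr - disc));
    lam1[f] = std::sqrt(mu1);
    lam2[f] = std::sqrt(mu2);
    I1v[f] = mu1 + mu2 - 2.0;
    I2v[f] = mu1 * mu2 - 1.0;
    // eigenvectors of G in the reference plane
    double v1[2];
    if (std::fabs(g12) > 1e-14 * (std::fabs(g11) + std::fabs(g22))) {
      v1[0] = g12;
      v1[1] = mu1 - g11;
    } else if (g11 >= g22) {
      v1[0] = 1.0;
      v1[1] = 0.0;
    } else {
      v1[0] = 0.0;
      v1[1] = 1.0;
    }
    double nv1 = std::sqrt(v1[0] * v1[0] + v1[1] * v1[1]);
    v1[0] /= nv1;
    v1[1] /= nv1;
    double v2[2] = {-v1[1], v1[0]};
    // push forward and normalise: principal directions in current plane
    double w1[2] = {F[0] * v1[0] + F[1] * v1[1], F[2] * v1[0] + F[3] * v1[1]};
    double w2[2] = {F[0] * v2[0] + F[1] * v2[1], F[2] * v2[0] + F[3] * v2[1]};
    double nw1 = std::sqrt(w1[0] * w1[0] + w1[1] * w1[1]);
    double nw2 = std::sqrt(w2[0] * w2[0] + w2[1] * w2[1]);
    for (int d = 0; d < 3; ++d) {
      e1m(f, d) = (w1[0] * t1[d] + w1[1] * t2[d]) / nw1;
      e2m(f, d) = (w2[0] * t1[d] + w2[1] * t2[d]) / nw2;
    }
    if (have_prev) {
      double detDs = Ds[0] * Ds[3] - Ds[1] * Ds[2];
      double Bs[4] = {Ds[3] / detDs, -Ds[1] / detDs, -Ds[2] / detDs,
                      Ds[0] / detDs};
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
      double L00 = dv1[0] * Bs[0] + dv2[0] * Bs[2];
      double L01 = dv1[0] * Bs[1] + dv2[0] * Bs[3];
      double L10 = dv1[1] * Bs[0] + dv2[1] * Bs[2];
      double L11 = dv1[1] * Bs[1] + dv2[1] * Bs[3];
      d11[f] = L00;
      d22[f] = L11;
      d12[f] = 0.5 * (L01 + L10);
      trD[f] = L00 + L11;
    }
  }
  List out = List::create(_["lambda1"] = lam1, _["lambda2"] = lam2,
                          _["e1"] = e1m, _["e2"] = e2m, _["I1"] = I1v,
                          _["I2"] = I2v);
  if (have_prev) {
    out["D11"] = d11;
    out["D22"] = d22;
    out["D12"] = d12;
    out["trD"] = trD;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_elastic_forces(NumericMatrix V, NumericMatrix Vref, IntegerMatrix Tri,
                        double Gs, double C) {
  std::vector<double> Vf = as_flat(V), Vr = as_flat(Vref);
  std::vector<int> tri = as_tri(Tri);
  MeshTopo topo;
  build_topo(tri, V.nrow(), topo);
  std::vector<RefElem> ref;
  build_ref_elems(Vr, topo, ref);
  std::vector<double> force, l1, l2, t1, t2;
  elastic_forces(Vf, topo, ref, Gs, C, force, &l1, &l2, &t1, &t2);
  return List::create(_["force"] = to_mat(force, V.nrow()),
                      _["lambda1"] = NumericVector(l1.begin(), l1.end()),
                      _["lambda2"] = NumericVector(l2.begin(), l2.end()),
                      _["tau1"] = NumericVector(t1.begin(), t1.end()),
                      _["tau2"] = NumericVector(t2.begin(), t2.end()));
}

// [[Rcpp::export]]
List cpp_viscous_forces(NumericMatrix V, NumericMatrix Vel, IntegerMatrix Tri,
                        double mu_s, double mu_s_dil) {
  std::vector<double> Vf = as_flat(V), Ve = as_flat(Vel);
  std::vector<int> tri = as_tri(Tri);
  MeshTopo topo;
  build_topo(tri, V.nrow(), topo);
  std::vector<double> force, d11, d22, d12;
  viscous_forces(Vf, Ve, topo, mu_s, mu_s_dil, force, &d11, &d22, &d12);
  return List::create(_["force"] = to_mat(force, V.nrow()),
                      _["D11"] = NumericVector(d11.begin(), d11.end()),
                      _["D22"] = NumericVector(d22.begin(), d22.end()),
                      _["D12"] = NumericVector(d12.begin(), d12.end()));
}

// [[Rcpp::export]]
List cpp_bending_forces(NumericMatrix V, IntegerMatrix Tri, double kc,
                        double c0) {
  std::vector<double> Vf = as_flat(V);
  std::vector<int> tri = as_tri(Tri);
  MeshTopo topo;
  build_topo(tri, V.nrow(), topo);
  std::vector<double> force;
  double Eb = bending_forces(Vf, topo, kc, c0, force);
  return List::create(_["energy"] = Eb,
                      _["force"] = to_mat(force, V.nrow()));
}

// [[Rcpp::export]]
double cpp_bending_energy(NumericMatrix V, IntegerMatrix Tri, double kc,
                          double c0) {
  std::vector<double> Vf = as_flat(V);
  std::vector<int> tri = as_tri(Tri);
  MeshTopo topo;
  build_topo(tri, V.nrow(), topo);
  return bending_energy(Vf, topo, kc, c0);
}
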