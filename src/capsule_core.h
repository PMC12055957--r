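// Shared membrane / mesh routines used by both the standalone Rcpp wrappers
// and the coupled IB-LBM engine.
#ifndef CAPSULE_CORE_H
#define CAPSULE_CORE_H

#include <vector>
#include <complex>
#include <cstddef>

namespace capsule {

struct Vec3 {
  double x, y, z;
};

// Per-element reference geometry precomputed once from the stress-free
// configuration: inverse of the 2x2 reference edge matrix and reference area.
struct RefElem {
  double Bm00, Bm01, Bm10, Bm11;  // inverse reference shape matrix
  double Aref;
};

// Triangle connectivity (0-based)
struct MeshTopo {
  int nv, nf;
  std::vector<int> tri;            // 3*nf
  // CSR vertex->triangle adjacency
  std::vector<int> vt_ptr, vt_idx;
  // CSR vertex->vertex (1-ring) adjacency
  std::vector<int> vv_ptr, vv_idx;
  // per-vertex union of triangles incident to the closed 1-ring (bending patch)
  std::vector<int> patch_ptr, patch_idx;
};

void build_topo(const std::vector<int>& tri, int nv, MeshTopo& topo);

// reference data for membrane elasticity
void build_ref_elems(const std::vector<double>& Vref, const MeshTopo& topo,
                     std::vector<RefElem>& ref);

// geometry measures: total area, signed volume, per-vertex barycentric area,
// outward (area-weighted) vertex normals, per-vertex signed mean curvature.
void mesh_measures(const std::vector<double>& V, const MeshTopo& topo,
                   double& area, double& volume,
                   std::vector<double>* vert_area,
                   std::vector<double>* vert_normal,
                   std::vector<double>* vert_H);

// Skalak elastic nodal forces; optionally returns per-element principal
// stretches (lam1 >= lam2) and principal elastic stresses.
void elastic_forces(const std::vector<double>& V, const MeshTopo& topo,
                    const std::vector<RefElem>& ref, double Gs, double C,
                    std::vector<double>& force,
                    std::vector<double>* lam1, std::vector<double>* lam2,
                    std::vector<double>* tau1, std::vector<double>* tau2);

// membrane surface-viscous nodal forces from nodal velocities
void viscous_forces(const std::vector<double>& V, const std::vector<double>& Vel,
                    const MeshTopo& topo, double mu_s, double mu_s_dil,
                    std::vector<double>& force,
                    std::vector<double>* D11, std::vector<double>* D22,
                    std::vector<double>* D12);

// Helfrich bending energy (returned) and nodal forces as minus the gradient
// of the discrete energy (complex-step differentiation over local patches).
double bending_forces(const std::vector<double>& V, const MeshTopo& topo,
                      double kc, double c0, std::vector<double>& force);

double bending_energy(const std::vector<double>& V, const MeshTopo& topo,
                      double kc, double c0);

}  // namespace capsule

#endif
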