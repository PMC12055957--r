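---
title: "Modelling flow-induced deformation of compound viscoelastic cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flow-induced deformation of compound viscoelastic cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(capsuleflow)
```

## The model

`capsuleflow` simulates the transit of a suspended cancer cell through a
microchannel, treating the cell as a three-layer compound capsule:

* **A viscoelastic outer membrane.** The lipid bilayer plus cortex is an
  infinitely thin 2D sheet whose total stress is the sum of an elastic and a
  viscous part, $\tau = \tau^e + \tau^\nu$.  The elastic part follows the
  strain-hardening Skalak law with strain energy
  $$W = \tfrac{1}{4} G_s\left(I_1^2 + 2I_1 - 2I_2\right)
      + \tfrac{1}{4} C G_s I_2^2,$$
  where $I_1 = \lambda_1^2 + \lambda_2^2 - 2$ and
  $I_2 = (\lambda_1\lambda_2)^2 - 1$ are invariants of the principal
  in-plane stretches, $G_s$ is the surface shear modulus and $C$ the
  hardness parameter; the area-dilatation modulus is $K_s = (1 + 2C)G_s$.
  The viscous part is the surface-Newtonian stress
  $\tau^\nu = \mu_s\,[2D - \mathrm{tr}(D)\,P] + \mu_s'\,\mathrm{tr}(D)\,P$
  with in-plane strain rate $D$; the dilatational surface viscosity
  $\mu_s'$ is neglected by default (its effect is negligible at the small
  area dilatations of cell membranes).  A small Helfrich bending energy
  $E_b = \tfrac{k_c}{2}\int_A (2H - c_0)^2\,dA$ with
  $k_c = 0.001\,G_s a^2$ and $c_0 = 0$ regularises the membrane against
  buckling wrinkles; it is not a fitted property.
* **A Newtonian cytoplasm** of viscosity $\mu_c = \lambda \mu_0$.
* **A nucleus**, a smaller hyperelastic capsule of radius $a_n = 0.5\,a$
  whose membrane moduli are twice those of the cell membrane (same $C$,
  no membrane viscosity) and whose interior has the cytoplasm viscosity.

The suspending buffer is weakly shear thinning,
$\mu = K (\dot\gamma/\dot\gamma_0)^{\alpha-1}$ with $K = 0.053$ Pa s,
$\alpha = 0.95$, $\dot\gamma_0 = 1\,\mathrm{s}^{-1}$, truncated outside
$\dot\gamma \in [10^{-2}, 10^{6}]\,\mathrm{s}^{-1}$ — bounds chosen wide
enough that duct-flow shear rates at the experimental conditions
($\sim 10^4\,\mathrm{s}^{-1}$) are never clamped.

The governing dimensionless groups are the capillary number
$Ca = \mu_0 U/G_s$, the hardness $C$, the reduced membrane viscosity
$\eta = \mu_s/(\mu_0 a)$, the viscosity ratio $\lambda = \mu_c/\mu_0$, the
confinement $2a/l$ and the nucleus ratio $a_n/a$.  The characteristic
viscosity $\mu_0$ is the cross-section average of the fully developed duct
flow; it is taken as an input (32.7 mPa s in the 20 µm channel at
$U = 0.19$ m/s, 33.9 mPa s in the 40 µm channel at $U = 0.17$ m/s) because
the exact averaging convention behind those numbers is not fully
determined — `mu0_cross_section()` computes both the area average and the
flow-weighted average for comparison; at the experimental conditions both fall
within about 15% of the quoted values, and neither is asserted to be "the"
convention.

## Numerical method

The fluid is solved with a D3Q19 lattice-Boltzmann method (BGK collision,
Guo forcing).  The local relaxation time follows the truncated power law
through the shear rate reconstructed from non-equilibrium moments at every
node.  Channel walls use Bouzidi linear interpolated bounce-back with link
fractions computed by bisection on the geometry's signed-distance function;
inlet and outlet faces impose densities (pressures) through non-equilibrium
extrapolation.  The collision operator is plain BGK: at the
operating Reynolds numbers (0.12–0.21) BGK with the resolutions used here is
accurate and stable, so the extra cost and parameters of a multi-relaxation
operator buy nothing.

Membranes are closed triangulated meshes built by recursive 1-to-4
subdivision of a regular octahedron projected to the sphere — the only seed
that reproduces the production counts of 8192 elements and 4098 nodes at
five levels.  Elastic nodal forces are the exact gradient of the element
Skalak energy under the linear (flat-triangle) finite-element map from the
reference configuration; because that energy depends only on the current
edge lengths, element resultants and torques vanish identically.  Viscous
membrane forces use the same virtual-work assembly with the in-plane strain
rate built from the nodal velocities.  Bending energy is discretised as
$\tfrac{k_c}{2}\sum_v (2H_v - c_0)^2 A_v$ with cotangent-Laplacian mean
curvature and barycentric vertex areas; nodal bending forces are the exact
negative gradient of this discrete energy, evaluated per vertex by
complex-step differentiation of the energy restricted to the patch of
triangles the vertex influences.  This keeps rigid modes exactly force-free
(machine-precision zero resultant force and torque) without hand-deriving
the cotangent gradient.  On the discrete sphere the scheme recovers
$E_b \to 8\pi k_c$ within 3% at the production mesh; pointwise force noise
concentrates at the six irregular valence-4 seed vertices and stays below
half a percent of $G_s a$ with the default $k_c$.

Fluid–membrane coupling is an immersed-boundary method with the 4-point
Peskin kernel (the piecewise square-root kernel), chosen because it
satisfies partition of unity and the zero-first-moment condition exactly,
so constant fields transfer exactly and linear fields interpolate to
rounding.  The cytoplasm/nucleus viscosity contrast is carried by a
front-tracking indicator per membrane, obtained by solving
$\nabla^2 I = -\nabla\cdot G$ (with $G$ the spread outward-normal field) by
warm-started red–black SOR on a local box around the capsule; because the
field is re-solved from the current geometry at every refresh, no drift can
accumulate and no separate geometric rebuild is needed.  The blended
viscosity is
$\mu = \mu_{ext}(\dot\gamma)(1 - I_{cell}) + \lambda\mu_0 (I_{cell} -
I_{nuc}) + \lambda_n \mu_0 I_{nuc}$.

### Time step and stability

A single explicit global step advances fluid, coupling and membranes.  The
step is the smaller of a compressibility bound (peak lattice speed
$\lesssim 0.05$) and a membrane-stiffness bound
$$\Delta t \le s\,\frac{\mu_0\,\Delta x}{G_{sn}\,(1 + 2C)},$$
with the nucleus moduli $G_{sn} = 2G_s$ the stiffest spring in the system
and $s = 0.3$ by default; the bound was set by stability experiments at the
operating conditions (at $s \gtrsim 0.5$ the coarse-mesh runs go unstable, at
$s = 0.3$ they are robust across the scan ranges used here).

The explicit surface-viscosity coupling is stiff: at $\eta = 30$–$80$ the
membrane viscous stress reacts to vertex-velocity differences strongly
enough that the highest-frequency interpolation–spreading feedback modes
can grow.  The vertex velocities entering $\tau^\nu$ are therefore passed
through an exponential moving average,
$\bar v \mathrel{+}= \beta\,(v - \bar v)$ with $\beta = 0.05$, which damps
the two-step feedback loop while leaving timescales beyond $\sim 20$ steps
(four orders of magnitude below a transit time) untouched.  This smoothing
is a stabilisation of the discrete coupling, not a change of the membrane
model; varying $\beta$ over 0.02–0.1 leaves the recorded volume and
deformation histories unchanged to well within the mesh-resolution effects
discussed below, while $\beta \gtrsim 0.2$ lets the feedback modes grow at
the largest membrane viscosities of the scan.

Enclosed volumes are monitored, not enforced: no artificial volume
correction force is applied, so a volume drift larger than a few percent is
a visible red flag rather than a silently compensated error.

### Geometry, units and conventions

Both computational domains follow the experimental chips: a 45°-converging
section into a 400 µm straight square channel of width $l = 20$ µm with
20 µm corner fillets, and a cross-slot of 40 µm branches (440 µm feeding
branch, 160 µm others) with 10 µm reentrant-corner fillets.  The x axis is
the flow axis, y the channel height, z the lateral axis; the origin sits at
the straight-channel entry or the cross centre.  Lattice nodes are
cell-centred ($x_i = (i - \tfrac12)\Delta x$), so flat channel walls fall
exactly mid-link.  The driving pressure difference is calibrated on the
cell-free channel by secant iteration until the flow rate matches the
experimental value within 0.5%, exactly as the experiments fix flow rates,
and the calibrated base flow is reused as the initial condition for every
cell release in that geometry.

All user-facing quantities are SI (lengths in metres, contours in µm);
internally the engine works in lattice units with
$G_s^{lat} = G_s\,\Delta t^2/(\rho\,\Delta x^3)$,
$\mu_s^{lat} = \mu_s\,\Delta t/(\rho\,\Delta x^3)$,
$k_c^{lat} = k_c\,\Delta t^2/(\rho\,\Delta x^5)$.

The Taylor parameter uses the maximum contour dimensions along the axes:
$D_{XZ} = (a_3 - a_1)/(a_3 + a_1)$ with $a_1$ along x and $a_3$ along z, so
a cell stretched along the outgoing axis of the cross-slot has positive
$D_{XZ}$.  The deformation index $DI = 1 - 2\sqrt{\pi A}/P$ is evaluated on
the convex hull of the x–z vertex shadow (the standard deformability
cytometry convention; concave bullet rears are closed by the hull).  The
mean Hausdorff distance is directed — simulation to experiment — after
centroid alignment, with both contours resampled to 512 equal-arc-length
points; halving or doubling the resampling count moves typical MHD values
by well under 0.01 µm, far below the 0.2 µm-scale differences that
discriminate between fit candidates.

## The inverse-fitting pipeline

Cell properties are inferred in stages, mirroring how the deformation data
constrain them:

1. **Elastic moduli from the steady shape.**  Forward simulations over the
   grid $0.1 \le Ca \le 5$ ($\delta Ca = 0.1$), $1 \le C \le 50$
   ($\delta C = 1$) give steady contours; candidates whose steady $DI$
   matches the observation within `tol_DI` (default $\pm 0.005$ — the
   shortlist gate is not stated quantitatively in the source experiments
   and is exposed in the interface) are ranked by MHD and the minimum wins,
   ties towards lower $Ca$ then lower $C$.
2. **Membrane viscosity from the transient.**  With $(Ca, C)$ fixed, the
   $\eta$ grid $0..80$ ($\delta\eta = 5$) is ranked by the RMS difference
   between simulated and observed deformation series on their common
   abscissa range (position in the constricted channel, time in the
   cross-slot).  RMS is the reproducible surrogate for the visual
   curve-matching that the protocol otherwise relies on; candidates whose RMS exceeds
   twice the minimum are flagged (the hyperelastic $\eta = 0$ model lands
   there whenever the observation is viscoelastic).
3. **Off-centre distance in the cross-slot.**  The trajectory $z(t^*)$ is
   matched over $d^z_{oc} \in [0.001, 0.016]\,l$ using hyperelastic
   simulations only — membrane viscosity barely moves the residence time,
   which is what the trajectory constrains.

Uncertainties are half grid increments propagated to the dimensional
properties, with the two contributions to $\delta K_s$ combined in
quadrature: $\delta G_s = G_s(\delta Ca/2)/Ca$,
$\delta K_s = \sqrt{(2G_s\,\delta C/2)^2 + ((1+2C)\delta G_s)^2}$,
$\delta \mu_s = \mu_s (\delta\eta/2)/\eta$.  Quadrature rather than linear
summation is used because the two scan axes are varied independently; it
reproduces the reference uncertainty magnitudes
($\pm0.9$ mN/m, $\pm21$ mN/m, $\pm0.6$ µN s/m at the constricted PC-3
conditions).

## What the synthetic data emulate — and what they do not

`make_pseudo_experiment()` stands in for a recorded cell: it runs a forward
simulation at known parameters, extracts the contour and deformation-index
series, and optionally adds seeded Gaussian noise to the contour points
(mimicking pixel-scale segmentation noise of a high-speed camera at
0.1–0.3 µm per point).  It does not emulate out-of-focus blur, frame-rate
aliasing, illumination gradients, cell-to-cell biological variability, or
contour-extraction bias — so a passing recovery test shows the pipeline is
self-consistent and deterministic, not that real segmentation errors are
harmless.

## Problem sizes used by the tests

The test suite and the acceptance script run the full physics at reduced
scale, chosen so the whole suite completes on a desk machine:

* flow benchmarks on 16–32 nodes across the duct;
* constricted transits at $l/8$ (2.5 µm spacing) in a shortened domain
  (80 µm straight section, release at $x = -40$ µm), cell mesh at 512
  elements, nucleus at 128;
* cross-slot transits at $l/12$ (3.33 µm spacing) with 60/50 µm branches
  and release at $x = -55$ µm.

Reduced scale has physical consequences that the tests respect.  In the
cross-slot the confinement is mild ($2a/l = 0.43$, wall gaps of several
nodes), and the reduced runs are quantitatively meaningful: the pilot runs
give residence time $t^* \approx 1.8$ at $d^z_{oc} = 0.007\,l$ and peak
$|D_{XZ}| \approx 0.5$, matching the full-scale behaviour.  In the narrow
constricted channel the lubrication gap is only 1–2 nodes at $l/8$, the
near-wall shear around the cell is unresolved, and the steady bullet-shape
$DI$ comes out several times smaller than at production resolution; the
entrance extension peak, which lives on the resolved converging-section
scale, remains usable.  Tests on the constricted geometry therefore assert
orderings and trends (e.g. the entrance $DI$ peak is non-increasing in
$\eta$), never absolute steady $DI$ magnitudes.  Production-quality curves
need the production resolution ($l/64$, 8192-element meshes), which the same
code runs given hours rather than minutes.

A validation of the coupled solver that does not depend on channel
confinement is the capsule-in-shear benchmark (moving-wall Couette): at a
capsule radius of 6 lattice units the steady Taylor parameter comes out
0.12 / 0.21 / 0.30 at shear capillary numbers 0.05 / 0.1 / 0.2 with
$C = 1$, in line with classical Skalak-capsule benchmark results once the finite
confinement of the benchmark box is accounted for.

## Degenerate inputs and numerical edge cases

* Zero shear rate: the power-law viscosity is evaluated at the lower
  truncation bound, never diverging.
* $\eta = 0$ or $a_n/a = 0$ switch off the membrane viscosity or the
  nucleus without special cases.
* A perfectly centred cross-slot release sits on an unstable equilibrium:
  the cell is trapped at the stagnation point by symmetry and
  `residence_time()` reports "not exited" rather than a number.
* Degenerate (zero-area) elements, open meshes, non-symmetric strain-rate
  tensors and off-grid fit requests are rejected with messages naming the
  offending element, edge or argument.
* Bouzidi fractions at $q = 1/2$ reduce exactly to mid-link bounce-back;
  $q$ outside $[0, 1)$ cannot be produced by the bisection construction.

## Known limitations

* Single cell only: no cell–cell interaction, adhesion or wall contact
  model (the immersed-boundary kernel effectively lubricates contacts at
  one-cell-width scale).
* Membrane viscosity is a single Kelvin–Voigt surface viscosity; the
  deformation-mode-dependent variant that some leukaemia cells appear to
  need is out of scope.
* No thermal fluctuations, no remeshing (fine for the moderate
  deformations studied; sustained tank-treading at high $Ca$ would distort
  elements).
* Volume conservation is monitored, not enforced; at test resolutions the
  enclosed volume drifts 2–3% per transit (worse for the very coarse
  nucleus mesh), at production resolution well under 1%.
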