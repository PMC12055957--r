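#' Skalak strain energy density
#'
#' The strain-hardening Skalak law for a 2D membrane,
#' \deqn{W = \tfrac{1}{4} G_s (I_1^2 + 2 I_1 - 2 I_2) + \tfrac{1}{4} C G_s I_2^2,}
#' with invariants \eqn{I_1 = \lambda_1^2+\lambda_2^2-2} and
#' \eqn{I_2 = (\lambda_1\lambda_2)^2 - 1}.
#'
#' @param lambda1,lambda2 principal in-plane stretches (> 0), vectorised.
#' @param Gs membrane shear modulus (N/m).
#' @param C hardness parameter; the area-dilatation modulus is
#'   `Ks = (1 + 2C) Gs`.
#' @return energy per unit reference area (N/m).
#' @export
strain_energy <- function(lambda1, lambda2, Gs, C) {
  if (any(lambda1 <= 0) || any(lambda2 <= 0))
    stop("stretches must be positive")
  I1 <- lambda1^2 + lambda2^2 - 2
  I2 <- (lambda1 * lambda2)^2 - 1
  0.25 * Gs * (I1^2 + 2 * I1 - 2 * I2) + 0.25 * C * Gs * I2^2
}

#' Principal elastic membrane stresses of the Skalak law
#'
#' Closed-form principal Cauchy surface stresses
#' \eqn{\tau_1 = (1/\lambda_2)\,\partial W/\partial\lambda_1} (and
#' symmetrically \eqn{\tau_2}):
#' \deqn{\tau_1 = \frac{G_s\lambda_1}{\lambda_2}(I_1 + 1 - \lambda_2^2)
#'   + C G_s I_2 \lambda_1\lambda_2.}
#'
#' @inheritParams strain_energy
#' @return list with vectors `tau1` and `tau2` (N/m).
#' @export
sk_stresses <- function(lambda1, lambda2, Gs, C) {
  if (any(lambda1 <= 0) || any(lambda2 <= 0))
    stop("stretches must be positive")
  I1 <- lambda1^2 + lambda2^2 - 2
  I2 <- (lambda1 * lambda2)^2 - 1
  list(tau1 = Gs * lambda1 / lambda2 * (I1 + 1 - lambda2^2) +
         C * Gs * I2 * lambda1 * lambda2,
       tau2 = Gs * lambda2 / lambda1 * (I1 + 1 - lambda1^2) +
         C * Gs * I2 * lambda1 * lambda2)
}

#' Viscous membrane stress
#'
#' Surface-viscous stress from the in-plane strain rate,
#' \deqn{\tau^\nu = \mu_s [\,2 D - \mathrm{tr}(D) P\,] + \mu_s' \mathrm{tr}(D) P,}
#' where `P` is the surface projection tensor.  The dilatational part
#' (`mu_s_dil`) is neglected by default.
#'
#' @param D in-plane strain-rate tensor (2 x 2 symmetric matrix, 1/s) in the
#'   element's local frame.
#' @param mu_s membrane shear viscosity (N s/m).
#' @param mu_s_dil membrane dilatational viscosity (N s/m).
#' @return 2 x 2 viscous stress tensor (N/m).
#' @export
viscous_stress <- function(D, mu_s, mu_s_dil = 0) {
  D <- as.matrix(D)
  stopifnot(all(dim(D) == c(2, 2)))
  if (max(abs(D - t(D))) > 1e-12 * max(1, max(abs(D))))
    stop("'D' must be symmetric")
  P <- diag(2)
  trD <- sum(diag(D))
  mu_s * (2 * D - trD * P) + mu_s_dil * trD * P
}

#' Helfrich bending energy and nodal bending forces
#'
#' Discrete Helfrich energy \eqn{E_b = (k_c/2)\int_A (2H - c_0)^2 dA}
#' evaluated by quadrature over barycentric vertex areas with cotangent
#' Laplace-Beltrami mean curvature.  Nodal forces are the negative gradient
#' of this discrete energy with respect to the vertex positions
#' (energy-variation scheme), so rigid translations and rotations produce no
#' net force or torque.
#'
#' @param mesh a closed [tri_mesh()].
#' @param kc bending modulus (J).
#' @param c0 spontaneous curvature (1/m).
#' @return list with `energy` (J) and `force` (n x 3 matrix, N).
#' @export
bending_forces <- function(mesh, kc, c0 = 0) {
  stopifnot(inherits(mesh, "tri_mesh"), kc >= 0)
  check_closed(mesh)
  cpp_bending_forces(mesh$vertices, mesh$triangles, kc, c0)
}

#' Discrete Helfrich bending energy
#'
#' Quadrature of the bending energy over barycentric vertex areas with
#' cotangent-Laplacian mean curvature (no force computation).
#'
#' @inheritParams bending_forces
#' @return energy (J).
#' @export
bending_energy <- function(mesh, kc, c0 = 0) {
  stopifnot(inherits(mesh, "tri_mesh"), kc >= 0)
  cpp_bending_energy(mesh$vertices, mesh$triangles, kc, c0)
}

#' Viscoelastic nodal membrane forces
#'
#' Assembles the total nodal force density of the membrane model: Skalak
#' elastic forces (virtual work of the in-plane stress against the reference
#' configuration), surface-viscous forces from the nodal velocities, and
#' Helfrich bending forces.  For a closed membrane the resultant force and
#' torque vanish to rounding because each contribution is the exact gradient
#' of a rigid-motion-invariant discrete energy (or a symmetric in-plane
#' stress).
#'
#' @param mesh a closed [tri_mesh()].
#' @param cell a [cell_params()] supplying `Gs`, `C`, `mu_s`, `mu_s_dil`,
#'   `kc`, `c0`.
#' @param velocities optional n x 3 nodal velocities (m/s) for the viscous
#'   part; omitted means no viscous contribution.
#' @param membrane `"cell"` (default) or `"nucleus"`: selects the moduli set.
#' @return list with `force` (n x 3, N) and components `elastic`, `viscous`,
#'   `bending`, plus per-element `lambda1`, `lambda2`, `tau1`, `tau2`.
#' @export
nodal_forces <- function(mesh, cell, velocities = NULL,
                         membrane = c("cell", "nucleus")) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(cell, "cell_params"))
  membrane <- match.arg(membrane)
  if (membrane == "cell") {
    Gs <- cell$Gs; C <- cell$C; mus <- cell$mu_s; musd <- cell$mu_s_dil
    kc <- cell$kc
  } else {
    Gs <- cell$Gsn; C <- cell$C; mus <- 0; musd <- 0; kc <- cell$kcn
  }
  el <- cpp_elastic_forces(mesh$vertices, mesh$reference_vertices,
                           mesh$triangles, Gs, C)
  if (!is.null(velocities) && mus > 0) {
    vel <- as.matrix(velocities)
    stopifnot(all(dim(vel) == dim(mesh$vertices)))
    vi <- cpp_viscous_forces(mesh$vertices, vel, mesh$triangles, mus, musd)
    fv <- vi$force
  } else {
    fv <- matrix(0, nrow(mesh$vertices), 3)
  }
  bd <- cpp_bending_forces(mesh$vertices, mesh$triangles, kc, cell$c0)
  list(force = el$force + fv + bd$force,
       elastic = el$force, viscous = fv, bending = bd$force,
       bending_energy = bd$energy,
       lambda1 = el$lambda1, lambda2 = el$lambda2,
       tau1 = el$tau1, tau2 = el$tau2)
}
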