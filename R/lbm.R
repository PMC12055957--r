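#' Lattice-Boltzmann simulation state
#'
#' Creates a D3Q19 lattice-Boltzmann solver over a flagged node array.  The
#' suspending fluid follows the truncated power law of the supplied
#' [fluid_model()]; the local relaxation time is updated every step from the
#' shear rate reconstructed from non-equilibrium moments (BGK collision with
#' Guo forcing).  Walls use Bouzidi interpolated bounce-back with the link
#' fractions in `qlink`; pressure (density) inlets/outlets use the
#' non-equilibrium extrapolation rule.
#'
#' @param flags integer array (nx x ny x nz): 0 = solid wall, 1 = fluid,
#'   `1 + p` = node of pressure plane `p` (p >= 1), 255 = moving wall.
#' @param fluid a [fluid_model()].
#' @param dx lattice spacing (m).
#' @param dt time step (s).
#' @param planes data.frame with columns `axis` (1..3), `side` (0 min / 1
#'   max) and `rho` (target lattice density), one row per pressure plane.
#' @param qlink numeric array (nx*ny*nz*19) of wall link fractions in
#'   `[0, 1)`, or `NULL` for mid-link bounce-back everywhere.
#' @param periodic logical length-3: periodic wrap per axis.
#' @param newtonian if `TRUE`, keep a fixed relaxation time `tau` instead of
#'   the power-law update (used for Newtonian benchmarks).
#' @param tau fixed relaxation time when `newtonian = TRUE`.
#' @param wall_u moving-wall velocity (m/s, length 3) applied to nodes
#'   flagged 255.
#' @param control named list of solver internals: `tau_max`,
#'   `bending_every`, `indicator_every`, `sor_max`, `sor_min`, `sor_tol`,
#'   `sor_omega`.
#' @return object of class `lbm_sim`.
#' @export
lbm_sim <- function(flags, fluid = fluid_model(), dx, dt, planes = NULL,
                    qlink = NULL, periodic = c(FALSE, FALSE, FALSE),
                    newtonian = FALSE, tau = 0.8, wall_u = c(0, 0, 0),
                    origin = c(0, 0, 0), control = list()) {
  dims <- dim(flags)
  stopifnot(length(dims) == 3, dx > 0, dt > 0)
  ctrl <- list(tau_max = 20, newtonian = newtonian, tau_fixed = tau,
               bending_every = 10, indicator_every = 10, visc_every = 2,
               sor_max = 600, sor_min = 24, sor_tol = 1e-3, sor_omega = 1.85,
               wall_u = wall_u * dt / dx, periodic = as.logical(periodic))
  ctrl[names(control)] <- control
  ctrl$wall_u <- wall_u * dt / dx
  if (is.null(planes)) {
    pm <- matrix(0, 0, 3)
  } else {
    pm <- cbind(planes$axis - 1, planes$side, planes$rho)
  }
  phys <- list(dx = dx, dt = dt, rho = fluid$rho, K = fluid$K,
               alpha = fluid$alpha, gamma0 = fluid$gamma0,
               gamma_min = fluid$gamma_min, gamma_max = fluid$gamma_max,
               mu0 = fluid$mu0)
  ptr <- sim_create(as.integer(dims), as.integer(flags),
                    if (is.null(qlink)) numeric(0) else as.numeric(qlink),
                    pm, phys, ctrl)
  structure(list(ptr = ptr, dims = dims, dx = dx, dt = dt, fluid = fluid,
                 planes = planes, origin = origin, capsules = list()),
            class = "lbm_sim")
}

#' Advance a lattice-Boltzmann simulation
#'
#' Runs `nsteps` collide-force-stream cycles (including immersed-boundary
#' coupling and membrane updates when capsules are present).
#'
#' @param sim an [lbm_sim()].
#' @param nsteps number of time steps.
#' @return the simulation, invisibly (state advances in place).
#' @export
lbm_step <- function(sim, nsteps = 1) {
  stopifnot(inherits(sim, "lbm_sim"), nsteps >= 0)
  if (nsteps > 0) sim_run(sim$ptr, as.integer(nsteps))
  invisible(sim)
}

#' Macroscopic fields of a simulation
#'
#' @param sim an [lbm_sim()].
#' @return list of arrays (nx x ny x nz): `rho` (lattice density), `ux`,
#'   `uy`, `uz` (m/s), `tau` (relaxation time), `shear_rate` (1/s), and the
#'   current `step` count.
#' @export
lbm_fields <- function(sim) {
  stopifnot(inherits(sim, "lbm_sim"))
  sim_macroscopic(sim$ptr)
}

#' Local shear rate field
#'
#' Shear rate \eqn{\dot\gamma = \sqrt{2 D : D}} reconstructed per node from
#' the non-equilibrium moments of the populations; this is the rate that
#' feeds the truncated power-law viscosity each step.
#'
#' @param sim an [lbm_sim()].
#' @return array (nx x ny x nz) of shear rate (1/s).
#' @export
local_shear_rate <- function(sim) {
  lbm_fields(sim)$shear_rate
}

#' Volumetric flow rate through a lattice slab
#'
#' @param sim an [lbm_sim()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @param index 1-based slab index along `axis`.
#' @return flow rate (m^3/s).
#' @export
lbm_flow_rate <- function(sim, axis, index) {
  sim_flow_rate(sim$ptr, as.integer(axis - 1), as.integer(index))
}

#' Total lattice mass
#' @param sim an [lbm_sim()].
#' @return sum of populations over non-solid nodes (lattice units).
#' @export
lbm_mass <- function(sim) sim_mass(sim$ptr)

#' Set the target density of a pressure plane
#' @param sim an [lbm_sim()].
#' @param plane 1-based plane index.
#' @param rho target lattice density.
#' @export
lbm_set_plane_rho <- function(sim, plane, rho) {
  sim_set_plane_rho(sim$ptr, as.integer(plane), rho)
  invisible(sim)
}

#' Constant body force
#' @param sim an [lbm_sim()].
#' @param g physical force density (N/m^3, length 3).
#' @export
lbm_set_body_force <- function(sim, g) {
  # convert N/m^3 to lattice force density
  conv <- sim$dt^2 / (sim$fluid$rho * sim$dx)
  sim_set_body_force(sim$ptr, g * conv)
  invisible(sim)
}

#' Insert a capsule membrane into the flow
#'
#' Adds a closed triangulated membrane coupled to the fluid by the immersed
#' boundary method.  Insert the outer cell membrane first and the nucleus
#' second; their indicator functions then carry the viscosity blending
#' exterior / cytoplasm / nucleus.
#'
#' @param sim an [lbm_sim()].
#' @param mesh a [tri_mesh()] in physical coordinates (m), already placed.
#' @param Gs,C membrane Skalak moduli (N/m, -).
#' @param mu_s,mu_s_dil membrane viscosities (N s/m).
#' @param kc,c0 bending modulus (J) and spontaneous curvature (1/m).
#' @param lambda interior-to-mu0 viscosity ratio behind this membrane.
#' @return the simulation, invisibly.
#' @export
lbm_add_capsule <- function(sim, mesh, Gs, C, mu_s = 0, mu_s_dil = 0,
                            kc = 0, c0 = 0, lambda = 1) {
  stopifnot(inherits(sim, "lbm_sim"), inherits(mesh, "tri_mesh"))
  V <- sweep(mesh$vertices, 2, sim$origin)
  lo <- apply(V, 2, min) / sim$dx
  hi <- apply(V, 2, max) / sim$dx
  if (any(lo < 0.5) || any(hi > sim$dims - 0.5))
    stop("capsule vertex outside the fluid domain interior margin")
  sim_add_capsule(sim$ptr, V, mesh$triangles, Gs, C, mu_s,
                  mu_s_dil, kc, c0, lambda)
  sim$capsules <- c(sim$capsules, list(mesh))
  invisible(sim)
}

#' Current state of a capsule
#' @param sim an [lbm_sim()].
#' @param k capsule index (insertion order).
#' @return list with `vertices` (m), `velocities` (m/s), `area` (m^2),
#'   `volume` (m^3).
#' @export
lbm_capsule_state <- function(sim, k = 1) {
  st <- sim_capsule_state(sim$ptr, as.integer(k))
  st$vertices <- sweep(st$vertices, 2, sim$origin, "+")
  st
}

#' @export
print.lbm_sim <- function(x, ...) {
  cat(sprintf("lbm_sim: %d x %d x %d nodes, dx = %.3g um, dt = %.3g s, %d capsule(s)\n",
              x$dims[1], x$dims[2], x$dims[3], x$dx * 1e6, x$dt,
              length(x$capsules)))
  invisible(x)
}
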