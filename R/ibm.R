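#' Immersed-boundary kernel weight
#'
#' The 4-point Peskin kernel used for force spreading and velocity
#' interpolation.  It satisfies the partition of unity and zero first moment
#' exactly, so constant fields are reproduced exactly and linear fields are
#' interpolated exactly.
#'
#' @param r signed distance in lattice units.
#' @return kernel weight, non-zero for `|r| < 2`.
#' @export
ib_kernel <- function(r) cpp_ib_kernel(r)

#' Spread Lagrangian forces onto the lattice
#'
#' Distributes point forces onto the surrounding 4x4x4 lattice stencil with
#' the Peskin kernel.  The total spread force equals the total input force
#' exactly (kernel partition of unity).  Lattice nodes are cell-centred:
#' node (i, j, k) (1-based) sits at lattice coordinates (i - 0.5, ...).
#'
#' @param positions n x 3 matrix of point positions in lattice coordinates.
#' @param forces n x 3 matrix of point forces.
#' @param dims lattice dimensions (length 3).
#' @return array dims x 3 of force density (force per unit lattice volume).
#' @export
spread_forces <- function(positions, forces, dims) {
  positions <- as.matrix(positions)
  forces <- as.matrix(forces)
  stopifnot(ncol(positions) == 3, all(dim(positions) == dim(forces)),
            length(dims) == 3)
  lo <- apply(positions, 2, min)
  hi <- apply(positions, 2, max)
  if (any(lo < 0) || any(hi > dims)) {
    bad <- which(apply(positions, 1, function(p) any(p < 0) || any(p > dims)))[1]
    stop("position ", bad, " outside the lattice domain")
  }
  cpp_ib_spread(positions, forces, as.integer(dims))
}

#' Interpolate a lattice field at Lagrangian points
#'
#' Adjoint of [spread_forces()]: evaluates a lattice field at off-grid
#' points with the same 4-point kernel, so the discrete power balance
#' between spreading and interpolation holds to rounding.
#'
#' @param field array (nx x ny x nz) or (nx x ny x nz x m).
#' @param positions n x 3 matrix in lattice coordinates.
#' @return n x m matrix of interpolated values.
#' @export
interpolate_velocity <- function(field, positions) {
  positions <- as.matrix(positions)
  d <- dim(field)
  stopifnot(length(d) %in% c(3, 4))
  cpp_ib_interp(as.numeric(field), positions, as.integer(d[1:3]))
}

#' Indicator (colour) function of a capsule in a simulation
#'
#' Front-tracking indicator in `[0, 1]` (1 inside the membrane), obtained by
#' solving the Poisson problem `laplace(I) = div(G)` where `G` is the spread
#' field of outward surface normals.  Refreshed periodically during time
#' stepping; this accessor forces a refresh and returns the field.
#'
#' @param sim an [lbm_sim()] containing at least one capsule.
#' @param k capsule index.
#' @return array (nx x ny x nz).
#' @export
indicator_field <- function(sim, k = 1) {
  stopifnot(inherits(sim, "lbm_sim"))
  if (length(sim$capsules) < k) stop("no such capsule in simulation")
  sim_refresh_indicator(sim$ptr)
  sim_indicator(sim$ptr, as.integer(k))
}

#' Blended viscosity field
#'
#' Mixes the exterior truncated power-law viscosity with the Newtonian
#' interior viscosities using the capsule indicator functions:
#' \deqn{\mu(x) = \mu_{ext}(\dot\gamma)(1 - I_{cell})
#'   + \lambda \mu_0 (I_{cell} - I_{nucleus})
#'   + \lambda_n \mu_0 I_{nucleus}.}
#'
#' @param I_cell,I_nucleus indicator arrays in `[0,1]` (`I_nucleus` may be
#'   `NULL`).
#' @param gamma_dot local shear rate array (1/s).
#' @param fluid a [fluid_model()].
#' @param lambda,lambda_n cytoplasm and nucleus viscosity ratios.
#' @return viscosity array (Pa s).
#' @export
blended_viscosity <- function(I_cell, gamma_dot, fluid, lambda = 1,
                              I_nucleus = NULL, lambda_n = lambda) {
  if (is.null(I_nucleus)) I_nucleus <- array(0, dim(I_cell))
  In <- pmin(I_nucleus, I_cell)
  mu_ext <- power_law_viscosity(gamma_dot, fluid)
  mu_ext * (1 - I_cell) + lambda * fluid$mu0 * (I_cell - In) +
    lambda_n * fluid$mu0 * In
}

#' Point-in-mesh test by ray casting
#'
#' Geometric oracle for indicator-function checks: counts crossings of the
#' ray from each query point along +x with the mesh triangles.
#'
#' @param mesh a closed [tri_mesh()].
#' @param points n x 3 matrix of query points (same units as the mesh).
#' @return logical vector, `TRUE` when inside.
#' @export
point_in_mesh <- function(mesh, points) {
  points <- as.matrix(points)
  V <- mesh$vertices
  Tr <- mesh$triangles
  A <- V[Tr[, 1], , drop = FALSE]
  B <- V[Tr[, 2], , drop = FALSE]
  C <- V[Tr[, 3], , drop = FALSE]
  # slightly tilted ray direction avoids exact vertex/edge hits on
  # axis-aligned meshes
  dir <- c(1, 1e-3 * pi, 1e-3 * exp(1))
  dir <- dir / sqrt(sum(dir^2))
  e1 <- B - A
  e2 <- C - A
  hx <- dir[2] * e2[, 3] - dir[3] * e2[, 2]
  hy <- dir[3] * e2[, 1] - dir[1] * e2[, 3]
  hz <- dir[1] * e2[, 2] - dir[2] * e2[, 1]
  a <- e1[, 1] * hx + e1[, 2] * hy + e1[, 3] * hz
  ok <- abs(a) > 1e-14 * max(abs(e1))
  apply(points, 1, function(p) {
    s <- sweep(A, 2, p, "-") * -1
    u <- (s[, 1] * hx + s[, 2] * hy + s[, 3] * hz) / a
    qx <- s[, 2] * e1[, 3] - s[, 3] * e1[, 2]
    qy <- s[, 3] * e1[, 1] - s[, 1] * e1[, 3]
    qz <- s[, 1] * e1[, 2] - s[, 2] * e1[, 1]
    v <- (dir[1] * qx + dir[2] * qy + dir[3] * qz) / a
    t <- (e2[, 1] * qx + e2[, 2] * qy + e2[, 3] * qz) / a
    hit <- ok & u >= 0 & v >= 0 & (u + v) <= 1 & t > 0
    sum(hit) %% 2 == 1
  })
}
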