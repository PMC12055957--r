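#' Transit simulation configuration
#'
#' Bundles everything needed for a full cell-transit simulation: the channel
#' geometry, the fluid, the cell's dimensionless groups, the release state
#' and the numerical controls.  Dimensional membrane properties are derived
#' from the groups at the channel flow conditions (`Gs = mu0 U / Ca`,
#' `mu_s = eta mu0 a`, `kc = 0.001 Gs a^2`; nucleus moduli twice the cell's,
#' no nucleus membrane viscosity).
#'
#' @param geometry a `channel_geometry` from [build_constricted()] or
#'   [build_cross_slot()].
#' @param fluid a [fluid_model()].
#' @param U target mean duct speed (m/s) in a branch / the narrow channel.
#' @param Ca,C,eta,lambda dimensionless groups of the cell.
#' @param confinement cell confinement ratio `2a/l`.
#' @param an_over_a nucleus size ratio (0 disables the nucleus).
#' @param d_oc_z,d_oc_y initial off-centre offsets as fractions of `l`.
#' @param release_x release position of the cell centre along x (m).
#' @param mesh_subdiv octahedron subdivisions for the cell membrane mesh.
#' @param mesh_subdiv_nucleus subdivisions for the nucleus mesh.
#' @param dt_safety safety factor in the membrane-stiffness time-step bound
#'   `dt <= dt_safety * mu0 dx / (Gsn (1 + 2C))`.
#' @param u_lat_max compressibility control: peak lattice speed budget.
#' @param record_every recording cadence in time steps.
#' @param max_tstar hard stop, in units of `l/U`.
#' @param vel_filter_beta blending factor of the exponential smoothing
#'   applied to the vertex velocities entering the membrane viscous stress
#'   (stabilises the stiff explicit surface-viscosity coupling).
#' @param control extra solver controls passed to [lbm_sim()].
#' @return object of class `transit_config`.
#' @export
transit_config <- function(geometry, fluid = fluid_model(), U,
                           Ca, C, eta = 0, lambda = 1,
                           confinement, an_over_a = 0.5,
                           d_oc_z = 0, d_oc_y = 0,
                           release_x = NULL,
                           mesh_subdiv = 3, mesh_subdiv_nucleus = 2,
                           dt_safety = 0.3, u_lat_max = 0.05,
                           record_every = 40, max_tstar = 20,
                           vel_filter_beta = 0.05,
                           control = list()) {
  stopifnot(inherits(geometry, "channel_geometry"), U > 0, Ca > 0, C >= 0,
            eta >= 0, confinement > 0, confinement < 1)
  if (abs(d_oc_z) >= 0.1 || abs(d_oc_y) >= 0.1)
    stop("off-centre offsets must satisfy |d| < 0.1 l")
  l <- geometry$params$l
  a <- confinement * l / 2
  Gs <- fluid$mu0 * U / Ca
  cell <- cell_params(a = a, Gs = Gs, C = C, mu_s = eta * fluid$mu0 * a,
                      mu_c = lambda * fluid$mu0, an_over_a = an_over_a)
  if (is.null(release_x)) {
    release_x <- if (geometry$kind == "constricted") -60e-6 else
      geometry$corner[1] + 2.5 * a
  }
  structure(list(geometry = geometry, fluid = fluid, U = U,
                 groups = list(Ca = Ca, C = C, eta = eta, lambda = lambda,
                               confinement = confinement,
                               an_over_a = an_over_a),
                 cell = cell, d_oc_z = d_oc_z, d_oc_y = d_oc_y,
                 release_x = release_x, mesh_subdiv = mesh_subdiv,
                 mesh_subdiv_nucleus = mesh_subdiv_nucleus,
                 dt_safety = dt_safety, u_lat_max = u_lat_max,
                 record_every = record_every, max_tstar = max_tstar,
                 vel_filter_beta = vel_filter_beta, control = control),
            class = "transit_config")
}

#' Global time step of a transit configuration
#'
#' The smaller of the membrane-stiffness bound
#' `dt_safety * mu0 dx / (Gsn (1 + 2C))` (the nucleus membrane is the
#' stiffest spring) and the lattice compressibility bound.
#'
#' @param config a [transit_config()].
#' @return time step (s).
#' @export
transit_dt <- function(config) {
  g <- config$geometry
  cell <- config$cell
  # stiffest membrane: nucleus moduli are Gsn (1 + 2C)
  stiff <- max(cell$Gs * (1 + 2 * cell$C),
               if (cell$an_over_a > 0) cell$Gsn * (1 + 2 * cell$C) else 0)
  dt_mem <- config$dt_safety * config$fluid$mu0 * g$dx / stiff
  dt_lat <- config$u_lat_max * g$dx / (2.5 * config$U)
  min(dt_mem, dt_lat)
}

#' Calibrate the inlet/outlet pressure difference
#'
#' Finds the constant pressure difference that drives the cell-free channel
#' at the target flow rate, as in the experimental protocol: secant
#' iteration on the density difference applied at the pressure planes, each
#' evaluation run to a steady flow rate on a mid-channel plane.
#'
#' @param geometry a `channel_geometry`.
#' @param fluid a [fluid_model()].
#' @param target_Q target volumetric flow rate per inlet branch (m^3/s).
#' @param dt time step (s); defaults to a pure-fluid choice.
#' @param tol relative flow-rate tolerance (default 0.5%).
#' @param max_iter secant iteration cap.
#' @param control solver controls for [lbm_sim()].
#' @return list with `dp` (Pa), `Q` (m^3/s), `sim` (the warm simulation) and
#'   `drho` (lattice density difference).
#' @export
calibrate_pressure <- function(geometry, fluid = fluid_model(), target_Q,
                               dt = NULL, tol = 0.005, max_iter = 20,
                               control = list()) {
  g <- geometry
  l <- g$params$l
  U <- target_Q / l^2
  if (target_Q == 0)
    return(list(dp = 0, Q = 0, sim = NULL, drho = 0))
  if (is.null(dt)) dt <- 0.04 * g$dx / (2.5 * U)
  sim <- lbm_sim(g$flags, fluid, g$dx, dt, planes = g$planes,
                 qlink = g$qlink, origin = g$corner, control = control)
  co <- node_coords(g)
  if (g$kind == "constricted") {
    x_meas <- g$params$straight_len / 2
  } else {
    x_meas <- -(l / 2 + g$params$feed_len / 2)
  }
  i_meas <- which.min(abs(co$x - x_meas))
  inlets <- which(g$planes$role == "inlet")
  outlets <- which(g$planes$role == "outlet")
  set_dp <- function(drho) {
    for (p in inlets) lbm_set_plane_rho(sim, p, 1 + drho / 2)
    for (p in outlets) lbm_set_plane_rho(sim, p, 1 - drho / 2)
  }
  nu_lat <- (fluid$mu0 / fluid$rho) * dt / g$dx^2
  chunk <- max(200L, as.integer(ceiling(g$params$nodes_per_l^2 / nu_lat / 3)))
  measure <- function() {
    qold <- Inf
    for (it in 1:40) {
      lbm_step(sim, chunk)
      q <- sim_flow_rate(sim$ptr, 0L, i_meas)
      if (is.finite(qold) && abs(q - qold) <= 1e-4 * abs(q)) return(q)
      qold <- q
    }
    qold
  }
  # initial guess from the square-duct resistance of an effective length
  s <- seq(1, 199, 2)
  bracket <- 1 - (192 / pi^5) * sum(tanh(s * pi / 2) / s^5)
  b <- l / 2
  Leff <- if (g$kind == "constricted")
    g$params$straight_len + g$params$converging_len / 2 else
    g$params$feed_len + g$params$other_len + l
  dp1 <- target_Q * 3 * fluid$mu0 * Leff / (4 * b^4 * bracket)
  conv <- (1 / 3) * fluid$rho * (g$dx / dt)^2  # dp per unit drho
  d1 <- dp1 / conv
  set_dp(d1)
  q1 <- measure()
  d2 <- d1 * target_Q / q1
  for (it in 1:max_iter) {
    set_dp(d2)
    q2 <- measure()
    if (abs(q2 - target_Q) <= tol * target_Q)
      return(list(dp = d2 * conv, Q = q2, sim = sim, drho = d2,
                  state = sim_get_state(sim$ptr)))
    dnew <- d2 + (target_Q - q2) * (d2 - d1) / (q2 - q1)
    d1 <- d2; q1 <- q2
    d2 <- dnew
  }
  stop("pressure calibration did not converge in ", max_iter, " iterations")
}

#' Run a full cell transit
#'
#' Calibrates the driving pressure, releases the compound cell (outer
#' membrane plus concentric nucleus) at the configured position and offsets,
#' advances the coupled immersed-boundary lattice-Boltzmann system with a
#' single global time step, and records the trajectory: centroid, shape
#' metrics on the x-z projection, volumes and the projected contour.
#'
#' Termination: in the constricted channel, when the deformation index is
#' steady (|dDI| < 1e-3 over one channel width of travel past the
#' constriction) or the cell nears the outlet; in the cross-slot, when the
#' whole cell has left the central region (or `max_tstar` elapses).
#'
#' @param config a [transit_config()].
#' @param calibration optional result of [calibrate_pressure()] to reuse
#'   (its simulation is consumed).
#' @param verbose print progress lines.
#' @return object of class `capsule_transit`: list with `series` (data frame
#'   t, t_star, x/y/z centroid, DI, D_XZ, volumes, extremes), `contours`
#'   (list of x-z hull polylines, um), `events`, `config`, diagnostics.
#' @export
run_transit <- function(config, calibration = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "transit_config"))
  g <- config$geometry
  fluid <- config$fluid
  l <- g$params$l
  U <- config$U
  dt <- transit_dt(config)
  target_Q <- U * l^2
  if (is.null(calibration))
    calibration <- calibrate_pressure(g, fluid, target_Q, dt = dt,
                                      control = config$control)
  sim <- calibration$sim
  if (is.null(sim)) {
    # rebuild a simulation from the calibrated snapshot
    sim <- lbm_sim(g$flags, fluid, g$dx, dt, planes = g$planes,
                   qlink = g$qlink, origin = g$corner,
                   control = config$control)
    for (p in which(g$planes$role == "inlet"))
      lbm_set_plane_rho(sim, p, 1 + calibration$drho / 2)
    for (p in which(g$planes$role == "outlet"))
      lbm_set_plane_rho(sim, p, 1 - calibration$drho / 2)
    sim_set_state(sim$ptr, calibration$state)
  }
  if (abs(sim$dt - dt) > 1e-15)
    stop("calibration must be run at the transit time step")
  cell <- config$cell
  centre <- c(config$release_x, config$d_oc_y * l, config$d_oc_z * l)
  mesh <- make_sphere_mesh(config$mesh_subdiv, cell$a, centre)
  sim <- lbm_add_capsule(sim, mesh, Gs = cell$Gs, C = cell$C,
                         mu_s = cell$mu_s, mu_s_dil = cell$mu_s_dil,
                         kc = cell$kc, c0 = cell$c0, lambda = config$groups$lambda)
  has_nucleus <- cell$an_over_a > 0
  if (has_nucleus) {
    nmesh <- make_sphere_mesh(config$mesh_subdiv_nucleus, cell$an, centre)
    sim <- lbm_add_capsule(sim, nmesh, Gs = cell$Gsn, C = cell$C,
                           mu_s = 0, mu_s_dil = 0, kc = cell$kcn, c0 = 0,
                           lambda = config$groups$lambda)
  }
  sim_set_filter_beta(sim$ptr, config$vel_filter_beta)
  tstar_unit <- l / U
  rec_steps <- config$record_every
  max_steps <- ceiling(config$max_tstar * tstar_unit / dt)
  st0 <- lbm_capsule_state(sim, 1)
  vol0 <- st0$volume
  voln0 <- if (has_nucleus) lbm_capsule_state(sim, 2)$volume else NA_real_
  rows <- list()
  contours <- list()
  k <- 0
  steady <- FALSE
  exited_at <- NA_real_
  di_hist <- numeric()
  x_hist <- numeric()
  record <- function(step) {
    st <- lbm_capsule_state(sim, 1)
    V <- st$vertices
    ctr <- colMeans(V)
    prof <- contour_profile(cbind(V[, 1], V[, 3]) * 1e6)
    di <- deformation_index(prof)
    dxz <- taylor_parameter(prof)
    voln <- if (has_nucleus) lbm_capsule_state(sim, 2)$volume else NA_real_
    k <<- k + 1
    rows[[k]] <<- data.frame(
      step = step, t = step * dt, t_star = step * dt / tstar_unit,
      x = ctr[1], y = ctr[2], z = ctr[3],
      DI = di, D_XZ = dxz,
      volume = st$volume, volume_nucleus = voln,
      xmin = min(V[, 1]), xmax = max(V[, 1]),
      zmin = min(V[, 3]), zmax = max(V[, 3]))
    contours[[k]] <<- prof$points
    invisible(NULL)
  }
  record(0L)
  step <- 0L
  while (step < max_steps) {
    lbm_step(sim, rec_steps)
    step <- step + rec_steps
    record(step)
    r <- rows[[k]]
    if (any(!is.finite(unlist(r[c("x", "DI")]))))
      stop("transit diverged at step ", step,
           " (time step too large for the membrane stiffness)")
    if (verbose && k %% 20 == 0)
      message(sprintf("t* = %.2f  x = %.1f um  DI = %.3f  D_XZ = %.3f",
                      r$t_star, r$x * 1e6, r$DI, r$D_XZ))
    if (g$kind == "constricted") {
      di_hist <- c(di_hist, r$DI)
      x_hist <- c(x_hist, r$x)
      if (r$x > 2 * l) {
        past <- which(x_hist <= r$x - l)
        if (length(past)) {
          if (abs(r$DI - di_hist[max(past)]) < 1e-3) {
            steady <- TRUE
            break
          }
        }
      }
      if (r$x > g$params$straight_len - 2.5 * cell$a) break
    } else {
      exited <- (r$zmin > l / 2) || (r$zmax < -l / 2)
      if (exited && is.na(exited_at)) exited_at <- r$t_star
      if (!is.na(exited_at) && r$t_star > exited_at + 0.3) break
      if (abs(r$z) > l / 2 + 2.5 * cell$a) break
    }
  }
  series <- do.call(rbind, rows)
  events <- list(steady = steady)
  if (g$kind == "cross_slot") {
    # entry: forefront (max vertex x) crossing -l/2
    ei <- which(series$xmax >= -l / 2)
    events$entry_tstar <- if (length(ei)) {
      i <- ei[1]
      if (i == 1) series$t_star[1] else {
        approx(series$xmax[(i - 1):i], series$t_star[(i - 1):i],
               xout = -l / 2)$y
      }
    } else NA_real_
    # closest approach to the stagnation point (channel centre)
    d2 <- series$x^2 + series$z^2
    events$closest_approach_tstar <- series$t_star[which.min(d2)]
  }
  out <- structure(list(
    series = series, contours = contours, events = events, config = config,
    dt = dt, dp = calibration$dp, Q = calibration$Q,
    volume_drift = max(abs(series$volume / vol0 - 1)),
    volume_drift_nucleus = if (has_nucleus)
      max(abs(series$volume_nucleus / voln0 - 1)) else NA_real_,
    sim = sim), class = "capsule_transit")
  out
}

#' Residence time in the cross-slot
#'
#' Dimensionless time, in units of `l/U`, between the cell's forefront
#' crossing the entry plane `x = -l/2` (defining t* = 0) and the whole cell
#' leaving the central cross region.
#'
#' @param record a `capsule_transit` from a cross-slot run.
#' @return t* at complete exit, or `NA` with attribute `not_exited = TRUE`
#'   if the run ended first (a perfectly centred cell is trapped at the
#'   stagnation point by symmetry).
#' @export
residence_time <- function(record) {
  stopifnot(inherits(record, "capsule_transit"))
  if (record$config$geometry$kind != "cross_slot")
    stop("residence_time needs a cross-slot transit record")
  if (is.null(record$events$entry_tstar) || is.na(record$events$entry_tstar))
    stop("record lacks an entry event (cell never reached x = -l/2)")
  l <- record$config$geometry$params$l
  s <- record$series
  t0 <- record$events$entry_tstar
  # exit when every vertex has |z| beyond l/2 (the cell leaves along z)
  out_up <- s$zmin > l / 2
  out_dn <- s$zmax < -l / 2
  out <- out_up | out_dn
  if (!any(out)) {
    res <- NA_real_
    attr(res, "not_exited") <- TRUE
    return(res)
  }
  i <- which(out)[1]
  texit <- if (i == 1) s$t_star[1] else {
    v <- if (out_up[i]) s$zmin else -s$zmax
    stats::approx(v[(i - 1):i], s$t_star[(i - 1):i], xout = l / 2)$y
  }
  texit - t0
}

#' @export
print.capsule_transit <- function(x, ...) {
  s <- x$series
  cat(sprintf("capsule_transit (%s): %d frames, t* up to %.2f\n",
              x$config$geometry$kind, nrow(s), max(s$t_star)))
  cat(sprintf("  DI range %.3f..%.3f, D_XZ range %.3f..%.3f\n",
              min(s$DI), max(s$DI), min(s$D_XZ), max(s$D_XZ)))
  cat(sprintf("  volume drift %.2f%%, dp = %.1f Pa\n",
              100 * x$volume_drift, x$dp))
  invisible(x)
}

#' @export
plot.capsule_transit <- function(x, which = c("DI", "D_XZ", "z"), ...) {
  which <- match.arg(which)
  s <- x$series
  if (x$config$geometry$kind == "constricted" && which == "DI") {
    plot(s$x * 1e6, s$DI, type = "l", xlab = "x (um)",
         ylab = "deformation index", ...)
  } else if (which == "z") {
    plot(s$t_star, s$z / x$config$geometry$params$l, type = "l",
         xlab = "t*", ylab = "z / l", ...)
  } else {
    plot(s$t_star, s[[which]], type = "l", xlab = "t*", ylab = which, ...)
  }
  invisible(x)
}
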