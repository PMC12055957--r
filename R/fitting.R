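#' Parameter scan grid for inverse fitting
#'
#' The default grid covers the standard deformability-cytometry scan: capillary number
#' 0.1..5 in steps of 0.1, hardness 1..50 in steps of 1, dimensionless
#' membrane viscosity 0..80 in steps of 5, and initial off-centre distance
#' 0.001 l .. 0.016 l in steps of 0.001 l.
#'
#' @param Ca,C,eta,d_oc numeric grids (strictly increasing).
#' @return list of class `fit_grid` with the grids and their increments.
#' @export
fit_grid <- function(Ca = seq(0.1, 5, by = 0.1), C = 1:50,
                     eta = seq(0, 80, by = 5),
                     d_oc = seq(0.001, 0.016, by = 0.001)) {
  chk <- function(x) length(x) >= 1 && all(diff(x) > 0)
  stopifnot(chk(Ca), chk(C), chk(eta), chk(d_oc), all(Ca > 0))
  inc <- function(x) if (length(x) > 1) x[2] - x[1] else 0
  structure(list(Ca = Ca, C = C, eta = eta, d_oc = d_oc,
                 dCa = inc(Ca), dC = inc(C), deta = inc(eta),
                 dd = inc(d_oc)),
            class = "fit_grid")
}

#' Stage 1: fit membrane elastic moduli from the steady shape
#'
#' Shortlists the (Ca, C) candidates whose steady deformation index matches
#' the observed one within `tol_DI`, then selects the candidate whose steady
#' contour has the minimum mean Hausdorff distance from the observed
#' contour.  Ties break towards the lowest Ca, then the lowest C.  If no
#' candidate passes the DI gate, the global MHD minimum is returned with a
#' warning flag.
#'
#' @param exp_contour observed steady contour ([contour_profile()] or n x 2
#'   matrix, um).
#' @param exp_DI observed steady deformation index.
#' @param library list of candidates, each a list with elements `Ca`, `C`,
#'   `DI` (steady) and `contour`.
#' @param tol_DI half-width of the DI shortlist gate.
#' @return list with `Ca`, `C`, `mhd` (at the optimum), `table` (data frame
#'   Ca, C, DI, mhd, shortlisted) and `empty_shortlist` flag.
#' @export
fit_steady <- function(exp_contour, exp_DI, library, tol_DI = 0.005) {
  stopifnot(length(library) >= 1)
  tab <- do.call(rbind, lapply(library, function(e) {
    data.frame(Ca = e$Ca, C = e$C, DI = e$DI,
               mhd = mean_hausdorff(e$contour, exp_contour))
  }))
  tab$shortlisted <- abs(tab$DI - exp_DI) <= tol_DI
  empty <- !any(tab$shortlisted)
  if (empty) {
    warning("no candidate matches the steady DI within tol_DI; ",
            "returning the global MHD minimum")
    cand <- tab
  } else {
    cand <- tab[tab$shortlisted, , drop = FALSE]
  }
  cand <- cand[order(cand$mhd, cand$Ca, cand$C), , drop = FALSE]
  list(Ca = cand$Ca[1], C = cand$C[1], mhd = cand$mhd[1], table = tab,
       empty_shortlist = empty)
}

#' Stage 2: fit the membrane viscosity from the transient deformation
#'
#' With (Ca, C) fixed by the steady fit, selects the dimensionless membrane
#' viscosity whose simulated deformation-index series best matches the
#' observed series in root-mean-square over the common abscissa range
#' (position in the constricted channel, or time in the cross-slot).
#' Candidates whose RMS exceeds `flag_factor` times the minimum are flagged
#' (an `eta = 0`, purely hyperelastic model typically lands here when the
#' observation is viscoelastic).
#'
#' @param exp_series data frame with columns `s` (abscissa) and `value`.
#' @param library list of candidates, each a list with `eta` and `series`
#'   (data frame `s`, `value`).
#' @param flag_factor RMS ratio above which a candidate is flagged.
#' @param min_overlap minimum common abscissa span, as a fraction of the
#'   observed span.
#' @return list with `eta`, `rms` (at optimum), `table` (eta, rms, flagged).
#' @export
fit_membrane_viscosity <- function(exp_series, library, flag_factor = 2,
                                   min_overlap = 0.5) {
  stopifnot(length(library) >= 1, all(c("s", "value") %in% names(exp_series)))
  rng_obs <- range(exp_series$s)
  rms <- vapply(library, function(e) {
    rng <- c(max(rng_obs[1], min(e$series$s)), min(rng_obs[2], max(e$series$s)))
    if (diff(rng) < min_overlap * diff(rng_obs))
      stop("simulated series overlaps less than ",
           round(100 * min_overlap), "% of the observed range")
    so <- seq(rng[1], rng[2], length.out = 200)
    a <- stats::approx(exp_series$s, exp_series$value, xout = so)$y
    b <- stats::approx(e$series$s, e$series$value, xout = so)$y
    sqrt(mean((a - b)^2))
  }, numeric(1))
  etas <- vapply(library, `[[`, numeric(1), "eta")
  tab <- data.frame(eta = etas, rms = rms,
                    flagged = rms > flag_factor * min(rms))
  i <- order(tab$rms, tab$eta)[1]
  list(eta = tab$eta[i], rms = tab$rms[i], table = tab)
}

#' Stage 3: infer the initial off-centre distance in the cross-slot
#'
#' Matches the observed centre-of-mass trajectory z(t*) against a library of
#' hyperelastic (eta = 0) simulations over the off-centre grid; membrane
#' viscosity hardly affects the residence time, so the cheap hyperelastic
#' library suffices.  A trajectory exiting towards -z is mirrored and the
#' returned offset carries a negative sign.
#'
#' @param exp_traj data frame `t_star`, `z` (m) of the observed cell centre;
#'   must leave the cross-slot (|z| exceeding l/2 by the end).
#' @param library list of candidates with `d_oc` (fraction of l) and
#'   `series` (data frame `t_star`, `z`).
#' @param l branch width (m).
#' @return list with `d_oc` (signed, fraction of l), `rms`, `table`.
#' @export
fit_offcenter <- function(exp_traj, library, l) {
  stopifnot(all(c("t_star", "z") %in% names(exp_traj)), length(library) >= 1)
  if (max(abs(exp_traj$z)) < l / 2)
    stop("observed cell never exits the cross-slot; off-centre distance ",
         "cannot be inferred from this trajectory")
  sgn <- sign(exp_traj$z[which.max(abs(exp_traj$z))])
  zobs <- exp_traj$z * sgn
  rms <- vapply(library, function(e) {
    rng <- c(max(min(exp_traj$t_star), min(e$series$t_star)),
             min(max(exp_traj$t_star), max(e$series$t_star)))
    so <- seq(rng[1], rng[2], length.out = 200)
    a <- stats::approx(exp_traj$t_star, zobs, xout = so)$y
    b <- stats::approx(e$series$t_star, e$series$z, xout = so)$y
    sqrt(mean((a - b)^2))
  }, numeric(1))
  ds <- vapply(library, `[[`, numeric(1), "d_oc")
  tab <- data.frame(d_oc = ds, rms = rms)
  i <- order(tab$rms, tab$d_oc)[1]
  list(d_oc = sgn * tab$d_oc[i], rms = tab$rms[i], table = tab)
}

#' Assemble a cell-property fit
#'
#' Combines the fitting stages into a classed result carrying the inferred
#' dimensionless groups, their half-increment uncertainties and the
#' dimensional membrane properties.
#'
#' @param Ca,C,eta best-fit groups (on the grid).
#' @param d_oc inferred off-centre fraction (optional).
#' @param mhd MHD at the steady-fit optimum (um).
#' @param grid the [fit_grid()] used.
#' @param fluid a [fluid_model()].
#' @param U mean duct speed (m/s).
#' @param a cell radius (m).
#' @return object of class `capsule_fit`.
#' @export
capsule_fit <- function(Ca, C, eta, d_oc = NA_real_, mhd = NA_real_,
                        grid = fit_grid(), fluid = fluid_model(), U, a) {
  dim <- propagate_uncertainty(Ca, C, eta, grid$dCa, grid$dC, grid$deta,
                               fluid, U, a)
  structure(list(Ca = Ca, C = C, eta = eta, d_oc = d_oc, mhd = mhd,
                 grid = grid, fluid = fluid, U = U, a = a,
                 dimensional = dim),
            class = "capsule_fit")
}

#' Dimensional summary of a fit in the style of a property table
#'
#' @param fit a [capsule_fit()].
#' @return data.frame with one row: `a_um`, `Gs_mN_m` and uncertainty,
#'   `Ks_mN_m` and uncertainty, `mu_s_uNs_m` and uncertainty.
#' @export
report <- function(fit) {
  stopifnot(inherits(fit, "capsule_fit"))
  d <- fit$dimensional
  data.frame(a_um = fit$a * 1e6,
             Gs_mN_m = d$Gs * 1e3, dGs_mN_m = d$dGs * 1e3,
             Ks_mN_m = d$Ks * 1e3, dKs_mN_m = d$dKs * 1e3,
             mu_s_uNs_m = d$mu_s * 1e6, dmu_s_uNs_m = d$dmu_s * 1e6)
}

#' @export
print.capsule_fit <- function(x, ...) {
  d <- x$dimensional
  cat("capsule_fit\n")
  cat(sprintf("  Ca = %.3g  C = %.3g  eta = %.3g%s\n", x$Ca, x$C, x$eta,
              if (is.na(x$d_oc)) "" else sprintf("  d_oc = %.3g l", x$d_oc)))
  if (!is.na(x$mhd)) cat(sprintf("  MHD at optimum: %.3g um\n", x$mhd))
  cat(sprintf("  Gs = %.3g +- %.2g mN/m\n", d$Gs * 1e3, d$dGs * 1e3))
  cat(sprintf("  Ks = %.3g +- %.3g mN/m\n", d$Ks * 1e3, d$dKs * 1e3))
  cat(sprintf("  mu_s = %.3g +- %.2g uN s/m\n", d$mu_s * 1e6, d$dmu_s * 1e6))
  invisible(x)
}

#' @export
summary.capsule_fit <- function(object, ...) {
  print(object)
  invisible(report(object))
}

#' @export
coef.capsule_fit <- function(object, ...) {
  c(Ca = object$Ca, C = object$C, eta = object$eta, d_oc = object$d_oc)
}
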