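ellipse_contour <- function(ar, r = 5, n = 128) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * ar * cos(th), r * sin(th))
}

test_that("the default scan grid spans the deformability-cytometry ranges", {
  g <- fit_grid()
  expect_equal(range(g$Ca), c(0.1, 5))
  expect_equal(g$dCa, 0.1)
  expect_equal(range(g$C), c(1, 50))
  expect_equal(g$dC, 1)
  expect_equal(range(g$eta), c(0, 80))
  expect_equal(g$deta, 5)
  expect_equal(range(g$d_oc), c(0.001, 0.016))
  expect_error(fit_grid(Ca = c(2, 1)), "increasing|TRUE")
})

test_that("steady-shape selection minimises the MHD among DI-matched candidates", {
  # three candidates that all capture the steady DI; the middle one has the
  # closest contour, mirroring the printed MHDs {0.70, 0.52, 0.76} um
  obs <- ellipse_contour(1.6)
  obs_di <- deformation_index(contour_profile(obs))
  shift <- function(P, d) P + matrix(c(0, d), nrow(P), 2, byrow = TRUE)
  mk <- function(Ca, C, mhd_off) {
    # build a contour at a controlled MHD from the observation by radial
    # perturbation
    th <- atan2(obs[, 2] / 1, obs[, 1] / 1.6)
    P <- obs + mhd_off * cbind(cos(th), sin(th))
    list(Ca = Ca, C = C, DI = obs_di + 0.002, contour = P)
  }
  lib <- list(mk(0.7, 1, 0.70), mk(0.6, 10, 0.52), mk(0.5, 50, 0.76))
  fit <- fit_steady(obs, obs_di, lib)
  expect_equal(fit$C, 10)
  expect_equal(fit$Ca, 0.6)
  expect_false(fit$empty_shortlist)
  expect_true(all(fit$table$shortlisted))
  expect_equal(order(fit$table$mhd)[1], 2)
  # measured MHDs scale with the imposed radial offsets
  expect_equal(fit$table$mhd, c(0.70, 0.52, 0.76), tolerance = 0.1)
  # single candidate returns itself
  f1 <- fit_steady(obs, obs_di, lib[2])
  expect_equal(f1$C, 10)
  # DI gate excludes mismatched candidates even at low MHD
  lib2 <- c(lib, list(list(Ca = 1, C = 5, DI = obs_di + 0.2, contour = obs)))
  f2 <- fit_steady(obs, obs_di, lib2)
  expect_equal(f2$C, 10)
  # empty shortlist falls back to the global minimum with a warning
  lib3 <- lapply(lib, function(e) { e$DI <- e$DI + 0.5; e })
  expect_warning(f3 <- fit_steady(obs, obs_di, lib3), "tol_DI")
  expect_true(f3$empty_shortlist)
  expect_equal(f3$C, 10)
})

test_that("ties in MHD break towards the lowest Ca then lowest C", {
  obs <- ellipse_contour(1.5)
  di <- deformation_index(contour_profile(obs))
  e <- list(DI = di, contour = obs)
  lib <- list(c(list(Ca = 0.8, C = 5), e), c(list(Ca = 0.4, C = 9), e),
              c(list(Ca = 0.4, C = 3), e))
  fit <- fit_steady(obs, di, lib)
  expect_equal(fit$Ca, 0.4)
  expect_equal(fit$C, 3)
})

test_that("membrane-viscosity fitting recovers the generating series", {
  # synthetic DI-vs-position series with an eta-dependent relaxation scale
  mkseries <- function(eta, s = seq(0, 10, by = 0.1)) {
    data.frame(s = s, value = 0.3 + 0.25 * exp(-s / (1 + eta / 20)))
  }
  lib <- lapply(c(0, 20, 40, 60), function(e) list(eta = e,
                                                   series = mkseries(e)))
  obs <- mkseries(40)
  fit <- fit_membrane_viscosity(obs, lib)
  expect_equal(fit$eta, 40)
  expect_equal(fit$rms, 0, tolerance = 1e-12)
  # the hyperelastic (eta = 0) candidate is flagged as under-damped
  expect_true(fit$table$flagged[fit$table$eta == 0])
  # insufficient overlap is rejected
  short <- list(list(eta = 0, series = mkseries(0, s = seq(8, 10, 0.1))))
  expect_error(fit_membrane_viscosity(obs, short), "overlap")
})

test_that("off-centre inference matches trajectories with sign convention", {
  l <- 40e-6
  mktraj <- function(d, sgn = 1) {
    t <- seq(0, 4, by = 0.05)
    # exponential escape from the stagnation point, rate set by d
    data.frame(t_star = t, z = sgn * d * l * exp(t / 0.8))
  }
  lib <- lapply(c(0.004, 0.007, 0.012), function(d)
    list(d_oc = d, series = mktraj(d)))
  fit <- fit_offcenter(mktraj(0.007), lib, l)
  expect_equal(fit$d_oc, 0.007)
  # mirror-symmetric trajectory returns a negative offset
  fitm <- fit_offcenter(mktraj(0.007, sgn = -1), lib, l)
  expect_equal(fitm$d_oc, -0.007)
  # trapped cell (never exits) is rejected
  stuck <- data.frame(t_star = seq(0, 4, 0.05), z = rep(1e-7, 81))
  expect_error(fit_offcenter(stuck, lib, l), "never exits")
})

test_that("the assembled fit reports the dimensional property table", {
  fit <- capsule_fit(Ca = 0.6, C = 10, eta = 80, mhd = 0.52,
                     fluid = fluid_model(), U = 0.19, a = 7.4e-6)
  r <- report(fit)
  expect_equal(r$Gs_mN_m, 10.4, tolerance = 0.005)
  expect_equal(r$Ks_mN_m, 217, tolerance = 0.005)
  expect_equal(r$mu_s_uNs_m, 19.4, tolerance = 0.005)
  expect_equal(r$dGs_mN_m, 0.9, tolerance = 0.05)
  expect_equal(r$dKs_mN_m, 21, tolerance = 0.01)
  expect_equal(r$dmu_s_uNs_m, 0.6, tolerance = 0.01)
  expect_equal(unname(coef(fit)["eta"]), 80)
  expect_output(print(fit), "Gs")
  # eta = 0: zero viscosity with a one-half-increment bound
  f0 <- capsule_fit(1.0, 10, 0, fluid = fluid_model(mu0 = 0.0339),
                    U = 0.17, a = 8.6e-6)
  expect_equal(report(f0)$mu_s_uNs_m, 0)
  expect_gt(report(f0)$dmu_s_uNs_m, 0)
})
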