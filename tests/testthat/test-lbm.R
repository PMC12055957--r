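# Flow-solver benchmarks against closed-form oracles.  Small lattices keep
# each case to a few seconds.

walled_box <- function(nx, ny, nz) {
  fl <- array(1L, c(nx, ny, nz))
  fl[, , 1] <- 0L
  fl[, , nz] <- 0L
  fl
}

test_that("uniform equilibrium is a fixed point and mass is conserved", {
  fl <- array(1L, c(6, 6, 12)); fl[, , 1] <- 0L; fl[, , 12] <- 0L
  flu <- fluid_model(K = 1e-3, alpha = 1, rho = 1000, mu0 = 1e-3)
  sim <- lbm_sim(fl, flu, dx = 1e-5, dt = 2e-5,
                 periodic = c(TRUE, TRUE, FALSE), newtonian = TRUE, tau = 0.9)
  m0 <- lbm_mass(sim)
  lbm_step(sim, 200)
  f <- lbm_fields(sim)
  expect_lt(max(abs(f$ux), abs(f$uy), abs(f$uz)), 1e-14)
  expect_equal(max(abs(f$rho[, , 2:11] - 1)), 0, tolerance = 1e-13)
  # mid-link bounce-back walls conserve mass to rounding
  expect_lt(abs(lbm_mass(sim) / m0 - 1), 1e-12)
})

test_that("body-force plane Poiseuille matches the parabolic profile", {
  nzn <- 34
  fl <- walled_box(4, 4, nzn)
  flu <- fluid_model(K = 1e-3, alpha = 1, rho = 1000, mu0 = 1e-3)
  dx <- 1e-5; dt <- 2e-5
  sim <- lbm_sim(fl, flu, dx, dt, periodic = c(TRUE, TRUE, FALSE),
                 newtonian = TRUE, tau = 1.1)
  G <- 1
  lbm_set_body_force(sim, c(G, 0, 0))
  lbm_step(sim, 6000)
  ux <- lbm_fields(sim)$ux[1, 1, ]
  z <- ((1:nzn) - 0.5) * dx
  zc <- mean(range(z))
  h <- (nzn - 2) * dx / 2
  ora <- analytic_flow_fixtures("plane_poiseuille_newtonian",
                                list(G = G, mu = 1e-3, h = h),
                                coords = list(z = z - zc))
  i <- 2:(nzn - 1)
  expect_lt(max(abs(ux[i] - ora$u[i])) / max(ora$u), 0.01)
})

test_that("power-law channel flow and shear rate match the analytic form", {
  nzn <- 34
  fl <- walled_box(4, 4, nzn)
  flu <- fluid_model()   # K = 0.053, alpha = 0.95
  dx <- 2.5e-6; dt <- 2e-8
  sim <- lbm_sim(fl, flu, dx, dt, periodic = c(TRUE, TRUE, FALSE))
  G <- 2e8
  lbm_set_body_force(sim, c(G, 0, 0))
  lbm_step(sim, 8000)
  f <- lbm_fields(sim)
  ux <- f$ux[1, 1, ]
  z <- ((1:nzn) - 0.5) * dx
  zc <- mean(range(z))
  h <- (nzn - 2) * dx / 2
  ora <- analytic_flow_fixtures("plane_poiseuille_powerlaw",
                                list(G = G, K = flu$K, alpha = flu$alpha,
                                     gamma0 = flu$gamma0, h = h),
                                coords = list(z = z - zc))
  i <- 2:(nzn - 1)
  expect_lt(max(abs(ux[i] - ora$u[i])) / max(ora$u), 0.02)
  # local shear rate linear in the wall-normal coordinate (2%)
  gd <- f$shear_rate[1, 1, i]
  keep <- ora$gamma_dot[i] > 0.2 * max(ora$gamma_dot[i])
  expect_lt(max(abs(gd[keep] - ora$gamma_dot[i][keep]) /
                  ora$gamma_dot[i][keep]), 0.02)
  # relaxation time stays within the clamped band
  expect_true(all(f$tau[, , i] > 0.5))
  expect_true(all(f$tau[, , i] <= 20))
})

test_that("moving-wall Couette recovers linear shear exactly", {
  nzn <- 20
  fl <- array(1L, c(4, 4, nzn)); fl[, , 1] <- 0L; fl[, , nzn] <- 255L
  flu <- fluid_model(K = 1e-3, alpha = 1, rho = 1000, mu0 = 1e-3,
                     gamma_min = 1e-4)
  dx <- 1e-5; dt <- 2e-5
  uw <- 0.01
  sim <- lbm_sim(fl, flu, dx, dt, periodic = c(TRUE, TRUE, FALSE),
                 wall_u = c(uw, 0, 0))
  lbm_step(sim, 5000)
  f <- lbm_fields(sim)
  i <- 2:(nzn - 1)
  H <- (nzn - 2) * dx
  gam <- uw / H
  z <- ((1:nzn) - 0.5) * dx
  ua <- gam * (z - 1 * dx)
  expect_lt(max(abs(f$ux[1, 1, i] - ua[i])) / uw, 1e-6)
  expect_lt(max(abs(f$shear_rate[1, 1, i] - gam)) / gam, 0.01)
})

test_that("Bouzidi bounce-back places the wall at the link fraction", {
  nzn <- 20
  cz <- c(0, 0, 0, 0, 0, 1, -1, 0, 0, 0, 0, 1, -1, -1, 1, 1, -1, -1, 1)
  flu <- fluid_model(K = 1e-3, alpha = 1, rho = 1000, mu0 = 1e-3)
  dx <- 1e-5; dt <- 2e-5
  fl <- walled_box(4, 4, nzn)
  for (q in c(0.3, 0.7)) {
    ql <- array(-1, c(19, 4, 4, nzn))
    for (d in which(cz == -1)) ql[d, , , 2] <- q
    for (d in which(cz == 1)) ql[d, , , nzn - 1] <- q
    sim <- lbm_sim(fl, flu, dx, dt, periodic = c(TRUE, TRUE, FALSE),
                   qlink = ql, newtonian = TRUE, tau = 1.1)
    lbm_set_body_force(sim, c(1, 0, 0))
    lbm_step(sim, 6000)
    ux <- lbm_fields(sim)$ux[1, 1, ]
    zz <- (1:nzn) - 0.5
    i <- 2:(nzn - 1)
    co <- stats::coef(stats::lm(ux[i] ~ zz[i] + I(zz[i]^2)))
    roots <- sort(Re(polyroot(co)))
    expect_lt(abs(roots[1] - (zz[2] - q)), 0.05)
    expect_lt(abs(roots[2] - (zz[nzn - 1] + q)), 0.05)
  }
  # q = 0.5 degenerates to the standard mid-link scheme: identical fields
  ql5 <- array(-1, c(19, 4, 4, nzn))
  for (d in which(cz == -1)) ql5[d, , , 2] <- 0.5
  for (d in which(cz == 1)) ql5[d, , , nzn - 1] <- 0.5
  run <- function(ql) {
    s <- lbm_sim(fl, flu, dx, dt, periodic = c(TRUE, TRUE, FALSE),
                 qlink = ql, newtonian = TRUE, tau = 1.1)
    lbm_set_body_force(s, c(1, 0, 0))
    lbm_step(s, 500)
    lbm_fields(s)$ux
  }
  expect_equal(run(ql5), run(NULL), tolerance = 1e-13)
})

test_that("pressure-driven square duct matches the series solution", {
  nx <- 40; nw <- 18
  fl <- array(1L, c(nx, nw, nw))
  fl[, 1, ] <- 0L; fl[, nw, ] <- 0L; fl[, , 1] <- 0L; fl[, , nw] <- 0L
  fl[1, 2:(nw - 1), 2:(nw - 1)] <- 2L
  fl[nx, 2:(nw - 1), 2:(nw - 1)] <- 3L
  drho <- 1e-3
  planes <- data.frame(axis = 1, side = c(0, 1),
                       rho = c(1 + drho / 2, 1 - drho / 2))
  flu <- fluid_model(K = 1e-3, alpha = 1, rho = 1000, mu0 = 1e-3)
  dx <- 1e-5; dt <- 2e-5
  sim <- lbm_sim(fl, flu, dx, dt, planes = planes, newtonian = TRUE,
                 tau = 1.1)
  lbm_step(sim, 8000)
  Q <- lbm_flow_rate(sim, 1, nx %/% 2)
  dp <- (drho / 3) * 1000 * dx^2 / dt^2
  G <- dp / ((nx - 1) * dx)       # plane nodes sit (nx-1) dx apart
  ora <- analytic_flow_fixtures("square_duct_newtonian",
                                list(G = G, mu = 1e-3, b = (nw - 2) * dx / 2))
  expect_lt(abs(Q / ora$Q - 1), 0.02)
  # pressure decays linearly along the duct (1%)
  rx <- apply(lbm_fields(sim)$rho[, 2:(nw - 1), 2:(nw - 1)], 1, mean)
  i <- 3:(nx - 2)
  fit <- stats::lm(rx[i] ~ i)
  expect_lt(max(abs(stats::resid(fit))) / drho, 0.01)
  # equal reservoir densities drive no net flow
  sim0 <- lbm_sim(fl, flu, dx, dt,
                  planes = data.frame(axis = 1, side = c(0, 1), rho = 1),
                  newtonian = TRUE, tau = 1.1)
  lbm_step(sim0, 2000)
  expect_lt(abs(lbm_flow_rate(sim0, 1, nx %/% 2)), 1e-6 * abs(Q))
})

test_that("duct error decreases near second order under grid refinement", {
  flu <- fluid_model(K = 1e-3, alpha = 1, rho = 1000, mu0 = 1e-3)
  err <- vapply(c(6, 12, 24), function(nwf) {
    nzn <- nwf + 2
    fl <- walled_box(4, 4, nzn)
    dx <- 1.2e-4 / nwf
    dt <- dx^2 / 5e-6    # keeps tau fixed across resolutions
    sim <- lbm_sim(fl, flu, dx, dt, periodic = c(TRUE, TRUE, FALSE),
                   newtonian = TRUE, tau = 1.1)
    G <- 1
    lbm_set_body_force(sim, c(G, 0, 0))
    lbm_step(sim, as.integer(4000 * (nwf / 6)^2))
    ux <- lbm_fields(sim)$ux[1, 1, ]
    z <- ((1:nzn) - 0.5) * dx
    zc <- mean(range(z))
    h <- nwf * dx / 2
    ua <- G / (2 * 1e-3) * (h^2 - (z - zc)^2)
    i <- 2:(nzn - 1)
    max(abs(ux[i] - ua[i])) / max(ua)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  rate <- mean(log2(err[-3] / err[-1]))
  expect_gt(rate, 1.5)
})
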