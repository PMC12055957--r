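test_that("truncated power-law viscosity follows the constitutive law", {
  fl <- fluid_model()
  expect_equal(power_law_viscosity(1, fl), 0.053)
  expect_equal(power_law_viscosity(100, fl), 0.053 * 100^(-0.05),
               tolerance = 1e-12)
  # clamp at the lower truncation bound
  expect_equal(power_law_viscosity(0, fl), power_law_viscosity(0.01, fl))
  expect_equal(power_law_viscosity(0.01, fl), 0.053 * 0.01^(-0.05),
               tolerance = 1e-12)
  expect_error(power_law_viscosity(NaN, fl), "finite")
  expect_error(power_law_viscosity(-1, fl), "non-negative")
  # non-increasing in shear rate for alpha < 1, constant for alpha = 1
  g <- 10^seq(-3, 7, length.out = 50)
  expect_true(all(diff(power_law_viscosity(g, fl)) <= 0))
  fl1 <- fluid_model(alpha = 1)
  expect_equal(diff(range(power_law_viscosity(g, fl1))), 0)
})

test_that("dimensionless groups match the experimental flow conditions", {
  fl <- fluid_model()                     # mu0 = 32.7 mPa s, rho = 1060
  chan <- channel_spec("constricted", l = 20e-6, Q = 4.5e-9 / 60)
  expect_equal(chan$U, 0.1875)            # 4.5 ul/min through (20 um)^2
  cell <- cell_params(a = 7.4e-6, Gs = 10.355e-3, C = 10,
                      mu_s = 80 * fl$mu0 * 7.4e-6)
  # use the rounded experimental speed for the groups
  chan$U <- 0.19
  gr <- dimensionless_groups(fl, cell, chan)
  expect_equal(gr$Ca, 0.6, tolerance = 0.001)
  expect_equal(gr$eta, 80)
  expect_equal(gr$confinement, 0.74)
  expect_equal(gr$Re, 0.123, tolerance = 0.01)
  # cross-slot branch: 16 ul/min through (40 um)^2, mu0 = 33.9 mPa s
  fl2 <- fluid_model(mu0 = 0.0339)
  chan2 <- channel_spec("cross_slot", l = 40e-6, Q = 16e-9 / 60)
  expect_equal(chan2$U, 1 / 6, tolerance = 1e-12)
  cell2 <- cell_params(a = 8.6e-6, Gs = fl2$mu0 * 0.17 / 1.0, C = 10)
  chan2$U <- 0.17
  gr2 <- dimensionless_groups(fl2, cell2, chan2)
  expect_equal(gr2$Re, 0.21, tolerance = 0.02)
  expect_equal(gr2$eta, 0)
})

test_that("dimensional conversions reproduce the inferred moduli", {
  fl <- fluid_model()
  d <- to_dimensional(Ca = 0.6, C = 10, eta = 80, fl, U = 0.19, a = 7.4e-6)
  expect_equal(d$Gs * 1e3, 10.4, tolerance = 0.005)
  expect_equal(d$Ks * 1e3, 217, tolerance = 0.005)
  expect_equal(d$mu_s * 1e6, 19.4, tolerance = 0.005)
  # K-562 constricted cell: Ca = 1.4, eta = 40, a = 6 um
  d2 <- to_dimensional(1.4, 10, 40, fl, U = 0.19, a = 6e-6)
  expect_equal(d2$Gs * 1e3, 4.4, tolerance = 0.01)
  expect_equal(d2$Ks * 1e3, 93, tolerance = 0.01)
  expect_equal(d2$mu_s * 1e6, 7.8, tolerance = 0.01)
  # cross-slot PC-3 cell: eta = 30 at mu0 = 33.9 mPa s, a = 8.6 um
  fl2 <- fluid_model(mu0 = 0.0339)
  d3 <- to_dimensional(1.0, 10, 30, fl2, U = 0.17, a = 8.6e-6)
  expect_equal(d3$mu_s * 1e6, 8.7, tolerance = 0.01)
  expect_equal(d3$Gs * 1e3, 5.8, tolerance = 0.01)
  # round trip through the groups
  cell <- cell_params(a = 7.4e-6, Gs = d$Gs, C = 10, mu_s = d$mu_s)
  chan <- channel_spec("constricted", l = 20e-6, U = 0.19)
  gr <- dimensionless_groups(fl, cell, chan)
  expect_equal(gr$Ca, 0.6, tolerance = 1e-12)
  expect_equal(gr$eta, 80, tolerance = 1e-12)
  expect_error(to_dimensional(0, 10, 0, fl, 0.19, 7.4e-6), "positive")
})

test_that("half-increment uncertainty propagation matches the printed bounds", {
  fl <- fluid_model()
  u <- propagate_uncertainty(Ca = 0.6, C = 10, eta = 80, dCa = 0.1, dC = 1,
                             deta = 5, fluid = fl, U = 0.19, a = 7.4e-6)
  expect_equal(u$dGs * 1e3, 0.9, tolerance = 0.05)
  expect_equal(u$dKs * 1e3, 21, tolerance = 0.01)
  expect_equal(u$dmu_s * 1e6, 0.6, tolerance = 0.01)
  # eta = 0: one half-increment bound
  u0 <- propagate_uncertainty(0.6, 10, 0, fluid = fl, U = 0.19, a = 7.4e-6)
  expect_equal(u0$mu_s, 0)
  expect_equal(u0$dmu_s, 2.5 * fl$mu0 * 7.4e-6)
  expect_error(propagate_uncertainty(0, 10, 0, fluid = fl, U = 0.19,
                                     a = 7.4e-6), "positive")
})

test_that("Ks identity and linear scaling invariants hold", {
  fl <- fluid_model()
  for (C in c(1, 7, 23, 50)) {
    cp <- cell_params(a = 5e-6, Gs = 2e-3, C = C)
    expect_identical(cp$Ks, (1 + 2 * C) * cp$Gs)
    expect_identical(cp$Ksn, (1 + 2 * C) * cp$Gsn)
  }
  # Re and Ca scale linearly in U over a decade
  U <- seq(0.05, 0.5, length.out = 7)
  cell <- cell_params(a = 7.4e-6, Gs = 1e-2, C = 10)
  vals <- t(vapply(U, function(u) {
    gr <- dimensionless_groups(fl, cell,
                               channel_spec("constricted", l = 20e-6, U = u))
    c(gr$Ca, gr$Re)
  }, numeric(2)))
  expect_equal(vals[, 1], vals[1, 1] * U / U[1], tolerance = 1e-12)
  expect_equal(vals[, 2], vals[1, 2] * U / U[1], tolerance = 1e-12)
})

test_that("cell defaults follow the compound-capsule model", {
  cp <- cell_params(a = 7.4e-6, Gs = 10e-3, C = 10)
  expect_equal(cp$kc, 0.001 * cp$Gs * cp$a^2)
  expect_equal(cp$an, 0.5 * cp$a)
  expect_equal(cp$Gsn, 2 * cp$Gs)
  expect_equal(cp$kcn, 0.001 * cp$Gsn * cp$an^2)
  expect_equal(cp$c0, 0)
  expect_equal(cp$mu_s_dil, 0)
})

test_that("cross-section average viscosity is near the quoted mu0", {
  fl <- fluid_model()
  mu_area <- mu0_cross_section(fl, U = 0.19, l = 20e-6, n = 40)
  # the quoted 32.7 mPa s lies within ~15% of both averaging conventions
  expect_lt(abs(mu_area - 0.0327) / 0.0327, 0.15)
  mu_flow <- mu0_cross_section(fl, U = 0.19, l = 20e-6, n = 40,
                               weighting = "flow")
  expect_lt(abs(mu_flow - 0.0327) / 0.0327, 0.15)
})
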