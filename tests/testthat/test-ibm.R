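test_that("the 4-point kernel has exact unity and first-moment sums", {
  set.seed(1)
  for (x in runif(25, -0.5, 0.5)) {
    k <- -3:3
    w <- ib_kernel(x - k)
    expect_equal(sum(w), 1, tolerance = 1e-14)
    expect_equal(sum((x - k) * w), 0, tolerance = 1e-13)
    expect_true(all(w[abs(x - k) >= 2] == 0))
  }
  # symmetric, peaked at 0
  expect_equal(ib_kernel(0.3), ib_kernel(-0.3))
  expect_gt(ib_kernel(0), ib_kernel(0.4))
})

test_that("force spreading conserves the total force exactly", {
  set.seed(2)
  dims <- c(14, 12, 13)
  pos <- cbind(runif(40, 3, 10), runif(40, 3, 9), runif(40, 3, 10))
  fr <- matrix(rnorm(120), 40, 3)
  fd <- spread_forces(pos, fr, dims)
  expect_equal(apply(fd, 4, sum), colSums(fr), tolerance = 1e-12)
  # single unit force: weights sum to 1 over the 4^3 stencil
  f1 <- spread_forces(matrix(c(6.3, 6.7, 6.1), 1), matrix(c(1, 0, 0), 1),
                      dims)
  expect_equal(sum(f1[, , , 1]), 1, tolerance = 1e-14)
  expect_identical(sum(f1[, , , 1] != 0) <= 64, TRUE)
  # point exactly on a node: symmetric pattern peaking there
  f2 <- spread_forces(matrix(c(6.5, 6.5, 6.5), 1), matrix(c(0, 0, 1), 1),
                      dims)
  w <- f2[, , , 3]
  expect_equal(which(w == max(w), arr.ind = TRUE)[1, ], c(7, 7, 7),
               ignore_attr = TRUE)
  expect_equal(w[6, 7, 7], w[8, 7, 7])
  expect_error(spread_forces(matrix(c(-1, 5, 5), 1),
                             matrix(0, 1, 3), dims), "outside")
})

test_that("interpolation reproduces constant and linear fields exactly", {
  dims <- c(12, 12, 12)
  set.seed(3)
  pos <- cbind(runif(30, 2.5, 9.5), runif(30, 2.5, 9.5), runif(30, 2.5, 9.5))
  u0 <- array(0.37, dims)
  expect_equal(interpolate_velocity(u0, pos)[, 1], rep(0.37, 30),
               tolerance = 1e-14)
  A <- c(0.3, -0.2, 0.5)
  g <- array(0, dims)
  for (i in 1:12) g[i, , ] <- g[i, , ] + A[1] * (i - 0.5)
  for (j in 1:12) g[, j, ] <- g[, j, ] + A[2] * (j - 0.5)
  for (k in 1:12) g[, , k] <- g[, , k] + A[3] * (k - 0.5)
  expect_equal(interpolate_velocity(g, pos)[, 1], as.numeric(pos %*% A),
               tolerance = 1e-12)
})

test_that("spreading and interpolation are adjoint (power balance)", {
  dims <- c(12, 12, 12)
  set.seed(4)
  pos <- cbind(runif(25, 3, 9), runif(25, 3, 9), runif(25, 3, 9))
  fr <- matrix(rnorm(75), 25, 3)
  u <- array(rnorm(prod(dims) * 3), c(dims, 3))
  fd <- spread_forces(pos, fr, dims)
  lhs <- sum(fd * u)                       # integral of f . u (dx = 1)
  uv <- interpolate_velocity(u, pos)
  rhs <- sum(fr * uv)                      # sum F_vertex . u_vertex
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("the indicator field reproduces the capsule geometry", {
  L <- 24
  fl <- array(1L, c(L, L, L))
  fl[, , 1] <- 0L; fl[, , L] <- 0L
  flu <- fluid_model(K = 1e-3, alpha = 1, rho = 1000, mu0 = 1e-3)
  dx <- 1e-6
  sim <- lbm_sim(fl, flu, dx, dt = 5e-8, periodic = c(TRUE, TRUE, FALSE))
  a <- 6e-6
  ctr <- c(L / 2, L / 2, L / 2) * dx
  mesh <- make_sphere_mesh(3, a, ctr)
  sim <- lbm_add_capsule(sim, mesh, Gs = 1e-3, C = 1)
  I <- indicator_field(sim, 1)
  # centre ~1, distant corner ~0
  expect_gt(I[L / 2, L / 2, L / 2], 0.98)
  expect_lt(I[3, 3, 3], 0.02)
  # integral matches the mesh volume within 2%
  vol_I <- sum(I) * dx^3
  vol_m <- mesh_measures(mesh)$volume
  expect_lt(abs(vol_I / vol_m - 1), 0.02)
  # 0.5 isosurface within half a cell of the true radius, against the
  # ray-casting oracle
  co <- ((1:L) - 0.5)
  mid <- L / 2
  prof <- I[, mid, mid]
  r_cross <- suppressWarnings(stats::approx(prof[mid:(L - 1)], co[mid:(L - 1)] - mid,
                           xout = 0.5))$y
  expect_lt(abs(r_cross - a / dx), 0.5)
  pts <- cbind(co, mid, mid) * dx
  inside <- point_in_mesh(mesh, pts)
  expect_equal(unname(inside), prof > 0.5)
})

test_that("blended viscosity mixes exterior and interior phases", {
  flu <- fluid_model()
  I <- array(0, c(4, 4, 4))
  gd <- array(1.6e4, c(4, 4, 4))
  # no cell: pure power-law exterior
  mu <- blended_viscosity(I, gd, flu)
  expect_equal(mu, power_law_viscosity(gd, flu), tolerance = 1e-12)
  # fully interior: Newtonian lambda mu0 independent of shear rate
  I1 <- array(1, c(4, 4, 4))
  mu1 <- blended_viscosity(I1, gd, flu, lambda = 2)
  expect_equal(as.numeric(mu1), rep(2 * flu$mu0, 64))
  gd2 <- gd * 100
  expect_equal(blended_viscosity(I1, gd2, flu, lambda = 2), mu1)
  # nucleus region dominates where I_nucleus = 1
  In <- array(0, c(4, 4, 4)); In[1, 1, 1] <- 1; I1n <- I1
  mun <- blended_viscosity(I1n, gd, flu, lambda = 2, I_nucleus = In,
                           lambda_n = 3)
  expect_equal(mun[1, 1, 1], 3 * flu$mu0)
  expect_equal(mun[2, 2, 2], 2 * flu$mu0)
  # half-half mixture matches the analytic average
  Ih <- array(0.5, c(4, 4, 4))
  muh <- blended_viscosity(Ih, gd, flu, lambda = 1)
  expect_equal(as.numeric(muh),
               rep(0.5 * power_law_viscosity(1.6e4, flu) + 0.5 * flu$mu0,
                   64), tolerance = 1e-12)
})

test_that("a capsule in uniform flow advects rigidly with stable volume", {
  L <- 20; NXL <- 32
  fl <- array(1L, c(NXL, L, L))
  flu <- fluid_model(K = 1e-3, alpha = 1, rho = 1000, mu0 = 1e-3)
  dx <- 1e-6; dt <- 5e-8
  sim <- lbm_sim(fl, flu, dx, dt, periodic = c(TRUE, TRUE, TRUE))
  u_lat <- 0.02
  U0 <- u_lat * dx / dt
  sim_set_uniform_velocity(sim$ptr, c(u_lat, 0, 0))
  a <- 4e-6
  x0 <- c(8, L / 2, L / 2) * dx
  mesh <- make_sphere_mesh(2, a, x0)
  sim <- lbm_add_capsule(sim, mesh, Gs = 1e-3, C = 1, kc = 1e-6 * a^2)
  v0 <- lbm_capsule_state(sim, 1)$volume
  nsteps <- 500
  lbm_step(sim, nsteps)
  st <- lbm_capsule_state(sim, 1)
  expect_lt(abs(st$volume / v0 - 1), 1e-3)
  # advected at U0 (within a percent) with no lateral drift
  ctr <- colMeans(st$vertices)
  expect_equal(ctr[1], x0[1] + U0 * nsteps * dt, tolerance = 0.01)
  expect_lt(max(abs(ctr[2:3] - x0[2:3])), 0.05 * dx)
  # shape stays spherical
  r <- sqrt(rowSums(sweep(st$vertices, 2, ctr)^2))
  expect_lt(diff(range(r)) / a, 0.02)
})
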