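test_that("Skalak strain energy matches hand evaluations", {
  expect_equal(strain_energy(1, 1, 5, 10), 0)
  # lambda = (1.1, 1.0), Gs = C = 1: I1 = I2 = 0.21
  expect_equal(strain_energy(1.1, 1, 1, 1),
               0.25 * (0.21^2 + 2 * 0.21 - 2 * 0.21) + 0.25 * 0.21^2)
  expect_equal(strain_energy(1.1, 1, 1, 1), 0.02205, tolerance = 1e-10)
  # non-negative with equality only at the undeformed state
  set.seed(42)
  l1 <- runif(500, 0.5, 2); l2 <- runif(500, 0.5, 2)
  W <- strain_energy(l1, l2, 1, 1)
  expect_true(all(W >= 0))
  expect_true(all(W[abs(l1 - 1) + abs(l2 - 1) > 1e-3] > 0))
  expect_error(strain_energy(-1, 1, 1, 1), "positive")
})

test_that("principal stresses agree with differentiation of the energy", {
  s <- sk_stresses(1, 1, 3, 7)
  expect_equal(s$tau1, 0)
  expect_equal(s$tau2, 0)
  # equibiaxial: tau1 = tau2 = (lam^2-1) + lam^2 (lam^4-1) for Gs = C = 1
  lam <- 1.01
  s2 <- sk_stresses(lam, lam, 1, 1)
  expect_equal(s2$tau1, (lam^2 - 1) + lam^2 * (lam^4 - 1), tolerance = 1e-12)
  expect_equal(s2$tau1, 0.06152, tolerance = 1e-3)
  s3 <- sk_stresses(1.1, 1.0, 1, 1)
  expect_equal(s3$tau1, 0.462, tolerance = 1e-3)
  expect_equal(s3$tau2, 0.231, tolerance = 1e-3)
  # central-difference oracle over random stretches
  set.seed(7)
  h <- 1e-6
  for (i in 1:50) {
    l1 <- runif(1, 0.6, 1.8); l2 <- runif(1, 0.6, 1.8)
    Gs <- runif(1, 0.5, 3); C <- runif(1, 0, 20)
    t1_num <- (strain_energy(l1 + h, l2, Gs, C) -
               strain_energy(l1 - h, l2, Gs, C)) / (2 * h) / l2
    t2_num <- (strain_energy(l1, l2 + h, Gs, C) -
               strain_energy(l1, l2 - h, Gs, C)) / (2 * h) / l1
    s <- sk_stresses(l1, l2, Gs, C)
    expect_equal(s$tau1, t1_num, tolerance = 1e-6)
    expect_equal(s$tau2, t2_num, tolerance = 1e-6)
  }
})

test_that("small-strain isotropic dilation recovers the Ks modulus", {
  for (C in c(1, 10, 50)) {
    Gs <- 2
    lam <- 1.0005
    s <- sk_stresses(lam, lam, Gs, C)
    Ks <- (1 + 2 * C) * Gs
    expect_equal(s$tau1, Ks * (lam^2 - 1), tolerance = 0.01)
    expect_equal(s$tau1, s$tau2)
  }
})

test_that("viscous membrane stress follows the surface Newtonian law", {
  expect_equal(viscous_stress(matrix(0, 2, 2), 5), matrix(0, 2, 2))
  # traceless pure shear: tau = 2 mu_s D
  D <- rbind(c(0.3, 0.1), c(0.1, -0.3))
  expect_equal(viscous_stress(D, 2), 4 * D)
  # isotropic dilation with zero dilatational viscosity cancels exactly
  Dd <- diag(2) * 0.4
  expect_equal(viscous_stress(Dd, 2, 0), matrix(0, 2, 2))
  expect_equal(viscous_stress(Dd, 2, 3), 3 * 0.8 * diag(2))
  expect_error(viscous_stress(rbind(c(0, 1), c(0, 0)), 1), "symmetric")
})

test_that("discrete Helfrich energy of a sphere approaches 8 pi kc", {
  e <- vapply(3:5, function(n) {
    m <- make_sphere_mesh(n, 1)
    cpp_bending_energy(m$vertices, m$triangles, 1, 0)
  }, numeric(1))
  expect_equal(e[3] / (8 * pi), 1, tolerance = 0.03)
  # improves under refinement and is scale invariant for c0 = 0
  expect_true(all(diff(abs(e - 8 * pi)) < 0))
  m2 <- make_sphere_mesh(4, 1)
  m2b <- make_sphere_mesh(4, 3.3)
  expect_equal(cpp_bending_energy(m2$vertices, m2$triangles, 1, 0),
               cpp_bending_energy(m2b$vertices, m2b$triangles, 1, 0),
               tolerance = 1e-10)
})

test_that("bending forces are the gradient of the discrete energy", {
  m <- make_sphere_mesh(2, 1)
  # perturb to a non-symmetric configuration
  set.seed(3)
  m$vertices <- m$vertices * (1 + 0.05 * sin(3 * m$vertices[, 1]))
  b <- bending_forces(m, kc = 1)
  # directional derivative oracle by central differences
  h <- 1e-6
  set.seed(4)
  for (rep in 1:5) {
    dir <- matrix(rnorm(length(m$vertices)), nrow(m$vertices), 3)
    dir <- dir / sqrt(sum(dir^2))
    mp <- m; mp$vertices <- m$vertices + h * dir
    mm_ <- m; mm_$vertices <- m$vertices - h * dir
    dE <- (cpp_bending_energy(mp$vertices, mp$triangles, 1, 0) -
           cpp_bending_energy(mm_$vertices, mm_$triangles, 1, 0)) / (2 * h)
    expect_equal(-sum(dir * b$force), dE, tolerance = 1e-5)
  }
  # zero resultant force and torque (rigid-motion invariance)
  expect_lt(max(abs(colSums(b$force))), 1e-10 * max(abs(b$force)))
  tq <- colSums(cbind(
    m$vertices[, 2] * b$force[, 3] - m$vertices[, 3] * b$force[, 2],
    m$vertices[, 3] * b$force[, 1] - m$vertices[, 1] * b$force[, 3],
    m$vertices[, 1] * b$force[, 2] - m$vertices[, 2] * b$force[, 1]))
  expect_lt(max(abs(tq)), 1e-10 * max(abs(b$force)))
})

test_that("bending of the discrete sphere is a small regularising force", {
  # with the default kc = 0.001 Gs a^2 the bending force density stays far
  # below the elastic scale Gs/a everywhere except discretisation noise at
  # the six irregular (valence-4) seed vertices
  a <- 1; Gs <- 1
  m <- make_sphere_mesh(4, a)
  b <- bending_forces(m, kc = 0.001 * Gs * a^2)
  f <- sqrt(rowSums(b$force^2))
  mm <- mesh_measures(m)
  dens <- f / mm$vertex_area
  expect_lt(stats::median(dens), 2e-3 * Gs / a)
  expect_lt(max(f), 5e-3 * Gs * a)
})

test_that("nodal force assembly balances and matches the Laplace law", {
  a <- 1; lam <- 1.05; Gs <- 1; C <- 1
  m0 <- make_sphere_mesh(4, a)
  cp <- cell_params(a = a, Gs = Gs, C = C)
  # undeformed sphere, no flow: only bending discretisation noise remains
  nf0 <- nodal_forces(m0, cp)
  expect_lt(max(abs(nf0$elastic)), 1e-9 * Gs * a)
  expect_lt(max(abs(nf0$force)), 5e-3 * Gs * a)
  # inflated sphere: normal forces with Young-Laplace pressure jump
  m <- m0
  m$vertices <- m0$vertices * lam
  el <- cpp_elastic_forces(m$vertices, m$reference_vertices, m$triangles,
                           Gs, C)
  mm <- mesh_measures(m)
  p_eq <- sum(rowSums(el$force * mm$vertex_normal)) / mm$area
  tau <- sk_stresses(lam, lam, Gs, C)$tau1
  expect_equal(p_eq, -2 * tau / (lam * a), tolerance = 0.02)
  expect_equal(el$lambda1, rep(lam, nrow(m$triangles)), tolerance = 1e-9)
  # resultants vanish on an arbitrary closed deformed configuration
  md <- m0
  md$vertices <- m0$vertices %*% diag(c(1.3, 0.9, 1.1))
  vel <- 0.1 * md$vertices^2
  nf <- nodal_forces(md, cell_params(a = a, Gs = Gs, C = C, mu_s = 0.5),
                     velocities = vel)
  scale <- max(abs(nf$force))
  expect_lt(max(abs(colSums(nf$force))), 1e-11 * scale)
  tq <- colSums(cbind(
    md$vertices[, 2] * nf$force[, 3] - md$vertices[, 3] * nf$force[, 2],
    md$vertices[, 3] * nf$force[, 1] - md$vertices[, 1] * nf$force[, 3],
    md$vertices[, 1] * nf$force[, 2] - md$vertices[, 2] * nf$force[, 1]))
  expect_lt(max(abs(tq)), 1e-10 * scale)
})

test_that("membrane viscous dissipation is non-negative", {
  m <- make_sphere_mesh(3, 1)
  set.seed(11)
  vel <- matrix(rnorm(length(m$vertices), sd = 0.3), ncol = 3)
  vi <- cpp_viscous_forces(m$vertices, vel, m$triangles, 2, 0)
  # tau_v : D = mu_s [(D11 - D22)^2 + 4 D12^2] >= 0 element-wise
  diss <- 2 * ((vi$D11 - vi$D22)^2 + 4 * vi$D12^2)
  expect_true(all(diss >= 0))
  # the nodal viscous forces remove kinetic energy: power <= 0
  expect_lt(sum(vi$force * vel), 0)
})
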