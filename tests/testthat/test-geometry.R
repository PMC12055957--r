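# Geometry builders at coarse test resolution.

test_that("constricted channel has the right widths and corner fillets", {
  g <- build_constricted(l = 20e-6, corner_r = 20e-6, straight_len = 120e-6,
                         converging_len = 40e-6, inlet_len = 20e-6,
                         nodes_per_l = 8)
  s <- g$sdf
  p <- function(x, y, z) s(matrix(c(x, y, z), 1))
  # centreline of the straight channel is fluid; the wall sits at |z| = l/2
  expect_gt(p(100e-6, 0, 0), 0)
  expect_equal(p(100e-6, 0, 10e-6), 0, tolerance = 1e-12)
  expect_lt(p(100e-6, 0, 10.5e-6), 0)
  expect_lt(p(100e-6, 10.5e-6, 0), 0)    # height walls
  # 45 degree walls: full width l + 2|x| in the converging section
  expect_gt(p(-30e-6, 0, 39.9e-6), 0)
  expect_lt(p(-30e-6, 0, 40.1e-6), 0)
  # corner fillet removes fluid near the junction: the point on the fillet
  # circle centre side is solid even though it satisfies the wall lines
  xc <- 20e-6 * (sqrt(2) - 1)
  expect_lt(p(xc, 0, 10e-6 + 1e-7), 0)           # just above tangent point
  expect_gt(p(xc, 0, 9.9e-6), 0)
  # narrowest gap equals l exactly between the straight walls
  zz <- seq(-15e-6, 15e-6, by = 1e-8)
  inside <- s(cbind(50e-6, 0, zz)) > 0
  expect_equal(diff(range(zz[inside])), 20e-6, tolerance = 2e-3)
  expect_error(build_constricted(corner_r = 1, straight_len = 1e-6),
               "corner radius")
})

test_that("cross-slot geometry is mirror symmetric with rounded corners", {
  g <- build_cross_slot(l = 40e-6, corner_r = 10e-6, feed_len = 80e-6,
                        other_len = 80e-6, nodes_per_l = 8)
  fl <- g$flags != 0L
  d <- dim(fl)
  expect_identical(fl, fl[, , d[3]:1])
  expect_identical(fl, fl[d[1]:1, , ])
  s <- g$sdf
  p <- function(x, y, z) s(matrix(c(x, y, z), 1))
  # geometric centre is fluid with wall distance >= l/2
  expect_gte(p(0, 0, 0), 20e-6 - 1e-9)
  # the entry plane of the cross region sits at x = -l/2 = -20 um
  expect_gt(p(-20e-6, 0, 0), 0)
  # sharp corner point would be (l/2, l/2); the fillet keeps the fluid
  # boundary on the arc of radius 10 um about (l/2 + r, l/2 + r)
  cc <- 20e-6 + 10e-6
  th <- seq(pi, 1.5 * pi, length.out = 11)
  on_arc <- cbind(cc + 10e-6 * cos(th), 0, cc + 10e-6 * sin(th))
  expect_lt(max(abs(s(on_arc))), 1e-9)
  expect_gt(p(21.5e-6, 0, 21.5e-6), 0) # pocket between corner point and arc
  expect_lt(p(24e-6, 0, 24e-6), 0)   # beyond the arc towards the centre: solid
  expect_identical(nrow(g$planes), 4L)
  expect_identical(sum(g$planes$role == "inlet"), 2L)
})

test_that("boundary link fractions match analytic wall positions", {
  g <- build_constricted(l = 20e-6, corner_r = 20e-6, straight_len = 120e-6,
                         converging_len = 40e-6, inlet_len = 20e-6,
                         nodes_per_l = 8)
  q <- g$qlink
  expect_true(all(q[q >= 0] <= 1))
  # flat wall in the straight channel: l/dx = 8 nodes span the width and
  # the wall falls exactly mid-link (q = 0.5) for axis links
  co <- lattice_coordinates(g)
  iz_top <- max(which(co$z < 10e-6))    # topmost fluid node row
  ix <- which.min(abs(co$x - 60e-6))
  iy <- 4
  # direction 5 is +z (1-based index 6 in the 19-velocity set)
  expect_equal(q[6, ix, iy, iz_top], 0.5, tolerance = 1e-6)
  # sphere oracle: line-sphere intersection for a spherical wall
  sph <- structure(list(
    kind = "test", dims = c(10L, 10L, 10L), dx = 1e-6,
    corner = c(0, 0, 0),
    flags = array(1L, c(10, 10, 10)),
    planes = data.frame(),
    sdf = function(P) {
      # fluid outside a sphere of radius 3.2 um centred at (5, 5, 5) um
      sqrt(rowSums(sweep(P, 2, c(5e-6, 5e-6, 5e-6))^2)) - 3.2e-6
    }), class = "channel_geometry")
  sph$flags <- array(ifelse(sph$sdf(as.matrix(expand.grid(
    x = (1:10 - 0.5) * 1e-6, y = (1:10 - 0.5) * 1e-6,
    z = (1:10 - 0.5) * 1e-6))) > 0, 1L, 0L), c(10, 10, 10))
  qs <- boundary_links(sph)
  # node (1.5, 4.5, 4.5) um looking in +x towards the sphere: the wall is
  # at x = 5 - sqrt(3.2^2 - 0.5^2 - 0.5^2) = 1.8398 um -> q = 0.3398
  qa <- (5 - sqrt(3.2^2 - 0.5^2 - 0.5^2)) - 1.5
  expect_equal(qs[2, 2, 5, 5], qa, tolerance = 1e-6)
})

test_that("cell-free cross-slot flow stalls at the stagnation point", {
  g <- build_cross_slot(l = 40e-6, corner_r = 10e-6, feed_len = 60e-6,
                        other_len = 60e-6, nodes_per_l = 8)
  U <- 0.17
  cal <- calibrate_pressure(g, fluid_model(mu0 = 0.0339), U * (40e-6)^2)
  f <- lbm_fields(cal$sim)
  # interpolate the velocity at the exact stagnation point (the geometric
  # centre falls between lattice nodes)
  ctr_lat <- matrix(-g$corner / g$dx, 1)
  u4 <- array(c(f$ux, f$uy, f$uz), c(dim(f$ux), 3))
  uc <- interpolate_velocity(u4, ctr_lat)
  expect_lt(sqrt(sum(uc^2)), 1e-3 * U)
  # flow splits symmetrically towards both outlets
  qup <- lbm_flow_rate(cal$sim, 3, dim(g$flags)[3] - 2)
  qdn <- lbm_flow_rate(cal$sim, 3, 3)
  expect_equal(qup, -qdn, tolerance = 0.02)
})
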