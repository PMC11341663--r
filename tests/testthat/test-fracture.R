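test_that("longitudinal G reproduces the published parameter orderings", {
  p <- 0.1
  # strain stiffening suppresses G: Jm = 1 < 10 < 100 at the operating point
  G_jm <- vapply(c(1, 10, 100), function(J)
    energy_release_longitudinal(op_geom(), gent1(J), p)$G_norm, numeric(1))
  expect_true(all(diff(G_jm) > 0))
  # thicker wall lowers G (Neo-Hookean)
  G_h2 <- vapply(c(0.15, 0.25), function(h)
    energy_release_longitudinal(op_geom(0.5, h), nh(), p)$G_norm, numeric(1))
  expect_gt(G_h2[1], G_h2[2])
  # deeper tear (smaller H1/H2) raises G (Neo-Hookean)
  G_d <- vapply(c(0.3, 0.7), function(d)
    energy_release_longitudinal(op_geom(d), nh(), p)$G_norm, numeric(1))
  expect_gt(G_d[1], G_d[2])
  expect_true(all(c(G_jm, G_h2, G_d) > 0))
})

test_that("G increases with pressure in both directions", {
  for (dir_fun in list(energy_release_longitudinal,
                       function(g, m, p) energy_release_circumferential(g, m, p))) {
    G <- vapply(c(0.04, 0.08, 0.12), function(p)
      dir_fun(op_geom(), gent1(1), p)$G_norm, numeric(1))
    expect_true(all(diff(G) > 0))
  }
})

test_that("circumferential G grows with crack angle and vanishes at H1 = H2", {
  p <- 0.1
  G_al <- vapply(c(30, 60, 90), function(a)
    energy_release_circumferential(op_geom(0.5, 0.2, a), gent1(1), p)$G_norm,
    numeric(1))
  expect_true(all(diff(G_al) > 0))
  # no thickness contrast: U_II independent of alpha, upwind difference zero
  G0 <- energy_release_circumferential(geometry_from_ratios(0.2, 1, 30),
                                       gent1(1), p)$G_norm
  expect_lt(abs(G0), 1e-10)
})

test_that("upwind scheme is first-order consistent with a centered oracle", {
  g <- op_geom(0.5)
  m <- gent1(1)
  rep4 <- finite_difference_G(g, m, 0.1, h = deg2rad(4))
  rep2 <- finite_difference_G(g, m, 0.1, h = deg2rad(2))
  expect_true(rep4$pass)
  expect_true(rep2$pass)
  # halving the increment roughly halves the upwind-centered gap
  gap4 <- abs(rep4$solver_value - rep4$oracle_value)
  gap2 <- abs(rep2$solver_value - rep2$oracle_value)
  expect_lt(gap2, gap4)
})

test_that("longitudinal G vs crack angle is non-monotonic with interior minimum", {
  prof <- crack_angle_profile(op_geom(0.5), gent1(1), 0.1, "longitudinal",
                              deg2rad(seq(10, 160, by = 10)))
  expect_false(any(is.na(prof$G_norm)))
  im <- which.min(prof$G_norm)
  expect_gt(im, 1)
  expect_lt(im, nrow(prof))
  expect_gt(prof$G_norm[1], prof$G_norm[im])
  expect_gt(prof$G_norm[nrow(prof)], prof$G_norm[im])
})

test_that("circumferential G vs crack angle is strictly increasing", {
  prof <- crack_angle_profile(op_geom(0.5), gent1(1), 0.1, "circumferential",
                              deg2rad(seq(10, 160, by = 10)))
  expect_true(all(diff(prof$G_norm) > 0))
  # without thickness contrast the whole profile vanishes
  prof0 <- crack_angle_profile(geometry_from_ratios(0.2, 1, 30), gent1(1),
                               0.1, "circumferential",
                               deg2rad(c(30, 60, 90)))
  expect_true(all(abs(prof0$G_norm) < 1e-10))
})

test_that("angle sweeps record per-point failures without aborting", {
  # Neo-Hookean above its membrane limit point: every node fails but the
  # sweep still returns a full data frame with messages
  prof <- crack_angle_profile(op_geom(0.5), nh(), 0.25, "circumferential",
                              deg2rad(c(30, 60)))
  expect_identical(nrow(prof), 2L)
  expect_true(all(is.na(prof$G_norm)))
  expect_true(all(grepl("limit point", prof$error)))
})

test_that("normalized G is invariant under unit rescaling", {
  # scale stresses by c and lengths by d: G/(mu R) must not change
  cs <- 3.7; ds <- 2.3
  m1 <- gent1(1)
  m2 <- material("gent", mu = cs, Jm = 1)
  g1 <- op_geom(0.5)
  g2 <- aorta_geometry(H2 = g1$H2 * ds, H1 = g1$H1 * ds,
                       alpha_lim = g1$alpha_lim, R = g1$R * ds)
  for (dir in c("longitudinal", "circumferential")) {
    f <- if (dir == "longitudinal") energy_release_longitudinal else
      energy_release_circumferential
    G1 <- f(g1, m1, 0.1)$G_norm
    G2 <- f(g2, m2, 0.1 * cs)$G_norm
    expect_equal(G1, G2, tolerance = 1e-8)
  }
})

test_that("HGO anisotropy lowers G and degenerates to Neo-Hookean", {
  p <- 0.08
  G_k1 <- vapply(c(0, 0.05, 0.2), function(k)
    energy_release_longitudinal(op_geom(), material("hgo", K1 = k, K2 = 1),
                                p)$G_norm, numeric(1))
  expect_true(all(diff(G_k1) < 0))
  G_k2 <- vapply(c(0.5, 2), function(k)
    energy_release_longitudinal(op_geom(), hgo_mat(0.05, k), p)$G_norm,
    numeric(1))
  expect_gt(G_k2[1], G_k2[2])
  # K1 = 0 equals Neo-Hookean exactly
  expect_equal(G_k1[1],
               energy_release_longitudinal(op_geom(), nh(), p)$G_norm,
               tolerance = 1e-12)
})

test_that("solver failures are tagged with the failing section", {
  expect_error(energy_release_longitudinal(op_geom(), nh(), 0.5),
               "normal section")
  # dissected membrane fails first at pressures between the two limit points
  expect_error(energy_release_longitudinal(op_geom(0.5), nh(), 0.19),
               "dissected section")
})
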