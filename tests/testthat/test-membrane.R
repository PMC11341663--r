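test_that("zero pressure returns the reference membrane state", {
  st <- solve_dissected_section(op_geom(), gent1(1), 0)
  expect_identical(st$U, 0)
  expect_identical(st$lam_fl, 1)
  expect_identical(st$lam_wall, 1)
  expect_identical(st$T, 0)
})

test_that("uniform Neo-Hookean membrane reproduces the closed form", {
  # P/mu = (H/R)(1 - lam^-4); at P/mu = 0.15, H/R = 0.2 the stretch is 2^(1/2)
  g <- aorta_geometry(H2 = 0.2, H1 = 0.2, alpha_lim = pi / 6, R = 1)
  st <- solve_dissected_section(g, nh(), 0.15)
  expect_equal(st$lam_fl, sqrt(2), tolerance = 1e-8)
  expect_equal(st$lam_wall, sqrt(2), tolerance = 1e-8)
  # closed form over a stretch grid
  for (lam in c(1.1, 1.2, 1.3)) {
    p <- 0.2 * (1 - lam^-4)
    st <- solve_dissected_section(g, nh(), p)
    expect_equal(st$lam_wall, lam, tolerance = 1e-8)
  }
  # no equilibrium at or above the limit point P/mu = H/R
  expect_error(solve_dissected_section(g, nh(), 0.2),
               class = "aortafract_no_equilibrium")
  expect_error(solve_dissected_section(g, nh(), 0.25),
               class = "aortafract_no_equilibrium")
})

test_that("equal thickness degenerates to the uniform ring", {
  m <- gent1(1)
  g30 <- geometry_from_ratios(0.2, 1, 30)
  g75 <- geometry_from_ratios(0.2, 1, 75)
  s30 <- solve_dissected_section(g30, m, 0.1)
  s75 <- solve_dissected_section(g75, m, 0.1)
  expect_identical(s30$lam_fl, s30$lam_wall)
  # U_II independent of the crack angle when H1 = H2
  expect_equal(s30$U, s75$U, tolerance = 1e-10)
})

test_that("thinner false-lumen wall stretches more at equal tension", {
  st <- solve_dissected_section(op_geom(0.5), gent1(1), 0.1)
  expect_gt(st$lam_fl, st$lam_wall)
  expect_gt(st$lam_wall, 1)
  # Laplace and closure residuals at convergence
  expect_lt(abs(st$T - 0.1 * st$rho) / st$T, 1e-10)
  expect_lt(abs(st$closure_residual), 1e-9 * st$geom$R)
})

test_that("membrane equilibrium equals the constrained energy minimum", {
  # deterministic parameter draws spanning material, depth, angle, pressure
  draws <- list(
    list(g = op_geom(0.5), m = gent1(1), p = 0.1),
    list(g = op_geom(0.3, 0.25, 45), m = gent1(10), p = 0.08),
    list(g = op_geom(0.75, 0.15, 20), m = nh(), p = 0.06),
    list(g = op_geom(0.6, 0.2, 60), m = hgo_mat(), p = 0.09),
    list(g = op_geom(0.9, 0.2, 90), m = gent1(1), p = 0.12))
  for (d in draws) {
    rep <- constrained_minimize_membrane(d$g, d$m, d$p)
    expect_true(rep$pass)
    expect_lt(rep$rel_diff, 1e-6)
    # Lagrange condition: equal segment tensions T_i = p rho at the minimizer
    st <- solve_dissected_section(d$g, d$m, d$p)
    par <- attr(rep, "par")
    T1 <- strain_energy_deriv(d$m, par[1]) * d$g$H1
    T2 <- strain_energy_deriv(d$m, par[2]) * d$g$H2
    expect_equal(T1, T2, tolerance = 1e-4)
    expect_equal(T1, st$T, tolerance = 1e-4)
  }
})

test_that("membrane energy matches the thick-wall ring in the thin-wall limit", {
  g <- aorta_geometry(H2 = 0.01, H1 = 0.01, alpha_lim = pi / 6, R = 1)
  p <- 0.004  # below the H/R = 0.01 membrane limit point
  U_mem <- solve_dissected_section(g, nh(), p)$U
  U_ring <- solve_normal_ring(g, nh(), p)$U
  expect_equal(U_mem, U_ring, tolerance = 1e-2)
})

test_that("radius and stretches increase monotonically with pressure", {
  g <- op_geom(0.5)
  sts <- lapply(c(0.04, 0.08, 0.12), function(p)
    solve_dissected_section(g, gent1(1), p))
  expect_true(all(diff(vapply(sts, `[[`, 0, "rho")) > 0))
  expect_true(all(diff(vapply(sts, `[[`, 0, "lam_fl")) > 0))
  expect_true(all(diff(vapply(sts, `[[`, 0, "lam_wall")) > 0))
})

test_that("dissection releases energy and deeper cracks release more", {
  m <- gent1(1)
  p <- 0.1
  U_I <- solve_normal_ring(op_geom(0.5), m, p)$U
  U_II_50 <- solve_dissected_section(op_geom(0.5), m, p)$U
  U_II_75 <- solve_dissected_section(op_geom(0.75), m, p)$U
  expect_lt(U_II_50, U_I)
  expect_lt(U_II_75, U_I)
  # deeper crack (smaller H1/H2) has lower potential energy
  expect_lt(U_II_50, U_II_75)
  expect_equal(potential_energy_dissected(
    solve_dissected_section(op_geom(0.5), m, p)), U_II_50)
})
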