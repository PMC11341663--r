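test_that("strain energy matches hand-evaluated reference values", {
  m <- nh()
  expect_identical(strain_energy(m, 1), 0)
  # (1/2)(1.2^2 + 1.2^-2 - 2)
  expect_equal(strain_energy(m, 1.2), 0.5 * (1.44 + 1 / 1.44 - 2),
               tolerance = 1e-12)
  expect_equal(strain_energy(m, 1.2), 0.06722222, tolerance = 1e-7)

  # Gent converges pointwise to Neo-Hookean as Jm -> Inf
  g <- gent1(1e6)
  expect_equal(strain_energy(g, 1.2), strain_energy(m, 1.2),
               tolerance = 1e-4)

  # HGO with K1 = 0 is exactly Neo-Hookean
  h <- material("hgo", K1 = 0, K2 = 1)
  expect_identical(strain_energy(h, 1.3), strain_energy(m, 1.3))

  # monotone on lam > 1 for all models
  lams <- seq(1, 1.6, by = 0.05)
  for (mat in list(m, gent1(3), hgo_mat())) {
    W <- strain_energy(mat, lams)
    expect_identical(W[1], 0)
    expect_true(all(diff(W) > 0))
  }
})

test_that("analytic stretch derivative agrees with finite differences", {
  # mu (lam - lam^-3) at lam = 1.2
  expect_equal(strain_energy_deriv(nh(), 1.2), 1.2 - 1.2^-3,
               tolerance = 1e-12)
  expect_identical(strain_energy_deriv(nh(), 1), 0)
  lams <- seq(1.05, 1.55, by = 0.1)
  for (mat in list(nh(), gent1(3), hgo_mat(), hgo_mat(0.2, 2),
                   material("hgo", K1 = 0.1, K2 = 1, beta = 0.3))) {
    for (l in lams) {
      num <- fd_central(function(x) strain_energy(mat, x), l, 1e-6)
      expect_equal(strain_energy_deriv(mat, l), num, tolerance = 1e-6)
    }
    # convexity: derivative strictly increasing on the operating range
    expect_true(all(diff(strain_energy_deriv(mat, lams)) > 0))
  }
})

test_that("fiber angle enters through the plane-strain invariant", {
  # beta = pi/2: fibers axial, I = 1, no anisotropic contribution
  h_axial <- material("hgo", K1 = 0.3, K2 = 2, beta = pi / 2)
  expect_identical(strain_energy(h_axial, 1.4), strain_energy(nh(), 1.4))
  # beta = 0: fibers circumferential, I = lam^2
  h_circ <- material("hgo", K1 = 0.3, K2 = 2, beta = 0)
  l <- 1.25
  expect_equal(strain_energy(h_circ, l),
               strain_energy(nh(), l) + 0.3 / 2 * expm1(2 * (l^2 - 1)^2),
               tolerance = 1e-12)
  # default beta = 45 deg: I = lam^2/2 + 1/2
  h45 <- hgo_mat(0.3, 2)
  expect_equal(strain_energy(h45, l),
               strain_energy(nh(), l) +
                 0.3 / 2 * expm1(2 * ((l^2 - 1) / 2)^2),
               tolerance = 1e-12)
})

test_that("Gent strain limit is enforced with informative errors", {
  g <- gent1(1)
  # closed form: lam^2 + lam^-2 - 2 = 1 at the golden ratio
  expect_equal(stretch_limit(g), (1 + sqrt(5)) / 2, tolerance = 1e-12)
  expect_identical(stretch_limit(nh()), Inf)
  lmax <- stretch_limit(g)
  expect_error(strain_energy(g, lmax), class = "aortafract_domain_error")
  expect_error(strain_energy_deriv(g, lmax * 1.01),
               class = "aortafract_domain_error")
  # just below the limit: finite, no overflow
  expect_true(is.finite(strain_energy_deriv(g, lmax * (1 - 1e-9))))
  expect_error(strain_energy(g, 0.8), class = "aortafract_input_error")
  expect_error(strain_energy_deriv(nh(), 0.5),
               class = "aortafract_input_error")
})

test_that("tension inversion round-trips the derivative", {
  expect_identical(invert_tension(nh(), 0), 1)
  expect_equal(invert_tension(nh(), 1.2 - 1.2^-3), 1.2, tolerance = 1e-8)
  for (mat in list(nh(), gent1(3), hgo_mat())) {
    for (l in seq(1, 1.6, by = 0.1)) {
      t <- strain_energy_deriv(mat, l)
      expect_equal(invert_tension(mat, t), l, tolerance = 1e-8)
    }
  }
  # Gent: solution exists for any finite target, below the strain limit
  lam <- invert_tension(gent1(1), 1e3)
  expect_gt(lam, 1)
  expect_lt(lam, (1 + sqrt(5)) / 2)
})

test_that("material constructor validates parameters", {
  expect_error(material("gent"), class = "aortafract_input_error")
  expect_error(material("gent", Jm = -1), class = "aortafract_input_error")
  expect_error(material("hgo", K1 = 0.1), class = "aortafract_input_error")
  expect_error(material("hgo", K1 = -0.1, K2 = 1),
               class = "aortafract_input_error")
  expect_error(material("neo_hookean", mu = 0),
               class = "aortafract_input_error")
  expect_error(material("hgo", K1 = 0.1, K2 = 1, beta = 2),
               class = "aortafract_input_error")
})
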