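#' Equilibrium of the dissected cross-section (two-segment membrane)
#'
#' Models the dissected cross-section as a closed thin-wall membrane with two
#' segments: the intact wall of reference thickness \eqn{H_2} over the angle
#' \eqn{2\pi - 2\alpha_{lim}} (reference mid-surface at `R`) and the
#' false-lumen wall of thickness \eqn{H_1} over \eqn{2\alpha_{lim}}
#' (mid-surface at `R_fl`). The intimal flap carries no load (equal pressure
#' on both sides), so tension and tangent are continuous at the two segment
#' junctions and the deformed mid-surface is a single circle of radius
#' \eqn{\rho}. Each segment obeys the plane membrane law
#' \eqn{T = H_i \hat W'(\lambda_i)} and Laplace's relation \eqn{T = p\rho};
#' the tension is found from the closure condition
#' \deqn{g(T) = \lambda_1(T) L_1 + \lambda_2(T) L_2 - 2\pi T / p = 0,}
#' with reference arc lengths \eqn{L_1 = 2\alpha_{lim} R_{fl}},
#' \eqn{L_2 = (2\pi - 2\alpha_{lim}) R} and
#' \eqn{\lambda_i = } [invert_tension()]`(mat, T/H_i)`.
#'
#' For a uniform Neo-Hookean membrane (`H1 = H2 = H`) this reduces to the
#' closed form \eqn{p/\mu = (H/R)(1 - \lambda^{-4})}, which has no solution
#' for \eqn{p/\mu \ge H/R} (inflation limit point); the solver reports this
#' as a missing equilibrium.
#'
#' @param geom an [aorta_geometry()].
#' @param mat an [material()] object.
#' @param p internal pressure (acts in true and false lumen alike); `p = 0`
#'   returns the reference state.
#' @return An object of class `membrane_state` with tension `T`, deformed
#'   mid-surface radius `rho`, segment stretches `lam_fl` (thin segment) and
#'   `lam_wall`, strain energy `W_SE`, lumen area change `dA_in`, total
#'   potential energy `U` (\eqn{U_{II}}) and `closure_residual`.
#' @examples
#' g <- geometry_from_ratios(0.2, 0.5, 30)
#' solve_dissected_section(g, material("gent", Jm = 1), p = 0.1)
#' @seealso [potential_energy_dissected()], [solve_dissected_bulge()]
#' @export
solve_dissected_section <- function(geom, mat, p) {
  if (!is_geometry(geom)) af_input_error("`geom` must be an aorta_geometry")
  if (!is_material(mat)) af_input_error("`mat` must be an aorta_material")
  stopifnot_scalar(p, "p", nonneg = TRUE)
  alpha <- geom$alpha_lim
  L1 <- 2 * alpha * geom$R_fl
  L2 <- (2 * pi - 2 * alpha) * geom$R

  if (p == 0) {
    return(new_membrane_state(geom, mat, p = 0, T = 0,
                              lam_fl = 1, lam_wall = 1,
                              rho = (L1 + L2) / (2 * pi), closure_residual = 0))
  }

  g <- function(T) {
    invert_tension(mat, T / geom$H1) * L1 +
      invert_tension(mat, T / geom$H2) * L2 - 2 * pi * T / p
  }
  # g(0+) = L1 + L2 > 0; find a sign change by geometric expansion. Near and
  # above the inflation limit point g approaches zero from above like
  # lam^-3, so rounding noise could fake a root at absurd stretches; a
  # stretch bound far outside the soft-tissue regime cuts this off.
  hi <- 1e-8 * mat$mu * geom$H2
  it <- 0L
  while (g(hi) > 0) {
    if (invert_tension(mat, hi / geom$H2) > 50)
      af_no_equilibrium(sprintf(
        "no equilibrium: pressure above membrane limit point (p/mu = %g)",
        p / mat$mu))
    hi <- hi * 2
    it <- it + 1L
    if (it > 80L)
      af_no_equilibrium(sprintf(
        "no equilibrium: pressure above membrane limit point (p/mu = %g)",
        p / mat$mu))
  }
  T <- stats::uniroot(g, c(hi / 1e6, hi), tol = 1e-14 * mat$mu * geom$H2,
                      extendInt = "downX")$root
  new_membrane_state(geom, mat, p, T = T,
                     lam_fl = invert_tension(mat, T / geom$H1),
                     lam_wall = invert_tension(mat, T / geom$H2),
                     rho = T / p, closure_residual = g(T))
}

new_membrane_state <- function(geom, mat, p, T, lam_fl, lam_wall, rho,
                               closure_residual) {
  alpha <- geom$alpha_lim
  L1 <- 2 * alpha * geom$R_fl
  L2 <- (2 * pi - 2 * alpha) * geom$R
  h1 <- geom$H1 / lam_fl
  h2 <- geom$H2 / lam_wall
  W_SE <- strain_energy(mat, lam_fl) * geom$H1 * L1 +
    strain_energy(mat, lam_wall) * geom$H2 * L2
  # Lumen bookkeeping on inner surfaces: reference inner surfaces at R_in
  # (intact) and R_c (crack surface); deformed at rho - h_i/2.
  dA_in <- ((pi - alpha) * (rho - h2 / 2)^2 + alpha * (rho - h1 / 2)^2) -
    ((pi - alpha) * geom$R_in^2 + alpha * geom$R_c^2)
  structure(list(
    T = T, rho = rho, lam_fl = lam_fl, lam_wall = lam_wall,
    W_SE = W_SE, dA_in = dA_in, U = W_SE - p * dA_in,
    closure_residual = closure_residual,
    p = p, geom = geom, mat = mat), class = "membrane_state")
}

#' @export
print.membrane_state <- function(x, ...) {
  cat(sprintf(
    "<membrane_state> p/mu = %g: T = %.8g, rho = %.8g\n  lam_fl = %.6f, lam_wall = %.6f, U = %.8g, closure = %.2e\n",
    x$p / x$mat$mu, x$T, x$rho, x$lam_fl, x$lam_wall, x$U,
    x$closure_residual))
  invisible(x)
}

#' Total potential energy of the dissected section
#'
#' Recomputes \eqn{U_{II} = W_{SE} - p\,\Delta A_{in}} from a converged
#' membrane state, with
#' \eqn{W_{SE} = \hat W(\lambda_1) H_1 L_1 + \hat W(\lambda_2) H_2 L_2} and
#' the lumen area change accounted on inner surfaces with deformed
#' thicknesses \eqn{h_i = H_i/\lambda_i}.
#'
#' @param state a `membrane_state` from [solve_dissected_section()].
#' @param geom geometry; defaults to the one stored in the state.
#' @param p pressure; defaults to the one stored in the state.
#' @return \eqn{U_{II}}, energy per unit axial length.
#' @export
potential_energy_dissected <- function(state, geom = state$geom, p = state$p) {
  if (!inherits(state, "membrane_state"))
    af_input_error("`state` must be a membrane_state")
  state$W_SE - p * state$dA_in
}

#' Dissected section with a pinned false-lumen bulge (alternative model)
#'
#' Alternative reconstruction of the dissected cross-section: the intact wall
#' keeps the thick-wall ring solution of [solve_normal_ring()] over its
#' angular extent \eqn{2\pi - 2\alpha_{lim}}, while the false-lumen wall is a
#' membrane arc of thickness \eqn{H_1} pinned at the deformed crack edges
#' (material points at reference radius `R_c`) and bulging outward as a
#' circular arc of radius \eqn{\rho_b = T/p} (Laplace). The bulge geometry is
#' set by its half-angle \eqn{\varphi}: with pin chord \eqn{c = 2 r_c
#' \sin\alpha_{lim}}, the arc stretch is \eqn{\lambda_1 = c\varphi /
#' (\sin\varphi\, L_1)} and \eqn{\varphi} solves the tension balance
#' \eqn{H_1 \hat W'(\lambda_1) = p\, c/(2\sin\varphi)}.
#'
#' Unlike the single-circle membrane of [solve_dissected_section()], this
#' model releases energy even at `H1 = H2` (the freed sector bulges beyond
#' the ring), mirroring the outward bulge finite-element models show for a
#' dissected section.
#'
#' @inheritParams solve_dissected_section
#' @return An object of class `bulge_state` with the ring sub-state, bulge
#'   half-angle `phi`, bulge radius `rho_b`, stretch `lam_fl`, `W_SE`,
#'   `dA_in` and total potential energy `U`.
#' @export
solve_dissected_bulge <- function(geom, mat, p) {
  if (!is_geometry(geom)) af_input_error("`geom` must be an aorta_geometry")
  if (!is_material(mat)) af_input_error("`mat` must be an aorta_material")
  stopifnot_scalar(p, "p", nonneg = TRUE)
  alpha <- geom$alpha_lim
  L1 <- 2 * alpha * geom$R_fl
  ring <- solve_normal_ring(geom, mat, p)
  if (p == 0) {
    return(structure(list(
      ring = ring, phi = alpha, rho_b = geom$R_c, lam_fl = 1,
      W_SE = 0, dA_in = 0, U = 0, p = p, geom = geom, mat = mat),
      class = "bulge_state"))
  }
  rc <- sqrt(ring$a^2 - geom$R_in^2 + geom$R_c^2)
  cch <- 2 * rc * sin(alpha)
  lam1 <- function(phi) cch * phi / (sin(phi) * L1)
  bal <- function(phi) {
    strain_energy_deriv(mat, lam1(phi)) * geom$H1 - p * cch / (2 * sin(phi))
  }
  # Bracket in phi: below, the smallest angle with lambda_1 >= 1; above, the
  # Gent strain limit (or nearly a full circle for unbounded materials).
  gl <- function(phi) lam1(phi) - 1
  lo <- if (gl(1e-8) >= 0) 1e-8 else
    stats::uniroot(gl, c(1e-8, pi - 1e-8), tol = 1e-14)$root + 1e-10
  lmax <- stretch_limit(mat)
  hi <- if (is.finite(lmax)) {
    stats::uniroot(function(phi) lam1(phi) - lmax * (1 - 1e-9),
                   c(lo, pi - 1e-9), tol = 1e-14)$root - 1e-10
  } else pi - 1e-7
  if (bal(hi) < 0)
    af_no_equilibrium(sprintf(
      "no equilibrium: false-lumen bulge above its limit point (p/mu = %g)",
      p / mat$mu))
  phi <- stats::uniroot(bal, c(lo, hi), tol = 1e-14)$root
  l1 <- lam1(phi)
  rho_b <- cch / (2 * sin(phi))
  h1 <- geom$H1 / l1
  W_SE <- ring$W_SE * (1 - alpha / pi) + strain_energy(mat, l1) * geom$H1 * L1
  # Enclosed (pressurized) area: intact inner-wall sector + triangle to the
  # pins + circular segment of the bulge inner surface.
  rho_in <- rho_b - h1 / 2
  phi_in <- asin(min(1, cch / (2 * rho_in)))
  if (phi > pi / 2) phi_in <- pi - phi_in
  seg <- 0.5 * rho_in^2 * (2 * phi_in - sin(2 * phi_in))
  A_def <- (pi - alpha) * ring$a^2 + rc^2 * sin(alpha) * cos(alpha) + seg
  A_ref <- (pi - alpha) * geom$R_in^2 + alpha * geom$R_c^2
  dA_in <- A_def - A_ref
  structure(list(
    ring = ring, phi = phi, rho_b = rho_b, lam_fl = l1,
    W_SE = W_SE, dA_in = dA_in, U = W_SE - p * dA_in,
    p = p, geom = geom, mat = mat), class = "bulge_state")
}

#' @export
print.bulge_state <- function(x, ...) {
  cat(sprintf(
    "<bulge_state> p/mu = %g: phi = %.6g rad, rho_b = %.8g, lam_fl = %.6f, U = %.8g\n",
    x$p / x$mat$mu, x$phi, x$rho_b, x$lam_fl, x$U))
  invisible(x)
}

# Potential energy of the dissected section under the selected model.
dissected_energy <- function(geom, mat, p,
                             model = c("single_circle", "bulge")) {
  model <- match.arg(model)
  switch(model,
    single_circle = solve_dissected_section(geom, mat, p)$U,
    bulge = solve_dissected_bulge(geom, mat, p)$U)
}
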