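#' Equilibrium of the normal (uncracked) aortic annulus
#'
#' Solves the exact axisymmetric finite-strain boundary-value problem of an
#' incompressible plane-strain thick-walled cylinder under internal pressure
#' `p`. Incompressibility fixes the kinematics to
#' \eqn{r(\rho) = \sqrt{a^2 - R_{in}^2 + \rho^2}} for reference radius
#' \eqn{\rho \in [R_{in}, R_{out}]}, so the deformed inner radius `a` is the
#' single unknown. Radial equilibrium with
#' \eqn{\sigma_{\theta\theta} - \sigma_{rr} = \lambda \hat W'(\lambda)} and
#' traction conditions \eqn{\sigma_{rr}(R_{in}) = -p},
#' \eqn{\sigma_{rr}(R_{out}) = 0} give the scalar condition
#' \deqn{\int_{R_{in}}^{R_{out}} \lambda \hat W'(\lambda)\, \frac{\rho}{r^2}
#'   \, d\rho = p,}
#' solved by safeguarded root finding with geometric bracket expansion.
#'
#' @param geom an [aorta_geometry()]; only `R`, `H2` matter here.
#' @param mat an [material()] object.
#' @param p internal pressure (same units as `mat$mu`), \eqn{\ge 0}.
#' @param warm_start optional previous deformed inner radius used to seed the
#'   bracket (continuation along a pressure sweep).
#' @return An object of class `ring_state` with elements
#'   \describe{
#'     \item{`a`}{deformed inner radius.}
#'     \item{`lam_profile`}{function \eqn{\rho \mapsto \lambda_\theta(\rho)}.}
#'     \item{`W_SE`}{strain energy per unit axial length,
#'       \eqn{\int \hat W\, 2\pi\rho\, d\rho} over the reference wall.}
#'     \item{`dA_in`}{lumen area change \eqn{\pi(a^2 - R_{in}^2)}.}
#'     \item{`U`}{total potential energy per unit length
#'       \eqn{U_I = W_{SE} - p\, \Delta A_{in}}.}
#'     \item{`residual`}{boundary-condition defect at the solution (stress
#'       units).}
#'   }
#' @examples
#' g <- geometry_from_ratios(0.2, 0.5, 30)
#' st <- solve_normal_ring(g, material("neo_hookean"), p = 0.1)
#' st$U
#' @seealso [potential_energy_normal()], [ring_stress()]
#' @export
solve_normal_ring <- function(geom, mat, p, warm_start = NULL) {
  if (!is_geometry(geom)) af_input_error("`geom` must be an aorta_geometry")
  if (!is_material(mat)) af_input_error("`mat` must be an aorta_material")
  stopifnot_scalar(p, "p", nonneg = TRUE)
  R_in <- geom$R_in; R_out <- geom$R_out

  if (p == 0) {
    return(new_ring_state(geom, mat, p, a = R_in, residual = 0))
  }

  resid <- function(a) ring_residual(a, R_in, R_out, mat) - p

  # The kinematic family is capped by the Gent strain limit at the inner wall
  # (lambda is largest there); for unbounded materials use a generous cap and
  # fail gracefully if the residual never reaches p (limit-point pressure).
  lmax <- stretch_limit(mat)
  cap <- if (is.finite(lmax)) R_in * lmax else R_in * 100
  k <- if (!is.null(warm_start) && warm_start > R_in) {
    min(1 - 1e-7, max(1e-6, (warm_start - R_in) / (cap - R_in)))
  } else 1e-6
  hi <- R_in + (cap - R_in) * k
  repeat {
    rv <- resid(hi)
    if (rv >= 0) break
    if (k >= 1 - 1e-7) {
      if (is.finite(lmax))
        af_domain_error(sprintf(
          "solve_normal_ring: Gent strain limit reached inside the wall before the residual matched p = %g", p))
      af_no_equilibrium(sprintf(
        "no equilibrium: pressure above limit point (p = %g, residual deficit %g)",
        p, -rv))
    }
    k <- min(1 - 1e-7, k * 2)
    hi <- R_in + (cap - R_in) * k
  }
  a <- stats::uniroot(resid, c(R_in, hi), tol = 1e-12 * R_in)$root
  new_ring_state(geom, mat, p, a = a, residual = resid(a))
}

# Pressure supported by the kinematic state with deformed inner radius a.
ring_residual <- function(a, R_in, R_out, mat) {
  if (a <= R_in) return(0)
  f <- function(rho) {
    r2 <- a^2 - R_in^2 + rho^2
    lam <- sqrt(r2) / rho
    lam * strain_energy_deriv(mat, lam) * rho / r2
  }
  af_quad(f, R_in, R_out)
}

new_ring_state <- function(geom, mat, p, a, residual) {
  R_in <- geom$R_in; R_out <- geom$R_out
  lam_profile <- function(rho) sqrt(1 + (a^2 - R_in^2) / rho^2)
  W_SE <- if (a > R_in) {
    af_quad(function(rho) strain_energy(mat, lam_profile(rho)) * 2 * pi * rho,
            R_in, R_out)
  } else 0
  dA_in <- pi * (a^2 - R_in^2)
  structure(list(
    a = a, lam_profile = lam_profile, W_SE = W_SE, dA_in = dA_in,
    U = W_SE - p * dA_in, residual = residual,
    p = p, geom = geom, mat = mat), class = "ring_state")
}

#' @export
print.ring_state <- function(x, ...) {
  cat(sprintf(
    "<ring_state> p/mu = %g: a = %.8g (a/R_in = %.6g)\n  W_SE = %.8g, dA_in = %.8g, U = %.8g, residual = %.2e\n",
    x$p / x$mat$mu, x$a, x$a / x$geom$R_in, x$W_SE, x$dA_in, x$U, x$residual))
  invisible(x)
}

#' Total potential energy of the normal section
#'
#' Recomputes \eqn{U_I = W_{SE} - p\,\Delta A_{in}} from a converged ring
#' state, integrating the strain-energy density over the reference
#' cross-section (reference and deformed wall areas coincide by
#' incompressibility).
#'
#' @param state a `ring_state` from [solve_normal_ring()].
#' @param p pressure; defaults to the pressure the state was solved at.
#' @return \eqn{U_I}, energy per unit axial length.
#' @export
potential_energy_normal <- function(state, p = state$p) {
  if (!inherits(state, "ring_state"))
    af_input_error("`state` must be a ring_state")
  state$W_SE - p * state$dA_in
}

#' Cauchy stress profile of the normal ring
#'
#' Radial and hoop Cauchy stresses through the wall at reference radii `rho`:
#' \eqn{\sigma_{rr}(\rho) = -p + \int_{R_{in}}^{\rho} \lambda \hat W'
#' (\lambda) \rho'/r^2 d\rho'} and \eqn{\sigma_{\theta\theta} = \sigma_{rr} +
#' \lambda \hat W'(\lambda)}.
#'
#' @param state a `ring_state`.
#' @param rho reference radii in `[R_in, R_out]`.
#' @return data frame with columns `rho`, `r`, `lam`, `srr`, `stt`.
#' @export
ring_stress <- function(state, rho) {
  geom <- state$geom; mat <- state$mat
  a <- state$a; R_in <- geom$R_in
  one <- function(rh) {
    if (rh < R_in - 1e-12 || rh > geom$R_out + 1e-12)
      af_input_error("`rho` outside the wall")
    srr <- -state$p + if (rh > R_in && a > R_in) {
      af_quad(function(x) {
        r2 <- a^2 - R_in^2 + x^2
        lam <- sqrt(r2) / x
        lam * strain_energy_deriv(mat, lam) * x / r2
      }, R_in, rh)
    } else 0
    lam <- state$lam_profile(rh)
    c(srr = srr, stt = srr + lam * strain_energy_deriv(mat, lam), lam = lam)
  }
  res <- vapply(rho, one, c(srr = 0, stt = 0, lam = 0))
  data.frame(rho = rho, r = sqrt(a^2 - R_in^2 + rho^2),
             lam = res["lam", ], srr = res["srr", ], stt = res["stt", ])
}
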