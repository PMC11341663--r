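#' Hyperelastic material specification
#'
#' Defines the constitutive law of the aortic wall. Three incompressible
#' plane-strain models are supported, all reduced to a single circumferential
#' stretch \eqn{\lambda} via \eqn{\lambda_1 = \lambda_\theta = \lambda},
#' \eqn{\lambda_2 = \lambda_r = 1/\lambda}, \eqn{\lambda_3 = \lambda_z = 1}:
#'
#' \describe{
#'   \item{`neo_hookean`}{\eqn{\hat W = (\mu/2)(\lambda^2 + \lambda^{-2} - 2)},
#'     ideal rubber elasticity.}
#'   \item{`gent`}{\eqn{\hat W = -(\mu J_m/2)\,
#'     \ln[1 - (\lambda^2 + \lambda^{-2} - 2)/J_m]}, strain stiffening from
#'     chain inextensibility; the strain invariant is capped at \eqn{J_m}.}
#'   \item{`hgo`}{Neo-Hookean elastin matrix plus an exponential collagen
#'     fiber term \eqn{(K_1/K_2)(e^{K_2 (I-1)^2} - 1)} with mean-fiber
#'     invariant \eqn{I = \lambda^2 \cos^2\beta + \sin^2\beta} (plane strain,
#'     \eqn{\lambda_z = 1}); the fiber term is active only in fiber tension
#'     (\eqn{I > 1}).}
#' }
#'
#' With \eqn{\beta = 45^\circ} (the default, representative of the mean
#' collagen direction in the aortic media) the invariant reduces to
#' \eqn{I = \lambda^2/2 + 1/2}.
#'
#' @param kind one of `"neo_hookean"`, `"gent"`, `"hgo"`.
#' @param mu shear modulus (stress units; 1 in dimensionless runs).
#' @param Jm Gent strain limit (dimensionless); required for `"gent"`.
#' @param K1 fiber stiffness (stress units, \eqn{\ge 0}); required for `"hgo"`.
#' @param K2 fiber strain-stiffening exponent (dimensionless, \eqn{> 0});
#'   required for `"hgo"`.
#' @param beta fiber angle from the circumferential direction, radians in
#'   \eqn{[0, \pi/2]}. Default \eqn{\pi/4}.
#' @return An object of class `aorta_material`.
#' @examples
#' material("gent", Jm = 1)
#' material("hgo", K1 = 0.05, K2 = 1)
#' @seealso [strain_energy()], [strain_energy_deriv()], [invert_tension()]
#' @export
material <- function(kind = c("neo_hookean", "gent", "hgo"), mu = 1,
                     Jm = NULL, K1 = NULL, K2 = NULL, beta = pi / 4) {
  kind <- match.arg(kind)
  stopifnot_scalar(mu, "mu", positive = TRUE)
  stopifnot_scalar(beta, "beta")
  if (beta < 0 || beta > pi / 2)
    af_input_error("`beta` must lie in [0, pi/2]")
  if (kind == "gent") {
    if (is.null(Jm)) af_input_error("`Jm` is required for the Gent model")
    stopifnot_scalar(Jm, "Jm", positive = TRUE)
  }
  if (kind == "hgo") {
    if (is.null(K1) || is.null(K2))
      af_input_error("`K1` and `K2` are required for the HGO model")
    stopifnot_scalar(K1, "K1", nonneg = TRUE)
    stopifnot_scalar(K2, "K2", positive = TRUE)
  }
  structure(list(kind = kind, mu = mu, Jm = Jm, K1 = K1, K2 = K2, beta = beta),
            class = "aorta_material")
}

#' @export
print.aorta_material <- function(x, ...) {
  par <- switch(x$kind,
    neo_hookean = sprintf("mu = %g", x$mu),
    gent = sprintf("mu = %g, Jm = %g", x$mu, x$Jm),
    hgo = sprintf("mu = %g, K1 = %g, K2 = %g, beta = %g deg",
                  x$mu, x$K1, x$K2, x$beta * 180 / pi))
  cat(sprintf("<aorta_material> %s (%s)\n", x$kind, par))
  invisible(x)
}

is_material <- function(x) inherits(x, "aorta_material")

#' Largest admissible stretch of a Gent material
#'
#' Solves \eqn{\lambda^2 + \lambda^{-2} - 2 = J_m} in closed form. Other
#' material models have no finite stretch limit and return `Inf`.
#'
#' @param mat an [material()] object.
#' @return the limiting stretch \eqn{\lambda_{max} > 1}, or `Inf`.
#' @examples
#' stretch_limit(material("gent", Jm = 1)) # golden ratio (1 + sqrt(5))/2
#' @export
stretch_limit <- function(mat) {
  if (!is_material(mat)) af_input_error("`mat` must be an aorta_material")
  if (mat$kind != "gent") return(Inf)
  # lam^2 solves x + 1/x = Jm + 2
  s <- mat$Jm + 2
  sqrt((s + sqrt(s^2 - 4)) / 2)
}

check_lam <- function(mat, lam) {
  if (any(!is.finite(lam)) || any(lam < 1 - 1e-12))
    af_input_error("stretch `lam` must be finite and >= 1")
  if (mat$kind == "gent") {
    lmax <- stretch_limit(mat)
    if (any(lam >= lmax))
      af_domain_error(sprintf(
        "Gent strain limit reached: lam = %g >= lam_max = %.10g (Jm = %g)",
        max(lam), lmax, mat$Jm))
  }
  invisible(lam)
}

hgo_invariant <- function(mat, lam) lam^2 * cos(mat$beta)^2 + sin(mat$beta)^2

#' Plane-strain strain-energy density
#'
#' Evaluates the reduced strain energy per unit reference volume
#' \eqn{\hat W(\lambda)} of an incompressible material in plane strain at
#' circumferential stretch \eqn{\lambda \ge 1}. \eqn{\hat W(1) = 0} and
#' \eqn{\hat W} is strictly increasing for \eqn{\lambda > 1}.
#'
#' @param mat an [material()] object.
#' @param lam circumferential stretch(es), \eqn{\ge 1}; vectorized.
#' @return energy per unit reference volume (stress units).
#' @examples
#' strain_energy(material("neo_hookean"), 1.2) # 0.0672222...
#' @export
strain_energy <- function(mat, lam) {
  if (!is_material(mat)) af_input_error("`mat` must be an aorta_material")
  check_lam(mat, lam)
  e <- lam^2 + lam^-2 - 2
  switch(mat$kind,
    neo_hookean = mat$mu / 2 * e,
    gent = -mat$mu * mat$Jm / 2 * log1p(-e / mat$Jm),
    hgo = {
      I <- hgo_invariant(mat, lam)
      fib <- ifelse(I > 1, mat$K1 / mat$K2 * expm1(mat$K2 * (I - 1)^2), 0)
      mat$mu / 2 * e + fib
    })
}

#' Stretch derivative of the strain-energy density
#'
#' Analytic \eqn{d\hat W/d\lambda}. The hoop--radial Cauchy stress difference
#' of the incompressible plane-strain problem is
#' \eqn{\sigma_{\theta\theta} - \sigma_{rr} = \lambda\, \hat W'(\lambda)}, and
#' the membrane tension per unit axial length of a wall of reference thickness
#' \eqn{H} is \eqn{T = H\, \hat W'(\lambda)}.
#'
#' @inheritParams strain_energy
#' @return \eqn{d\hat W/d\lambda} (stress units); zero at \eqn{\lambda = 1},
#'   positive and strictly increasing for \eqn{\lambda > 1}.
#' @examples
#' strain_energy_deriv(material("neo_hookean"), 1.2) # 0.6212963
#' @export
strain_energy_deriv <- function(mat, lam) {
  if (!is_material(mat)) af_input_error("`mat` must be an aorta_material")
  check_lam(mat, lam)
  base <- mat$mu * (lam - lam^-3)
  switch(mat$kind,
    neo_hookean = base,
    gent = base / (1 - (lam^2 + lam^-2 - 2) / mat$Jm),
    hgo = {
      I <- hgo_invariant(mat, lam)
      fib <- ifelse(I > 1,
        4 * mat$K1 * lam * cos(mat$beta)^2 * (I - 1) * exp(mat$K2 * (I - 1)^2),
        0)
      base + fib
    })
}

#' Invert the tension--stretch relation
#'
#' Finds the unique \eqn{\lambda \ge 1} with
#' \eqn{\hat W'(\lambda) = } `target`. Used by the membrane solver to map a
#' tension (per unit reference thickness) back to a stretch. For the Gent
#' model the solution always exists below the strain limit because
#' \eqn{\hat W'} diverges there.
#'
#' @param mat an [material()] object.
#' @param target value of \eqn{d\hat W/d\lambda}, \eqn{\ge 0}.
#' @param tol relative tolerance on \eqn{\lambda}.
#' @return the stretch \eqn{\lambda \ge 1}.
#' @examples
#' invert_tension(material("neo_hookean"), 0.6212963) # 1.2
#' @export
invert_tension <- function(mat, target, tol = 1e-12) {
  if (!is_material(mat)) af_input_error("`mat` must be an aorta_material")
  stopifnot_scalar(target, "target", nonneg = TRUE)
  if (target == 0) return(1)
  f <- function(l) strain_energy_deriv(mat, l) - target
  lmax <- stretch_limit(mat)
  if (is.finite(lmax)) {
    hi <- lmax * (1 - 1e-13)
    if (f(hi) < 0)
      af_solver_error(sprintf(
        "invert_tension: no root below the Gent strain limit in [1, %g]", hi))
  } else {
    hi <- 2
    it <- 0L
    while (f(hi) < 0) {
      hi <- hi * 2
      it <- it + 1L
      if (it > 200L)
        af_solver_error(sprintf(
          "invert_tension: bracketing failed, last bracket [1, %g]", hi))
    }
  }
  stats::uniroot(f, c(1, hi), tol = tol)$root
}
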