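#' Reference cross-section geometry of the aorta
#'
#' Describes the stress-free cross-section of a (possibly dissected) aorta:
#' an annulus of mean radius `R` and full-wall (true-lumen wall) thickness
#' `H2`; the tear spans the angle \eqn{2\,\alpha_{lim}} and leaves a
#' false-lumen wall of thickness `H1` on the outside of the crack surface.
#'
#' Derived radii:
#' \describe{
#'   \item{`R_in = R - H2/2`}{inner wall surface.}
#'   \item{`R_out = R + H2/2`}{outer wall surface.}
#'   \item{`R_c = R + H2/2 - H1`}{crack surface (outer wall radius minus the
#'     false-lumen wall thickness).}
#'   \item{`R_fl = R + H2/2 - H1/2`}{mid-surface of the false-lumen wall.}
#' }
#'
#' @param H2 true-lumen wall thickness (TLWT), `0 < H2 < 2 R`.
#' @param H1 false-lumen wall thickness (FLWT), `0 < H1 <= H2`.
#' @param alpha_lim crack half-angle in radians, in \eqn{(0, \pi)}; the crack
#'   spans `2 * alpha_lim`.
#' @param R mean wall radius (1 in dimensionless runs).
#' @return An object of class `aorta_geometry`.
#' @examples
#' aorta_geometry(H2 = 0.2, H1 = 0.1, alpha_lim = deg2rad(30))
#' @export
aorta_geometry <- function(H2, H1 = H2, alpha_lim = pi / 6, R = 1) {
  stopifnot_scalar(R, "R", positive = TRUE)
  stopifnot_scalar(H2, "H2", positive = TRUE)
  stopifnot_scalar(H1, "H1", positive = TRUE)
  stopifnot_scalar(alpha_lim, "alpha_lim", positive = TRUE)
  if (H1 > H2 + 1e-15) af_input_error("`H1` must satisfy 0 < H1 <= H2")
  if (H2 >= 2 * R) af_input_error("`H2` must be < 2 R (positive inner radius)")
  if (alpha_lim >= pi) af_input_error("`alpha_lim` must be < pi")
  g <- list(R = R, H2 = H2, H1 = H1, alpha_lim = alpha_lim,
            R_in = R - H2 / 2, R_out = R + H2 / 2,
            R_c = R + H2 / 2 - H1, R_fl = R + H2 / 2 - H1 / 2)
  structure(g, class = "aorta_geometry")
}

#' Geometry from dimensionless ratios
#'
#' Convenience wrapper building an [aorta_geometry()] with `R = 1` from the
#' dimensionless ratios the literature reports.
#'
#' @param h2_over_r wall thickness ratio \eqn{H_2/R}.
#' @param h1_over_h2 tear-depth ratio \eqn{H_1/H_2} (deeper tear = smaller
#'   ratio).
#' @param alpha_deg crack half-angle in degrees.
#' @return An `aorta_geometry` with `R = 1`.
#' @examples
#' geometry_from_ratios(0.2, 0.5, 30)
#' @export
geometry_from_ratios <- function(h2_over_r, h1_over_h2, alpha_deg = 30) {
  aorta_geometry(H2 = h2_over_r, H1 = h1_over_h2 * h2_over_r,
                 alpha_lim = deg2rad(alpha_deg), R = 1)
}

#' @export
print.aorta_geometry <- function(x, ...) {
  cat(sprintf(
    "<aorta_geometry> R = %g, H2/R = %g, H1/H2 = %g, alpha_lim = %g deg\n",
    x$R, x$H2 / x$R, x$H1 / x$H2, x$alpha_lim * 180 / pi))
  cat(sprintf("  R_in = %g, R_out = %g, R_c = %g, R_fl = %g\n",
              x$R_in, x$R_out, x$R_c, x$R_fl))
  invisible(x)
}

is_geometry <- function(x) inherits(x, "aorta_geometry")

# Replace the crack half-angle, keeping everything else (used by the
# circumferential upwind difference and angle sweeps).
with_alpha <- function(geom, alpha) {
  aorta_geometry(H2 = geom$H2, H1 = geom$H1, alpha_lim = alpha, R = geom$R)
}
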