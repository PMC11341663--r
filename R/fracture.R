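#' Energy release rate for longitudinal tear propagation
#'
#' As a tear advances longitudinally, a slice of normal aorta (potential
#' energy \eqn{U_I} per unit length) is converted into dissected aorta
#' (\eqn{U_{II}}) at fixed crack angle. The crack length is the reference arc
#' length of the crack surface, \eqn{(R + H_2/2 - H_1)\cdot 2\alpha_{lim}},
#' so
#' \deqn{G = \frac{U_I - U_{II}}{(R + H_2/2 - H_1)\, 2 \alpha_{lim}},}
#' reported in the dimensionless form \eqn{G/(\mu R)}.
#'
#' @param geom an [aorta_geometry()].
#' @param mat an [material()] object.
#' @param p internal pressure.
#' @param normal_model `"thick"` (default; exact thick-wall ring) or
#'   `"membrane"` (uniform single-circle membrane with `H1 = H2`, a thin-wall
#'   consistency mode).
#' @param dissected_model `"single_circle"` (default, [solve_dissected_section()])
#'   or `"bulge"` ([solve_dissected_bulge()]).
#' @return An object of class `energy_release` with `direction`, `G_norm`
#'   (\eqn{G/(\mu R)}), `U_I_norm`, `U_II_norm` (energies over \eqn{\mu R^2})
#'   and the inputs.
#' @examples
#' g <- geometry_from_ratios(0.2, 0.5, 30)
#' energy_release_longitudinal(g, material("gent", Jm = 1), p = 0.1)
#' @export
energy_release_longitudinal <- function(geom, mat, p,
                                        normal_model = c("thick", "membrane"),
                                        dissected_model = c("single_circle",
                                                            "bulge")) {
  normal_model <- match.arg(normal_model)
  dissected_model <- match.arg(dissected_model)
  U_I <- normal_energy(geom, mat, p, normal_model)
  U_II <- withCallingHandlers(
    dissected_energy(geom, mat, p, dissected_model),
    aortafract_error = function(e) {
      e$message <- paste0("dissected section: ", conditionMessage(e))
      stop(e)
    })
  crack_len <- geom$R_c * 2 * geom$alpha_lim
  new_energy_release("longitudinal", (U_I - U_II) / crack_len,
                     U_I, U_II, geom, mat, p, delta_alpha = NA_real_,
                     dissected_model = dissected_model)
}

normal_energy <- function(geom, mat, p, normal_model) {
  withCallingHandlers({
    if (normal_model == "thick") {
      solve_normal_ring(geom, mat, p)$U
    } else {
      solve_dissected_section(
        aorta_geometry(H2 = geom$H2, H1 = geom$H2,
                       alpha_lim = geom$alpha_lim, R = geom$R),
        mat, p)$U
    }
  }, aortafract_error = function(e) {
    e$message <- paste0("normal section: ", conditionMessage(e))
    stop(e)
  })
}

#' Energy release rate for circumferential tear propagation
#'
#' As the tear widens circumferentially from crack half-angle
#' \eqn{\alpha_{lim}} to \eqn{\alpha_{lim} + \Delta\alpha}, the dissected
#' section's potential energy drops and the crack gains reference length
#' \eqn{R_c \cdot 2\Delta\alpha}. The upwind (forward-difference) scheme is
#' \deqn{G = \frac{U_{II}(\alpha_{lim}) - U_{II}(\alpha_{lim} +
#'   \Delta\alpha)}{(R + H_2/2 - H_1)\, 2\Delta\alpha},}
#' reported as \eqn{G/(\mu R)}. The default increment is
#' \eqn{\Delta\alpha = 4^\circ}.
#'
#' @inheritParams energy_release_longitudinal
#' @param delta_alpha angular increment in radians (default `deg2rad(4)`).
#' @return An `energy_release` object (here `U_I_norm` holds
#'   \eqn{U_{II}(\alpha_{lim})} and `U_II_norm` holds
#'   \eqn{U_{II}(\alpha_{lim}+\Delta\alpha)}).
#' @examples
#' g <- geometry_from_ratios(0.2, 0.5, 30)
#' energy_release_circumferential(g, material("gent", Jm = 1), p = 0.1)
#' @export
energy_release_circumferential <- function(geom, mat, p,
                                           delta_alpha = deg2rad(4),
                                           dissected_model = c("single_circle",
                                                               "bulge")) {
  dissected_model <- match.arg(dissected_model)
  stopifnot_scalar(delta_alpha, "delta_alpha", positive = TRUE)
  if (geom$alpha_lim + delta_alpha >= pi)
    af_input_error("`alpha_lim + delta_alpha` must be < pi")
  U_a <- dissected_energy(geom, mat, p, dissected_model)
  U_b <- dissected_energy(with_alpha(geom, geom$alpha_lim + delta_alpha),
                          mat, p, dissected_model)
  crack_len_inc <- geom$R_c * 2 * delta_alpha
  new_energy_release("circumferential", (U_a - U_b) / crack_len_inc,
                     U_a, U_b, geom, mat, p, delta_alpha = delta_alpha,
                     dissected_model = dissected_model)
}

new_energy_release <- function(direction, G, U_I, U_II, geom, mat, p,
                               delta_alpha, dissected_model) {
  muR <- mat$mu * geom$R
  structure(list(
    direction = direction,
    G_norm = G / muR,
    U_I_norm = U_I / (muR * geom$R),
    U_II_norm = U_II / (muR * geom$R),
    inputs = list(geom = geom, mat = mat, p = p, delta_alpha = delta_alpha,
                  dissected_model = dissected_model)),
    class = "energy_release")
}

#' @export
print.energy_release <- function(x, ...) {
  cat(sprintf("<energy_release> %s: G/(mu R) = %.6g  (p/mu = %g)\n",
              x$direction, x$G_norm,
              x$inputs$p / x$inputs$mat$mu))
  invisible(x)
}

#' Energy release rate along a grid of crack angles
#'
#' Sweeps the crack half-angle at fixed pressure, material and thickness
#' ratios. Failures at individual grid points (e.g. a pressure above a local
#' limit point) are recorded as `NA` with the error message, without aborting
#' the sweep.
#'
#' @param geom an [aorta_geometry()] providing `R`, `H1`, `H2`; its
#'   `alpha_lim` is replaced by each grid value.
#' @param mat an [material()] object.
#' @param p internal pressure.
#' @param direction `"longitudinal"` or `"circumferential"`.
#' @param alpha_grid crack half-angles in radians, each in
#'   \eqn{(0, \pi - \Delta\alpha)}.
#' @param delta_alpha upwind increment for the circumferential direction.
#' @param dissected_model dissected-section model, as in
#'   [energy_release_longitudinal()].
#' @return data frame with columns `alpha`, `alpha_deg`, `G_norm`, `error`.
#' @export
crack_angle_profile <- function(geom, mat, p,
                                direction = c("longitudinal",
                                              "circumferential"),
                                alpha_grid,
                                delta_alpha = deg2rad(4),
                                dissected_model = c("single_circle",
                                                    "bulge")) {
  direction <- match.arg(direction)
  dissected_model <- match.arg(dissected_model)
  if (length(alpha_grid) < 1) af_input_error("`alpha_grid` must be non-empty")
  rows <- lapply(alpha_grid, function(al) {
    gi <- with_alpha(geom, al)
    res <- tryCatch({
      er <- if (direction == "longitudinal") {
        energy_release_longitudinal(gi, mat, p,
                                    dissected_model = dissected_model)
      } else {
        energy_release_circumferential(gi, mat, p, delta_alpha,
                                       dissected_model = dissected_model)
      }
      list(G = er$G_norm, err = NA_character_)
    }, aortafract_error = function(e) {
      list(G = NA_real_, err = conditionMessage(e))
    })
    data.frame(alpha = al, alpha_deg = al * 180 / pi,
               G_norm = res$G, error = res$err,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
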