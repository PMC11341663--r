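#' Dimensionless fracture-energy threshold
#'
#' Normalizes a dimensional fracture energy \eqn{\Gamma} (resistance to tear
#' propagation) by \eqn{\mu R}, the natural energy-release scale of the
#' dimensionless model. With the reported abdominal-aorta values
#' (\eqn{\Gamma = 76} and 51 J/m^2 along the longitudinal and
#' circumferential directions, \eqn{\mu = 157} kPa, \eqn{R = 20} mm) this
#' gives about 0.024 and 0.016.
#'
#' @param gamma fracture energy in J/m^2 (\eqn{\ge 0}).
#' @param mu shear modulus in Pa (> 0).
#' @param radius mean aortic radius in m (> 0).
#' @return \eqn{\Gamma/(\mu R)}, dimensionless.
#' @examples
#' gamma_over_muR(76, 157e3, 0.020) # ~0.0242
#' gamma_over_muR(51, 157e3, 0.020) # ~0.0162
#' @export
gamma_over_muR <- function(gamma, mu, radius) {
  stopifnot_scalar(gamma, "gamma", nonneg = TRUE)
  stopifnot_scalar(mu, "mu", positive = TRUE)
  stopifnot_scalar(radius, "radius", positive = TRUE)
  gamma / (mu * radius)
}

# G/(mu R) over a depth grid at one pressure, reusing the normal-section
# solution (it does not depend on the tear depth).
g_over_depths <- function(p, depths, h2_over_r, alpha_lim, mat, direction,
                          dissected_model, delta_alpha = deg2rad(4)) {
  U_I <- if (direction == "longitudinal") {
    g0 <- aorta_geometry(H2 = h2_over_r, H1 = h2_over_r,
                         alpha_lim = alpha_lim, R = 1)
    solve_normal_ring(g0, mat, p)$U
  } else NA_real_
  vapply(depths, function(d) {
    geom <- geometry_from_ratios(h2_over_r, d, alpha_lim * 180 / pi)
    tryCatch({
      if (direction == "longitudinal") {
        U_II <- dissected_energy(geom, mat, p, dissected_model)
        (U_I - U_II) / (geom$R_c * 2 * alpha_lim) / mat$mu
      } else {
        energy_release_circumferential(geom, mat, p, delta_alpha,
                                       dissected_model = dissected_model)$G_norm
      }
    }, aortafract_error = function(e) NA_real_)
  }, numeric(1))
}

#' Critical pressure for tear propagation across a depth range
#'
#' The smallest dimensionless pressure \eqn{P/\mu} at which the energy
#' release rate meets or exceeds the threshold \eqn{\Gamma/(\mu R)} for
#' *every* tear depth in `depths` (i.e. the worst-case, shallowest tear also
#' propagates). Found by bisection on \eqn{P/\mu} of the minimum-over-depth
#' \eqn{G/(\mu R)}.
#'
#' @param mat an [material()] object (dimensionless, `mu = 1`).
#' @param threshold dimensionless fracture energy \eqn{\Gamma/(\mu R)} (> 0),
#'   e.g. from [gamma_over_muR()].
#' @param depths grid of tear-depth ratios \eqn{H_1/H_2} in (0, 1].
#' @param direction `"longitudinal"` or `"circumferential"`.
#' @param h2_over_r wall thickness ratio \eqn{H_2/R}.
#' @param alpha_lim crack half-angle in radians.
#' @param p_range search interval for \eqn{P/\mu}.
#' @param tol bisection tolerance on \eqn{P/\mu}.
#' @param dissected_model dissected-section model.
#' @return the critical \eqn{P/\mu}.
#' @examples
#' \donttest{
#' critical_pressure(material("gent", Jm = 1), threshold = 0.024,
#'                   depths = seq(0.3, 0.9, 0.05))
#' }
#' @export
critical_pressure <- function(mat, threshold,
                              depths = seq(0.3, 0.9, by = 0.05),
                              direction = c("longitudinal",
                                            "circumferential"),
                              h2_over_r = 0.2, alpha_lim = deg2rad(30),
                              p_range = c(1e-3, 1), tol = 1e-3,
                              dissected_model = c("single_circle", "bulge")) {
  direction <- match.arg(direction)
  dissected_model <- match.arg(dissected_model)
  stopifnot_scalar(threshold, "threshold", positive = TRUE)
  if (any(depths <= 0 | depths > 1))
    af_input_error("`depths` must lie in (0, 1]")
  worst <- function(p) {
    g <- g_over_depths(p, depths, h2_over_r, alpha_lim, mat, direction,
                       dissected_model)
    if (all(is.na(g))) NA_real_ else min(g, na.rm = TRUE)
  }
  lo <- p_range[1]; hi <- p_range[2]
  whi <- worst(hi)
  if (is.na(whi) || whi < threshold)
    af_no_equilibrium(sprintf(
      "threshold %g not reached below p/mu = %g: above solvable range",
      threshold, hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    wm <- worst(mid)
    if (!is.na(wm) && wm >= threshold) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Safety map over pressure and tear depth
#'
#' Evaluates \eqn{G/(\mu R)} on a rectangular (pressure x tear-depth) grid at
#' fixed crack angle, wall thickness and material, and marks the region where
#' it meets or exceeds the fracture-energy threshold \eqn{\Gamma/(\mu R)}
#' (conditions favorable for tear propagation).
#'
#' @param pressure_grid dimensionless pressures \eqn{P/\mu}, strictly
#'   increasing.
#' @param depth_grid tear-depth ratios \eqn{H_1/H_2}, strictly monotone.
#' @param mat an [material()] object.
#' @param direction `"longitudinal"` or `"circumferential"`.
#' @param threshold \eqn{\Gamma/(\mu R)} (\eqn{\ge 0}).
#' @param h2_over_r wall thickness ratio.
#' @param alpha_lim crack half-angle in radians.
#' @param dissected_model dissected-section model.
#' @return An object of class `safety_map`: grids, matrix `G` (depth rows x
#'   pressure columns), logical `unsafe` mask, and the inputs. Unsolvable
#'   nodes are `NA`.
#' @examples
#' \donttest{
#' sm <- build_safety_map(seq(0.02, 0.14, 0.02), seq(0.3, 0.9, 0.1),
#'                        material("gent", Jm = 1), "longitudinal", 0.024)
#' print(sm)
#' }
#' @export
build_safety_map <- function(pressure_grid, depth_grid, mat,
                             direction = c("longitudinal",
                                           "circumferential"),
                             threshold,
                             h2_over_r = 0.2, alpha_lim = deg2rad(30),
                             dissected_model = c("single_circle", "bulge")) {
  direction <- match.arg(direction)
  dissected_model <- match.arg(dissected_model)
  stopifnot_scalar(threshold, "threshold", nonneg = TRUE)
  if (length(pressure_grid) < 1 || any(diff(pressure_grid) <= 0))
    af_input_error("`pressure_grid` must be non-empty and strictly increasing")
  if (length(depth_grid) < 1 ||
      (length(depth_grid) > 1 && !(all(diff(depth_grid) > 0) ||
                                   all(diff(depth_grid) < 0))))
    af_input_error("`depth_grid` must be non-empty and strictly monotone")
  G <- vapply(pressure_grid, function(p) {
    g_over_depths(p, depth_grid, h2_over_r, alpha_lim, mat, direction,
                  dissected_model)
  }, numeric(length(depth_grid)))
  G <- matrix(G, nrow = length(depth_grid),
              dimnames = list(depth = signif(depth_grid, 6),
                              p_over_mu = signif(pressure_grid, 6)))
  structure(list(
    pressure_grid = pressure_grid, depth_grid = depth_grid,
    G = G, threshold = threshold, unsafe = !is.na(G) & G >= threshold,
    direction = direction, h2_over_r = h2_over_r, alpha_lim = alpha_lim,
    mat = mat, dissected_model = dissected_model), class = "safety_map")
}

#' @export
print.safety_map <- function(x, ...) {
  cat(sprintf(
    "<safety_map> %s, %s, H2/R = %g, alpha_lim = %g deg, threshold = %g\n",
    x$direction, x$mat$kind, x$h2_over_r, x$alpha_lim * 180 / pi,
    x$threshold))
  cat(sprintf("  %d pressures x %d depths; unsafe nodes: %d / %d\n",
              length(x$pressure_grid), length(x$depth_grid),
              sum(x$unsafe), length(x$unsafe)))
  invisible(x)
}

#' @export
as.data.frame.safety_map <- function(x, ...) {
  data.frame(
    p_over_mu = rep(x$pressure_grid, each = length(x$depth_grid)),
    h1_over_h2 = rep(x$depth_grid, times = length(x$pressure_grid)),
    G_over_muR = as.vector(x$G),
    unsafe = as.vector(x$unsafe))
}

#' @param x a `safety_map`.
#' @param ... passed to [graphics::contour()].
#' @describeIn build_safety_map contour plot with the unsafe region shaded.
#' @export
plot.safety_map <- function(x, ...) {
  graphics::image(x$pressure_grid, x$depth_grid,
                  t(ifelse(x$unsafe, 1, 0)),
                  col = c("white", "grey75"),
                  xlab = "P / mu", ylab = "H1 / H2 (tear depth ratio)",
                  main = sprintf("Safety map (%s, G/muR >= %g shaded)",
                                 x$direction, x$threshold))
  graphics::contour(x$pressure_grid, x$depth_grid, t(x$G), add = TRUE, ...)
  invisible(x)
}

# Figure-sweep recipes: fixed parameters follow the published captions;
# pressure grids stay below the Neo-Hookean limit points.
figure_recipes <- function() {
  p_nh <- seq(0.01, 0.10, by = 0.01)
  p_gent <- seq(0.01, 0.15, by = 0.01)
  alpha_grid <- deg2rad(seq(10, 160, by = 10))
  p_levels <- c(0.05, 0.10, 0.15)
  list(
    "3a" = list(direction = "longitudinal", mat = list(kind = "neo_hookean"),
                vary = "h2_over_r", values = c(0.15, 0.2, 0.25),
                pressures = p_nh, h1_over_h2 = 0.5, alpha_deg = 30),
    "3b" = list(direction = "longitudinal", mat = list(kind = "neo_hookean"),
                vary = "h1_over_h2", values = c(0.3, 0.5, 0.7, 0.9),
                pressures = p_nh, h2_over_r = 0.2, alpha_deg = 30),
    "4a" = list(direction = "longitudinal", mat = list(kind = "gent"),
                vary = "Jm", values = c(1, 10, 100),
                pressures = p_gent, h2_over_r = 0.2, h1_over_h2 = 0.5,
                alpha_deg = 30),
    "4b" = list(direction = "longitudinal", mat = list(kind = "gent", Jm = 1),
                vary = "h2_over_r", values = c(0.15, 0.2, 0.25),
                pressures = p_gent, h1_over_h2 = 0.5, alpha_deg = 30),
    "4c" = list(direction = "longitudinal", mat = list(kind = "gent", Jm = 1),
                vary = "h1_over_h2", values = c(0.3, 0.5, 0.7, 0.9),
                pressures = p_gent, h2_over_r = 0.2, alpha_deg = 30),
    "4d" = list(direction = "longitudinal", mat = list(kind = "gent", Jm = 1),
                vary = "alpha", values = alpha_grid, pressures = p_levels,
                h2_over_r = 0.2, h1_over_h2 = 0.5),
    "5a" = list(direction = "circumferential", mat = list(kind = "gent"),
                vary = "Jm", values = c(1, 10, 100),
                pressures = p_gent, h2_over_r = 0.2, h1_over_h2 = 0.5,
                alpha_deg = 30),
    "5b" = list(direction = "circumferential",
                mat = list(kind = "gent", Jm = 1),
                vary = "h2_over_r", values = c(0.15, 0.2, 0.25),
                pressures = p_gent, h1_over_h2 = 0.5, alpha_deg = 30),
    "5c" = list(direction = "circumferential",
                mat = list(kind = "gent", Jm = 1),
                vary = "h1_over_h2", values = c(0.3, 0.5, 0.7, 0.9),
                pressures = p_gent, h2_over_r = 0.2, alpha_deg = 30),
    "5d" = list(direction = "circumferential",
                mat = list(kind = "gent", Jm = 1),
                vary = "alpha", values = alpha_grid, pressures = p_levels,
                h2_over_r = 0.2, h1_over_h2 = 0.5),
    "6a" = list(direction = "longitudinal", mat = list(kind = "hgo", K2 = 1),
                vary = "K1", values = c(0, 0.05, 0.2),
                pressures = p_nh, h2_over_r = 0.2, h1_over_h2 = 0.5,
                alpha_deg = 30),
    "6b" = list(direction = "longitudinal",
                mat = list(kind = "hgo", K1 = 0.05),
                vary = "K2", values = c(0.5, 1, 2),
                pressures = p_nh, h2_over_r = 0.2, h1_over_h2 = 0.5,
                alpha_deg = 30),
    "6c" = list(direction = "circumferential",
                mat = list(kind = "hgo", K2 = 1),
                vary = "K1", values = c(0, 0.05, 0.2),
                pressures = p_nh, h2_over_r = 0.2, h1_over_h2 = 0.5,
                alpha_deg = 30),
    "6d" = list(direction = "circumferential",
                mat = list(kind = "hgo", K1 = 0.05),
                vary = "K2", values = c(0.5, 1, 2),
                pressures = p_nh, h2_over_r = 0.2, h1_over_h2 = 0.5,
                alpha_deg = 30))
}

build_material <- function(spec) {
  switch(spec$kind,
    neo_hookean = material("neo_hookean"),
    gent = material("gent", Jm = spec$Jm),
    hgo = material("hgo", K1 = spec$K1, K2 = spec$K2))
}

#' Run a published-figure parameter sweep
#'
#' Reproduces one of the trend studies: energy release rate versus pressure
#' while varying one parameter (wall thickness \eqn{H_2/R}, tear depth
#' \eqn{H_1/H_2}, Gent \eqn{J_m}, HGO \eqn{K_1/\mu} or \eqn{K_2}), or versus
#' crack angle at several pressures. Figure ids follow the published layout:
#' `"3a"`, `"3b"` (Neo-Hookean, longitudinal), `"4a"`-`"4d"` (Gent,
#' longitudinal), `"5a"`-`"5d"` (Gent, circumferential), `"6a"`-`"6d"` (HGO,
#' both directions).
#'
#' @param figure figure id string, e.g. `"4c"`.
#' @param dissected_model dissected-section model.
#' @return data frame of the sweep (columns `figure`, `direction`,
#'   `p_over_mu`, `h2_over_r`, `h1_over_h2`, `alpha_deg`, `material`,
#'   `vary`, `vary_value`, `G_over_muR`, `U_I`, `U_II`).
#' @examples
#' \donttest{
#' sw <- run_figure_sweeps("4a")
#' head(sw)
#' }
#' @export
run_figure_sweeps <- function(figure,
                              dissected_model = c("single_circle", "bulge")) {
  dissected_model <- match.arg(dissected_model)
  rec <- figure_recipes()[[figure]]
  if (is.null(rec))
    af_input_error(sprintf("unknown figure id '%s' (known: %s)", figure,
                           paste(names(figure_recipes()), collapse = ", ")))
  rows <- list()
  for (v in rec$values) {
    spec <- rec$mat
    h2r <- rec$h2_over_r; d <- rec$h1_over_h2
    alpha_deg <- rec$alpha_deg
    if (rec$vary == "Jm") spec$Jm <- v
    if (rec$vary == "K1") spec$K1 <- v
    if (rec$vary == "K2") spec$K2 <- v
    if (rec$vary == "h2_over_r") h2r <- v
    if (rec$vary == "h1_over_h2") d <- v
    if (rec$vary == "alpha") alpha_deg <- v * 180 / pi
    mat <- build_material(spec)
    for (p in rec$pressures) {
      geom <- geometry_from_ratios(h2r, d, alpha_deg)
      res <- tryCatch({
        er <- if (rec$direction == "longitudinal") {
          energy_release_longitudinal(geom, mat, p,
                                      dissected_model = dissected_model)
        } else {
          energy_release_circumferential(geom, mat, p,
                                         dissected_model = dissected_model)
        }
        list(G = er$G_norm, UI = er$U_I_norm, UII = er$U_II_norm)
      }, aortafract_error = function(e) {
        list(G = NA_real_, UI = NA_real_, UII = NA_real_)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        figure = figure, direction = rec$direction, p_over_mu = p,
        h2_over_r = h2r, h1_over_h2 = d, alpha_deg = alpha_deg,
        material = spec$kind, vary = rec$vary, vary_value = v,
        G_over_muR = res$G, U_I = res$UI, U_II = res$UII,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Plot a figure sweep
#'
#' One curve of \eqn{G/(\mu R)} per value of the varied parameter.
#'
#' @param sweep data frame from [run_figure_sweeps()].
#' @param ... passed to [graphics::matplot()].
#' @return the sweep, invisibly.
#' @export
plot_sweep <- function(sweep, ...) {
  xvar <- if (sweep$vary[1] == "alpha") "alpha_deg" else "p_over_mu"
  xs <- sort(unique(sweep[[xvar]]))
  vals <- unique(sweep$vary_value)
  if (sweep$vary[1] == "alpha") {
    ys <- sapply(vals, function(v)
      sweep$G_over_muR[sweep$vary_value == v][order(sweep$alpha_deg[sweep$vary_value == v])])
    xlab <- "crack half-angle (deg)"
  } else {
    ys <- sapply(vals, function(v)
      sweep$G_over_muR[sweep$vary_value == v][order(sweep$p_over_mu[sweep$vary_value == v])])
    xlab <- "P / mu"
  }
  graphics::matplot(xs, ys, type = "l", lty = 1, xlab = xlab,
                    ylab = "G / (mu R)",
                    main = sprintf("sweep %s (vary %s)", sweep$figure[1],
                                   sweep$vary[1]), ...)
  graphics::legend("topleft", legend = signif(vals, 3), lty = 1,
                   col = seq_along(vals), bty = "n")
  invisible(sweep)
}
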