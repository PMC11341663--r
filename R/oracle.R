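# Independent verification oracles. These deliberately do NOT reuse the
# equilibrium root-finding of the main solvers: the ring oracle samples the
# potential-energy functional directly, the membrane oracle minimizes the
# constrained energy numerically, the Lame oracle is a closed form, and the
# energy-release oracle uses centered finite differences.

#' Oracle comparison report
#'
#' @param quantity label of the compared quantity.
#' @param solver_value value from the production solver.
#' @param oracle_value value from the independent oracle.
#' @param tolerance relative tolerance defining a pass.
#' @return An `oracle_report` with `rel_diff` and logical `pass`.
#' @export
oracle_report <- function(quantity, solver_value, oracle_value, tolerance) {
  rel <- abs(solver_value - oracle_value) /
    max(abs(oracle_value), .Machine$double.eps)
  structure(list(quantity = quantity, solver_value = solver_value,
                 oracle_value = oracle_value, rel_diff = rel,
                 tolerance = tolerance, pass = rel <= tolerance),
            class = "oracle_report")
}

#' @export
print.oracle_report <- function(x, ...) {
  cat(sprintf("<oracle_report> %-28s solver %.10g | oracle %.10g | rel %.2e | %s\n",
              x$quantity, x$solver_value, x$oracle_value, x$rel_diff,
              if (x$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Ritz stationarity check of the ring solution
#'
#' Evaluates the one-parameter potential energy \eqn{U_I(a)} of the
#' incompressible kinematic family on a local grid around the solver's
#' deformed inner radius and verifies that the solution is an interior
#' minimum with vanishing derivative. Equilibrium of the thick-walled ring is
#' equivalent to stationarity of the energy functional on this family, so
#' this re-derives the solution without the radial-equilibrium quadrature.
#'
#' @param geom an [aorta_geometry()].
#' @param mat an [material()] object.
#' @param p internal pressure (> 0).
#' @param delta relative half-width of the sampling grid around `a`.
#' @param tol pass tolerance on the scaled energy slope
#'   \eqn{|dU/da| \cdot R / (\mu R^2)}.
#' @return An [oracle_report()] for the scaled slope, with attributes
#'   `interior_minimum` (logical) and `a_opt` (the grid optimum from
#'   [stats::optimize()]).
#' @export
stationarity_check <- function(geom, mat, p, delta = 1e-4, tol = 1e-6) {
  st <- solve_normal_ring(geom, mat, p)
  U_of_a <- function(a) ring_energy_kinematic(a, geom, mat, p)
  a <- st$a
  h <- delta * a
  slope <- (U_of_a(a + h) - U_of_a(a - h)) / (2 * h)
  scaled <- abs(slope) * geom$R / (mat$mu * geom$R^2)
  rep <- oracle_report("ring dU/da stationarity", scaled, 0, tol)
  rep$pass <- scaled <= tol
  rep$rel_diff <- scaled
  opt <- stats::optimize(U_of_a, c(a * (1 - 50 * delta), a * (1 + 50 * delta)))
  attr(rep, "interior_minimum") <-
    U_of_a(a) <= U_of_a(a - h) && U_of_a(a) <= U_of_a(a + h)
  attr(rep, "a_opt") <- opt$minimum
  rep
}

# Potential energy of the incompressible ring family at trial inner radius a
# (no equilibrium solving; direct functional evaluation).
ring_energy_kinematic <- function(a, geom, mat, p) {
  R_in <- geom$R_in
  if (a < R_in) return(Inf)
  W <- if (a > R_in) {
    af_quad(function(rho) {
      lam <- sqrt(1 + (a^2 - R_in^2) / rho^2)
      strain_energy(mat, lam) * 2 * pi * rho
    }, R_in, geom$R_out)
  } else 0
  W - p * pi * (a^2 - R_in^2)
}

#' Constrained energy minimization of the two-segment membrane
#'
#' Independently re-derives the dissected-section equilibrium by minimizing
#' the membrane potential over \eqn{(\lambda_1, \lambda_2, \rho)} subject to
#' the closure constraint \eqn{\lambda_1 L_1 + \lambda_2 L_2 = 2\pi\rho}
#' (the constraint eliminates \eqn{\rho}, leaving an unconstrained 2-D
#' minimization solved by Nelder-Mead from several deterministic starts).
#' The pressure potential uses the mid-surface enclosed area
#' \eqn{\pi\rho^2}, the work-conjugate form whose Lagrange condition is
#' exactly equal segment tensions with \eqn{T = p\rho}; the reported
#' \eqn{U_{II}} (inner-surface bookkeeping) is then evaluated at the
#' minimizer and compared with the solver's.
#'
#' @inheritParams stationarity_check
#' @param tol pass tolerance on the relative energy difference.
#' @return An [oracle_report()] comparing \eqn{U_{II}}; attribute `par` holds
#'   the minimizing \eqn{(\lambda_1, \lambda_2)}.
#' @export
constrained_minimize_membrane <- function(geom, mat, p, tol = 1e-6) {
  st <- solve_dissected_section(geom, mat, p)
  alpha <- geom$alpha_lim
  L1 <- 2 * alpha * geom$R_fl
  L2 <- (2 * pi - 2 * alpha) * geom$R
  A_ref_mid <- (pi - alpha) * geom$R^2 + alpha * geom$R_fl^2
  lmax <- stretch_limit(mat)
  obj <- function(par) {
    l1 <- par[1]; l2 <- par[2]
    if (l1 < 1 || l2 < 1 || l1 >= lmax || l2 >= lmax) return(1e10)
    rho <- (l1 * L1 + l2 * L2) / (2 * pi)
    strain_energy(mat, l1) * geom$H1 * L1 +
      strain_energy(mat, l2) * geom$H2 * L2 -
      p * (pi * rho^2 - A_ref_mid)
  }
  ub <- if (is.finite(lmax)) lmax else 4
  starts <- list(c(1.05, 1.02), c(0.6 + 0.4 * ub, 0.7 + 0.3 * ub),
                 c(0.5 + 0.5 * ub, 1.05), c(1.2, 1.1))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$value >= 1e9)
    af_solver_error("membrane oracle: minimization failed from all starts")
  # Reported energy (inner-surface bookkeeping) at the oracle's minimizer.
  l1 <- best$par[1]; l2 <- best$par[2]
  rho <- (l1 * L1 + l2 * L2) / (2 * pi)
  h1 <- geom$H1 / l1; h2 <- geom$H2 / l2
  dA <- ((pi - alpha) * (rho - h2 / 2)^2 + alpha * (rho - h1 / 2)^2) -
    ((pi - alpha) * geom$R_in^2 + alpha * geom$R_c^2)
  U_orc <- strain_energy(mat, l1) * geom$H1 * L1 +
    strain_energy(mat, l2) * geom$H2 * L2 - p * dA
  rep <- oracle_report("membrane U_II", st$U, U_orc, tol)
  attr(rep, "par") <- best$par
  rep
}

#' Small-strain thick-wall (Lame) reference stresses
#'
#' Closed-form incompressible plane-strain linear-elastic stresses of a
#' pressurized thick-walled cylinder:
#' \eqn{\sigma_{rr} = p R_{in}^2 (1 - R_{out}^2/r^2) / (R_{out}^2 -
#' R_{in}^2)}, \eqn{\sigma_{\theta\theta} = p R_{in}^2 (1 + R_{out}^2/r^2) /
#' (R_{out}^2 - R_{in}^2)}. Valid as a comparison for the finite-strain
#' solver only at vanishing load (\eqn{p/\mu \lesssim 10^{-4}}).
#'
#' @param geom an [aorta_geometry()].
#' @param p internal pressure.
#' @return list of functions `srr(r)` and `stt(r)`.
#' @export
lame_reference <- function(geom, p) {
  Ri2 <- geom$R_in^2; Ro2 <- geom$R_out^2
  k <- p * Ri2 / (Ro2 - Ri2)
  list(srr = function(r) k * (1 - Ro2 / r^2),
       stt = function(r) k * (1 + Ro2 / r^2))
}

#' Finite-difference check of the circumferential energy release rate
#'
#' Compares the upwind (forward-difference) circumferential \eqn{G} with a
#' centered-difference oracle built directly from \eqn{U_{II}(\alpha)}; both
#' converge to \eqn{-dU_{II}/d(crack\ length)} as the increment shrinks, the
#' upwind scheme at first order.
#'
#' @inheritParams stationarity_check
#' @param h angular increment in radians (default \eqn{4^\circ}).
#' @param tol pass tolerance on the relative difference (first-order in `h`;
#'   the default is loose accordingly).
#' @param dissected_model dissected-section model.
#' @return An [oracle_report()] comparing upwind vs centered \eqn{G/(\mu R)}.
#' @export
finite_difference_G <- function(geom, mat, p, h = deg2rad(4), tol = 0.15,
                                dissected_model = c("single_circle",
                                                    "bulge")) {
  dissected_model <- match.arg(dissected_model)
  up <- energy_release_circumferential(geom, mat, p, delta_alpha = h,
                                       dissected_model = dissected_model)
  Um <- dissected_energy(with_alpha(geom, geom$alpha_lim - h), mat, p,
                         dissected_model)
  Up <- dissected_energy(with_alpha(geom, geom$alpha_lim + h), mat, p,
                         dissected_model)
  centered <- (Um - Up) / (2 * h * 2 * geom$R_c) / (mat$mu * geom$R)
  oracle_report("circumferential G (upwind vs centered)",
                up$G_norm, centered, tol)
}

#' Run the full oracle suite
#'
#' Convenience wrapper executing all oracles at a representative operating
#' point and returning a pass/fail table.
#'
#' @param geom an [aorta_geometry()]; default is the published operating
#'   point (\eqn{H_2/R = 0.2}, \eqn{H_1/H_2 = 0.5},
#'   \eqn{\alpha_{lim} = 30^\circ}).
#' @param mat an [material()]; default Gent with \eqn{J_m = 1}.
#' @param p internal pressure.
#' @return data frame with one row per oracle.
#' @export
run_oracle_suite <- function(geom = geometry_from_ratios(0.2, 0.5, 30),
                             mat = material("gent", Jm = 1), p = 0.1) {
  reports <- list(
    stationarity_check(geom, mat, p),
    constrained_minimize_membrane(geom, mat, p),
    finite_difference_G(geom, mat, p))
  st <- solve_normal_ring(geom, mat, 1e-4 * mat$mu)
  lam <- lame_reference(geom, 1e-4 * mat$mu)
  pr <- ring_stress(st, geom$R)
  reports <- c(reports, list(
    oracle_report("mid-wall hoop stress vs Lame", pr$stt,
                  lam$stt(geom$R), 0.01)))
  do.call(rbind, lapply(reports, function(r) {
    data.frame(quantity = r$quantity, solver = r$solver_value,
               oracle = r$oracle_value, rel_diff = r$rel_diff,
               tolerance = r$tolerance, pass = r$pass,
               stringsAsFactors = FALSE)
  }))
}
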