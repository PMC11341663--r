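# Internal helpers shared by the solvers.

# Classed error so callers can distinguish solver failures from user mistakes.
af_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "aortafract_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

af_input_error <- function(msg) af_stop(msg, "aortafract_input_error")
af_domain_error <- function(msg) af_stop(msg, "aortafract_domain_error")
af_no_equilibrium <- function(msg) af_stop(msg, "aortafract_no_equilibrium")
af_solver_error <- function(msg) af_stop(msg, "aortafract_solver_error")

# Adaptive quadrature with graceful degradation near integrable singularities
# (the Gent integrand is log-singular when the inner wall sits at the strain
# limit; stats::integrate then reports roundoff even though the value is fine).
af_quad <- function(f, lower, upper, rel.tol = 1e-10, abs.tol = 1e-12) {
  out <- tryCatch(
    stats::integrate(f, lower, upper, rel.tol = rel.tol, abs.tol = abs.tol)$value,
    error = function(e) NULL)
  if (is.null(out)) {
    out <- tryCatch(stats::integrate(f, lower, upper, rel.tol = 1e-8)$value,
                    error = function(e) NULL)
  }
  if (is.null(out)) {
    out <- stats::integrate(f, lower, upper, rel.tol = 1e-6,
                            stop.on.error = FALSE)$value
  }
  out
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    af_input_error(sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0)
    af_input_error(sprintf("`%s` must be positive", name))
  if (nonneg && x < 0)
    af_input_error(sprintf("`%s` must be non-negative", name))
  invisible(x)
}

#' Convert degrees to radians
#'
#' Angles are degrees at the user interface and radians internally.
#'
#' @param deg angle in degrees.
#' @return angle in radians.
#' @export
deg2rad <- function(deg) deg * pi / 180
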