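#' Integrated interferon transient
#'
#' Closed form of `IT(t) = integral of A exp(-zeta2 s) ds` over `[0, t]`:
#' `(A/zeta2) * (1 - exp(-zeta2 t))`, saturating at `A/zeta2`.
#'
#' @param t Time(s), nonnegative.
#' @param A Interferon deviation amplitude.
#' @param zeta2 Decay rate, positive.
#' @param allow_zero If `TRUE`, `zeta2 = 0` returns the limit `A * t`
#'   instead of erroring.
#' @return Numeric vector of integrated values.
#' @export
transient_it <- function(t, A, zeta2, allow_zero = FALSE) {
  if (zeta2 < 0 || (zeta2 == 0 && !allow_zero)) {
    abort("`zeta2` must be positive (set `allow_zero = TRUE` for the A*t limit).",
          class = "imm_degenerate_parameter")
  }
  if (zeta2 == 0) return(A * t)
  A / zeta2 * (1 - exp(-zeta2 * t))
}

#' Integrated upregulation transient
#'
#' Closed form of the integral of the oscillatory deviation
#' `j(s) = r1 V0 exp(r2 V0 s) cos(r3 V0 s - r4 V0)` over `[0, t]`:
#' \deqn{JT(t) = \theta_1 e^{r_2 V_0 t} \cos(r_3 V_0 t - r_4 V_0 - \theta_2)
#'              - \theta_1 \cos(r_4 V_0 + \theta_2)}
#' with `theta1 = r1/sqrt(r2^2 + r3^2)` and `theta2 = atan(r3/r2)`. The
#' phase-folded form is numerically stable for every admissible parameter
#' combination, including `V0 = 0` (where both terms cancel) and `r2 = 0`
#' (pure trigonometric antiderivative).
#'
#' @param t Time(s), nonnegative.
#' @param theta1,theta2 Reduced constants; see [reduced_constants()].
#' @param r2,r3,r4 Dose-scaling constants.
#' @param V0 Trigger dose.
#' @return Numeric vector of integrated values.
#' @export
transient_jt <- function(t, theta1, theta2, r2, r3, r4, V0) {
  if (r2^2 + r3^2 <= 0) abort("`r2^2 + r3^2` must be positive.",
                              class = "imm_degenerate_parameter")
  delta <- r4 * V0
  theta1 * exp(r2 * V0 * t) * cos(r3 * V0 * t - delta - theta2) -
    theta1 * cos(delta + theta2)
}

#' Integrated free-signal transient
#'
#' Closed form of the integral of
#' `k(s) = -r1 V0 exp(r2 V0 s) sin(r3 V0 s - r4 V0)` over `[0, t]`:
#' \deqn{KT(t) = -\theta_1 e^{r_2 V_0 t} \sin(r_3 V_0 t - r_4 V_0 - \theta_2)
#'              - \theta_1 \sin(r_4 V_0 + \theta_2)}
#' The growing exponential `exp(+r2 V0 t)` is used throughout, consistent
#' with the trajectory pair it integrates (verified against adaptive
#' quadrature).
#'
#' @inheritParams transient_jt
#' @return Numeric vector of integrated values.
#' @export
transient_kt <- function(t, theta1, theta2, r2, r3, r4, V0) {
  if (r2^2 + r3^2 <= 0) abort("`r2^2 + r3^2` must be positive.",
                              class = "imm_degenerate_parameter")
  delta <- r4 * V0
  -theta1 * exp(r2 * V0 * t) * sin(r3 * V0 * t - delta - theta2) -
    theta1 * sin(delta + theta2)
}

# pre-phase-fold (integration-by-parts) form of JT; kept for the identity
# check between the raw and the theta-folded expressions
transient_jt_parts <- function(t, R, alpha, beta, delta) {
  hyp2 <- alpha^2 + beta^2
  R / hyp2 * exp(alpha * t) *
    (beta * sin(beta * t - delta) + alpha * cos(beta * t - delta)) +
    R / hyp2 * (beta * sin(delta) - alpha * cos(delta))
}

transient_kt_parts <- function(t, R, alpha, beta, delta) {
  hyp2 <- alpha^2 + beta^2
  -R / hyp2 * exp(alpha * t) *
    (-beta * cos(beta * t - delta) + alpha * sin(beta * t - delta)) -
    R / hyp2 * (beta * cos(delta) + alpha * sin(delta))
}

#' Adaptive quadrature oracle
#'
#' Thin wrapper over [stats::integrate()] at tight tolerance, used to verify
#' the closed-form transients independently. Errors if the reported error
#' estimate exceeds `max_error`.
#'
#' @param f Integrand, vectorized over its first argument.
#' @param upper Upper limit; the integral runs over `[lower, upper]`.
#' @param lower Lower limit, default 0.
#' @param max_error Acceptable absolute error estimate.
#' @return The integral value, with the error estimate attached as the
#'   `"abs.error"` attribute.
#' @export
quadrature <- function(f, upper, lower = 0, max_error = 1e-10) {
  res <- integrate(f, lower, upper, rel.tol = 1e-12, abs.tol = 1e-13,
                   subdivisions = 500L)
  if (res$message != "OK") {
    abort(sprintf("quadrature failed: %s", res$message),
          class = "imm_solver_failure")
  }
  if (res$abs.error > max_error) {
    abort(sprintf("quadrature error estimate %.3g exceeds %.3g.",
                  res$abs.error, max_error),
          class = "imm_solver_failure")
  }
  structure(res$value, abs.error = res$abs.error)
}
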