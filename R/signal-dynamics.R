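#' Eigenstructure of the signal-interaction Jacobian
#'
#' The i-column of the signal Jacobian has zeros below its first entry, so
#' the spectrum splits: one eigenvalue equals `G1i` exactly and the other two
#' are the eigenvalues of the lower-right 2x2 block in (j, k). Under the
#' oscillation condition the block takes rotation-plus-growth form and the
#' pair is `alpha +/- beta*i`.
#'
#' @param phi A [jacobian_phi()] object.
#' @return An object of class `imm_eigen` with elements `values` (block
#'   shortcut: `G1i` first, then the 2x2 pair), `full` (a full 3x3 eigen
#'   solve, for cross-checking) and `block` (the 2x2 submatrix).
#' @export
eigen_analysis <- function(phi) {
  stopifnot(inherits(phi, "imm_phi"))
  block <- matrix(c(phi$G2j, phi$G3j, phi$G2k, phi$G3k), 2, 2)
  dimnames(block) <- list(c("j", "k"), c("j", "k"))
  # quadratic formula on the characteristic polynomial: exact for the 2x2
  # block (and preserves alpha +/- beta*i without eigen() roundoff)
  half_tr <- (block[1, 1] + block[2, 2]) / 2
  disc <- (block[1, 1] - block[2, 2])^2 + 4 * block[1, 2] * block[2, 1]
  block_values <- if (disc < 0) {
    complex(real = half_tr, imaginary = c(1, -1) * sqrt(-disc) / 2)
  } else {
    as.complex(half_tr + c(1, -1) * sqrt(disc) / 2)
  }
  structure(list(
    values = c(as.complex(phi$G1i), as.complex(block_values)),
    full = eigen(as.matrix(phi), only.values = TRUE)$values,
    block = block
  ), class = "imm_eigen")
}

#' @export
tidy.imm_eigen <- function(x, ...) {
  tibble(
    eigenvalue = x$values,
    real = Re(x$values),
    imaginary = Im(x$values),
    source = c("i_decoupled", "jk_block", "jk_block")
  )
}

#' Classify the oscillatory regime of a 2x2 signal block
#'
#' The j/k deviations oscillate exactly when the block has complex
#' eigenvalues, i.e. a negative discriminant `(a - d)^2 + 4*b*c`. Growth
#' versus damping follows the trace. The exact oscillation condition (equal
#' diagonal, opposite off-diagonal) is flagged separately; either sign
#' arrangement of the off-diagonal pair is accepted since both generate the
#' same rotation-plus-growth trajectories up to orientation.
#'
#' @param block A numeric 2x2 matrix.
#' @param tol Tolerance for the exact-condition flag, relative to the largest
#'   block entry (floor 1).
#' @return An object of class `imm_osc`: a list with `regime` (one of
#'   `"oscillatory_growing"`, `"oscillatory_damped"`, `"non_oscillatory"`),
#'   `oscillatory`, `growing`, `exact_condition`, `alpha`, `beta` and
#'   `discriminant`.
#' @examples
#' classify_oscillation(rbind(c(2, -3), c(3, 2)))
#' @export
classify_oscillation <- function(block, tol = 1e-8) {
  stopifnot(is.matrix(block), all(dim(block) == 2L), all(is.finite(block)))
  a <- block[1, 1]; b <- block[1, 2]; c <- block[2, 1]; d <- block[2, 2]
  disc <- (a - d)^2 + 4 * b * c
  oscillatory <- disc < 0
  growing <- (a + d) > 0
  scale <- max(abs(block), 1)
  exact <- abs(a - d) <= tol * scale && abs(b + c) <= tol * scale &&
    abs(b) > tol * scale
  regime <- if (!oscillatory) "non_oscillatory"
            else if (growing) "oscillatory_growing"
            else "oscillatory_damped"
  structure(list(
    regime = regime, oscillatory = oscillatory, growing = growing,
    exact_condition = exact,
    alpha = (a + d) / 2,
    beta = if (oscillatory) sqrt(-disc) / 2 else 0,
    discriminant = disc
  ), class = "imm_osc")
}

#' @export
print.imm_osc <- function(x, ...) {
  cat(sprintf("<imm_osc> %s (alpha = %.4g, beta = %.4g%s)\n",
              x$regime, x$alpha, x$beta,
              if (x$exact_condition) ", exact condition" else ""))
  invisible(x)
}

#' Closed-form signal deviation trajectories
#'
#' Under the oscillation condition the deviations take phase-amplitude form
#' \deqn{i(t) = A e^{-\zeta_2 t}, \quad
#'       j(t) = R e^{\alpha t} \cos(\beta t - \delta), \quad
#'       k(t) = -R e^{\alpha t} \sin(\beta t - \delta)}
#' with `R = r1*V0`, `alpha = r2*V0`, `beta = r3*V0`, `delta = r4*V0` and
#' `zeta2 = r6*V0`. The initial values are `j(0) = R cos(delta)` and
#' `k(0) = R sin(delta)`; they coincide with `J0 = q1*V0` and
#' `K0 = (1-p0)*V0` when `r1` and `r4` are chosen consistently with the
#' partition fractions (see [random_oscillatory_params()]).
#'
#' @param t Nonnegative, sorted time grid.
#' @param sp A [split_params()] object carrying the dose.
#' @param ds A [dose_scaling()] object.
#' @param H1i Collateral partial used for the default interferon amplitude.
#' @return A tibble with columns `t`, `i`, `j`, `k`.
#' @export
signal_trajectories <- function(t, sp, ds, H1i = 1) {
  stopifnot(inherits(sp, "imm_split"), inherits(ds, "imm_scaling"))
  check_time_grid(t)
  sc <- scaled_at_dose(ds, sp$V0)
  A <- i_amplitude(ds, sp$V0, H1i)
  ph <- sc$beta * t - sc$delta
  env <- sc$R * exp(sc$alpha * t)
  tibble(
    t = t,
    i = A * exp(-sc$zeta2 * t),
    j = env * cos(ph),
    k = -env * sin(ph)
  )
}

#' Numerically integrate a linear deviation system
#'
#' High-accuracy integration of `x' = J x`, used as the independent oracle
#' for the closed-form trajectories and in diagnostics. Not used by any
#' closed-form code path.
#'
#' @param jacobian A square numeric matrix.
#' @param y0 Initial deviations (length matching `jacobian`).
#' @param t Nonnegative, sorted time grid.
#' @param rtol,atol Solver tolerances.
#' @return A tibble with column `t` and one column per state.
#' @export
ode_trajectories <- function(jacobian, y0, t, rtol = 1e-11, atol = 1e-12) {
  stopifnot(is.matrix(jacobian), nrow(jacobian) == ncol(jacobian),
            all(is.finite(jacobian)), length(y0) == nrow(jacobian))
  check_time_grid(t)
  nms <- names(y0) %||% paste0("x", seq_along(y0))
  sol <- deSolve::ode(
    y = setNames(as.numeric(y0), nms), times = t,
    func = function(time, y, parms) list(as.numeric(jacobian %*% y)),
    parms = NULL, rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) {
    abort("ODE solver failed to converge at the requested tolerance.",
          class = "imm_solver_failure")
  }
  as_tibble(as.data.frame(unclass(sol))) |>
    dplyr::rename(t = "time")
}

#' Linear system generating the closed-form deviations
#'
#' Returns the 3x3 generator and initial condition whose solution is exactly
#' the phase-amplitude closed form of [signal_trajectories()]: the interferon
#' deviation decays at `zeta2` and the (j, k) pair rotates under
#' `[[alpha, beta], [-beta, alpha]]`. Note the off-diagonal orientation: this
#' is the matrix that generates the printed trajectory pair
#' `(cos, -sin)`; the conventional presentation `[[alpha, -beta],
#' [beta, alpha]]` generates its mirror image.
#'
#' @inheritParams signal_trajectories
#' @return A list with elements `jacobian` (3x3 matrix) and `y0`.
#' @export
closed_form_system <- function(sp, ds, H1i = 1) {
  sc <- scaled_at_dose(ds, sp$V0)
  A <- i_amplitude(ds, sp$V0, H1i)
  jac <- rbind(c(-sc$zeta2, 0, 0),
               c(0, sc$alpha, sc$beta),
               c(0, -sc$beta, sc$alpha))
  dimnames(jac) <- list(c("i", "j", "k"), c("i", "j", "k"))
  list(jacobian = jac,
       y0 = c(i = A, j = sc$R * cos(sc$delta), k = sc$R * sin(sc$delta)))
}

check_time_grid <- function(t) {
  if (!is.numeric(t) || length(t) < 1L || anyNA(t) || any(t < 0) ||
      is.unsorted(t)) {
    abort("`t` must be a sorted, nonnegative numeric grid.",
          class = "imm_grid_error")
  }
  invisible(t)
}
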