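#' Buffered reaction-diffusion configuration
#'
#' One-dimensional model of a trigger diffusing through a host whose two
#' altered cell populations bind it reversibly: free trigger `u` diffuses at
#' `D0` while the bound fractions `C_M`, `C_N` (capacities `B_M`, `B_N`)
#' diffuse at `DM`, `DN` and exchange with `u` at on/off rates `k+`, `k-`.
#' The dissociation constants are `K = k-/k+`, the buffering strengths
#' `gamma = B/K`, and `Lambda = 1 + gamma_M + gamma_N` relates the composite
#' field `w = u + C_M + C_N` to `u` in the linear-buffering regime.
#'
#' @param L Domain length.
#' @param n Number of grid points.
#' @param D0,DM,DN Diffusion constants (length^2/time), positive.
#' @param kM_on,kM_off,kN_on,kN_off Binding/dissociation rates, positive.
#' @param B_M,B_N Bound-fraction capacities, in (0, 1].
#' @param flux Length-2 boundary flux `-D u_x` at `x = 0` and `x = L`
#'   (zero flux default).
#' @return An object of class `imm_diffcfg` with derived `K_M, K_N,
#'   gamma_M, gamma_N, Lambda, x` (cell-centered grid) and `dx`.
#' @export
diffusion_config <- function(L = 10, n = 200, D0 = 1, DM = 0.05, DN = 0.02,
                             kM_on = 100, kM_off = 100,
                             kN_on = 100, kN_off = 100,
                             B_M = 1, B_N = 1, flux = c(0, 0)) {
  stopifnot(L > 0, n >= 10, all(c(D0, DM, DN) > 0),
            all(c(kM_on, kM_off, kN_on, kN_off) > 0),
            B_M > 0, B_N > 0, length(flux) == 2L)
  K_M <- kM_off / kM_on
  K_N <- kN_off / kN_on
  gamma_M <- B_M / K_M
  gamma_N <- B_N / K_N
  structure(list(
    L = L, n = as.integer(n), D0 = D0, DM = DM, DN = DN,
    kM_on = kM_on, kM_off = kM_off, kN_on = kN_on, kN_off = kN_off,
    B_M = B_M, B_N = B_N, flux = flux,
    K_M = K_M, K_N = K_N, gamma_M = gamma_M, gamma_N = gamma_N,
    Lambda = 1 + gamma_M + gamma_N,
    x = seq(0, L, length.out = n), dx = L / (n - 1)
  ), class = "imm_diffcfg")
}

#' Rapid-equilibrium bound fractions
#'
#' Setting the binding kinetics to instantaneous equilibrium gives the
#' saturating forms `C_M = B_M u/(K_M + u)` and `C_N = B_N u/(K_N + u)`:
#' half-capacity at `u = K`, capped at `B`.
#'
#' @param u Free trigger concentration(s), nonnegative.
#' @param B_M,K_M,B_N,K_N Capacities and dissociation constants.
#' @return A tibble with columns `u, C_M, C_N`.
#' @export
equilibrium_fractions <- function(u, B_M, K_M, B_N, K_N) {
  if (any(u < 0)) abort("`u` must be nonnegative.",
                        class = "imm_invalid_parameter")
  tibble(u = u, C_M = B_M * u / (K_M + u), C_N = B_N * u / (K_N + u))
}

#' Linear-buffering bound fractions
#'
#' For `u` far below both dissociation constants the equilibrium fractions
#' linearize: `C_M = gamma_M u`, `C_N = gamma_N u` and the composite field
#' becomes `w = (1 + gamma_M + gamma_N) u`, so `u` is recoverable as
#' `w / Lambda`. Outside the regime (`u` not small against `K`) the linear
#' map overestimates binding; a warning, not an error, since the map itself
#' stays well defined.
#'
#' @param u Free trigger concentration(s), nonnegative.
#' @param gamma_M,gamma_N Buffering strengths `B/K`.
#' @param K_M,K_N Optional dissociation constants used only to warn when
#'   `u` leaves the validity regime (`u > 0.1 * min(K)`).
#' @return A tibble with columns `u, C_M, C_N, w`.
#' @export
linear_fractions <- function(u, gamma_M, gamma_N, K_M = NULL, K_N = NULL) {
  if (any(u < 0)) abort("`u` must be nonnegative.",
                        class = "imm_invalid_parameter")
  if (!is.null(K_M) && !is.null(K_N) && any(u > 0.1 * min(K_M, K_N))) {
    warn("`u` is not small against the dissociation constants; the linear-buffering approximation degrades.")
  }
  tibble(u = u, C_M = gamma_M * u, C_N = gamma_N * u,
         w = (1 + gamma_M + gamma_N) * u)
}

#' Effective diffusion coefficient of the composite field
#'
#' `D = D0 + (DM - D0) dC_M/dw + (DN - D0) dC_N/dw`: the free-trigger
#' diffusivity corrected by how strongly the composite field partitions into
#' the slower-moving bound fractions.
#'
#' @param dCM_dw,dCN_dw Partials of the bound fractions with respect to `w`.
#' @param D0,DM,DN Diffusion constants.
#' @return The effective coefficient.
#' @export
effective_diffusion <- function(dCM_dw, dCN_dw, D0, DM, DN) {
  stopifnot(all(is.finite(c(dCM_dw, dCN_dw, D0, DM, DN))))
  D0 + (DM - D0) * dCM_dw + (DN - D0) * dCN_dw
}

#' Reduced (linear-buffering) diffusion constant
#'
#' In the linear regime `dC/dw = gamma/Lambda`, collapsing the composite
#' dynamics to constant-coefficient diffusion of the free trigger at
#' \deqn{\hat D = (D_0 + D_M \gamma_M + D_N \gamma_N) / \Lambda}
#' a convex combination of the three diffusivities: it always lies between
#' their extremes and moves toward `D_N` as `gamma_N` grows.
#'
#' @param gamma_M,gamma_N Buffering strengths, nonnegative.
#' @param D0,DM,DN Diffusion constants.
#' @return The reduced constant `D_hat`.
#' @examples
#' reduced_diffusion_constant(1, 1, D0 = 1, DM = 2, DN = 4)  # 7/3
#' @export
reduced_diffusion_constant <- function(gamma_M, gamma_N, D0, DM, DN) {
  stopifnot(gamma_M >= 0, gamma_N >= 0)
  (D0 + DM * gamma_M + DN * gamma_N) / (1 + gamma_M + gamma_N)
}

#' Perturbation of the reduced constant by a shift in the M population
#'
#' Increasing the M bound fraction by `eps` lowers the N capacity by the
#' same amount, changing `Lambda` to `Lambda - eps*xi` with `xi = 1/K_N` and
#' the reduced constant to
#' \deqn{\tilde D = (\Lambda \hat D - \epsilon \xi D_N) / (\Lambda - \epsilon \xi)}
#' The change and its first-order approximation are
#' \deqn{\Delta \hat D = \epsilon \xi (D_N - \hat D) / (\Lambda - \epsilon \xi)
#'   \approx \epsilon \xi (D_N - \hat D) / \Lambda}
#' both vanishing at `eps = 0` and when `D_N` equals the reduced constant.
#' `paper_literal = TRUE` reproduces the first-order form without the `xi`
#' factor, kept for comparison with the printed approximation.
#'
#' @param eps Bound-fraction increment.
#' @param D_hat Reduced diffusion constant.
#' @param Lambda Composite buffering factor `1 + gamma_M + gamma_N`.
#' @param D_N Diffusivity of the N bound fraction.
#' @param K_N Dissociation constant of the N population.
#' @param paper_literal Drop the `xi` factor from the first-order value.
#' @return A list with `D_tilde`, `delta_exact` and `delta_first_order`.
#' @export
perturbed_diffusion <- function(eps, D_hat, Lambda, D_N, K_N,
                                paper_literal = FALSE) {
  xi <- 1 / K_N
  denom <- Lambda - eps * xi
  if (denom <= 0) abort("`Lambda - eps/K_N` must stay positive.",
                        class = "imm_degenerate_parameter")
  first <- if (paper_literal) eps * (D_N - D_hat) / Lambda
           else eps * xi * (D_N - D_hat) / Lambda
  list(
    D_tilde = (Lambda * D_hat - eps * xi * D_N) / denom,
    delta_exact = eps * xi * (D_N - D_hat) / denom,
    delta_first_order = first
  )
}

#' Free-space heat kernel
#'
#' `phi(t, x) = (4 pi D t)^{-1/2} exp(-x^2 / (4 D t))`: the fundamental
#' solution of the diffusion equation, integrating to one over the line.
#' Used as an analytic check on the numerical solvers.
#'
#' @param t Time, positive.
#' @param x Position(s).
#' @param D Diffusion constant, positive.
#' @return Kernel values at `x`.
#' @export
heat_kernel <- function(t, x, D) {
  if (t <= 0 || D <= 0) abort("`t` and `D` must be positive.",
                              class = "imm_invalid_parameter")
  exp(-x^2 / (4 * D * t)) / sqrt(4 * pi * D * t)
}
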