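# Method-of-lines solvers for the trigger diffusion models. Second-order
# central differencing in space, stiff (lsoda-family) stepping in time,
# ghost-node flux boundaries: -D u_x = flux at x = 0 and x = L. With zero
# flux the trapezoid-weighted mass of the composite field is a conserved
# quantity of the semi-discrete system, so drift measures solver error only.

laplacian_flux <- function(y, dx, D, flux_lo, flux_hi) {
  n <- length(y)
  ghost_lo <- y[2] + 2 * dx * flux_lo / D
  ghost_hi <- y[n - 1] - 2 * dx * flux_hi / D
  c(y[2] - 2 * y[1] + ghost_lo,
    y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)],
    ghost_hi - 2 * y[n] + y[n - 1]) / dx^2
}

resolve_profile <- function(u0, cfg) {
  if (is.function(u0)) u0 <- u0(cfg$x)
  if (length(u0) != cfg$n) abort("initial profile length must match the grid.",
                                 class = "imm_grid_error")
  if (anyNA(u0) || any(!is.finite(u0))) abort("initial profile must be finite.",
                                              class = "imm_grid_error")
  u0
}

#' Simulate the full three-field trigger model
#'
#' Evolves free trigger `u` and the bound fractions `C_M`, `C_N` under
#' \deqn{u_t = D_0 u_{xx} + k^-_M C_M - k^+_M (B_M - C_M) u
#'                        + k^-_N C_N - k^+_N (B_N - C_N) u}
#' \deqn{(C_M)_t = D_M (C_M)_{xx} - k^-_M C_M + k^+_M (B_M - C_M) u}
#' and the analogous `C_N` equation. The reaction terms cancel in the sum,
#' so under zero boundary flux the composite field `w = u + C_M + C_N`
#' conserves mass.
#'
#' @param cfg A [diffusion_config()] object.
#' @param u0 Initial free-trigger profile: numeric vector of length `cfg$n`
#'   or a function of `x`.
#' @param times Output times (the first is the initial time).
#' @param CM0,CN0 Initial bound profiles; default the rapid-equilibrium
#'   fractions of `u0`.
#' @param rtol,atol Solver tolerances.
#' @return A long tibble of class `imm_field` with columns
#'   `time, x, u, C_M, C_N, w`.
#' @export
simulate_trigger_full <- function(cfg, u0, times, CM0 = NULL, CN0 = NULL,
                                  rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(cfg, "imm_diffcfg"))
  u0 <- resolve_profile(u0, cfg)
  eq <- equilibrium_fractions(u0, cfg$B_M, cfg$K_M, cfg$B_N, cfg$K_N)
  CM0 <- CM0 %||% eq$C_M
  CN0 <- CN0 %||% eq$C_N
  n <- cfg$n
  rhs <- function(time, y, parms) {
    u <- y[1:n]; CM <- y[(n + 1):(2 * n)]; CN <- y[(2 * n + 1):(3 * n)]
    bind_M <- cfg$kM_on * (cfg$B_M - CM) * u
    bind_N <- cfg$kN_on * (cfg$B_N - CN) * u
    free_M <- cfg$kM_off * CM
    free_N <- cfg$kN_off * CN
    du <- cfg$D0 * laplacian_flux(u, cfg$dx, cfg$D0, cfg$flux[1], cfg$flux[2]) +
      free_M - bind_M + free_N - bind_N
    dCM <- cfg$DM * laplacian_flux(CM, cfg$dx, cfg$DM, 0, 0) - free_M + bind_M
    dCN <- cfg$DN * laplacian_flux(CN, cfg$dx, cfg$DN, 0, 0) - free_N + bind_N
    list(c(du, dCM, dCN))
  }
  sol <- deSolve::ode.1D(y = c(u0, CM0, CN0), times = times, func = rhs,
                         parms = NULL, nspec = 3L, dimens = n,
                         method = "lsoda", rtol = rtol, atol = atol)
  check_solution(sol, "full three-field solver")
  field_to_tibble(sol, cfg, three_field = TRUE)
}

#' Simulate the reduced constant-coefficient trigger model
#'
#' Rapid-equilibrium, linear-buffering reduction of the full system:
#' `u_t = D_hat u_xx` with the same ghost-node flux boundaries.
#'
#' @param cfg A [diffusion_config()] object.
#' @param u0 Initial free-trigger profile (vector or function of `x`).
#' @param times Output times.
#' @param D Diffusion constant; defaults to the reduced constant implied by
#'   `cfg` via [reduced_diffusion_constant()].
#' @param rtol,atol Solver tolerances.
#' @return A long tibble of class `imm_field` with columns `time, x, u`.
#' @export
simulate_trigger_reduced <- function(cfg, u0, times, D = NULL,
                                     rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(cfg, "imm_diffcfg"))
  u0 <- resolve_profile(u0, cfg)
  D <- D %||% reduced_diffusion_constant(cfg$gamma_M, cfg$gamma_N,
                                         cfg$D0, cfg$DM, cfg$DN)
  rhs <- function(time, y, parms) {
    list(D * laplacian_flux(y, cfg$dx, D, cfg$flux[1], cfg$flux[2]))
  }
  sol <- deSolve::ode.1D(y = u0, times = times, func = rhs, parms = NULL,
                         nspec = 1L, dimens = cfg$n, method = "lsoda",
                         rtol = rtol, atol = atol)
  check_solution(sol, "reduced solver")
  field_to_tibble(sol, cfg, three_field = FALSE)
}

check_solution <- function(sol, label) {
  if (anyNA(sol) || any(!is.finite(sol))) {
    abort(sprintf("%s blew up (non-finite state); reduce the time step or rates.",
                  label),
          class = "imm_solver_failure")
  }
  invisible(sol)
}

field_to_tibble <- function(sol, cfg, three_field) {
  n <- cfg$n
  times <- sol[, 1]
  rows <- purrr::map(seq_along(times), function(i) {
    y <- sol[i, -1]
    if (three_field) {
      tibble(time = times[i], x = cfg$x, u = y[1:n],
             C_M = y[(n + 1):(2 * n)], C_N = y[(2 * n + 1):(3 * n)],
             w = y[1:n] + y[(n + 1):(2 * n)] + y[(2 * n + 1):(3 * n)])
    } else {
      tibble(time = times[i], x = cfg$x, u = y[1:n])
    }
  })
  out <- dplyr::bind_rows(rows)
  structure(out, dx = cfg$dx, class = c("imm_field", class(out)))
}

#' Trapezoid mass of a simulated field
#'
#' @param field An `imm_field` tibble.
#' @param value Column to integrate (default the composite field `w` when
#'   present, otherwise `u`).
#' @return A tibble with columns `time, mass`.
#' @export
field_mass <- function(field, value = NULL) {
  stopifnot(inherits(field, "imm_field"))
  value <- value %||% if ("w" %in% names(field)) "w" else "u"
  dx <- attr(field, "dx")
  field |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(mass = trapz_mass(.data[[value]], dx),
                     .groups = "drop")
}

trapz_mass <- function(y, dx) {
  dx * (sum(y) - (y[1] + y[length(y)]) / 2)
}

#' Spatial variance of a field snapshot
#'
#' Second central moment of the profile, used to check that a Gaussian pulse
#' under the reduced solver spreads with variance growing as `2 * D * t`.
#'
#' @param field An `imm_field` tibble.
#' @param value Column to treat as density (default `u`).
#' @return A tibble with columns `time, mean, variance`.
#' @export
field_variance <- function(field, value = "u") {
  stopifnot(inherits(field, "imm_field"))
  field |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(
      mean = sum(.data$x * .data[[value]]) / sum(.data[[value]]),
      variance = sum((.data$x - mean)^2 * .data[[value]]) /
        sum(.data[[value]]),
      .groups = "drop"
    )
}
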