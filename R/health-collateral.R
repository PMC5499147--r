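#' Assemble the population curves from the integrated transients
#'
#' Builds collateral damage `C(t)`, the two altered populations `M(t)`,
#' `N(t)` and healthy cells `H(t) = T - C - M - N` from the closed-form
#' transients:
#' \deqn{C(t) = \Lambda^1 V_0 + H_{1i} IT + H_{1j} JT + H_{1k} KT}
#' \deqn{M(t) = p_2 p_0 V_0 + H_{2j}(q_1 V_0 + JT) + H_{2k}((1-p_0)V_0 + KT)}
#' \deqn{N(t) = p_1 p_0 V_0 + H_{3j}(q_1 V_0 + JT) + H_{3k}((1-p_0)V_0 + KT)}
#' Conservation `H + C + M + N = T` holds by construction; the identity
#' `H = T - Lambda V0 - H1i IT - cj JT - ck KT` is available independently
#' through [health_reduced()].
#'
#' The linear model carries no positivity guarantee: `H` can go negative at
#' large doses. It is reported as computed; only percentage summaries in
#' [dose_sweep()] floor it at zero.
#'
#' @param t Nonnegative, sorted time grid.
#' @param sp A [split_params()] object carrying the dose.
#' @param psi A [jacobian_psi()] object.
#' @param ds A [dose_scaling()] object.
#' @param T_total Total cell count. `T_total > Lambda * V0` is recommended
#'   so that `H(0) > 0`; smaller values are allowed and simply reported.
#' @return A tibble of class `imm_curves` with columns `t, H, C, M, N` and
#'   attributes `V0` and `T_total`.
#' @export
assemble_populations <- function(t, sp, psi, ds, T_total) {
  stopifnot(inherits(sp, "imm_split"), inherits(psi, "imm_psi"),
            inherits(ds, "imm_scaling"))
  check_time_grid(t)
  rc <- reduced_constants(sp, psi, ds, T_total)
  V0 <- sp$V0
  jt <- transient_jt(t, rc$theta1, rc$theta2, ds$r2, ds$r3, ds$r4, V0)
  kt <- transient_kt(t, rc$theta1, rc$theta2, ds$r2, ds$r3, ds$r4, V0)
  it <- if (V0 > 0) {
    transient_it(t, i_amplitude(ds, V0, psi$H1i), ds$r6 * V0)
  } else {
    rep(0, length(t))
  }
  C <- rc$Lambda1 * V0 + psi$H1i * it + psi$H1j * jt + psi$H1k * kt
  M <- sp$p2 * sp$p0 * V0 + psi$H2j * (sp$q1 * V0 + jt) +
    psi$H2k * ((1 - sp$p0) * V0 + kt)
  N <- sp$p1 * sp$p0 * V0 + psi$H3j * (sp$q1 * V0 + jt) +
    psi$H3k * ((1 - sp$p0) * V0 + kt)
  out <- tibble(t = t, H = T_total - C - M - N, C = C, M = M, N = N)
  structure(out, V0 = V0, T_total = T_total,
            class = c("imm_curves", class(out)))
}

#' @rdname assemble_populations
#' @param model An [autoimmune_model()] bundle.
#' @param V0 Trigger dose.
#' @export
population_curves <- function(model, V0, t = seq(0, 5, length.out = 1001)) {
  stopifnot(inherits(model, "imm_model"))
  assemble_populations(t, model_split(model, V0), model$psi, model$scaling,
                       model$T_total)
}

#' @export
glance.imm_curves <- function(x, rebound_frac = 0.01, ...) {
  T_total <- attr(x, "T_total")
  ext <- find_extrema(x$H, tol = 1e-9 * T_total)
  tibble(
    V0 = attr(x, "V0"),
    T_total = T_total,
    min_health_pct = 100 * max(min(x$H), 0) / T_total,
    max_collateral = max(x$C),
    min_collateral = min(x$C),
    n_health_extrema = ext$n,
    rebound = has_rebound(x$H, ext, rebound_frac * T_total)
  )
}

#' Reduced closed form of the healthy-cell curve
#'
#' The fully collapsed health estimate
#' \deqn{H(t) = T - \Lambda V_0 - r_5 V_0 (1 - e^{-r_6 V_0 t})
#'   - s_1 e^{r_2 V_0 t} \cos(r_3 V_0 t - r_4 V_0 - \theta_2 + \theta_3)
#'   + s_1 \cos(r_4 V_0 + \theta_2 - \theta_3)}
#' which is identical (analytically, not just numerically) to the assembled
#' `H` of [assemble_populations()] when the interferon amplitude takes its
#' default value.
#'
#' The sign of `theta2` in the constant phase term matters: the variant with
#' `cos(r4 V0 - theta2 - theta3)` (available via `paper_literal = TRUE`)
#' does not cancel against the oscillatory term at `t = 0` and violates
#' `H(t; V0 = 0) = T`; it is retained only as a negative control.
#'
#' @param t Time(s).
#' @param sp A [split_params()] object.
#' @param ds A [dose_scaling()] object.
#' @param rc A [reduced_constants()] object.
#' @param paper_literal Use the literal (inconsistent) constant-phase term.
#' @return Numeric vector `H(t)`.
#' @export
health_reduced <- function(t, sp, ds, rc, paper_literal = FALSE) {
  stopifnot(inherits(rc, "imm_constants"))
  V0 <- sp$V0
  delta <- ds$r4 * V0
  const_phase <- if (paper_literal) delta - rc$theta2 - rc$theta3
                 else delta + rc$theta2 - rc$theta3
  rc$T_total - rc$Lambda * V0 -
    ds$r5 * V0 * (1 - exp(-ds$r6 * V0 * t)) -
    rc$s1 * exp(ds$r2 * V0 * t) *
      cos(ds$r3 * V0 * t - delta - rc$theta2 + rc$theta3) +
    rc$s1 * cos(const_phase)
}

#' Reduced closed form of the collateral-damage curve
#'
#' \deqn{C(t) = \Lambda^1 V_0 + r_5 V_0 (1 - e^{-r_6 V_0 t})
#'   + s_2 e^{r_2 V_0 t} \cos(r_3 V_0 t - r_4 V_0 - \theta_2 + \phi)
#'   - s_2 \cos(r_4 V_0 + \theta_2 - \phi)}
#' with `C(0) = Lambda1 * V0` exactly (the two `s2` terms cancel at `t = 0`).
#'
#' @inheritParams health_reduced
#' @return Numeric vector `C(t)`.
#' @export
collateral_reduced <- function(t, sp, ds, rc) {
  stopifnot(inherits(rc, "imm_constants"))
  V0 <- sp$V0
  delta <- ds$r4 * V0
  rc$Lambda1 * V0 + ds$r5 * V0 * (1 - exp(-ds$r6 * V0 * t)) +
    rc$s2 * exp(ds$r2 * V0 * t) *
      cos(ds$r3 * V0 * t - delta - rc$theta2 + rc$phi) -
    rc$s2 * cos(delta + rc$theta2 - rc$phi)
}

#' Decay / push-pull decomposition of the health curve
#'
#' Splits `H(t) = T + decay(t) + Delta(t)` into the monotone decay terms
#' `-Lambda V0 - r5 V0 (1 - exp(-r6 V0 t))` and the oscillatory push-pull
#' term `Delta(t)` built from the two `s1` cosines. Health can only rebound
#' when the two cosines are out of phase, which allows a gain of up to about
#' `2 * s1` times the growing envelope; the column `xi` reports the
#' difference of the two cosine factors at each time and `gain = s1 * xi`
#' its contribution.
#'
#' @inheritParams health_reduced
#' @return A tibble with columns `t, decay, delta, xi, gain, H`.
#' @export
pushpull_decomposition <- function(t, sp, ds, rc) {
  stopifnot(inherits(rc, "imm_constants"))
  V0 <- sp$V0
  dphase <- ds$r4 * V0
  decay <- -rc$Lambda * V0 - ds$r5 * V0 * (1 - exp(-ds$r6 * V0 * t))
  cos_moving <- cos(ds$r3 * V0 * t - dphase - rc$theta2 + rc$theta3)
  cos_const <- cos(dphase + rc$theta2 - rc$theta3)
  delta_term <- -rc$s1 * exp(ds$r2 * V0 * t) * cos_moving + rc$s1 * cos_const
  xi <- cos_const - cos_moving
  tibble(t = t, decay = decay, delta = delta_term, xi = xi,
         gain = rc$s1 * xi, H = rc$T_total + decay + delta_term)
}

#' Sweep the trigger dose and summarize each response
#'
#' Evaluates the assembled population curves at every dose and reports the
#' minimal health percentage (floored at zero), the extrema of collateral
#' damage over a post-transient window, the number of interior local extrema
#' of health, and whether health rebounds (an interior local minimum
#' followed by a recovery exceeding `rebound_frac` of the total cell count).
#'
#' @param model An [autoimmune_model()] bundle.
#' @param V0_grid Doses to sweep.
#' @param t Time grid per dose.
#' @param window Optional time window `c(lo, hi)` for the collateral
#'   max/min; default the full horizon.
#' @param rebound_frac Recovery threshold as a fraction of `T_total`.
#' @return A tibble of class `imm_sweep`, one row per dose, with columns
#'   `V0, min_health_pct, max_collateral, min_collateral, n_health_extrema,
#'   rebound`.
#' @export
dose_sweep <- function(model, V0_grid = 0:50,
                       t = seq(0, 5, length.out = 1001),
                       window = NULL, rebound_frac = 0.01) {
  stopifnot(inherits(model, "imm_model"), length(V0_grid) >= 1L)
  check_time_grid(t)
  in_window <- if (is.null(window)) rep(TRUE, length(t))
               else t >= window[1] & t <= window[2]
  if (!any(in_window)) abort("`window` excludes every time point.",
                             class = "imm_grid_error")
  rows <- purrr::map(V0_grid, function(v) {
    curves <- population_curves(model, v, t)
    ext <- find_extrema(curves$H, tol = 1e-9 * model$T_total)
    tibble(
      V0 = v,
      min_health_pct = 100 * max(min(curves$H), 0) / model$T_total,
      max_collateral = max(curves$C[in_window]),
      min_collateral = min(curves$C[in_window]),
      n_health_extrema = ext$n,
      rebound = has_rebound(curves$H, ext, rebound_frac * model$T_total)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("imm_sweep", class(out)))
}

#' @export
glance.imm_sweep <- function(x, ...) {
  tibble(
    n_doses = nrow(x),
    worst_health_pct = min(x$min_health_pct),
    worst_dose = x$V0[which.min(x$min_health_pct)],
    n_rebound_doses = sum(x$rebound),
    health_nonmonotone = n_sign_changes(x$min_health_pct) > 0,
    collateral_nonmonotone = n_sign_changes(x$max_collateral) > 0
  )
}

# interior local extrema via first-difference sign changes; runs of values
# within tol (plateaus) collapse so each flat extremum counts once
find_extrema <- function(y, tol = 0) {
  d <- diff(y)
  s <- sign(d)
  s[abs(d) <= tol] <- 0
  nz <- which(s != 0)
  minima <- integer(0)
  maxima <- integer(0)
  if (length(nz) >= 2L) {
    for (a in seq_len(length(nz) - 1L)) {
      s1 <- s[nz[a]]; s2 <- s[nz[a + 1L]]
      if (s1 < 0 && s2 > 0) minima <- c(minima, nz[a] + 1L)
      if (s1 > 0 && s2 < 0) maxima <- c(maxima, nz[a] + 1L)
    }
  }
  list(minima = minima, maxima = maxima, n = length(minima) + length(maxima))
}

has_rebound <- function(h, ext, rise) {
  if (length(ext$minima) == 0L) return(FALSE)
  any(vapply(ext$minima, function(ix) {
    max(h[ix:length(h)]) - h[ix] > rise
  }, TRUE))
}

n_sign_changes <- function(y) {
  d <- diff(y)
  s <- sign(d)[sign(d) != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}
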