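#' Second-messenger pathway configuration
#'
#' Parameters of the sigmoid cascade that converts an extracellular trigger
#' concentration into a bounded change in protein expression: a membrane
#' port stage, an enzyme-binding stage at the nuclear membrane, and an
#' expression stage capped at a fraction of baseline. Each stage is a tanh
#' switch whose transition speed at threshold is `1/(2g)`.
#'
#' Defaults are illustrative fixtures in abstract concentration units; the
#' theory fixes only the ranges, not the magnitudes.
#'
#' @param r Free fraction of the induced trigger, in (0, 1).
#' @param s Fraction binding the enzyme, in (0, 1).
#' @param e Conversion efficiency, in (0, 1).
#' @param g_p,g_e,g_Q Positive gains of the three switches.
#' @param T0_base Port activation threshold concentration.
#' @param T1_nominal Nominal induced-trigger concentration.
#' @param delta_Q Maximal fractional expression change, in (0, 1].
#' @param Q_max Baseline maximal expression, positive.
#' @return An object of class `imm_pathway`.
#' @export
pathway_config <- function(r = 0.6, s = 0.5, e = 0.7,
                           g_p = 0.2, g_e = 0.5, g_Q = 1,
                           T0_base = 1, T1_nominal = 10,
                           delta_Q = 0.25, Q_max = 100) {
  if (r <= 0 || r >= 1) abort("`r` must lie in (0, 1).", class = "imm_invalid_parameter")
  if (s <= 0 || s >= 1) abort("`s` must lie in (0, 1).", class = "imm_invalid_parameter")
  if (e <= 0 || e >= 1) abort("`e` must lie in (0, 1).", class = "imm_invalid_parameter")
  if (any(c(g_p, g_e, g_Q) <= 0)) {
    abort("gains `g_p`, `g_e`, `g_Q` must be positive.", class = "imm_invalid_parameter")
  }
  if (delta_Q <= 0 || delta_Q > 1) abort("`delta_Q` must lie in (0, 1].",
                                         class = "imm_invalid_parameter")
  if (Q_max <= 0) abort("`Q_max` must be positive.", class = "imm_invalid_parameter")
  structure(list(r = r, s = s, e = e, g_p = g_p, g_e = g_e, g_Q = g_Q,
                 T0_base = T0_base, T1_nominal = T1_nominal,
                 delta_Q = delta_Q, Q_max = Q_max),
            class = "imm_pathway")
}

#' Trigger-induced fragility increment
#'
#' A relative change `eps` in an upstream transcription factor produces a
#' fragility change `delta = mu * (2*eps + eps^2) = mu * ((1+eps)^2 - 1)`;
#' quadratic in the perturbation, hence potentially explosive for large
#' `eps`, and approximately `2*mu*eps` for small ones.
#'
#' @param mu Scale, either sign.
#' @param eps Relative increment, `>= -1`.
#' @return `mu * (2*eps + eps^2)`, vectorized.
#' @examples
#' fragility_delta(1, 0.1)  # 0.21
#' @export
fragility_delta <- function(mu, eps) {
  mu * (2 * eps + eps^2)
}

#' Scaled tanh switch
#'
#' `f(x) = (scale/2) * (1 + tanh((x - x0)/g))`: output in `(0, scale)`,
#' value `scale/2` at the switch point and derivative `scale/(2g)` there.
#'
#' @param x Input concentration(s).
#' @param x0 Switch point.
#' @param g Gain, positive; smaller values switch faster.
#' @param scale Output supremum.
#' @return Numeric vector in `(0, scale)`.
#' @export
sigmoid_switch <- function(x, x0 = 0, g = 1, scale = 1) {
  if (!is.numeric(g) || length(g) != 1L || g <= 0) {
    abort("`g` must be a single positive gain.", class = "imm_invalid_parameter")
  }
  scale / 2 * (1 + tanh((x - x0) / g))
}

#' Port activation stage
#'
#' `h_p(T0) = (r/2) * (1 + tanh((T0 - T0_base)/g_p))`: the fraction of the
#' induced trigger freed into the cytosol, in `(0, r)`.
#'
#' @param T0 Extracellular trigger concentration(s).
#' @param cfg A [pathway_config()] object.
#' @return Numeric vector in `(0, r)`.
#' @export
port_activation <- function(T0, cfg) {
  stopifnot(inherits(cfg, "imm_pathway"))
  sigmoid_switch(T0, x0 = cfg$T0_base, g = cfg$g_p, scale = cfg$r)
}

#' Enzyme-binding stage
#'
#' `h_e(x) = (s/2) * (1 + tanh((x - r*T1_nominal/2)/g_e))` where the input
#' `x = h_p(T0) * T1_nominal` ranges over `(0, r*T1_nominal)`; the threshold
#' sits at the midpoint of that range.
#'
#' @param x Activated trigger reaching the nuclear membrane.
#' @param cfg A [pathway_config()] object.
#' @return Numeric vector in `(0, s)`.
#' @export
enzyme_activation <- function(x, cfg) {
  stopifnot(inherits(cfg, "imm_pathway"))
  sigmoid_switch(x, x0 = cfg$r * cfg$T1_nominal / 2, g = cfg$g_e,
                 scale = cfg$s)
}

#' Expression-change stage
#'
#' `h_Q(P) = (e/2) * delta_Q * Q_max * (1 + tanh(P/g_Q))` with switch point
#' at zero, since translation proceeds at any transcript level. The output
#' is bounded by `e * delta_Q * Q_max`, capping how far expression can move
#' from baseline. The nonzero floor `h_Q(0) = (e/2) delta_Q Q_max` is part
#' of the printed model; `baseline_subtract = TRUE` reports the change
#' relative to that floor instead.
#'
#' @param P Transcribed-protein concentration(s).
#' @param cfg A [pathway_config()] object.
#' @param baseline_subtract Subtract the zero-stimulus output.
#' @return Numeric vector in `(0, e * delta_Q * Q_max)`.
#' @export
expression_change <- function(P, cfg, baseline_subtract = FALSE) {
  stopifnot(inherits(cfg, "imm_pathway"))
  out <- sigmoid_switch(P, x0 = 0, g = cfg$g_Q,
                        scale = cfg$e * cfg$delta_Q * cfg$Q_max)
  if (baseline_subtract) out <- out - cfg$e * cfg$delta_Q * cfg$Q_max / 2
  out
}

#' Compose the full trigger-to-expression cascade
#'
#' Chains the three stages: `h_p(T0)` frees a fraction of the induced
#' trigger, `h_e(h_p(T0) * T1_nominal)` binds the enzyme, the transcript
#' `P = h_e(...) * T1_nominal` drives the expression change
#' `dQ_max = h_Q(P)`. Monotone nondecreasing in `T0` throughout.
#'
#' @param T0 Extracellular trigger grid.
#' @param cfg A [pathway_config()] object.
#' @param baseline_subtract Passed to [expression_change()].
#' @return A tibble with columns `T0, h_p, x_e, h_e, P, dQ_max`.
#' @export
compose_pathway <- function(T0, cfg, baseline_subtract = FALSE) {
  stopifnot(inherits(cfg, "imm_pathway"))
  h_p <- port_activation(T0, cfg)
  x_e <- h_p * cfg$T1_nominal
  h_e <- enzyme_activation(x_e, cfg)
  P <- h_e * cfg$T1_nominal
  tibble(T0 = T0, h_p = h_p, x_e = x_e, h_e = h_e, P = P,
         dQ_max = expression_change(P, cfg, baseline_subtract))
}

#' Per-population cascade outputs
#'
#' Evaluates the cascade with population-specific parameter sets for the two
#' altered cell populations, whose fragility proteins differ.
#'
#' @param T0 Extracellular trigger grid.
#' @param cfg_M,cfg_N [pathway_config()] objects for the M and N populations.
#' @return A long tibble with a `population` column.
#' @export
compose_pathway_populations <- function(T0, cfg_M, cfg_N) {
  dplyr::bind_rows(
    dplyr::mutate(compose_pathway(T0, cfg_M), population = "M"),
    dplyr::mutate(compose_pathway(T0, cfg_N), population = "N")
  )
}
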