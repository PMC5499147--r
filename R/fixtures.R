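#' Default macro-model parameter set
#'
#' A documented reference parameter set in the growing-oscillation regime.
#' The theory constrains only signs and proportionalities; these magnitudes
#' are fixtures chosen so that (i) every sign assumption holds, (ii) the
#' signal block satisfies the exact oscillation condition with `r2 > 0`,
#' (iii) the total cell count keeps `H(0) > 0` across the default dose grid,
#' and (iv) the dose sweep exhibits the qualitative dose-response features
#' the theory predicts: non-monotone minimal health and collateral extrema
#' versus dose, and health rebound at many doses.
#'
#' @return An [autoimmune_model()] object.
#' @examples
#' model <- default_model()
#' glance(dose_sweep(model, V0_grid = seq(0, 50, by = 5)))
#' @export
default_model <- function() {
  autoimmune_model(
    p0 = 0.8, p1 = 0.99, p2 = 0.01, q1 = 0.5,
    psi = jacobian_psi(H1i = 1, H1j = 0.4, H1k = 0.3,
                       H2j = -0.5, H2k = 0.2, H3j = -0.4, H3k = -0.6),
    scaling = dose_scaling(r1 = 0.05, r2 = 0.02, r3 = 0.05,
                           r4 = 0.5, r5 = 0.1, r6 = 0.1),
    T_total = 100
  )
}

#' Signal-interaction Jacobian implied by a model at a reference dose
#'
#' Builds the full 3x3 signal Jacobian whose (j, k) block satisfies the
#' exact oscillation condition at the given dose: diagonal `alpha = r2*V0`,
#' off-diagonal `+/- beta = r3*V0` in the sign arrangement the theory
#' assumes (`G2k < 0`, `G3j > 0`). The interferon row uses a positive
#' self-term and a positive upregulation coupling, with no back-coupling
#' from the free signal.
#'
#' @param model An [autoimmune_model()] object.
#' @param V0 Reference dose.
#' @param G1i,G1j Interferon-row entries (fixtures; positive).
#' @return A [jacobian_phi()] object.
#' @export
default_phi <- function(model, V0 = 10, G1i = 0.1, G1j = 0.2) {
  stopifnot(inherits(model, "imm_model"), V0 > 0)
  alpha <- model$scaling$r2 * V0
  beta <- model$scaling$r3 * V0
  jacobian_phi(G1i = G1i, G1j = G1j, G1k = 0,
               G2i = 0, G2j = alpha, G2k = -beta,
               G3i = 0, G3j = beta, G3k = alpha)
}

#' Draw a random parameter set in the exact oscillatory regime
#'
#' Samples partition fractions, sign-conforming population partials and
#' dose-scaling constants, then derives `r1 = sqrt(q1^2 + (1-p0)^2)` and
#' `r4 = atan2(1-p0, q1) / V0` so that the phase-amplitude closed form
#' starts exactly at the dose-implied initial conditions
#' `j(0) = J0 = q1*V0` and `k(0) = K0 = (1-p0)*V0` (the amplitude and phase
#' are otherwise free constants that the dose-proportionality assumption
#' cannot pin to the initial state).
#'
#' @param seed Integer seed.
#' @param T_total Total cell count of the drawn model.
#' @return A list with elements `model` (an [autoimmune_model()]), `V0` (the
#'   consistent dose) and `sp` (the matching [split_params()]).
#' @export
random_oscillatory_params <- function(seed = NULL, T_total = 100) {
  with_seed(seed, {
    p0 <- runif(1, 0.5, 0.95)
    q1 <- runif(1, 0.3, 1.5)
    V0 <- runif(1, 1, 5)
    psi <- jacobian_psi(
      H1i = runif(1, 0.2, 1.5),
      H1j = runif(1, 0.1, 1), H1k = runif(1, 0.1, 1),
      H2j = -runif(1, 0.1, 1), H2k = runif(1, 0.1, 1),
      H3j = -runif(1, 0.1, 1), H3k = -runif(1, 0.1, 1)
    )
    scaling <- dose_scaling(
      r1 = sqrt(q1^2 + (1 - p0)^2),
      r2 = runif(1, 0.01, 0.08),
      r3 = runif(1, 0.05, 0.3),
      r4 = atan2(1 - p0, q1) / V0,
      r5 = runif(1, 0.05, 0.3),
      r6 = runif(1, 0.05, 0.3)
    )
    model <- autoimmune_model(p0 = p0, p1 = 0.99, p2 = 0.01, q1 = q1,
                              psi = psi, scaling = scaling,
                              T_total = T_total)
    list(model = model, V0 = V0, sp = model_split(model, V0))
  })
}
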