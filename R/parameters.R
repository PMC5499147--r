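#' Trigger dose and partition fractions
#'
#' Bundles the trigger dose `V0` with the fractions that partition it across
#' the host: `p0` of the dose enters cells, of which fraction `p1` lands in
#' the N population and `p2` in the M population (`p1 + p2 = 1`); `q1` scales
#' the initial upregulation signal J0 = q1 * V0. The remaining `(1 - p0) * V0`
#' stays free and sets K0.
#'
#' @param V0 Trigger dose, nonnegative (abstract concentration units).
#' @param p0 Fraction of the dose entering cells, in `[0, 1]`.
#' @param p1 Fraction of infected cells in population N, in `[0, 1]`.
#' @param p2 Fraction in population M; defaults to `1 - p1`.
#' @param q1 Upregulation scaling for J0, positive.
#' @param tol Relative tolerance for the `p1 + p2 = 1` invariant.
#'
#' @return An object of class `imm_split`.
#' @examples
#' split_params(V0 = 100, p0 = 1, p1 = 0.99, q1 = 0.5)
#' @export
split_params <- function(V0, p0, p1 = 0.99, p2 = 1 - p1, q1 = 0.5,
                         tol = 1e-12) {
  stopifnot(is.numeric(V0), length(V0) == 1L, is.finite(V0))
  if (V0 < 0) abort("`V0` must be nonnegative.", class = "imm_invalid_parameter")
  for (nm in c("p0", "p1", "p2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a single value in [0, 1].", nm),
            class = "imm_invalid_parameter")
    }
  }
  if (!is.numeric(q1) || length(q1) != 1L || !is.finite(q1) || q1 <= 0) {
    abort("`q1` must be a single positive value.", class = "imm_invalid_parameter")
  }
  if (abs(p1 + p2 - 1) > tol) {
    abort(sprintf("`p1 + p2` must equal 1 (got %.15g).", p1 + p2),
          class = "imm_invalid_parameter")
  }
  structure(list(V0 = V0, p0 = p0, p1 = p1, p2 = p2, q1 = q1),
            class = "imm_split")
}

#' Initial conditions implied by a trigger dose
#'
#' At the moment the trigger is applied the collateral-damage pool and the
#' interferon deviation start at zero; the altered populations receive
#' `p2*p0*V0` (M) and `p1*p0*V0` (N); the upregulation signal starts at
#' `q1*V0` and the free trigger at `(1 - p0)*V0`.
#'
#' @param sp A [split_params()] object.
#' @return A one-row tibble with columns `C0, M0, N0, I0, J0, K0`.
#' @examples
#' initial_state(split_params(100, p0 = 1, p1 = 0.99, q1 = 0.5))
#' @export
initial_state <- function(sp) {
  stopifnot(inherits(sp, "imm_split"))
  tibble(
    C0 = 0,
    M0 = sp$p2 * sp$p0 * sp$V0,
    N0 = sp$p1 * sp$p0 * sp$V0,
    I0 = 0,
    J0 = sp$q1 * sp$V0,
    K0 = (1 - sp$p0) * sp$V0
  )
}

#' Population-response Jacobian (partials of the C, M, N rates)
#'
#' Entries are the partial derivatives of the collateral, M and N growth
#' rates with respect to the signal deviations i, j, k at the operating
#' point. The i-column partials for M and N are structurally zero: the
#' interferon deviation feeds only collateral damage.
#'
#' @param H1i,H1j,H1k Partials of the collateral rate; expected `> 0`.
#' @param H2j,H2k Partials of the M rate; expected signs `-`, `+`.
#' @param H3j,H3k Partials of the N rate; expected signs `-`, `-`.
#' @return An object of class `imm_psi`.
#' @seealso [validate_sign_pattern()] to audit the assumed signs.
#' @export
jacobian_psi <- function(H1i, H1j, H1k, H2j, H2k, H3j, H3k) {
  vals <- c(H1i = H1i, H1j = H1j, H1k = H1k,
            H2j = H2j, H2k = H2k, H3j = H3j, H3k = H3k)
  stopifnot(all(vapply(vals, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), TRUE)))
  structure(as.list(vals), class = "imm_psi")
}

#' @export
as.matrix.imm_psi <- function(x, ...) {
  m <- rbind(c(x$H1i, x$H1j, x$H1k),
             c(0,     x$H2j, x$H2k),
             c(0,     x$H3j, x$H3k))
  dimnames(m) <- list(c("C", "M", "N"), c("i", "j", "k"))
  m
}

#' Signal-interaction Jacobian (partials of the I, J, K rates)
#'
#' @param G1i,G1j,G1k Partials of the interferon rate.
#' @param G2i,G2j,G2k Partials of the J rate.
#' @param G3i,G3j,G3k Partials of the K rate.
#' @return An object of class `imm_phi`.
#' @export
jacobian_phi <- function(G1i, G1j, G1k = 0, G2i = 0, G2j, G2k,
                         G3i = 0, G3j, G3k) {
  vals <- c(G1i = G1i, G1j = G1j, G1k = G1k, G2i = G2i, G2j = G2j,
            G2k = G2k, G3i = G3i, G3j = G3j, G3k = G3k)
  stopifnot(all(vapply(vals, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), TRUE)))
  structure(as.list(vals), class = "imm_phi")
}

#' @export
as.matrix.imm_phi <- function(x, ...) {
  m <- rbind(c(x$G1i, x$G1j, x$G1k),
             c(x$G2i, x$G2j, x$G2k),
             c(x$G3i, x$G3j, x$G3k))
  dimnames(m) <- list(c("i", "j", "k"), c("i", "j", "k"))
  m
}

#' Dose-proportionality constants for the oscillatory solution
#'
#' The phase-amplitude description of the signal deviations scales with the
#' trigger dose: amplitude `R = r1*V0`, growth rate `alpha = r2*V0`, angular
#' frequency `beta = r3*V0`, phase `delta = r4*V0`, interferon drive
#' `zeta1 = r5*V0` and interferon decay `zeta2 = r6*V0`.
#'
#' @param r1,r2,r3,r4,r5,r6 Positive proportionality constants.
#' @param A Optional override for the interferon deviation amplitude; when
#'   `NULL` (default) it is derived as `r5*V0*zeta2/H1i` so the integrated
#'   interferon transient reproduces the saturating term of the reduced
#'   health form exactly.
#' @return An object of class `imm_scaling`.
#' @export
dose_scaling <- function(r1, r2, r3, r4, r5, r6, A = NULL) {
  vals <- c(r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = r5, r6 = r6)
  stopifnot(all(vapply(vals, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), TRUE)))
  if (any(vals < 0)) abort("dose-scaling constants must be nonnegative.",
                           class = "imm_invalid_parameter")
  if (r2^2 + r3^2 <= 0) abort("`r2` and `r3` cannot both be zero.",
                              class = "imm_degenerate_parameter")
  structure(c(as.list(vals), list(A = A)), class = "imm_scaling")
}

# per-dose phase-amplitude parameters
scaled_at_dose <- function(ds, V0) {
  list(R = ds$r1 * V0, alpha = ds$r2 * V0, beta = ds$r3 * V0,
       delta = ds$r4 * V0, zeta1 = ds$r5 * V0, zeta2 = ds$r6 * V0)
}

# i-amplitude default: makes H1i * IT equal zeta1 * (1 - exp(-zeta2 t))
i_amplitude <- function(ds, V0, H1i) {
  if (!is.null(ds$A)) return(ds$A)
  ds$r5 * V0 * (ds$r6 * V0) / H1i
}

#' Reduced-form constants shared by the health and collateral closed forms
#'
#' Collapses the dose-scaling constants and population-response partials into
#' the phase/amplitude constants of the closed forms: `theta1 =
#' r1/sqrt(r2^2+r3^2)`, `theta2 = atan(r3/r2)`, the column sums `cj`, `ck`,
#' the oscillation amplitudes `s1`, `s2`, the phase angles `theta3`
#' (`atan2(ck, cj)`) and `phi` (`atan2(H1k, H1j)`), and the per-dose mass
#' coefficients `Lambda` and `Lambda1`. All are independent of the dose
#' itself; only their products with `V0` enter the curves.
#'
#' The two-argument arctangent is used for both phase angles so that
#' `cos(theta3) = cj/sqrt(cj^2+ck^2)` in every quadrant; this is the only
#' convention under which the reduced health form reproduces the assembled
#' population curves.
#'
#' @param sp A [split_params()] object (only the fractions are used).
#' @param psi A [jacobian_psi()] object.
#' @param ds A [dose_scaling()] object.
#' @param T_total Total cell count, positive.
#' @return An object of class `imm_constants`.
#' @export
reduced_constants <- function(sp, psi, ds, T_total) {
  stopifnot(inherits(sp, "imm_split"), inherits(psi, "imm_psi"),
            inherits(ds, "imm_scaling"))
  if (!is.numeric(T_total) || length(T_total) != 1L || T_total <= 0) {
    abort("`T_total` must be a single positive number.",
          class = "imm_invalid_parameter")
  }
  hyp <- sqrt(ds$r2^2 + ds$r3^2)
  if (hyp == 0) abort("`r2^2 + r3^2` must be positive.",
                      class = "imm_degenerate_parameter")
  cj <- psi$H1j + psi$H2j + psi$H3j
  ck <- psi$H1k + psi$H2k + psi$H3k
  if (cj == 0 && ck == 0) {
    abort("column sums `cj` and `ck` are both zero: `theta3` is undefined.",
          class = "imm_degenerate_parameter")
  }
  if (psi$H1j == 0 && psi$H1k == 0) {
    abort("`H1j` and `H1k` are both zero: `phi` is undefined.",
          class = "imm_degenerate_parameter")
  }
  theta1 <- ds$r1 / hyp
  structure(list(
    theta1 = theta1,
    theta2 = atan2(ds$r3, ds$r2),
    theta3 = atan2(ck, cj),
    phi    = atan2(psi$H1k, psi$H1j),
    cj = cj, ck = ck,
    s1 = theta1 * sqrt(cj^2 + ck^2),
    s2 = theta1 * sqrt(psi$H1j^2 + psi$H1k^2),
    Lambda  = (sp$p1 + sp$p2) * sp$p0 + cj * sp$q1 + ck * (1 - sp$p0),
    Lambda1 = psi$H1j * sp$q1 + psi$H1k * (1 - sp$p0),
    T_total = T_total
  ), class = "imm_constants")
}

#' Audit a parameter set against the assumed sign patterns
#'
#' Checks each Jacobian entry against the sign pattern the model assumes:
#' population response `[[+,+,+],[0,-,+],[0,-,-]]` and signal interaction
#' `[[+,+,0],[0,+,-],[0,+,+]]`. Violations are reported, never raised, so a
#' parameter set outside the autoimmune-capable regime can still be explored.
#'
#' @param psi A [jacobian_psi()] object, or `NULL` to skip.
#' @param phi A [jacobian_phi()] object, or `NULL` to skip.
#' @return A tibble with columns `matrix`, `entry`, `expected`, `value`,
#'   `pass`.
#' @export
validate_sign_pattern <- function(psi = NULL, phi = NULL) {
  check <- function(value, expected) {
    switch(expected,
           "+" = value > 0,
           "-" = value < 0,
           "0" = value == 0)
  }
  out <- list()
  if (!is.null(psi)) {
    stopifnot(inherits(psi, "imm_psi"))
    exp_psi <- c(H1i = "+", H1j = "+", H1k = "+",
                 H2j = "-", H2k = "+", H3j = "-", H3k = "-")
    out$psi <- tibble(
      matrix = "psi",
      entry = names(exp_psi),
      expected = unname(exp_psi),
      value = vapply(names(exp_psi), function(nm) psi[[nm]], 0),
      pass = vapply(names(exp_psi), function(nm) check(psi[[nm]], exp_psi[[nm]]), TRUE)
    )
  }
  if (!is.null(phi)) {
    stopifnot(inherits(phi, "imm_phi"))
    exp_phi <- c(G1i = "+", G1j = "+", G1k = "0",
                 G2i = "0", G2j = "+", G2k = "-",
                 G3i = "0", G3j = "+", G3k = "+")
    out$phi <- tibble(
      matrix = "phi",
      entry = names(exp_phi),
      expected = unname(exp_phi),
      value = vapply(names(exp_phi), function(nm) phi[[nm]], 0),
      pass = vapply(names(exp_phi), function(nm) check(phi[[nm]], exp_phi[[nm]]), TRUE)
    )
  }
  dplyr::bind_rows(out)
}

#' Bundle a complete macro-model parameter set
#'
#' Everything except the dose: partition fractions, population-response
#' Jacobian, dose-scaling constants and the total cell count. Dose-dependent
#' quantities are derived per dose by [population_curves()], [dose_sweep()]
#' and friends.
#'
#' @param p0,p1,p2,q1 Partition fractions and upregulation scale; see
#'   [split_params()].
#' @param psi A [jacobian_psi()] object.
#' @param scaling A [dose_scaling()] object.
#' @param T_total Total cell count.
#' @return An object of class `imm_model`.
#' @export
autoimmune_model <- function(p0, p1, p2 = 1 - p1, q1, psi, scaling, T_total) {
  sp0 <- split_params(0, p0, p1, p2, q1)  # validates fractions
  stopifnot(inherits(psi, "imm_psi"), inherits(scaling, "imm_scaling"))
  rc <- reduced_constants(sp0, psi, scaling, T_total)  # validates degeneracies
  structure(list(p0 = p0, p1 = p1, p2 = p2, q1 = q1, psi = psi,
                 scaling = scaling, T_total = T_total, constants = rc),
            class = "imm_model")
}

#' @export
print.imm_model <- function(x, ...) {
  cat("<imm_model>\n")
  cat(sprintf("  fractions: p0 = %g, p1 = %g, p2 = %g, q1 = %g\n",
              x$p0, x$p1, x$p2, x$q1))
  cat(sprintf("  dose scaling r1..r6: %s\n",
              paste(signif(unlist(x$scaling[paste0("r", 1:6)]), 4), collapse = ", ")))
  cat(sprintf("  T = %g cells; Lambda = %.4g, Lambda1 = %.4g\n",
              x$T_total, x$constants$Lambda, x$constants$Lambda1))
  invisible(x)
}

# dose-specific split for a bundled model
model_split <- function(model, V0) {
  split_params(V0, model$p0, model$p1, model$p2, model$q1)
}
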