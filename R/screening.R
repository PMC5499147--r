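#' Pairwise sensitivity measurements for candidate signals
#'
#' Container for the four n-by-n arrays of measured relative sensitivities
#' between ordered signal pairs (p, q): `A1 = dj/j`, `A2 = dj/k`,
#' `A3 = dk/j`, `A4 = dk/k`, where signal p plays the role of j and signal q
#' the role of k. Diagonals are undefined and stored as `NA`.
#'
#' @param A1,A2,A3,A4 Square numeric matrices of equal dimension.
#' @return An object of class `imm_screen`.
#' @export
screen_measurement <- function(A1, A2, A3, A4) {
  mats <- list(A1 = A1, A2 = A2, A3 = A3, A4 = A4)
  dims <- unique(lapply(mats, dim))
  if (length(dims) != 1L || dims[[1]][1] != dims[[1]][2]) {
    abort("the four arrays must be square matrices of identical shape.",
          class = "imm_shape_mismatch")
  }
  n <- dims[[1]][1]
  if (n < 2L) abort("at least two candidate signals are required.",
                    class = "imm_invalid_parameter")
  mats <- lapply(mats, function(m) { diag(m) <- NA_real_; m })
  off <- !diag(n)
  if (any(vapply(mats, function(m) any(!is.finite(m[off])), TRUE))) {
    abort("off-diagonal measurements must be finite.",
          class = "imm_invalid_parameter")
  }
  structure(c(mats, list(n = n)), class = "imm_screen")
}

#' Screen signal pairs for autoimmune-capable sign patterns
#'
#' For each ordered pair (p, q), tests the oscillation sign recipe on the
#' measured sensitivities: growth `A1 > 0` (undamped oscillations need a
#' positive self-sensitivity of j), opposed cross terms
#' `sign(A3) = -sign(A2)`, and matched diagonal `sign(A1) = sign(A4)`. A
#' pair passing all three could sustain the growing oscillations that
#' underlie remission/relapse cycling. Measurements within `zero_tol` of
#' zero are sign-indeterminate and conservatively fail.
#'
#' @param m An [screen_measurement()] object.
#' @param zero_tol Magnitudes at or below this are treated as zero.
#' @return A tibble with one row per ordered pair: columns `p, q,
#'   A1, A2, A3, A4, growth, opposed_cross, matched_diag, passes`, ordered
#'   by `p` then `q`.
#' @export
screen_pairs <- function(m, zero_tol = 1e-8) {
  stopifnot(inherits(m, "imm_screen"))
  pairs <- expand.grid(q = seq_len(m$n), p = seq_len(m$n))[, 2:1]
  pairs <- pairs[pairs$p != pairs$q, ]
  pairs <- pairs[order(pairs$p, pairs$q), ]
  sgn <- function(x) sign(x) * (abs(x) > zero_tol)
  a1 <- m$A1[cbind(pairs$p, pairs$q)]
  a2 <- m$A2[cbind(pairs$p, pairs$q)]
  a3 <- m$A3[cbind(pairs$p, pairs$q)]
  a4 <- m$A4[cbind(pairs$p, pairs$q)]
  growth <- a1 > zero_tol
  opposed <- sgn(a3) != 0 & sgn(a3) == -sgn(a2)
  matched <- sgn(a1) != 0 & sgn(a1) == sgn(a4)
  tibble(
    p = pairs$p, q = pairs$q,
    A1 = a1, A2 = a2, A3 = a3, A4 = a4,
    growth = growth, opposed_cross = opposed, matched_diag = matched,
    passes = growth & opposed & matched
  )
}

#' Map micro-level pathway parameters to a signal Jacobian block
#'
#' Each Jacobian entry of the (j, k) block is approximated by the fragility
#' form `G = theta * (2*eps + eps^2)` of its pathway. The exact oscillation
#' conditions become
#' `theta_2j(2e+e^2) = theta_3k(2e+e^2)` and
#' `theta_3j(2e+e^2) = -theta_2k(2e+e^2)`; the relaxed verdict only asks
#' that the algebraic signs work out (opposed cross signs, matched diagonal
#' signs, positive diagonal for growth).
#'
#' @param theta_2j,theta_2k,theta_3j,theta_3k Pathway scales (either sign).
#' @param eps_2j,eps_2k,eps_3j,eps_3k Relative increments.
#' @param tol Tolerance for the exact-equality flags, relative to the
#'   largest block entry (floor 1).
#' @return An object of class `imm_micro`: list with `block` (2x2 matrix),
#'   `exact_diagonal`, `exact_cross`, `sign_verdict` and `classification`
#'   (an [classify_oscillation()] result).
#' @export
micro_gradient_map <- function(theta_2j, theta_2k, theta_3j, theta_3k,
                               eps_2j, eps_2k, eps_3j, eps_3k,
                               tol = 1e-8) {
  G2j <- fragility_delta(theta_2j, eps_2j)
  G2k <- fragility_delta(theta_2k, eps_2k)
  G3j <- fragility_delta(theta_3j, eps_3j)
  G3k <- fragility_delta(theta_3k, eps_3k)
  block <- matrix(c(G2j, G3j, G2k, G3k), 2, 2,
                  dimnames = list(c("j", "k"), c("j", "k")))
  scale <- max(abs(block), 1)
  sign_verdict <- G2j > 0 && sign(G2j) == sign(G3k) &&
    sign(G3j) != 0 && sign(G3j) == -sign(G2k)
  structure(list(
    block = block,
    exact_diagonal = abs(G2j - G3k) <= tol * scale,
    exact_cross = abs(G3j + G2k) <= tol * scale,
    sign_verdict = sign_verdict,
    classification = classify_oscillation(block, tol)
  ), class = "imm_micro")
}

#' Generate a synthetic pairwise-sensitivity assay
#'
#' Seeded stand-in for the proposed organoid well assay: builds the four
#' sensitivity arrays so that a chosen set of ordered pairs satisfies all
#' three screening conditions exactly (before noise) while every other pair
#' violates at least one, then adds Gaussian measurement noise.
#'
#' @param n_signals Number of candidate signals (>= 2).
#' @param planted Ordered index pairs that must pass: a list of length-2
#'   vectors or a 2-column matrix.
#' @param noise_sd Standard deviation of additive measurement noise.
#' @param seed Integer seed; the same seed reproduces the arrays exactly.
#' @return An [screen_measurement()] object with a `planted` attribute.
#' @export
screen_fixture <- function(n_signals = 5, planted = list(c(1, 2)),
                           noise_sd = 0, seed = NULL) {
  stopifnot(n_signals >= 2, noise_sd >= 0)
  if (is.matrix(planted)) planted <- asplit(planted, 1)
  for (pq in planted) {
    if (length(pq) != 2L || pq[1] == pq[2] ||
        any(pq < 1) || any(pq > n_signals)) {
      abort("each planted pair must be two distinct indices within range.",
            class = "imm_impossible_plant")
    }
  }
  with_seed(seed, {
    n <- n_signals
    mag <- function() matrix(runif(n * n, 0.5, 2), n, n)
    A1 <- mag(); A2 <- mag(); A3 <- mag(); A4 <- mag()
    # default every pair to a violation of one randomly chosen condition
    viol <- matrix(sample(1:3, n * n, replace = TRUE), n, n)
    A1[viol == 1] <- -A1[viol == 1]                       # damped: A1 < 0
    same <- viol == 2                                      # cross signs equal
    A3[same] <- A2[same] * runif(sum(same), 0.5, 2)
    A4[viol == 3] <- -A4[viol == 3]                        # diagonal mismatch
    cross_sign <- matrix(sample(c(-1, 1), n * n, replace = TRUE), n, n)
    A2[!same] <- cross_sign[!same] * abs(A2[!same])
    A3[!same] <- -cross_sign[!same] * abs(A3[!same])
    for (pq in planted) {
      p <- pq[1]; q <- pq[2]
      A1[p, q] <- abs(A1[p, q])
      A4[p, q] <- abs(A4[p, q])
      s <- sample(c(-1, 1), 1)
      A2[p, q] <- s * abs(A2[p, q])
      A3[p, q] <- -s * abs(A3[p, q])
    }
    if (noise_sd > 0) {
      A1 <- A1 + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
      A2 <- A2 + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
      A3 <- A3 + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
      A4 <- A4 + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
    }
    out <- screen_measurement(A1, A2, A3, A4)
    attr(out, "planted") <- planted
    out
  })
}
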