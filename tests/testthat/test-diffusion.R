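test_that("equilibrium fractions saturate with half-capacity at u = K", {
  eq0 <- equilibrium_fractions(0, 1, 2, 0.8, 3)
  expect_equal(eq0$C_M, 0)
  expect_equal(eq0$C_N, 0)
  expect_equal(equilibrium_fractions(2, B_M = 1, K_M = 2, B_N = 1, K_N = 5)$C_M, 0.5)
  sat <- equilibrium_fractions(1e9, 1, 2, 0.8, 3)
  expect_equal(sat$C_M, 1, tolerance = 1e-8)
  expect_equal(sat$C_N, 0.8, tolerance = 1e-8)
  expect_error(equilibrium_fractions(-1, 1, 1, 1, 1),
               class = "imm_invalid_parameter")
})

test_that("linear buffering matches its formulas and its validity bound", {
  expect_equal(linear_fractions(2, 0, 0)$w, 2)
  expect_equal(linear_fractions(1, 2, 3)$w, 6)
  # relative deviation from the saturating form is exactly u/K
  K <- 50
  u <- seq(0.001, 0.01, length.out = 10) * K
  lin <- linear_fractions(u, gamma_M = 1 / K, gamma_N = 2 / K)
  eq <- equilibrium_fractions(u, B_M = 1, K_M = K, B_N = 2, K_N = K)
  expect_true(all(abs(lin$C_M - eq$C_M) / eq$C_M <= u / K + 1e-12))
  expect_true(all(abs(lin$C_N - eq$C_N) / eq$C_N <= u / K + 1e-12))
  expect_warning(linear_fractions(10, 1, 1, K_M = 1, K_N = 1),
                 "linear-buffering")
})

test_that("effective and reduced diffusion constants obey their algebra", {
  expect_equal(effective_diffusion(0.3, 0.4, D0 = 2, DM = 2, DN = 2), 2)
  expect_equal(effective_diffusion(1, 0, D0 = 1, DM = 3, DN = 7), 3)
  expect_equal(reduced_diffusion_constant(0, 0, 1, 2, 4), 1)
  expect_equal(reduced_diffusion_constant(3, 5, 2, 2, 2), 2)
  expect_equal(reduced_diffusion_constant(1, 1, 1, 2, 4), 7 / 3)
  # linear-regime derivatives gamma/Lambda recover the reduced constant
  gM <- 0.7; gN <- 1.3; L <- 1 + gM + gN
  expect_equal(effective_diffusion(gM / L, gN / L, 1, 2, 4),
               reduced_diffusion_constant(gM, gN, 1, 2, 4))
  # convex-combination property over random buffering strengths
  set.seed(1)
  for (i in 1:20) {
    g <- runif(2, 0, 5); d <- runif(3, 0.1, 3)
    dh <- reduced_diffusion_constant(g[1], g[2], d[1], d[2], d[3])
    expect_gte(dh, min(d) - 1e-12)
    expect_lte(dh, max(d) + 1e-12)
  }
  # monotone in gamma_N toward D_N
  dhs <- sapply(seq(0, 10, 1), function(g) reduced_diffusion_constant(1, g, 1, 2, 4))
  expect_false(is.unsorted(dhs))
})

test_that("the perturbed constant vanishes appropriately and is second-order accurate", {
  p0 <- perturbed_diffusion(0, D_hat = 1.5, Lambda = 3, D_N = 4, K_N = 2)
  expect_equal(p0$D_tilde, 1.5)
  expect_equal(p0$delta_exact, 0)
  expect_equal(p0$delta_first_order, 0)
  pd <- perturbed_diffusion(0.3, D_hat = 2, Lambda = 3, D_N = 2, K_N = 5)
  expect_equal(pd$delta_exact, 0)
  # gap between exact and first order shrinks ~4x when eps halves
  gap <- function(eps) {
    p <- perturbed_diffusion(eps, D_hat = 1.2, Lambda = 3, D_N = 4, K_N = 2)
    abs(p$delta_exact - p$delta_first_order)
  }
  ratio <- gap(0.2) / gap(0.1)
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 4.8)
  expect_error(perturbed_diffusion(10, 1, 1, 1, K_N = 1),
               class = "imm_degenerate_parameter")
})

test_that("the heat kernel is normalized and solves the diffusion equation", {
  D <- 0.7; t0 <- 0.5
  expect_equal(as.numeric(quadrature(function(x) heat_kernel(t0, x, D),
                                     upper = 40, lower = -40)),
               1, tolerance = 1e-8)
  expect_equal(heat_kernel(t0, 0, D), 1 / sqrt(4 * pi * D * t0))
  # residual phi_t - D*phi_xx -> 0 at second order under grid refinement
  resid <- function(h) {
    x <- seq(-2, 2, length.out = 41)
    pt <- (heat_kernel(t0 + h, x, D) - heat_kernel(t0 - h, x, D)) / (2 * h)
    pxx <- (heat_kernel(t0, x + h, D) - 2 * heat_kernel(t0, x, D) +
              heat_kernel(t0, x - h, D)) / h^2
    max(abs(pt - D * pxx))
  }
  r1 <- resid(1e-2); r2 <- resid(5e-3)
  expect_gt(log2(r1 / r2), 1.8)
  expect_error(heat_kernel(0, 0, 1), class = "imm_invalid_parameter")
  expect_error(heat_kernel(1, 0, -1), class = "imm_invalid_parameter")
})

test_that("equilibrated flat profiles are stationary in both solvers", {
  cfg <- diffusion_config(n = 60, L = 4)
  u0 <- rep(0.002, 60)
  ff <- simulate_trigger_full(cfg, u0, times = c(0, 0.5, 1))
  expect_lt(max(abs(ff$u - 0.002)), 1e-8)
  fr <- simulate_trigger_reduced(cfg, u0, times = c(0, 0.5, 1))
  expect_lt(max(abs(fr$u - 0.002)), 1e-10)
})

test_that("composite mass is conserved under zero flux for arbitrary data", {
  cfg <- diffusion_config(n = 120, L = 8, kM_on = 20, kM_off = 10,
                          kN_on = 5, kN_off = 50)
  u0 <- function(x) 0.05 * (1 + sin(2 * pi * x / 8)^2) * exp(-(x - 3)^2)
  # start far from binding equilibrium on purpose
  ff <- simulate_trigger_full(cfg, u0, times = seq(0, 1, 0.25),
                              CM0 = rep(0.3, 120), CN0 = rep(0.1, 120))
  mass <- field_mass(ff)
  expect_lt(max(abs(mass$mass / mass$mass[1] - 1)), 1e-8)
  # bound fractions respect their capacities
  expect_true(all(ff$C_M >= -1e-10 & ff$C_M <= cfg$B_M + 1e-10))
  expect_true(all(ff$C_N >= -1e-10 & ff$C_N <= cfg$B_N + 1e-10))
})

test_that("the reduced solver obeys a discrete maximum principle", {
  cfg <- diffusion_config(n = 100, L = 10)
  u0 <- function(x) 0.01 * exp(-(x - 5)^2)
  fr <- simulate_trigger_reduced(cfg, u0, times = seq(0, 2, 0.5))
  init <- fr[fr$time == 0, ]$u
  expect_lte(max(fr$u), max(init) + 1e-9)
  expect_gte(min(fr$u), min(init) - 1e-9)
})

test_that("stiff kinetics collapse the full model onto the reduced constant", {
  # u << K and fast exchange: rapid-equilibrium linear buffering applies
  cfg <- diffusion_config(n = 150, L = 10, D0 = 1, DM = 0.05, DN = 0.02,
                          kM_on = 100, kM_off = 100, kN_on = 100,
                          kN_off = 100, B_M = 1, B_N = 1)
  u0 <- function(x) 1e-3 * exp(-(x - 5)^2 / 0.5)
  times <- seq(0, 1, 0.25)
  ff <- simulate_trigger_full(cfg, u0, times)
  fr <- simulate_trigger_reduced(cfg, u0, times)
  uf <- ff[ff$time == 1, ]$u
  ur <- fr[fr$time == 1, ]$u
  expect_lt(sqrt(sum((uf - ur)^2) / sum(ur^2)), 0.05)
})

test_that("a narrow pulse under the reduced solver follows the heat kernel", {
  D <- 0.8
  cfg <- diffusion_config(n = 300, L = 30, D0 = D, DM = D, DN = D)
  t0 <- 0.05
  u0 <- heat_kernel(t0, cfg$x - 15, D)
  fr <- simulate_trigger_reduced(cfg, u0, times = c(0, 0.5), D = D)
  got <- fr[fr$time == 0.5, ]$u
  want <- heat_kernel(t0 + 0.5, cfg$x - 15, D)
  expect_lt(sqrt(sum((got - want)^2) / sum(want^2)), 0.01)
})

test_that("a Gaussian pulse spreads with variance 2*D*t", {
  cfg <- diffusion_config(n = 250, L = 40)
  Dhat <- reduced_diffusion_constant(cfg$gamma_M, cfg$gamma_N,
                                     cfg$D0, cfg$DM, cfg$DN)
  sig0 <- 0.5
  u0 <- function(x) exp(-(x - 20)^2 / (2 * sig0^2))
  times <- seq(0, 2, 0.25)
  fr <- simulate_trigger_reduced(cfg, u0, times)
  v <- field_variance(fr)
  slope <- coef(lm(variance ~ time, data = v))[["time"]]
  expect_equal(slope, 2 * Dhat, tolerance = 0.01)
})
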