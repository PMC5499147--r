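test_that("assembled curves satisfy their initial-value identities", {
  m <- default_model()
  rc <- m$constants
  V0 <- 12
  curves <- population_curves(m, V0, t = c(0, 1, 2))
  sp <- split_params(V0, m$p0, m$p1, m$p2, m$q1)
  expect_equal(curves$C[1], rc$Lambda1 * V0)
  expect_equal(curves$H[1], m$T_total - rc$Lambda * V0)
  expect_equal(curves$M[1],
               m$p2 * m$p0 * V0 + m$psi$H2j * m$q1 * V0 +
                 m$psi$H2k * (1 - m$p0) * V0)

  # zero dose leaves the host untouched
  flat <- population_curves(m, 0, t = seq(0, 5, length.out = 21))
  expect_equal(flat$H, rep(m$T_total, 21))
  expect_true(all(flat$C == 0) && all(flat$M == 0) && all(flat$N == 0))
})

test_that("populations conserve the total cell count pointwise", {
  for (seed in 1:5) {
    rp <- random_oscillatory_params(seed)
    curves <- population_curves(rp$model, rp$V0)
    drift <- abs(curves$H + curves$C + curves$M + curves$N -
                   rp$model$T_total)
    expect_lt(max(drift), 1e-9 * rp$model$T_total)
  }
})

test_that("assembled health equals the independent summation oracle", {
  t <- seq(0, 5, length.out = 101)
  for (seed in 1:5) {
    rp <- random_oscillatory_params(seed)
    curves <- population_curves(rp$model, rp$V0, t)
    oracle <- health_summation_oracle(t, rp$model, rp$V0)
    expect_lt(max(abs(curves$H - oracle)) / rp$model$T_total, 1e-12)
  }
})

test_that("reduced closed forms reproduce the assembled curves", {
  t <- seq(0, 5, length.out = 201)
  for (seed in 1:5) {
    rp <- random_oscillatory_params(seed)
    m <- rp$model
    curves <- population_curves(m, rp$V0, t)
    h <- health_reduced(t, rp$sp, m$scaling, m$constants)
    cc <- collateral_reduced(t, rp$sp, m$scaling, m$constants)
    expect_lt(max(abs(h - curves$H)) / m$T_total, 1e-10)
    expect_lt(max(abs(cc - curves$C)) / m$T_total, 1e-10)
    expect_equal(collateral_reduced(0, rp$sp, m$scaling, m$constants),
                 m$constants$Lambda1 * rp$V0)
  }
})

test_that("the literal constant-phase variant breaks the zero-dose identity", {
  m <- default_model()
  sp0 <- split_params(0, m$p0, m$p1, m$p2, m$q1)
  t <- seq(0, 5, length.out = 11)
  consistent <- health_reduced(t, sp0, m$scaling, m$constants)
  literal <- health_reduced(t, sp0, m$scaling, m$constants,
                            paper_literal = TRUE)
  expect_equal(consistent, rep(m$T_total, 11))
  expect_gt(max(abs(literal - m$T_total)), 1e-3)
})

test_that("push-pull decomposition re-sums to health and can rebound ~2*s1", {
  m <- default_model()
  rc <- m$constants
  V0 <- 9
  sp <- split_params(V0, m$p0, m$p1, m$p2, m$q1)
  t <- sort(runif(100, 0, 5))
  pp <- pushpull_decomposition(t, sp, m$scaling, rc)
  expect_equal(pp$H, health_reduced(t, sp, m$scaling, rc))
  expect_equal(pp$H, rc$T_total + pp$decay + pp$delta)
  expect_equal(pushpull_decomposition(0, sp, m$scaling, rc)$delta, 0)

  # dose chosen so the constant cosine sits at +1; half a period later the
  # moving cosine reaches -1 and the push-pull gain approaches 2*s1*envelope
  v_star <- (rc$theta3 - rc$theta2 + 2 * pi) / m$scaling$r4
  sp_star <- split_params(v_star, m$p0, m$p1, m$p2, m$q1)
  t_star <- pi / (m$scaling$r3 * v_star)
  pp_star <- pushpull_decomposition(t_star, sp_star, m$scaling, rc)
  envelope <- exp(m$scaling$r2 * v_star * t_star)
  expect_equal(pp_star$delta, rc$s1 * (1 + envelope), tolerance = 1e-8)
  expect_gt(pp_star$xi, 1.99)
})

test_that("dose sweep summarizes each dose and finds the predicted features", {
  m <- default_model()
  only0 <- dose_sweep(m, V0_grid = 0)
  expect_equal(only0$min_health_pct, 100)
  expect_equal(only0$max_collateral, 0)
  expect_equal(only0$min_collateral, 0)
  expect_false(only0$rebound)

  sw <- dose_sweep(m, V0_grid = seq(0, 50, by = 1),
                   t = seq(0, 5, length.out = 501))
  expect_equal(nrow(sw), 51)
  expect_true(all(sw$min_collateral <= sw$max_collateral))
  expect_true(all(sw$min_health_pct <= 100))
  g <- glance(sw)
  expect_true(g$health_nonmonotone)
  expect_gte(g$n_rebound_doses, 1)
})

test_that("extrema detection tolerates plateaus and counts interior extrema", {
  fe <- oscimmune:::find_extrema
  flat_min <- fe(c(3, 1, 1, 1, 2), tol = 0)
  expect_equal(length(flat_min$minima), 1L)
  expect_equal(length(flat_min$maxima), 0L)
  wave <- fe(sin(seq(0, 4 * pi, length.out = 200)), tol = 0)
  expect_equal(length(wave$minima), 2L)
  expect_equal(length(wave$maxima), 2L)
  expect_equal(fe(seq(0, 1, 0.1), tol = 0)$n, 0L)
  # jitter below tolerance is not an extremum
  noisy <- fe(c(0, 1, 1 + 1e-12, 1, 2), tol = 1e-9)
  expect_equal(noisy$n, 0L)
})
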