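test_that("initial state follows the dose partition exactly", {
  zero <- initial_state(split_params(0, p0 = 0.7, p1 = 0.6, p2 = 0.4, q1 = 2))
  expect_true(all(unlist(zero) == 0))

  # high-asymmetry split: almost all infected cells land in N
  st <- initial_state(split_params(100, p0 = 1, p1 = 0.99, p2 = 0.01, q1 = 0.5))
  expect_equal(st$K0, 0)
  expect_equal(st$J0, 50)
  expect_equal(st$M0, 1)
  expect_equal(st$N0, 99)
  expect_equal(st$C0, 0)
  expect_equal(st$I0, 0)

  st2 <- initial_state(split_params(10, p0 = 0.8, p1 = 0.5, p2 = 0.5, q1 = 1))
  expect_equal(st2$M0, 4)
  expect_equal(st2$N0, 4)
  expect_equal(st2$J0, 10)
  expect_equal(st2$K0, 2)
})

test_that("initial state is homogeneous of degree 1 in the dose", {
  for (seed in 1:5) {
    rp <- random_oscillatory_params(seed)
    s1 <- initial_state(rp$sp)
    s2 <- initial_state(split_params(2 * rp$V0, rp$model$p0, rp$model$p1,
                                     rp$model$p2, rp$model$q1))
    expect_equal(unlist(s2), 2 * unlist(s1))
  }
})

test_that("invalid partitions are rejected", {
  expect_error(split_params(-1, 0.5, 0.5, 0.5, 1), class = "imm_invalid_parameter")
  expect_error(split_params(1, 0.5, 0.6, 0.6, 1), class = "imm_invalid_parameter")
  expect_error(split_params(1, 1.2, 0.5, 0.5, 1), class = "imm_invalid_parameter")
  expect_error(split_params(1, 0.5, 0.5, 0.5, q1 = 0), class = "imm_invalid_parameter")
})

test_that("reduced constants match their defining formulas", {
  sp <- split_params(1, 0.5, 0.5, 0.5, 1)

  ds <- dose_scaling(1, 1, 1, 0.1, 0.1, 0.1)
  psi <- jacobian_psi(1, 0.4, 0.3, -0.5, 0.2, -0.4, -0.6)
  rc <- reduced_constants(sp, psi, ds, 100)
  expect_equal(rc$theta1, 1 / sqrt(2))
  expect_equal(rc$theta2, pi / 4)

  # cj = 0, ck = 1 with theta1 = 1: s1 = 1 and theta3 = pi/2
  psi2 <- jacobian_psi(1, 0.5, 0.5, -0.3, 0.3, -0.2, 0.2)
  ds2 <- dose_scaling(sqrt(2), 1, 1, 0.1, 0.1, 0.1)
  rc2 <- reduced_constants(sp, psi2, ds2, 100)
  expect_equal(rc2$cj, 0)
  expect_equal(rc2$ck, 1)
  expect_equal(rc2$s1, 1)
  expect_equal(rc2$theta3, pi / 2)

  # s2 = theta1 * sqrt(H1j^2 + H1k^2) = 2 * 5
  psi3 <- jacobian_psi(1, 3, 4, -0.5, 0.2, -0.4, -0.6)
  ds3 <- dose_scaling(2 * sqrt(2), 1, 1, 0.1, 0.1, 0.1)
  rc3 <- reduced_constants(sp, psi3, ds3, 100)
  expect_equal(rc3$s2, 10)
})

test_that("reduced constants are dose-free and Lambda*V0 is the initial altered mass", {
  for (seed in 1:5) {
    rp <- random_oscillatory_params(seed)
    m <- rp$model
    rc <- m$constants
    # theta/phase constants computed at any dose agree (they never see V0)
    rc2 <- reduced_constants(split_params(17, m$p0, m$p1, m$p2, m$q1),
                             m$psi, m$scaling, m$T_total)
    expect_equal(unclass(rc), unclass(rc2))
    # cross-module: Lambda*V0 = C(0) + M(0) + N(0)
    curves <- population_curves(m, rp$V0, t = 0)
    expect_equal(curves$C + curves$M + curves$N, rc$Lambda * rp$V0)
  }
})

test_that("degenerate reductions raise classed errors", {
  sp <- split_params(1, 0.5, 0.5, 0.5, 1)
  ds <- dose_scaling(1, 1, 1, 0.1, 0.1, 0.1)
  expect_error(dose_scaling(1, 0, 0, 0.1, 0.1, 0.1),
               class = "imm_degenerate_parameter")
  # cj = ck = 0
  psi_cjck0 <- jacobian_psi(1, 0.5, 0.5, -0.2, -0.2, -0.3, -0.3)
  expect_error(reduced_constants(sp, psi_cjck0, ds, 100),
               class = "imm_degenerate_parameter")
  # H1j = H1k = 0
  psi_h10 <- jacobian_psi(1, 0, 0, -0.2, 0.2, -0.3, -0.3)
  expect_error(reduced_constants(sp, psi_h10, ds, 100),
               class = "imm_degenerate_parameter")
})

test_that("sign-pattern audit reports violations without raising", {
  m <- default_model()
  rep_ok <- validate_sign_pattern(m$psi, default_phi(m))
  expect_true(all(rep_ok$pass))

  bad_psi <- jacobian_psi(1, 0.4, 0.3, -0.5, -0.2, -0.4, -0.6)  # H2k < 0
  rep_bad <- validate_sign_pattern(bad_psi)
  expect_false(rep_bad$pass[rep_bad$entry == "H2k"])
  expect_true(all(rep_bad$pass[rep_bad$entry != "H2k"]))

  # free-signal deviations must not feed the interferon rate
  bad_phi <- jacobian_phi(G1i = 0.1, G1j = 0.2, G1k = 0.3,
                          G2j = 0.2, G2k = -0.5, G3j = 0.5, G3k = 0.2)
  rep_phi <- validate_sign_pattern(phi = bad_phi)
  expect_false(rep_phi$pass[rep_phi$entry == "G1k"])
})

test_that("model configurations round-trip losslessly through JSON", {
  rp <- random_oscillatory_params(11)
  path <- tempfile(fileext = ".json")
  write_model_config(rp$model, path)
  back <- read_model_config(path)
  expect_equal(back$psi, rp$model$psi)
  expect_equal(back$scaling, rp$model$scaling)
  expect_identical(back$p0, rp$model$p0)
  expect_identical(back$T_total, rp$model$T_total)
  unlink(path)
})
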