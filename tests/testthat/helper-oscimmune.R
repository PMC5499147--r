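# shared helpers for the suite

# per-component relative error of a trajectory against its oracle,
# normalized by the oracle's scale
traj_rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), .Machine$double.eps)
}

# closed-form deviations and their ODE oracle for one seeded parameter set
seeded_closed_vs_ode <- function(seed, t = seq(0, 5, length.out = 201)) {
  rp <- random_oscillatory_params(seed)
  ds <- rp$model$scaling
  cf <- signal_trajectories(t, rp$sp, ds, H1i = rp$model$psi$H1i)
  sys <- closed_form_system(rp$sp, ds, rp$model$psi$H1i)
  od <- ode_trajectories(sys$jacobian, sys$y0, t)
  list(rp = rp, closed = cf, ode = od,
       err = c(i = traj_rel_err(cf$i, od$i),
               j = traj_rel_err(cf$j, od$j),
               k = traj_rel_err(cf$k, od$k)))
}

# trajectory component evaluated at arbitrary (quadrature-node) order
traj_component <- function(component, sp, ds, H1i) {
  function(s) {
    ord <- order(s)
    out <- numeric(length(s))
    out[ord] <- signal_trajectories(s[ord], sp, ds, H1i)[[component]]
    out
  }
}

# direct-summation oracle for the assembled health curve
health_summation_oracle <- function(t, model, V0) {
  sp <- split_params(V0, model$p0, model$p1, model$p2, model$q1)
  rc <- model$constants
  ds <- model$scaling
  jt <- transient_jt(t, rc$theta1, rc$theta2, ds$r2, ds$r3, ds$r4, V0)
  kt <- transient_kt(t, rc$theta1, rc$theta2, ds$r2, ds$r3, ds$r4, V0)
  it <- if (V0 > 0) {
    A <- ds$r5 * V0 * (ds$r6 * V0) / model$psi$H1i
    A / (ds$r6 * V0) * (1 - exp(-ds$r6 * V0 * t))
  } else {
    rep(0, length(t))
  }
  model$T_total - rc$Lambda * V0 - model$psi$H1i * it - rc$cj * jt - rc$ck * kt
}
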