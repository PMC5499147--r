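---
title: "Oscillatory collateral damage: model, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillatory collateral damage: model, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscimmune)
```

## The model

A trigger — virus, bacterium, environmental toxin — hits a host of `T` cells
and partitions them: a fraction `p0` of the dose `V0` enters cells, splitting
`p1 : p2` between two populations `N` and `M` that the trigger alters in
different ways (in West Nile virus infection these are the nondividing and
dividing infected cells). Three mediating signals connect the populations:
the interferon-gamma deviation `i`, an upregulation signal `j` (e.g. MHC-1
surface density) and a free-trigger signal `k` (e.g. free antigen). Healthy
cells lost to the immune response itself — collateral damage `C` — are the
model's operationalization of an autoimmune effect.

Both layers of the model are tangent-plane linearizations about the
pre-trigger equilibrium. The population layer is driven by a sign-constrained
Jacobian of partials `H` (class `jacobian_psi()`): interferon raises
collateral damage only; the upregulation signal depletes both altered
populations; the free signal grows `M` and depletes `N`. The signal layer has
its own Jacobian `G` (class `jacobian_phi()`) whose lower-right 2x2 block in
`(j, k)` decides everything interesting: when it takes the
rotation-plus-growth form with equal diagonal `alpha` and opposite
off-diagonal `±beta`, the signals oscillate with growing envelope, and the
health and collateral curves inherit the oscillation — the model's account
of remission/relapse cycling.

Under that oscillation condition the deviations have the phase-amplitude
closed form

    i(t) = A exp(-zeta2 t)
    j(t) =  R exp(alpha t) cos(beta t - delta)
    k(t) = -R exp(alpha t) sin(beta t - delta)

with every parameter proportional to dose: `R = r1 V0`, `alpha = r2 V0`,
`beta = r3 V0`, `delta = r4 V0`, `zeta1 = r5 V0`, `zeta2 = r6 V0`.
Integrating the deviations gives the transients `IT`, `JT`, `KT`
(`transient_it()`, `transient_jt()`, `transient_kt()`), from which the
population curves assemble (`assemble_populations()`), and two fully reduced
closed forms follow for health (`health_reduced()`) and collateral damage
(`collateral_reduced()`). The health curve decomposes into monotone decay
plus an oscillatory push–pull term (`pushpull_decomposition()`); rebound is
possible exactly when the push–pull cosines drift out of phase.

## Conventions the algebra forces

The source derivations contain internal inconsistencies; each was resolved
by requiring that the reduced closed forms equal the assembled curves, with
an independent numerical oracle as referee. The package fixes:

* **Phase angle `theta3`.** Defined here as `atan2(ck, cj)`, so that
  `cos(theta3) = cj / sqrt(cj^2 + ck^2)` in every quadrant. The alternative
  reading `atan(cj/ck)` contradicts the reference-triangle substitution used
  two lines later and does not reproduce the assembled health curve. The
  collateral phase `phi = atan2(H1k, H1j)` is unambiguous.
* **Constant phase of the reduced health form.** The consistent term is
  `+ s1 cos(r4 V0 + theta2 - theta3)`; the variant with `- theta2` breaks
  the sanity identity `H(t; V0 = 0) = T` by a visible margin (about 0.17
  cells out of 100 for the default fixture). Both are available —
  `health_reduced(..., paper_literal = TRUE)` keeps the inconsistent variant
  as a documented negative control.
* **Orientation of the oscillation block.** The generator of the trajectory
  pair `(cos, -sin)` is `[[alpha, beta], [-beta, alpha]]`, the mirror of the
  conventionally displayed block. The printed trajectories are canonical
  (they feed the health model); `classify_oscillation()` therefore accepts
  either off-diagonal sign arrangement for its exact-condition flag.
* **Interferon decay.** The deviation `i` decays at `zeta2 = r6 V0 > 0`,
  with default amplitude `A = r5 V0 zeta2 / H1i` so that `H1i * IT(t)`
  equals the saturating interferon term `r5 V0 (1 - exp(-r6 V0 t))` of the
  reduced health form exactly. A positive self-partial for interferon
  coexists in the source with a decaying exponential; the decaying form is
  the one every downstream formula uses, so it is the one implemented.
* **`KT` exponent.** Intermediate lines alternate between `exp(-alpha t)`
  and `exp(alpha t)`; the growing exponential is correct (it is the
  antiderivative of the stated `k`), confirmed by adaptive quadrature.
* **`N(t)` assembly.** The initial mass of `N` is `p1 p0 V0` (the stated
  partition), and its last transient term uses `KT`, following the pattern
  of the other populations; the total `Lambda V0` is unaffected.
* **Characteristic polynomial.** The 2x2 determinant uses the product of
  the off-diagonal entries, not the diagonal ones.
* **Dissociation constants.** `K = k_off / k_on`, forced by the stated
  equivalence between `u << K` and `k_on * u << k_off`.
* **First-order diffusion perturbation.** The exact change in the reduced
  diffusion constant carries a factor `xi = 1/K_N`; the first-order value
  keeps it (`perturbed_diffusion()`), with a `paper_literal` variant that
  drops it for comparison.

## Parameters, units, defaults

All concentrations and cell counts are abstract units; the theory fixes
signs, ranges and dose-proportionalities but no magnitudes (the original
numeric settings live in unpublished companion code). The default fixture
(`default_model()`) is therefore a documented stand-in chosen once:

| parameter | default | role |
|---|---|---|
| `p0` | 0.8 | fraction of dose entering cells |
| `p1`, `p2` | 0.99, 0.01 | N : M split of infected cells |
| `q1` | 0.5 | upregulation scale, `J0 = q1 V0` |
| `r1..r6` | 0.05, 0.02, 0.05, 0.5, 0.1, 0.1 | dose proportionalities |
| `H` partials | (1, 0.4, 0.3, -0.5, 0.2, -0.4, -0.6) | sign-conforming response |
| `T` | 100 | total cells |

The choice satisfies the constraints the theory itself imposes: all sign
assumptions hold, the signal block meets the exact oscillation condition
with `r2 > 0` (growing oscillations), `H(0) > 0` across the default dose
grid `0..50`, and the dose sweep shows the predicted qualitative features —
non-monotone minimal health and collateral extrema versus dose, and health
rebound at many doses. `r3` and `r4` control how many oscillation periods
fit in the horizon and how fast the phase wraps with dose; values giving
roughly one period over `t in [0, 5]` at mid doses produce the
characteristic up-and-down dose-response profile, which disappears when the
horizon contains many periods (the envelope then dominates).

Default grids: time `t in [0, 5]` with 1001 points, doses `0..50` in unit
steps. These sizes keep every verification (20-set oracle comparisons, a
400-point diffusion grid) within seconds on one CPU.

## The seeded generator

`random_oscillatory_params()` is the package's synthetic-data generator: it
draws sign-conforming partials and dose constants uniformly from ranges that
keep the growth factor `exp(r2 V0 t)` moderate over the horizon, and then
*derives* `r1 = sqrt(q1^2 + (1-p0)^2)` and `r4 = atan2(1-p0, q1) / V0`. The
derivation is forced: the closed form starts at `j(0) = R cos(delta)`,
`k(0) = R sin(delta)`, and these equal the dose-implied initial conditions
`J0 = q1 V0`, `K0 = (1-p0) V0` only for that amplitude and phase. A draw is
therefore internally consistent at its own dose — which is precisely what
the ODE-oracle comparison requires — while remaining dose-proportional in
form.

What the generator does *not* emulate: measurement noise, parameter
correlations a real pathway would induce, non-exact oscillation conditions
(sign-correct but unequal diagonals), or any nonlinearity beyond the
tangent-plane approximation. Passing tests demonstrate internal consistency
of the closed forms and solvers, not fidelity to any host.

## Micro level: pathway and diffusion

The trigger pathway (`pathway_config()`, `compose_pathway()`) is a chain of
three tanh switches — port, enzyme, expression — each `f(x) = (scale/2)(1 +
tanh((x - x0)/g))` with transition speed `1/(2g)` at threshold. The
expression stage switches at zero (translation proceeds at any transcript
level), which leaves a nonzero floor `h_Q(0) = (e/2) delta_Q Q_max`; the
floor is part of the printed model and kept, with a `baseline_subtract`
flag for users who want the change from floor. Fragility increments follow
`mu (2 eps + eps^2)` (`fragility_delta()`), whose first-order limit
`2 mu eps` has relative error exactly `|eps|/2`.

The diffusion layer treats the trigger as a 1-D buffered
reaction–diffusion system (`simulate_trigger_full()`), with the two cell
populations as saturable buffers. Its rapid-equilibrium, linear-buffering
reduction collapses everything to constant-coefficient diffusion at
`D_hat = (D0 + DM gamma_M + DN gamma_N) / (1 + gamma_M + gamma_N)`
(`reduced_diffusion_constant()`, `simulate_trigger_reduced()`). The bound
fractions `C_M`, `C_N` are treated as dimensionless occupancies with
capacities `B`; the source alternates between a cell-fraction and a
concentration reading, and the occupancy reading is the one consistent with
the binding kinetics.

Numerical scheme: method of lines, second-order central differences, ghost
nodes implementing `-D u_x = J` at both boundaries, `deSolve`'s banded
stiff integrator (`ode.1D`) at `rtol = 1e-10`, `atol = 1e-12`. With zero
flux, the trapezoid-weighted mass of the semi-discrete composite field is
conserved identically, so observed drift measures time-integration error
alone. Blow-up (non-finite state) aborts with a classed error rather than
returning garbage.

The stiff-kinetics validation regime uses `k_on = k_off = 100` with `K = 1`
and a pulse of amplitude `1e-3` (so `u << K` by three orders of magnitude),
`gamma_M = gamma_N = 1`, and strongly contrasting diffusivities
(`D0 = 1`, `DM = 0.05`, `DN = 0.02`), making the reduction a real test:
`D_hat ≈ 0.357` differs from every raw diffusivity by a factor of three or
more.

## The sign-pattern screen

`screen_pairs()` implements the proposed assay analysis: for each *ordered*
pair of candidate signals, with measured sensitivities `A1 = dj/j`,
`A2 = dj/k`, `A3 = dk/j`, `A4 = dk/k`, flag pairs with `A1 > 0`, opposed
cross signs, and matched diagonal signs. Ordered pairs are screened because
the four arrays are asymmetric in the roles of `j` and `k`; both
orientations are reported. Measurements within `zero_tol` of zero are
sign-indeterminate and fail conservatively — a screen should not nominate a
pair on the strength of a value indistinguishable from noise. The strict
`A1 > zero_tol` implements the growth (undamped) requirement; no magnitude
threshold separates acceptably-damped from overdamped pairs because the
theory supplies none. `screen_fixture()` plants known-passing pairs for
recovery testing; `micro_gradient_map()` connects the pathway-level
`theta (2 eps + eps^2)` parameters to the block entries and applies the
same verdict.

## Numerical choices and edge cases

* Phase angles always via `atan2`; the transients use the phase-folded
  (theta) forms, which are well defined at `V0 = 0` and `r2 = 0` without
  special-casing, and equal the raw integration-by-parts forms to machine
  precision wherever both are defined.
* `transient_it()` requires `zeta2 > 0`; the `zeta2 = 0` limit `A t` is
  available behind an explicit flag rather than silently.
* Extrema of the health curve are detected by first-difference sign changes
  with tolerance `1e-9 T`; plateau runs collapse so a flat minimum counts
  once. A *rebound* is an interior local minimum followed by a later rise
  exceeding 1% of `T` (configurable); 1% separates genuine recovery from
  discretization ripple at the default grid.
* Health can go negative at large doses — the linearization has no
  positivity guarantee. Curves are reported as computed; only the
  percentage summaries floor at zero.
* The 2x2 eigenvalues come from the quadratic formula (exact real parts for
  rotation blocks), and the 3x3 solve is only a cross-check.
* Sigmoid outputs are *mathematically* inside their open intervals, but
  `tanh` saturates to 1.0 in double precision roughly 18 gain-widths past
  threshold; contract tests therefore probe the unsaturated range.

## Limitations

The macro model is a linearization: valid near the pre-trigger equilibrium,
silent about saturation, and capable of negative populations at high dose.
The closed forms assume the *exact* oscillation condition; sign-correct but
non-exact blocks oscillate with an envelope the closed forms do not
describe (the ODE oracle still applies). Dose proportionality of all six
rate constants is an assumption, not a derivation. The diffusion model is
one-dimensional by construction. The screen is a sign filter on error-free
measurements; it performs no statistical inference, and its behavior under
measurement noise is reported by the fixtures rather than guaranteed.
Nothing here models T-cell recognition, avidity, or any specific pathogen.
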