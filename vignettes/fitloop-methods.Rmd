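---
title: "Methods: fitness estimation, feedback inversion, and the two-stage loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitness estimation, feedback inversion, and the two-stage loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitloop)
```

## The model

`fitloop` simulates a theory in which an organism maintains an internal
estimate of its own evolutionary fitness and uses it twice over: to
modulate the magnitude of random changes of its own form, and — after
inversion into sensorimotor space — to communicate the estimate to
others. The theory is stated at the level of operators:

- fitness is `f = F w`, with `w` the effective world (environment plus the
  organism's own form `θ`) and `F` a nonlinear, nonstationary operator;
- the estimate is `x = X u`, with `u` the sensed part of the world and `X`
  the estimator, decomposed into components `x_i = X_i u_i`;
- the communicable signal is `û_i = X̄_i x_i`, where `X̄_i ≈ X_i⁻¹` is
  realized by a high-gain feedback circuit, not analytically;
- a receiver applies its own similar operator to the (possibly degraded)
  signal: `x'_i = X'_i u'_i ≈ x_i`.

The source theory deliberately leaves `F`, `X_i`, the pooling of
components, and all magnitudes unspecified. Everything concrete below is
therefore this package's own modelling choice, made once and documented
here.

## Concretizations

**Fitness landscape.** `F` is a sum of Gaussian bumps over form space:
bump `j` contributes `height_j · exp(−‖θ − center_j‖² / (2 width_j²))`,
optionally multiplied by a positive environment gate
`exp(env_gate · mean(env))`. A smooth multi-peak landscape is the minimal
structure that exercises the variance-modulation mechanism (peaks to find
and hold, valleys to escape), and positivity keeps `f ≥ 0` as the theory
requires. Components are the per-bump contributions and the scalar `f` is
their sum — the simplest monotone pooling; both are swappable.

**Environment.** A mean-reverting (Ornstein–Uhlenbeck) process around
zero, advanced with the exact discrete transition
`env' = a·env + env_sd·sqrt(1 − a²)·ξ`, `a = exp(−dt/τ)`, so the
stationary sd is exactly `env_sd` at any step size. `τ = Inf` freezes it.

**Estimator components.** The default family is `x_i = φ(A u_i + b)` with
`φ` strictly increasing and bijective on ℝ (tokens: `identity`, and
`leaky_softplus` = `0.25 z + 0.75 log(1 + e^z)`, whose slope is bounded in
(0.25, 1)). This family is invertible by construction, which the
communication story requires, and has a closed-form inverse
(`analytic_linear_oracle()`) that the test suite uses as an independent
oracle — the simulator itself never calls it. A `blackbox` kind exposes
forward evaluation only, so feedback inversion is the only inversion path
for it: the honest test of the mechanism.

Two structural conditions are enforced at construction:

- *condition cap*: square matrices are resampled and finally spectrally
  clipped so `cond(A) ≤ cond_cap` (default `1e4`); ill-conditioned
  operators make any inversion meaningless;
- *monotonicity*: square Gaussian-ensemble draws are shifted so the
  symmetric part of `A` is at least `0.3 I`. A negative-feedback loop
  around a non-monotone operator is genuinely unstable (feedback becomes
  positive in some directions), so strong monotonicity is the property
  that makes the circuit's premise true of the operator family, not a
  numerical convenience.

**Nonstationarity.** Every entry of `A` and `b` follows the exact OU
transition around its construction-time anchor with timescale
`drift_timescale` (time units) and stationary sd `drift_sd`; the condition
cap is re-enforced by clipping after each step. Drift timescales are meant
to be much longer than the loop's cycle period ("slow compared with the
switching rate"); a warning fires when `dt` is not small relative to the
timescale.

**Aggregation to the scalar estimate.** `x = output_map(Σ w_i mean(x_i))`
with a non-negative squashing (`softplus`, so `x(0) = log 2`, or `relu`).
The source theory says only that `x` is "produced by transforming" the
components; this is an explicit open choice.

## The feedback inverter

The circuit `q = G(p − S q)`, `G = g·B`, is realized two ways:

- **Fixed-point mode** iterates `q ← (1−η) q + η·g·B·(p − S q)` from
  `q₀ = 0` until the update norm falls below `tol·(1 + ‖q‖)`. The raw
  iteration is only stable for `η < 2/(1 + g·s)`, which no fixed default
  can satisfy across gains, so `damping` (default 0.5) is treated as the
  *maximum* step: the step is halved until the circuit residual
  `‖g·B·(p − S q) − q‖` decreases, and the accepted step carries over
  (allowed to grow 2× per iteration). For monotone `S` the direction is a
  descent direction for the residual, so this backtracked relaxation
  converges without ever becoming a Newton-type method — the circuit
  equation itself is the only thing iterated. Scalar linear cases
  reproduce the closed form `q = g·p/(1 + g·s)` to machine precision.
- **Dynamical mode** integrates
  `q(t+1) = q(t) + relax_step·(−q(t) + g·B·(p − S q(t − d)))` with a
  circular history buffer of `d = delay_steps`. There is deliberately no
  step safeguard here: with enough gain or delay the loop really goes
  unstable, which is the dynamical-feasibility claim under study.
  Divergence is flagged on a norm bound (`‖q‖ > 1e6·(1 + ‖p‖)`),
  non-finite iterates, or a run of `divergence_run` consecutive residual
  increases. Convergence requires small updates across a *full delay
  window* after the delayed feedback has cycled at least once: under
  delay the loop can sit on a quasi-equilibrium plateau for `d` steps
  between growing kicks, and a single small update proves nothing.

**Preconditioner.** `B = I` for square operators. For non-square or
cited-as-ill-conditioned cases, `"transpose_linearization"` uses the
transpose of a finite-difference linearization of `S` at `q = 0` (step
`fd_step`, default `1e-6`), scaled by `1/σ_max²`, giving gradient-like
convergence to the minimum-distance solution. When `m_out < m_in` the
solution is non-unique; the converged solution is returned with a
`non_unique` flag.

## The switched two-stage loop

One component instance serves both stages: stage 1 latches
`x_buf ← X(u)`, stage 2 latches `u_buf ← X̄(x_buf)`. Buffers are
sample-and-hold — each changes only at its own stage boundary, and a
diverged inversion leaves `u_buf` holding its previous value (flagged in
the trace) rather than emitting garbage. Parameter drift is frozen within
a cycle and applied at cycle boundaries; the option `drift_within_cycle`
drifts between the stages instead, reproducing the small round-trip error
that arises because the two uses of `X_i` are not simultaneous. The
round-trip error in the trace is always judged against the *stage-1*
parameter snapshot, so that nonstationarity between the stages is visible
in it. The cycle period defaults to 0.1 time units (about ten switches
per unit time, echoing switching rates discussed for cortical circuits);
`duty` splits the cycle (default 0.5). Nothing in the theory says what
triggers stage 2; here it runs every cycle.

In the internal-dialogue mode, stage-2 output feeds the next stage 1. For
a stationary component the composition `X̄∘X` shrinks its argument by a
factor `≈ λ/(λ + 1/g)` per cycle (the finite-gain leak), so the sequence
of `û` contracts monotonically toward the fixed point; strict per-cycle
monotonicity of the increments is guaranteed when the linearization has
positive real spectrum, which is why the canonical `internal_dialogue`
fixture uses a symmetric positive-definite `A` (gain 30, 800 cycles,
reaching increments below `1e-6`). Under drift, the `û` trajectory
wanders; because drift enters the composition only through the `1/g`
leak, its per-cycle imprint is small, and the package measures it as the
spread of `û` across independent drift realizations of the *same*
component, which scales as `drift_sd²` by linear response.

## Dialogue

Agents alternate turns: the speaker runs one two-stage cycle on its
pending input, transmits `û` through the channel
(`u' = gain_loss·û + noise`), and the listener reconstructs
`x' = X'(u')`. Receiver mismatch is modelled by perturbing every
parameter block with zero-mean noise of sd `delta` times the block's RMS
entry, so `delta` is the relative parameter difference; the perturbed
copy becomes a distinct individual (its drift anchors move with it). Each
error source — finite gain, channel noise, operator mismatch — is
individually monotone in the reconstruction error, and with all three
zeroed the error vanishes as `1/g`. The theory begins its dialogue
mid-stream; here turn 1 starts from a configured `u_init`, and a
listener's next utterance takes the received signal as its own stage-1
input (an explicit choice; the theory does not specify the reply map).

## The stochastic drive

Per fast step: `f` is evaluated at the current form; the estimate is
`x = max(0, f + ξ·estimate_noise_sd)` (the noise dial *is* estimator
quality; a full sense→bank chain is available via `use_bank` for
integration runs); the step sd is `σ(x)`; and the form takes the step
`θ' = θ + σ·ξ`. Two modulation families are provided, both strictly
decreasing with `σ(0) = sigma_max`: `hill`
(`sigma_max/(1 + (x/x_half)^steepness)`, halved exactly at `x_half`) and
`exponential`. Fitness-to-be `f⁺` is the trailing-window mean of `f` over
the last `window_frac` (default 20%) of the horizon — the effect is
meant to accrue "slowly and gradually", and the window length is an
explicit, configurable reading of that.

The canonical `two_bump_drive` scenario places the form on a low bump
(height 0.4, width 0.6) with a higher bump (height 1.2) a distance 1.2
away, with `sigma_max = 0.15`, hill modulation (`x_half = 0.3`,
`steepness = 6`) and a horizon of 2500 steps. In this regime a perfect
estimator reliably escapes the low bump, finds the high one, and freezes
there (modulation at the peak cuts σ by ~250×), while the matched
control — constant σ equal to the modulated run's own time-average, same
seed, same draws — keeps diffusing off the peak. The control equalizes
the mean step size so that *only* the estimate-dependence of σ differs:
that is the fair null for "modulation matters". Significance uses a
one-sided paired sign-flip permutation test (10⁴ flips), which assumes
nothing about the distribution of per-seed differences. Degrading the
estimator (noise sds 0, 0.5, 1, 2, 4 against a peak height of 1.2)
collapses capture monotonically; the trend is assessed by Spearman rank
correlation with a label-permutation p-value across all seed-level runs.

## What the generator does and does not emulate

The synthetic world gives the mechanisms something real to do —
multi-peak landscapes, slow operator drift, noisy channels — under full
control of every rate and magnitude, with one root seed and documented
per-module streams (`stream_seed()`) so any module can be re-run in
isolation bit-identically. It does not attempt ecological realism: no
births, deaths, inheritance, or populations (the drive is a within-
lifetime mechanism); no learned communication conventions; no partner
modelling (the receiver never predicts the sender's operator); no neural
implementation of the two stages beyond their computational roles. Passing
tests therefore establish the *computational* soundness of the theory's
mechanisms under stated conditions, not their biological adequacy.

## Numerical choices and degenerate inputs

- Backtracked fixed-point steps shrink to `1e-16` before giving up;
  non-finite iterates return the last finite `q` with `diverged = TRUE`.
- `Q = 1/max(ε, 1e-12)`: the floor keeps perfect estimators finite and is
  reported alongside every quality value.
- Spectral clipping preserves singular vectors and clamps singular values
  from below at `σ_max/cond_cap`.
- `sigma_max = 0` freezes the form (the null drive); `dim_env = 0` and
  `env_timescale = Inf` are honest degenerate environments.
- For scalar series the L1 and L2 per-sample norms coincide (`|x − f|`);
  both tokens are accepted for vector quantities.
- Problem sizes in the shipped scenarios (components up to 8×8, 10³ loop
  cycles, 20 paired seeds × 2500 drive steps, 2×10³ permutations) were
  chosen so the whole property suite characterizes each mechanism with
  comfortable statistical margins while remaining quick to run on a
  laptop.

## Known limitations

- The fixed-point inverter's convergence argument relies on monotone
  operators; arbitrary non-monotone maps may legitimately fail (flagged,
  never silent).
- The internal dialogue's attractor under the pure feedback circuit is
  the origin: the finite-gain leak always shrinks the signal. Persistent
  nonzero internal content would need an external or re-afferent input,
  which the theory itself leaves open.
- The estimate-noise dial bypasses the estimator bank by default; the
  full-chain mode exists but its estimator is untrained by design (no
  learning is in scope), so its estimates are only as good as the
  hand-configured bank.
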