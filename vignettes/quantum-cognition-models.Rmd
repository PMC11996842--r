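---
title: "Quantum-cognition decision models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-cognition decision models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcogsim)
```

## What this package models

Classical probability cannot produce `P(A and B) > P(A)`, yet people
reliably do — the conjunction fallacy — and cooperate under uncertainty in
one-shot prisoner's dilemmas where classical decision theory says they
should defect — the sure-thing-principle violation. Quantum probability
theory (QPT) models both by placing cognitive states in a finite complex
Hilbert space: beliefs are unit vectors, judgments are projective
measurements, and *interference* between belief components produces the
classically impossible orderings.

`qcogsim` implements that modeling stack in layers:

1. **Hilbert core** — labeled states, operators, density matrices, the
   Born rule, tensor products. Compatibility is checked by *basis label*,
   not just dimension, so a system-space operator can never be silently
   applied to an observer-space state.
2. **Conjunction model** — the two-angle Linda model
   `|psi> = cos(theta)|B> + sin(theta)|F>` with conjunction direction
   `|B_F> = cos(phi)|B> + sin(phi)|F>`, giving `P(T) = cos^2(theta)` and
   `P(T and F) = cos^2(theta - phi)`; the fallacy region is exactly
   `|theta - phi| < theta`.
3. **Observer perturbation** — a contextual angle shift
   `(delta_theta, delta_phi)` plus a multiplicative conscious-influence
   factor `g = 1 + eta |<focus|initial>|^2`, and first-order
   time-dependent perturbation theory for a weak observer-system coupling
   `H_int = lambda (A_sys ⊗ |focus><focus|)`.
4. **Non-Hermitian collapse** — generators `H - i*Gamma` with `Gamma`
   Hermitian PSD, whose anti-Hermitian part damps non-preferred cognitive
   states irreversibly (a quantum-Zeno-style continuous-measurement
   picture).
5. **Contextual/QBist layer** — CPTP context channels, a contextual Born
   rule that reduces bit-for-bit to the standard one under the identity
   context, Kraus-instrument Bayesian updating, and the literal
   `(d+1)/d` mixture update.
6. **Observer thermodynamics** — closed forms: the Landauer bound
   `ln(2) k_B T`, the one-question energy `beta k_B T`,
   Schwarzschild/Bekenstein–Hawking quantities, and the
   fitness-beats-truth ratio `(n-3)/(n-1)`.

## The worked Linda pipeline

The package's standard configuration is `theta = 60°`, `phi = 50°`,
contextual shifts `delta_theta = 5°`, `delta_phi = 2°`, influence
`eta = 0.01` with squared overlap `0.5`:

```{r}
worked_examples()
```

Reading the table: the single event is judged at `cos^2(60°) = 0.25`
while the conjunction reaches `cos^2(10°) ≈ 0.9698` — the fallacy. The
contextual shift moves the effective angle difference to
`10 + (5 - 2) = 13°`, so the perturbed conjunction probability is
`cos^2(13°) ≈ 0.949`; the single event falls faster (to
`cos^2(65°) ≈ 0.18`), so the fallacy is *reinforced* in relative terms.
The conscious factor `g = 1 + 0.01 × 0.5 = 1.005` then multiplies the
perturbed value to give the combined probability. At full precision the
product is `0.9494 × 1.005 = 0.95414`; rounding the intermediate first
(`0.949 × 1.005`) gives `0.9537`. Both are exposed; the table reports
full precision.

### Degrees vs radians

Worked scenarios are quoted in degrees, so `angle_model()` and
`perturbation_params()` accept a `unit = "degrees"` flag, but the
internal unit is radians throughout: the first-order term
`sin(2*Delta) * (delta_theta - delta_phi)` is only dimensionally
meaningful with the shifts in radians, and the worked numbers (0.949
exact vs 0.952 first-order) confirm that convention.

### First-order validity

`first_order_conjunction_shift()` truncates at `O(delta^2)`: halving the
shift shrinks the error against the exact oracle
`exact_perturbed_conjunction()` by a factor of ~4 (verified over a grid
of `Delta` values away from `Delta = 45°`, where the leading quadratic
coefficient `cos(2*Delta)` vanishes and the next order dominates).

### Raw vs renormalized modified probabilities

`modified_probability()` reports the raw product `P * g`, matching the
model's printed arithmetic even though a factor applied uniformly to a
full outcome set makes the raw values sum to more than 1. When the full
outcome distribution is supplied, a companion renormalized distribution
(divide by `sum(p_i g_i)`) is returned next to the raw one; raw products
above 1 are clipped with a warning. The expansion form of
`combined_conjunction_probability()` keeps the `O(eta)` and `O(delta)`
terms and drops `O(eta*delta)` cross-terms; product and expansion agree
to that order.

## The collapse engine

For the three-state Linda system `(F, F&BT, BT)` the generator is
diagonal: alignment couplings `lam` on the real axis, decay rates
`gamma` on the imaginary axis, so each branch amplitude evolves as
`a_i(t) = a_i(0) exp((-1i*lam_i - gamma_i) t)` (hbar = 1). The
conjunction is not an independent degree of freedom but the balanced
superposition of its branches, `a2 = (a1 + a3)/sqrt(2)`, so its
probability carries the interference cross term
`2 Re(a1(0) Conj(a3(0)) exp((-1i*dlam - dgam) t))`. The incongruent
branch's probability is defined by subtraction,
`P(BT) = |a3|^2 - P(F&BT)`, which can go negative; the engine returns
that raw algebra untouched in `raw_p` and a clamped, renormalized
distribution in `reported_p`.

Two independent evolution routes are maintained: the analytic closed
form above, and a general matrix-exponential engine (`evolve()`) built
on a complex scaling-and-squaring Padé exponential (`expm_c()`),
computed per time point — dimensions here never exceed 12, so no
Trotterization or sparsity is warranted. The two routes agree to 1e-10
on diagonal systems, and `evolve()` conserves norm to 1e-9 for Hermitian
generators.

### Default scenario parameters

The underlying model constrains only *orderings*: the congruent branch
(`F`, or cooperation `A`) has the strongest alignment and slowest decay,
the incongruent branch (`BT`, defection `B`) the weakest alignment and
fastest decay. Magnitudes are the package's choice, fixed once:

* `lam = (1.0, 0.6, 0.3)` — order-one salience splittings in units of
  inverse time; only differences enter the interference phase.
* `gamma = (0.05, 0.15, 0.4)` (Linda) and `(0.1, 0.2, 0.5)` (PD) — decay
  separated by factors of ~3, so branch distinctions resolve on a time
  scale of a few units without any branch dying instantly.
* Initial amplitudes `(1, 0, 1)/sqrt(2)` — equal weight on the two real
  branches, none on the derived conjunction slot.
* Evaluation time: "after sufficient time" is unquantified in the model,
  so `t_eval` defaults to the grid time maximizing the separation of the
  top two reported probabilities (configurable); on the default grid
  (`t_max = 6`, 121 steps) that lands at `t = 4`, where the ranking
  `P(F) > P(F&BT) > P(BT)` is stable. Ties are broken lexicographically
  by label and flagged explicitly.

For the prisoner's dilemma the three *conditions* are separate dynamical
regimes sharing one initial state: unknown opponent keeps both branches
and the interference boost, `P(A_unknown) = |a1|^2 + P(A&B)`; known
cooperation collapses to the `|A>` branch alone (`P = |a1|^2`, no
interference); known defection additionally accelerates the cooperation
amplitude's decay (`gamma_defect = 0.8` replacing `0.1`), the
collapse-dynamics reading of "rationally choose defection". The
sure-thing flag is `P(A_unknown) > max(P(A_cooperate), P(A_defect))`.
Because the three conditions are different dynamics, their probabilities
are *not* renormalized against each other, and the unknown-condition
value can exceed 1 at early times — it is the model's raw
interference-boosted quantity, reported as such.

## The contextual/QBist layer

A context is a CPTP channel acting before the Born rule:
`P(a_i | C) = Tr(E_C(rho) Pi_i)`. Under the identity channel the
implementation reuses the exact same trace arithmetic as
`born_probability()`, so the reduction is bit-identical, not merely
within tolerance. Measurement-and-update follows the instrument rule
`rho -> M rho M^dag / Tr(rho M^dag M)`; a zero-probability outcome
raises an explicit zero-support error. `collapse_instrument()` absorbs
the non-unitary collapse propagator into measurement operators
`M_i = Pi_i exp(-1i (H - 1i Gamma) t)`, making the asserted equivalence
between the collapse engine and the instrument picture a *testable*
identity: `Tr(rho M_i^dag M_i)` equals the engine's `|a_i(t)|^2` exactly
(to 1e-10 in the suite). The mixture update
`q(j) = ((d+1)/d) sum_i p(i) r(j|i)` is implemented literally as the
model states it, alongside a normalized variant; the literal form is not
a distribution (its factor exceeds 1) and no corrected form is guessed.

## Two-path shift sessions

`run_two_path_shift()` emulates a two-outcome focused-intent experiment:
the focused path's probability is shifted to
`p = baseline (1 + eta * overlap^2)` and `n` seeded Bernoulli trials are
drawn at that probability (defaults: baseline 0.5, `eta = 0.01`,
overlap² 0.5, `n = 10^6`). The generator emulates *only* the shifted
i.i.d. Bernoulli statistics — no drift, no session structure, no human
variability — so a passing binomial-bound test shows the simulator and
the analytic shift are consistent with each other, and nothing about
empirical claims regarding human participants, which are far outside
desk scale.

## Numerical choices

* Tolerances are centralized (`qcog_tol`): 1e-10 structural (Hermiticity,
  idempotence, normalization), 1e-8 probabilistic (completeness,
  distribution sums). All predicates take an explicit `tol`.
* The perturbation quadrature uses adaptive `stats::integrate` on real
  and imaginary parts with absolute tolerance 1e-10, on the
  interaction-picture matrix element evaluated in the Hamiltonian's
  eigenbasis.
* `hbar = 1` throughout the dynamics; all couplings and rates are in
  inverse time. SI constants enter only the thermodynamics calculators,
  where they are injectable (e.g. `k_B = 1`) for transparent testing.
* Degenerate inputs fail loudly with classed conditions: all-zero
  amplitude vectors, non-PSD decay operators, non-projector outcome
  operators, zero-support measurement updates, incomplete projector
  sets.
* Problem sizes: property suites run on dimensions 2–5 with 10–100
  seeded fixtures per invariant, and session simulations at `n = 10^6`
  trials; these sizes resolve every tested effect comfortably while
  keeping the full suite in seconds.

## Known limitations

* The angle parameters are not fitted to empirical data; the frequently
  cited ~15%/~85% Linda rates ship only as reference constants
  (`linda_empirical_anchors()`).
* The collapse engine is amplitude-level (non-Hermitian Schrödinger
  dynamics), not a Lindblad master equation; decoherence proper is out
  of scope.
* Second-order perturbation theory and time-dependent `eta` are not
  implemented.
* The observer-driven amplification of branch amplitudes is represented
  by the multiplicative `g` factor; applying an observer-space operator
  directly to system amplitudes is dimensionally ill-posed and is not
  attempted.
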