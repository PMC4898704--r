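---
title: "Passive titin forces under length ramps: model, solvers and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive titin forces under length ramps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The model

`titinsim` computes the passive force contributed by titin strands in a
half sarcomere whose length `l(t)` is imposed (a length-ramp experiment,
the opposite of a force clamp). Strands act in parallel and independently,
so the half-sarcomere force is the number of strands times the expectation
of a single-strand force — and the single strand is where all the physics
sits.

## Strand mechanics

A strand is five mechanical elements in series, all carrying the same
tension `F` at equilibrium:

| element | model | parameters (defaults) |
|---|---|---|
| PEVK segment | modified WLC | `pl` = 0.6 nm, contour = 800 × 0.36 nm, `F0` = 150 pN |
| folded proximal Ig chain | WLC | `pl` = 0.85 nm, contour = `n_folded` × 4.5 nm |
| unfolded proximal Ig chain | WLC | `pl` = 0.85 nm, contour = `n_unfolded` × 25 nm (`d_u`) |
| end-filament (distal Ig) | linear spring | `k_end` = 2 N/m |
| A-band + slack | linear spring + slack | `k_rest` = 2 N/m, slack 0.9 µm |

The WLC interpolation formula and its modified (stretch-modulus) variant
are implemented in `wlc_force()` and `modified_wlc_force()`. The imposed
length is distributed over the elements by requiring equal tension — the
first-order condition of the underlying convex energy minimisation, which
we solve by a monotone scalar root-find on `F` (`solve_strand()`) rather
than by a generic convex-programming solver: the objective is a sum of
one-dimensional convex element potentials, so force balance is equivalent
and numerically far more robust. Below the slack configuration the force is
exactly zero.

Two interpretation choices deserve explicit notice:

* **Per-unit contour lengths.** The literature parameter set quotes
  sub-nanometre "contour lengths" for the PEVK residue (0.36 nm) and the
  Ig unit (0.45 nm). A whole-chain reading is untenable (a 22.5 nm folded
  chain cannot span the I-band), so we interpret them per residue / per
  domain, and take the folded Ig per-domain contour as 4.5 nm — the folded
  domain size scale — while each unfolding adds `d_u` = 25 nm. Both are
  `mechanical_params()` arguments, so any other convention is one keyword
  away.
* **Slack.** The A-band/slack spring absorbs a configurable slack length at
  zero force; the 0.9 µm default puts force onset near a 1 µm
  half-sarcomere length, where ramp experiments start.
* **Temperature** defaults to 300 K (not part of the literature set) and is
  configurable everywhere.

`build_force_curves()` tabulates `F_i(l)` for every possible number of
unfolded domains `i = 0…N` on a 1 nm grid (linear interpolation between
nodes). For the default rabbit psoas isoform — 50 proximal Ig domains, 800
PEVK residues, 26 distal Ig domains — that is 51 curves. This family is
computed once per model and shared verbatim by both solvers, so any
MC-vs-exact comparison cannot be contaminated by mechanical discretization
differences.

## Unfolding and refolding kinetics

Domains unfold thermally with the Bell rate
`u(F) = ω0 · exp(F·x_u / kB·T)` and refold with
`r(F) = ω1 · exp(−F·x_f / kB·T)`, with barrier widths `x_u` = 0.25 nm and
`x_f` = 2.2 nm from the literature parameter set. Domains are grouped into
`m` stability clusters with distinct spontaneous rates `ω0` (ordered so
that `u_1 ≤ … ≤ u_m` at every force); clusters may instead differ in
`x_u`, which the constructor also accepts.

The zero-force rate constants `ω0`, `ω1` are **not** experimentally pinned
down for this model. The package defaults — five clusters of ten domains
with `ω0` spaced geometrically from 1e-5 to 1e-3 s⁻¹, `ω1` = 1 s⁻¹ — are
placeholders calibrated only so that unfolding happens within a 1 → 2 µm
ramp at 1 µm/s. Consequences: all force scales of simulated unfolding
events depend on these choices, and published Monte Carlo error values for
a comparable model cannot be reproduced at face value; what is invariant
(and what the test suite asserts) is the ordering and the `1/√R`
scaling of the Monte Carlo error, and the agreement between the two
solvers under identical rates.

The exponent of the unfolding rate is capped at 700 before exponentiation.
Beyond that point rates are astronomically beyond any dynamically
distinguishable scale, and the cap keeps every product appearing in the
solvers inside double-precision range.

# The Monte Carlo solver

`simulate_ensemble()` advances each strand on a fixed grid (`dt` = 1 ms by
default): per step one uniform draw `z` is compared against the cumulative
intervals of the per-cluster event probabilities
`(n_k − i_k)·u_k(F)·dt` (and `i_k·r(F)·dt` with refolding), so at most one
event fires per step. This reproduces the classical fixed-step scheme for
this problem, in preference to a Gillespie-type exact simulation, because
the forcing `l(t)` makes rates explicitly time-dependent and the fixed grid
is what the master-equation solver discretizes too. Rates are evaluated at
the start-of-step force without refolding and at the end-of-step force with
refolding, matching the respective update rules as usually stated;
`rate_timing` makes either convention uniform if wanted.

**Step-probability guard.** The single-event scheme is valid while the
total per-step event probability is small. Under ramps, however, any strand
that is driven up the steep (near-saturation) part of its current force
curve passes through a short burst in which the Bell factor explodes and
the total step probability approaches 1 before the (then certain) unfolding
relieves the force. This is intrinsic to the protocol, not a sign of a
wrong step size: at `dt` = 1 ms roughly one strand in ten briefly exceeds a
total probability of 0.1 near its first unfolding. A hard error at such a
threshold would make the canonical protocols unrunnable, so the guard
threshold defaults to 1 — the point where the scheme genuinely loses its
probabilistic interpretation — and exceedances are *counted* and reported
(`on_overrun = "warn"` by default, `"error"` available, the count always in
`$overrun_steps`). For ensemble means the effect of these saturated steps
is negligible (the strand unfolds one step later than it should, shifting
its force by ~`dF/dt · dt`).

The whole ensemble is driven by one seeded RNG stream with draws in
step-major order, so `seed` fixes the result bit-for-bit. `mce()`
implements the across-repeat error estimator
`MCE(R)² = ‖⟨F_h²⟩ − ⟨F_h⟩²‖∞` over `H` repeats (population variance, as
the estimator is usually written), and `first_unfolding_forces()` extracts
the per-strand first-event forces for comparison with the exact density.

# The exact solver

The state of a strand is the per-cluster unfolded count `(i_1, …, i_m)`;
the probabilities `p_{i_1…i_m}(t)` obey a linear master equation with
outflow `Σ_k (n_k − i_k)·u_k(F_L(t))` (`L` = total unfolded) and inflow
from each predecessor `(n_k − i_k + 1)·u_k(F_{L−1}(t))`. Two notational
slips in the usual statement of these equations are corrected here, and
flagged rather than silently assumed: the inflow term for the `k`-th
cluster uses that cluster's own rate function (not the first cluster's),
and the refolding inflow from a state with `i + 1` unfolded domains
carries the coefficient `i + 1` (the number of domains able to refold
there) — the alternatives violate probability conservation, which our
generator satisfies to machine precision (column sums of
`generator_matrix()` are zero).

`solve_master()` integrates with implicit Euler,
`(I − dt·A(t_{j+1}))·p_{j+1} = p_j`, the standard stiffness-proof choice
here: rates span many orders of magnitude along a ramp, and the implicit
step is unconditionally stable, exactly conservative (the system matrix
has unit column sums) and positivity-preserving (it is an M-matrix).
Renormalization is applied only if the probability sum drifts beyond
1e-12, and counted; in practice it never triggers.

The crucial structural observation: **without refolding the state graph is
a DAG** — transitions only increase the total unfolded count. Ordering
states by that count makes `I − dt·A` block-triangular, so the implicit
step is solved *exactly* by forward substitution level-by-level: divide the
level-0 states by their diagonal, propagate their (already final) values
into level 1, and so on. No factorization, no matrix at all — just indexed
vector operations over a precomputed transition table. The default
5-clusters-of-10 model has `11⁵ = 161051` states and integrates a 1000-step
ramp in tens of seconds in pure R. Aggregation to `P_0…P_N`
(`aggregate_states()`) and the expectation
`E(F(t)) = Σ_l P_l(t)·F_l(t)` (`expected_force()`, optionally scaled by a
strand count per half sarcomere) follow directly.

With refolding the graph has cycles, so `solve_master_refolding()`
assembles the generator densely and solves each implicit step with
partial-pivoting LU. This is intended for modest state spaces — the
single-cluster model (51 states, tridiagonal generator) used for
hysteresis studies is the canonical case — and deliberately refuses large
multi-cluster refolding spaces, where Monte Carlo is the appropriate tool.
Its `init` argument admits non-standard initial conditions (e.g. fully
unfolded, for pure-refolding checks); both solvers default to the
experimentally standard all-folded start.

**Time-discretization error and extrapolation.** Implicit Euler is
first-order. For cross-validation against closed forms at tolerances far
below the step-size error, `solve_master(extrapolate = TRUE)` runs `dt`
and `dt/2` and combines them (Richardson), removing the `O(dt)` term; the
test suite stacks a second level where it compares against
matrix-exponential oracles at 1e-6 relative accuracy. First-order
convergence itself is asserted separately by step-halving.

`first_unfolding_distribution()` computes the density of the force at the
first unfolding event in closed form: hazard `Σ_k n_k·u_k(F_0(t))` times
the survival `P_0(t)` (obtained by quadrature of the survival integral),
mapped through the monotone `F_0(l(t))`; when a protocol makes `F_0`
non-monotone the density is reported over time instead. The no-event mass
`P_0(T)` is always reported rather than silently renormalized away.

# Protocols and canonical experiments

`length_protocol()` objects are piecewise-linear breakpoints;
`make_ramp()`, `make_rest()`, `make_cycles()` and `protocol_join()` build
the canonical experiments exposed by `canonical_protocol()`:

* `ramp_1to2` — 1 → 2 µm at 1 µm/s. Ramp speeds are nowhere stated for the
  motivating experiments; 1 µm/s is the package-wide default and every
  fixture carries its speed explicitly.
* `hysteresis_rest` — two 1 → 1.7 → 1 µm stretch–shortening cycles, 30 s
  rest, a third cycle; run with the single-cluster refolding model. The
  expected signature (asserted in the tests): hysteresis area collapses in
  cycle 2 and recovers in cycle 3, because refolding is strongly
  force-suppressed (`x_f` = 2.2 nm) and only proceeds during the rest.
  Because simulations start all-folded, no later cycle can exceed the
  first — single-molecule observations of third-cycle hysteresis *above*
  the first are outside this model's reach, a known limitation.
* `repeated_cycles` — lead-in ramp to 1.85 µm (half of a 3.7 µm average
  sarcomere length), then ten 0.25 µm triangle cycles. Reported cycle
  amplitudes for the motivating myofibril experiment are contradictory
  (±2.5 µm in one place, 0.25 µm in another; the former is geometrically
  impossible at that sarcomere length), so the fixture uses 0.25 µm on the
  half-sarcomere trace. The expected signature: peak force declines from
  cycle to cycle as unfolding accumulates faster than refolding recovers.

`analyze_cycles()` splits any force trace at the protocol's rising-edge
breakpoints (cycle `i` owns the half-open window up to the next start),
takes the peak over the loading phase, and integrates the loading-minus-
unloading loop area by the trapezoidal rule.

The cluster-granularity comparison (`cluster_comparison_models()`) builds
a 50-cluster model — one cluster per domain, rates declining linearly with
Gaussian noise of SD 0.2 applied on the log10 ordinate (the noise scale is
a documented choice; `noise_scale = "linear"` is available) — against 5
equidistant clusters over the same rate envelope. Ensemble forces from the
two differ by a few percent of peak force at `R` = 50, supporting the use
of few-cluster models for ensemble quantities (they remain consequential
for event-level quantities and for any parameter estimation).

# What the simulations do and do not emulate

The generator's defaults *are* the study conditions: rabbit psoas isoform,
the mechanical parameter set above, 5×10 clusters with placeholder rate
constants, 1 µm/s ramps, `dt` = 1 ms, `R` = 200 strands (the usual
accuracy/time compromise, at which the ensemble mean tracks the exact
expectation within ~2 pN over the full ramp). Passing tests therefore
demonstrate internal consistency of the two solvers and the qualitative
experimental signatures (saw-tooth single strands, smooth ensembles,
hysteresis recovery, peak-force decline) — not quantitative agreement with
any particular wet experiment. Deliberately out of scope: sarcomere
non-uniformity and the half-sarcomere-to-myofibril scaling, titin–actin
binding upon activation, intermediate (molten-globule) unfolding states,
force-clamp order statistics, and any parameter estimation.

# Numerical choices, in one place

* WLC inversion: 60 bracketed bisection steps on the dimensionless
  extension in `[0, 1 − 1e-12]` plus 3 clamped Newton polishes (machine
  precision); strand force balance: safeguarded Newton inside a rigorous
  bracket `[0, k_eff·(l − slack)]`, length residual tolerance `1e-14·l`.
* Modified WLC given extension: bracketed bisection on the equivalent
  monotone problem, residual checked to `1e-12` relative.
* Force curves: 1 nm grid, linear interpolation, exact at nodes.
* Master equation: fully implicit (generator at the step's end time);
  negative probabilities below −1e-10 abort with advice to reduce `dt`.
* Monte Carlo: step-major single RNG stream; guard threshold 1 with
  warn/error/ignore handling; events recorded with the force used for
  their hazard.
* Degenerate inputs: zero-contour elements have zero extension; `l` below
  slack gives exactly zero force; empty first-unfolding samples return a
  zero-length result with the exclusion count; zero IQR falls back to
  square-root binning in `freedman_diaconis_bins()` (IQR uses
  empirical-CDF quantiles with averaging, R type 2).

Problem sizes used by the test suite (chosen to exercise every code path
at desk scale): toy isoforms of 5–6 domains for oracle equivalence (dense
matrix exponentials, survival quadratures, 10⁴-strand histograms), the
full 161051-state model for the ramp cross-validation at `R` = 200 and
3 seeds, `H` = 50 repeats over `R` ∈ {10…500} on a shortened ramp for the
error-scaling law, and the 51-state refolding model for the hysteresis
protocol.
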