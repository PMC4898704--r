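# titinsim

Passive forces in relaxed sarcomeres are carried almost entirely by titin,
the giant protein whose I-band region acts as a serial molecular spring.
When a half sarcomere is stretched, the proximal immunoglobulin (Ig)
domains of each titin strand unfold stochastically in a force- and
time-dependent manner; in single-molecule experiments this produces the
classic saw-tooth force trace, while in a half sarcomere — with more than a
thousand strands in parallel — only the smooth ensemble average survives.
`titinsim` is for muscle biophysicists and modellers who need that average
(and the full distribution behind it) under prescribed length-ramp
protocols: ramps, stretch–shortening cycles, rest periods.

The package provides two routes to the same quantity and uses each to check
the other:

* **Monte Carlo** — simulate `R` independent strands with a fixed-step,
  single-event update rule and average their forces;
* **Exact** — integrate the linear master equation for the probabilities of
  all unfolding states and form the expectation directly.

## Model

A titin strand spanning a half sarcomere of length `l` is a series chain of

* the PEVK segment: a modified worm-like chain with stretch modulus `F0`,
  `F = (kB·T/pl)·(¼(1 − x/cl + F/F0)⁻² − ¼ + x/cl − F/F0)`;
* the folded and unfolded proximal Ig sub-chains: worm-like chains,
  `F = (kB·T/pl)·(¼(1 − x/cl)⁻² − ¼ + x/cl)`, the unfolded chain gaining
  `d_u = 25 nm` of contour length per unfolded domain;
* the distal-Ig end-filament and the A-band/slack portion: stiff linear
  springs.

Solving the series equilibrium for every possible number of unfolded
domains `i = 0…N` gives the force-curve family `F_i(l)` — for the rabbit
psoas isoform (N = 50 proximal Ig domains) a discrete random variable with
51 states. Domains unfold with the Bell rate `u(F) = ω0·exp(F·x_u/kB·T)`
and refold with `r(F) = ω1·exp(−F·x_f/kB·T)`; domains are grouped into
stability clusters with distinct `ω0`, encoding hierarchical mechanical
stability. The state of a strand is the per-cluster unfolded count
`(i_1, …, i_m)`, and the ensemble obeys a linear master equation whose
expectation `E(F(t)) = Σ_l P_l(t)·F_l(t)` is the per-strand passive force
of the half sarcomere.

Without refolding the state graph is acyclic, so the implicit-Euler step of
the master equation is solved exactly by forward substitution level-by-level
in the total unfolded count — the full 161051-state space of the default
5-cluster model integrates in well under a minute without assembling any
matrix.

## Worked example

A 1 → 2 µm half-sarcomere ramp at 1 µm/s with a single stability cluster
(50 domains, ω0 = 1e-4 s⁻¹):

```r
library(titinsim)
mod  <- titin_model(clusters = cluster_model(n = 50, omega0 = 1e-4),
                    length_grid = seq(1e-6, 2e-6, by = 1e-9))
prot <- make_ramp(1e-6, 2e-6, 1e-6)
sol  <- solve_master(prot, mod, dt = 1e-3)        # exact probabilities
ens  <- simulate_ensemble(prot, R = 200, mod, dt = 1e-3, seed = 1)
max(abs(ens$mean_force - sol$expected_force)) * 1e12
```

which prints (among others):

```
Master-equation solution: 51 aggregated states, 1001 time points, dt = 0.001 s
  E(F) range [1.86, 158] pN; renormalizations: 0
Monte Carlo ensemble: R = 200 strands, 1001 time points, seed 1
  mean force range [1.86, 158] pN; 3579 unfolding events logged
max |MC - exact| = 1.21 pN

  length_um exact_pN mc_pN P_still_folded
1      1.50     81.9  81.9          0.967
2      1.75    151.7 152.1          0.000
3      2.00    157.8 157.9          0.000
```

Reading: at 1.5 µm the strand is still almost surely fully folded and both
methods sit on the all-folded curve (81.9 pN); by 1.75 µm unfolding is
essentially certain, the expected force flattens as unfolding releases
contour length, and the 200-strand Monte Carlo mean tracks the exact
expectation to within ~1 pN everywhere. The per-strand forces at the first
unfolding event are available via `first_unfolding_forces(ens)` (here 200
events, median 139 pN; histogram bin edges from `freedman_diaconis_bins()`)
and their exact density via `first_unfolding_distribution()`.

Hysteresis experiments use the refolding solver:

```r
mod1 <- titin_model(clusters = cluster_model(n = 50, omega0 = 1e-4,
                      refolding = list(omega1 = 1, x_f = 2.2e-9)),
                    length_grid = seq(1e-6, 2e-6, by = 1e-9))
prot <- canonical_protocol("hysteresis_rest")  # 2 cycles, 30 s rest, 1 cycle
analyze_cycles(solve_master_refolding(prot, mod1, dt = 1e-3), prot)
#  cycle peak_pN area_aJ
#      1   148.4   8.903
#      2   134.4   2.603
#      3   148.4   8.873
```

— the hysteresis collapses on the immediate repeat cycle and recovers
after the 30 s rest through refolding.

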