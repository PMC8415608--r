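---
title: "Evolving phase-separating disordered sequences: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving phase-separating disordered sequences: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpevolve)
```

## The problem

Many intrinsically disordered protein regions (IDRs) — the FUS prion-like
domain, the hnRNPA1 low-complexity region, the LAF-1 RGG domain — demix from
solution into a protein-rich liquid and a dilute phase (liquid–liquid phase
separation, LLPS). `idpevolve` couples a residue-resolution coarse-grained
model of such IDRs to a genetic algorithm so that sequences can be evolved
toward stronger or weaker phase separation, and provides the sequence-space
diagnostics used to interpret what the evolution did.

## The energy model

Each residue is one bead. Bonded neighbours interact through a harmonic
spring `U = k_b (r - r_0)^2`. All non-bonded pairs (excluding directly
bonded neighbours) interact through

* a hydrophobicity-scaled short-range potential of Ashbaugh–Hatch form:
  below the Lennard-Jones minimum `2^(1/6) sigma_ij` the full 12-6 potential
  shifted up by `(1 - lambda_ij) eps`; above it, the 12-6 potential scaled
  by `lambda_ij`. `lambda_ij` and `sigma_ij` are arithmetic means of
  per-residue values; `lambda` is a normalised hydrophobicity scale
  (glycine sits at 0.64865) and `sigma` a residue contact diameter;
* a Debye–Hückel screened Coulomb term
  `U = 332.06371 q_i q_j exp(-r/kappa) / (eps_r r)` between formal charges
  (Asp/Glu −1, Lys/Arg +1, His neutral by default).

The KH variant replaces the single well depth by a pair-energy matrix
`e_ij`, mapped onto the same Ashbaugh–Hatch kernel via
`eps_ij = |alpha (e_ij - e0)|` with `lambda_ij = +1` (attractive) or `-1`
(repulsive). Because the KH map only produces binary `lambda`, exact
HPS/KH agreement is possible (and is tested) where the effective HPS
`lambda` is 1.

Defaults live in `inst/extdata/hps_globals.yaml`, not in code: well depth
`eps = 0.2` kcal/mol, screening length 10 Å, relative dielectric 80, bond
constant 2.39006 kcal mol⁻¹ Å⁻² with `r_0 = 3.8` Å, cutoffs 20 Å
(short-range) and 35 Å (electrostatic). The short-range potential is
shifted to zero at its cutoff so Langevin runs do not accumulate truncation
drift; the screened Coulomb term is likewise shifted. Units throughout:
kcal/mol, Å, amu, fs, K.

`sigma` is recorded in the table schema as the *pair-potential contact
diameter*; any table transcribed from sources that quote a van der Waals
radius must be converted before use — the schema field
`sigma_convention` documents the choice.

## Direct coexistence and the binodal

Phase behaviour is measured in slab geometry: an elongated periodic box
(`L_z >= L_x = L_y`) with a dense protein slab in the middle and vapour
above and below. `build_slab()` packs chains as compact serpentine coils on
a jittered grid at a target starting density (0.5 g/cm³ by default, in the
massless-implicit-solvent convention used for all densities here);
`run_langevin()` integrates NVT dynamics with a BAOAB splitting, which
samples configurations accurately at practical timesteps (default 10 fs,
friction 1 ps⁻¹; friction 0 gives the velocity-Verlet limit used for
energy-conservation tests). A single integer seed determines the whole
stochastic stream, so runs are bit-reproducible.

`density_profile()` recentres the dense phase each frame (periodic centre
of mass mapped to the box middle) and averages the mass density in 25 z
bins. `fit_coexistence()` fits two plateaus joined by symmetric
hyperbolic-tangent interfaces; when the plateau contrast
`(rho_l - rho_v)/(rho_l + rho_v)` falls below 0.25 the state is flagged
single-phase (`converged = FALSE`) instead of erroring — near and above the
critical temperature this is the expected outcome, and the genetic
algorithm treats it as vanishing phase-diagram width.

`build_binodal()` fits the order-parameter scaling law
`rho_l - rho_v = A (1 - T/T_c)^beta` together with the law of rectilinear
diameters `(rho_l + rho_v)/2 = rho_c + B (T_c - T)`. The exponent is fixed
at the 3D-Ising value `beta = 0.325`: fitting it on small systems is
unstable, and it is exposed as an argument for anyone who disagrees.
Unconverged points and points at or above the fitted `T_c` are excluded
(and reported via the `included` flag); points within a small margin below
`T_c` are down-weighted because interfacial broadening makes them hard to
equilibrate. Predicted vapour densities are clipped at zero.

## The genetic algorithm

A chromosome is the amino-acid string itself. The fitness of a candidate
is the width of its phase diagram at a fixed sub-critical temperature,
relative to the wild type:

```
f(x) = (rho_l(x) - rho_v(x)) / (rho_l(WT) - rho_v(WT))
```

with the reciprocal used when evolution should *narrow* the phase diagram.
Width is a cheap, monotone proxy for the critical temperature: it needs one
direct-coexistence run instead of a whole phase diagram. Default
evaluation temperatures follow the reference campaigns: 200 K
(≈ 0.8 T_c of wild-type FUS) for FUS, 0.57 T_c^wt for hnRNPA1 and
0.85 T_c^wt for LAF-1.

Per round, with the published defaults `N = 20`, `N_par = 8`,
`N_tour = 5`, mutation rate 0.01: evaluate; select 8 parents as winners of
8 tournaments of 5 uniformly drawn members; pair the parents at random;
single-point crossover after a uniform `k in [1, n]`; re-mutate the
children at the same rate (a mutated position redraws uniformly from all
20 amino acids, so it keeps its residue with probability 1/20); evaluate
the children; insert them by weak-population replacement — each child in
turn replaces the current weakest member iff strictly fitter, ties broken
toward the lowest index so seeded runs are exactly reproducible. The
initial population is 20 mutated copies of the wild type; whether the
unmutated wild type itself is included is immaterial at rate 0.01 (many
initial members are identical to it by chance), and we do not force it in.

Randomness is organised as named substreams spawned from one master seed
(initial mutations, tournaments, pairing, crossover points, child
mutations), so fitness backends may consume any amount of randomness —
derived from the candidate sequence itself, never from a shared stream —
without perturbing the evolution trajectory. This is also what makes
fitness evaluations order-independent, the contract a master–worker
parallel evaluation needs.

`run_dummy_ga()` keeps every mutation and crossover step but randomises
parent choice and replacement targets. Its mean-fitness trajectory is
statistically flat, which is the control showing that fitness gains in
`run_ga()` come from selection pressure, not mutation drift.

Candidates whose coexistence fit finds no dense phase get fitness 0 with a
flag rather than an exception: a vanishing width is a legitimate (terrible)
fitness, and evolution should continue past such candidates.

## Sequence diagnostics

* `scd()` — sequence charge decoration,
  `Q_SCD = (1/N) * sum_{m>n} q_m q_n sqrt(m-n)`; exact double sum.
* `charge_stats()`, `hydropathy_stats()`, `population_map()` — composition,
  per-residue `lambda`/`sigma`/charge maps and population averages over
  equal-length sequences.
* `chunk_shuffle()` — swaps two length-`l` windows per step with periodic
  indexing so chain ends are not under-sampled; composition is invariant;
  the pairs-changed counter is `steps * l`. The hydrophobicity-biased
  variant restricts both windows to the top fraction (e.g. 30%) of all `n`
  periodic windows ranked by mean `lambda`, *re-ranked after each accepted
  swap* (a fixed initial ranking is the other defensible reading; we chose
  re-ranking because successive swaps change which regions are
  hydrophobic). Overlapping window pairs are redrawn — an exchange between
  overlapping windows is ill-defined — except at `l = n`, where all windows
  coincide as sets and the swap reduces to a well-defined cyclic rotation.
* `glycine_scan()` — successive non-overlapping chunks (default 6; a final
  shorter chunk is scanned as-is) are replaced by glycine, and each chunk's
  `delta_lambda = <lambda>_chunk - lambda(G)` is reported; the weighted
  chunk means reconstruct the sequence mean `lambda` exactly, which is
  asserted in the tests.
* `radial_distribution()` — g(r) over non-bonded bead pairs, normalised by
  shell volume and the common number density; bins of 0.5 Å by default,
  range capped at half the smallest box edge.
* `energy_decomposition()` — time-averaged Coulomb vs short-range pairwise
  energy per bead, the split that attributes an evolution run's gains to
  charge rearrangement or hydrophobicity.

## What the synthetic generators emulate

`make_synthetic_profile()` and `make_synthetic_binodal()` generate slab
profiles and coexistence points *exactly on* the fitted functional forms
with known parameters, plus Gaussian noise. They are ground-truth oracles
for the fitting machinery: recovery at zero noise must be exact to
tight tolerances, and recovery error must scale with the noise amplitude.
They do not emulate correlated bin noise, interface fluctuations,
finite-size interface interactions or drifting slabs, so passing these
tests validates the estimators, not the sampling quality of any particular
simulation. `make_random_sequence()` and `make_charge_pattern()` provide
composition-controlled and charge-patterned sequences (alternating E/K
blocks, whose |SCD| grows with block size) for the sequence metrics.

## Problem sizes and numerical choices

The shipped presets are desk-scale by design and state their sizes
explicitly: the test suite and the acceptance script use a 12-chain
20-residue homopolymer slab (two temperatures) for the
widening-on-cooling check, and 20 chains of the full 163-residue FUS PLD
at 200 K — about 3,300 beads for 60 ps, with the Langevin friction
lowered to 0.05 ps^-1 so the slab relaxes faster at fixed wall time — for
the directional width comparison against poly-F, averaging two
independent seeds per sequence. At this scale the slab has not reached its equilibrium
coexistence densities; the transient still orders sequences correctly by
cohesion, which is what a directional check needs, but absolute widths
are not converged observables. Reproducing the reference campaigns
(populations of 20 over 20 rounds, hundreds of chains per evaluation at
multiple temperatures, microsecond trajectories) is cluster-grade and out
of desk scope; the package's paper-scale presets are the same functions
with larger `n_chains`, `n_equil`, `n_prod`.

Numerical details worth knowing: the Verlet neighbour lists (3 Å skin,
displacement-triggered rebuilds) are split — a short-range list over all
beads and an electrostatic list over charged beads only, which is what
makes nearly-neutral IDRs like the FUS PLD cheap; forces above
10⁴ kcal/mol/Å abort the run with the offending step and bead; the
packing generator guarantees a minimum non-bonded bead separation of
`0.8 sigma_min` and errors out («density too high») when the requested
chain count cannot fit.

## Known limitations

* The force-field parameter values are transcribed from the published
  residue-level model; the package derives none of them.
* Mass densities are reported for protein in a massless implicit solvent;
  comparisons with experimental condensate densities need that convention.
* The KH map cannot reproduce intermediate HPS `lambda` values exactly
  (binary attractive/repulsive only) — a property of the published map,
  not of this implementation.
* Desk-scale direct coexistence under-equilibrates the vapour branch;
  vapour densities at these run lengths are lower bounds.
* RNA (poly-U) mixtures are mechanically supported (equal-length harmonic
  chains, user-supplied bead parameters); no RNA parameters ship with the
  package, so mixed-system energetics are entirely the user's table.
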