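# idpevolve

Design and analysis of liquid–liquid phase separation (LLPS) in
intrinsically disordered protein regions (IDRs), for computational
biophysicists who want to *steer* phase behaviour by mutating sequences
rather than just measure it.

The package implements, end to end:

* a **residue-level coarse-grained model**: one bead per residue, harmonic
  bonds (`U = k_b (r − r_0)²`), a hydrophobicity-scaled Ashbaugh–Hatch
  short-range potential (per-residue scale λ, contact diameter σ; pair
  values are arithmetic means; KH pair-energy matrices supported) and
  Debye–Hückel screened electrostatics
  `U = 332.064 q_i q_j e^{−r/κ} / (ε_r r)`;
* a **Langevin dynamics engine** (BAOAB splitting, Rcpp core, seeded and
  bit-reproducible) for periodic slab direct-coexistence simulations;
* **phase analysis**: recentred 25-bin slab density profiles, two-plateau
  tanh interface fits for the coexisting densities ρ_v and ρ_l, and binodal
  fits combining the order-parameter scaling law
  ρ_l − ρ_v = A(1 − T/T_c)^β (β = 0.325) with the law of rectilinear
  diameters to estimate the critical point (T_c, ρ_c);
* a **genetic algorithm** over amino-acid sequences whose fitness is the
  phase-diagram width at fixed temperature relative to the wild type,
  f(x) = (ρ_l(x) − ρ_v(x)) / (ρ_l(WT) − ρ_v(WT)) — tournament selection
  (N = 20, 8 parents, tournaments of 5), single-point crossover, 0.01
  mutation rate, weak-population replacement, plus a selection-free dummy
  control;
* **sequence diagnostics**: sequence charge decoration
  Q_SCD = (1/N) Σ_{m>n} q_m q_n √(m−n), charge/hydropathy statistics and
  population maps, periodic chunk shuffling (plain and
  hydrophobicity-biased), glycine scanning, pair correlation functions and
  Coulomb-vs-hydrophobic energy decompositions.

Wild-type fixtures ship with the package: the FUS prion-like domain
(163 aa), the hnRNPA1 IDR (first 135 residues) and the LAF-1 RGG domain
(168 aa), together with the default residue parameter table (λ(G) = 0.649).

## Worked example

A toy homopolymer slab, its coexisting densities, and a two-temperature
width comparison:

```r
library(idpevolve)

tab <- default_param_table()
tab$globals$lj_cutoff <- 12        # short cutoffs for a small neutral toy
tab$globals$coul_cutoff <- 12

spec <- system_spec(strrep("A", 20), n_chains = 12, box = c(42, 42, 168),
                    temperature = 250, n_equil = 3000, n_prod = 5000,
                    sample_interval = 100, seed = 11, table = tab)
traj <- run_langevin(build_slab(spec, tab), spec, tab)
fit_coexistence(density_profile(traj, table = tab))
#> # A tibble: 1 × 6
#>   temperature  rho_v rho_l    se_v    se_l converged
#>         <dbl>  <dbl> <dbl>   <dbl>   <dbl> <lgl>
#> 1         250     0 0.266 0.00572 0.00834 TRUE
```

At 250 K the alanine homopolymer slab holds a dense phase near
0.27 g/cm³ (protein mass in a massless implicit solvent) against an
essentially empty vapour; rerunning at 450 K gives a denser vapour and a
thinner liquid (ρ_l ≈ 0.25), i.e. the binodal narrows on heating, and
`build_binodal()` on a set of such points locates T_c.

Driving a sequence with the genetic algorithm (surrogate backend shown;
`backend_md_width()` is the production MD-in-the-loop backend):

```r
fus <- wt_sequence("fus_pld")
h <- run_ga(fus, ga_config(rounds = 20, seed = 3),
            backend_surrogate_lambda())
glance(h)
#> # A tibble: 1 × 7
#>   rounds n_pop initial_mean_fitness final_mean_fitness final_max_fitness
#> 1     20    20                 1.00               1.07              1.08
#> # final_diversity 17, coverage 0.804
```

Mean fitness rises ~7% in 20 rounds under the (weak, deterministic)
mean-hydrophobicity surrogate while diversity stays high; the dummy
control `run_dummy_ga()` stays flat. `autoplot(h)` shows the progression,
`tidy(h)` the full per-round sequence listing, and
`scd()`, `glycine_scan()`, `chunk_shuffle()`, `energy_decomposition()`
dissect what changed.

## Command line

A thin CLI over the same functions lives at `inst/cli/idpevolve.R`:

```sh
Rscript inst/cli/idpevolve.R simulate --config run.yaml --out traj/
Rscript inst/cli/idpevolve.R evolve --wt fus.fasta --rounds 20 --out rundir/
Rscript inst/cli/idpevolve.R scan --mode glycine --seq fus.fasta --out scan.tsv
```
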