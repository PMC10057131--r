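# chiralpmf

Umbrella-sampling free-energy analysis for the chiral-selective
aminoacylation of an RNA minihelix.

## The problem

A D-ribose RNA minihelix aminoacylates L-amino acids about four times faster
than D-amino acids, without any enzyme — a candidate origin for protein
homochirality. The kinetics are set by the free-energy profile (potential of
mean force, PMF) of the transfer reaction along the reaction coordinate

```
RC = d(H3'...O3') - d(Ccarb...O3')   [Å]
```

the difference between the 3'-hydroxyl O–H distance and the distance from
the attacking 3'-oxygen to the carbonyl carbon of the acyl phosphate.
Umbrella sampling places harmonic restraints w_i(ξ) = ½k(ξ − ξ0)² along RC
(101 windows from −4.0 to 3.0 Å, k = 500 kcal/mol/Å²) and the weighted
histogram analysis method (WHAM) recombines the biased histograms into one
unbiased PMF by iterating

```
P(b)  = Σ_i n_i(b) / Σ_i N_i exp[(f_i − w_i(ξ_b)) / kBT]
f_i   = −kBT ln Σ_b P(b) exp[−w_i(ξ_b) / kBT]
```

to a tolerance of 10⁻⁷ on max |Δf_i|, with Monte Carlo bootstrap error
bars. A barrier difference ΔΔG between the L and D pathways implies a
Boltzmann selectivity ratio exp(ΔΔG / kBT); a fourfold preference needs
only kBT·ln 4 ≈ 0.83 kcal/mol at 300 K.

This package implements the full analysis stack — window schedules, WHAM
with bootstrap, transition-state/barrier extraction, selectivity
arithmetic — plus the reaction-site approach geometry (Bürgi–Dunitz angle,
Flippin–Lodge angle, the amino-group torsion τ(Ob-Ccarb-Cα-N) whose
cis/trans flip distinguishes the two stereochemistries, and the key
N...O3' / N...P5' distances). Because the original data come from a QM/MM
engine that cannot run at desk scale, the package ships a first-class
synthetic generator: overdamped Langevin sampling on parametric
free-energy surfaces with landmark-controlled barriers, and 3-D
reaction-site frames following configurable geometric schedules. Every
stage of the pipeline is therefore testable against known ground truth.

For whom: computational chemists and structural bioinformaticians who want
a tested, scriptable WHAM/geometry stack with tidyverse semantics — every
user-facing function takes a data frame and returns a tibble, fitted
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Recover a 17 kcal/mol barrier from a full synthetic campaign:

```r
library(chiralpmf)

windows <- build_window_schedule(umbrella_segments())  # 101 windows
surface <- surface_from_landmarks(reactant_rc = -3, ts_rc = -0.5,
                                  barrier = 17, product_rc = 2,
                                  overall_dG = -7)
campaign <- generate_campaign(surface, windows, langevin_params(seed = 1))
fit <- solve_wham(campaign, windows)
fit <- bootstrap_pmf(fit, campaign, n_boot = 20, seed = 1)
locate_transition_state(fit)
```

```
# A tibble: 1 × 6
  ts_rc barrier reactant_min_rc product_min_rc overall_dG ts_uncertainty
  <dbl>   <dbl>           <dbl>          <dbl>      <dbl>          <dbl>
1 -0.515    17.1           -3.01           1.99      -6.88          0.114
```

The transition state is found at RC ≈ −0.5 Å with a 17.1 kcal/mol barrier
and −6.9 kcal/mol overall reaction free energy — the landmarks of the
surface the campaign sampled, recovered to within the statistical
resolution of 4000 samples per window (the bootstrap SD at the barrier bin
is ~0.1 kcal/mol). `autoplot(fit)` draws the PMF with its bootstrap
ribbon, and

```r
selectivity_ratio(barrier_required_for_ratio(4))  # 4
barrier_required_for_ratio(4)                     # 0.826455 kcal/mol
```

shows the selectivity arithmetic: a fourfold kinetic preference costs less
than 1 kcal/mol at the barrier.

Geometry side:

```r
frames <- generate_geometry_frames(geometry_schedule_preset("D-Ala"),
                                   rc_values = seq(-4, 0, 0.05), seed = 1)
obs <- geometry_observables(frames)
window_statistics(obs, "tau", windows, circular = TRUE)
```

tracks the D-pathway cis→trans torsion flip near RC = −2.2 Å, with the
coupled jump of d(N...P5') from ~4.3 to 5.1 Å.

A command-line driver wrapping these functions ships at
`inst/cli/chiralpmf.R` (subcommands `make-windows`, `simulate`, `wham`,
`analyze`, `geometry`, `report`; YAML config, `--seed`, `--out`).

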