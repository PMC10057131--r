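---
title: "Free-energy profiles and approach geometry of chiral-selective RNA aminoacylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy profiles and approach geometry of chiral-selective RNA aminoacylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralpmf)
```

## The model and its assumptions

The non-enzymatic transfer of an amino acid from an acyl-phosphate donor to
the 3'-hydroxyl of an RNA minihelix is followed along a single reaction
coordinate, the distance difference

$$\xi = d(\mathrm{H3'}\!\cdots\!\mathrm{O3'}) -
        d(\mathrm{C_{carb}}\!\cdots\!\mathrm{O3'}),$$

negative in the reactant state (the hydroxyl proton still bonded at
0.96 Å, the carbonyl carbon ~5 Å away) and positive after transfer.
Umbrella sampling restrains $\xi$ with harmonic windows
$w_i(\xi) = \tfrac12 k (\xi - \xi_{0,i})^2$; the package's reference
schedule uses $k = 500$ kcal/mol/Å² with spacing 0.1 Å on
$[-4.0, -1.5)$ and $(1.5, 3.0]$ and 0.05 Å on $[-1.5, 1.5]$, i.e. 101
windows, each contributing 4000 production samples at a 5 fs cadence
(20 ps) after 10 ps of discarded equilibration. The half-prefactor bias
convention is the default; the full-$k$ (AMBER NMR-restraint) convention
is available as a switch because restraint conventions differ between
codes and the schedule metadata alone does not disambiguate them.

WHAM recombines the biased histograms $n_i(b)$ into one consistent
unbiased distribution,

$$P(b) = \frac{\sum_i n_i(b)}
             {\sum_i N_i\, e^{(f_i - w_i(\xi_b))/k_BT}},
  \qquad
  f_i = -k_BT \ln \sum_b P(b)\, e^{-w_i(\xi_b)/k_BT},$$

iterated until the largest change in any window free energy $f_i$ falls
below $10^{-7}$ kcal/mol. The monitored quantity is the $f_i$ increment —
the standard choice when a convergence figure is quoted without naming the
metric. The PMF is $-k_BT \ln P$, anchored so that its minimum over the
reactant region ($\xi < -2$ Å by default) is zero, because barrier heights
are quoted relative to the reactant basin. Bins with zero counts stay
`NA`: an empty bin carries no information and imputing a number there
would silently fabricate free energies.

Statistical errors come from a Monte Carlo bootstrap: each window's sample
set is resampled with replacement (optionally in contiguous blocks when
serial correlation matters), WHAM is re-solved per replicate
(warm-started from the base solution, which changes nothing about the
fixpoint and much about the runtime), and per-bin standard deviations are
reported. Replicates that fail to converge are dropped and counted; more
than 20% dropped aborts the analysis rather than reporting a mirage.

## What the synthetic generator emulates — and what it does not

The original sampling engine is a QM/MM molecular-dynamics code; nothing
at desk scale reproduces its energetics. The generator therefore emulates
only what the estimator consumes: *biased stationary sampling on a known
one-dimensional free-energy surface*. Surfaces are sums of Gaussians plus
a linear term — smooth, analytic gradients, and shapeable to any
single-barrier profile. `surface_from_landmarks()` fits six Gaussian
amplitudes, a slope and an offset to value/derivative constraints at the
reactant minimum ($G=0$), barrier top and product minimum, plus two
confining values one landmark-gap outside the outer minima (without
confinement a shallow product well is not a true local minimum of the
solved surface, and biased sampling beyond the landmarks would wander).
The solve is an exactly determined linear least-squares system, and every
constructed surface is verified on a dense grid to 0.05 kcal/mol / 0.05 Å
before use; infeasible landmark sets raise a construction error.

Dynamics are overdamped (Brownian) Euler–Maruyama steps

$$d\xi = -\frac{1}{\gamma}\, \frac{d(G + w_i)}{d\xi}\, dt
       + \sqrt{2 k_B T\, dt/\gamma}\; \mathcal N(0,1),$$

with reflection at the domain edges (reflections are counted; more than 1%
triggers a warning). Inertia is deliberately absent: WHAM only sees the
stationary measure, and the overdamped process has an exactly known one,
which makes every property of the sampler checkable in closed form (window
variance $k_BT/k$, tilted-window mean shift $-s/k$, Boltzmann well
occupancies, Kolmogorov–Smirnov agreement with the analytic biased
density). The defaults $\gamma = 1000$ kcal·fs/(mol·Å²), $dt = 0.01$ fs
were set by calibration: the relaxation time $\gamma/k = 2$ fs keeps
successive 5 fs samples nearly independent, and the Euler–Maruyama
stationary-density bias ($\sim k\,dt/2\gamma$ per window, 0.25% here)
stays far below the statistical error — at coarser steps that bias is
invisible in any single window yet chains across 101 window free energies
into a systematic drift of the reconstructed profile, which is why the
step is an order of magnitude below what single-window statistics alone
would demand. Per-window seeds derive deterministically from one master
seed, and each window starts from the previous window's final coordinate,
as sequential umbrella protocols do.

The geometry generator plays the same role for the analyzer of the
reaction-site observables. Scheduled targets (Bürgi–Dunitz angle,
Flippin–Lodge angle, torsion $\tau(\mathrm{O_b\!-\!C_{carb}\!-\!C_\alpha\!-\!N})$,
key distances) are piecewise-linear functions of $\xi$, realized exactly
in 3-D: carbonyl scaffold in a plane, O3' placed by the two approach
angles and $d(\mathrm{C_{carb}\cdots O3'})$, H3' along the recession line
(so the frame's computed RC equals its nominal one identically), N from
the torsion by internal-coordinate construction, P5' at its scheduled
distance. $d(\mathrm{N\cdots O3'})$ is left *emergent* by default: once
the torsion fixes the amino-group orientation, that distance follows from
the cis/trans state and the approach distance — exactly the coupling the
reaction shows, where the D-pathway's cis→trans flip at $\xi \approx
-2.2$ Å drops $d(\mathrm{N\cdots O3'})$ abruptly. An explicit
$d(\mathrm{N\cdots O3'})$ schedule is honoured when feasible by solving
the $\mathrm{C_\alpha\!-\!N}$ bond length (infeasible targets raise a
construction error naming the triangle-inequality conflict).

What the generator does **not** emulate: electronic structure, solvent,
ions, kinetics, barrier recrossing, or any coupling between the reaction
coordinate and the geometric observables beyond their shared schedules.
Passing tests therefore demonstrate that the *estimators* are correct and
well-calibrated on data whose truth is known — they say nothing about
whether a real QM/MM campaign would produce these profiles.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| force constant $k$ | 500 | kcal/mol/Å² | stiff enough to hold windows on a 26 kcal/mol barrier flank |
| window spacing | 0.05 / 0.1 | Å | fine where the barrier lives, coarse on the plateaus; 101 windows total |
| samples/window | 4000 | – | 20 ps at 5 fs cadence; the equilibration discard is 10 ps |
| WHAM bin width | 0.02 | Å | a few bins per window SD ($\sqrt{k_BT/k} \approx 0.035$ Å); exposed in the config |
| WHAM tolerance | $10^{-7}$ | kcal/mol | on $\max_i |\Delta f_i|$ per iteration |
| anchor region | $\xi < -2$ | Å | barrier heights are relative to the reactant basin |
| TS search range | $(-2, 1)$ | Å | brackets the barrier, excludes end plateaus |
| bootstrap replicates | 20–50 | – | per-bin SDs stabilize quickly; replicate count is a cost knob |
| $\gamma$, $dt$ | 1000, 0.01 | kcal·fs/mol/Å², fs | sampler calibration, see above |

The histogram bin width and the bootstrap replicate count are the
package's own choices, exposed in the configuration; they are not
reproductions of any reference protocol.

## Numerical choices and degenerate inputs

* Window centers are generated by integer stepping and rounded to three
  decimals, so shared segment boundaries can never duplicate through
  floating-point drift; the boundary windows at $\pm 1.5$ Å belong to the
  fine segment — the only ownership consistent with 101 windows.
* Histogram binning is half-open $[lo, hi)$: a value exactly on an edge
  belongs to the bin on its right. Out-of-range values are counted and
  reported per window, and a window with *no* in-range samples is an
  error naming the window.
* The WHAM iteration runs in compiled code with the window free energies
  gauge-fixed ($f_0 = 0$) and max-shifted exponentials; a per-window step
  is halved when its update oscillates (sign flip) and relaxes back
  toward 1 otherwise, which damps limit cycles without moving the
  fixpoint. Non-convergence returns an honestly flagged result plus a
  warning, never a silent number.
* Transition states are reported on bin centers by default — the honest
  resolution of a histogram estimator; a three-point quadratic refinement
  is reported separately on request. Ties at the barrier top break toward
  smaller RC. A monotone profile raises a "no barrier" error; an argmax
  on the search boundary asks the caller to widen the range rather than
  guessing.
* The Flippin–Lodge angle is computed against the least-squares plane of
  the four carbonyl atoms (they need not be coplanar in sampled frames),
  with the normal oriented right-handedly from the carbonyl axis and the
  in-plane direction toward the bridging oxygen O$_b$. On the approach
  side this makes "tilts toward O$_b$" positive, and it makes the angle a
  *handed* quantity that flips sign under reflection — the property that
  lets the observable distinguish stereochemistry at all. The purely
  material reading ("positive toward O$_b$", regardless of side) would be
  reflection-invariant and thus blind to chirality; the handed
  operationalization was chosen deliberately and is validated by internal
  consistency (generator round-trips, reflection tests), since the verbal
  definition does not pin down an analytic formula.
* Torsions use the standard signed convention (clockwise positive looking
  along the central bond; cis = 0, trans reported as +180). A synthetic
  fixture frame with $\tau = -60^\circ$, built by the package's own
  internal-coordinate construction, pins the sign convention in the test
  suite. Circular means and SDs (vector mean, $\sqrt{-2\ln \bar R}$) are
  used for torsions near ±180°, where a linear mean of $\{+179, -179\}$
  would report 0° instead of 180°; both modes are available and labelled
  because window averages of a torsion that visits both signs are
  convention-dependent.

## Design choices where the design was open

* **Bias prefactor.** The printed restraint form elsewhere in the
  protocol is $\tfrac12 k (r - r_0)^2$; whether the production umbrella
  code used $\tfrac12 k$ or $k$ is not restated. The package defaults to
  $\tfrac12 k$ and exposes `convention = "full_k"`, so either reading is
  one argument away and the schedule metadata stays identical.
* **Window duplication.** Feeding the whole campaign twice leaves the
  WHAM estimate exactly unchanged (numerator and denominator both
  double), and the tests assert that form of estimator invariance.
  Duplicating a *single* window is not an invariance of the
  finite-sample estimator — the duplicated window's empirical histogram
  legitimately gains weight — so no such claim is tested.
* **Per-window sample count.** The 20 ps / 5 fs cadence implies 4000
  samples per window; that inference is the generator default and is
  flagged here rather than presented as a reproduced setting.
* **TS positions from raw bins vs smoothing.** Both modes exist
  (`refine = "none"` default, `"quadratic"` on request) because reported
  transition-state positions on a 0.05 Å grid are consistent with either
  reading.

## Problem sizes used by the test suite

The full parameter-recovery checks run two complete campaigns (101
windows × 4000 samples each, ~$4 \times 10^8$ integrator steps) and
re-solve WHAM to $10^{-7}$; this is the package's reference resolution
and completes in a few minutes on one CPU. Unit and property tests use
reduced systems — a nine-window well for estimator invariances (gauge,
duplication, temperature scaling, MBAR cross-check), 50 000 direct
Gaussian draws for the single-window quadratic oracle, 300–1000 random
frames for the geometry oracles, and 16-replicate bootstraps for the
error-scaling law — sizes chosen so each property is measured well above
its sampling noise.

## Known limitations

* One-dimensional reaction coordinate only; no 2-D WHAM, no periodic
  coordinates, no autocorrelation-time estimation beyond the optional
  fixed block length.
* The geometric observables and the reaction-coordinate sampling are
  generated independently; joint distributions between them are not
  modelled.
* The synthetic surfaces are smooth by construction; estimator behavior
  on rugged or discontinuous profiles is untested.
* Barrier differences are converted to selectivities by a pure Boltzmann
  ratio — no transition-state-theory prefactors, recrossing corrections,
  or kinetic modelling.
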