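---
title: "Methods: free-energy reconstruction and barrier screening in felscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy reconstruction and barrier screening in felscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(felscreen)
```

felscreen implements the analysis half of an enzymatic-degradation screen
for polymer–drug conjugates: umbrella-window design, weighted-histogram
free-energy reconstruction, minimum-energy-path and stationary-point
analysis, dual-level spline energy correction, and rate-limiting-barrier
screening. This vignette records the models, the defaults and why they were
chosen, the numerical decisions, and what the synthetic landscapes do and do
not establish about real enzyme free-energy surfaces.

## Units and constants

All internal energies are kcal mol⁻¹ and coordinates Angstrom; temperature
defaults to the physiological 310.15 K. Restraint force constants are
conventionally declared in kJ mol⁻¹ Å⁻² and converted on input with the
thermochemical calorie (1 kcal = 4.184 kJ), so the standard 200 kJ mol⁻¹ Å⁻²
restraint becomes 47.8011 kcal mol⁻¹ Å⁻². One internal unit avoids the
double-conversion errors that mixing kJ-based restraints with kcal-based
energies invites. k_B is fixed at 0.0019872041 kcal mol⁻¹ K⁻¹; the Eyring
prefactor uses the exact SI values of k_B and h.

## Surrogate landscapes

The sampler draws from analytic surfaces rather than a QM/MM engine. Each
preset stores its stationary points in closed form, which is what makes
every downstream stage testable against an exact reference:

* `harmonic` — a convex bowl; the PMF is known exactly (½κx²) and the
  unbiased sampling variance is k_BT/κ.
* `double_well_1d` / `double_well_2d` — a quartic double well
  U = 16h·u²(1−u)², u = (x−a)/(b−a), with wells at 1.2 and 2.2 Å (typical
  bond-forming/bond-breaking distances) and a construction barrier h
  (default 5 kcal mol⁻¹) exactly at the midpoint. The 2D variant adds a
  harmonic transverse coordinate, mimicking the pairing of a heavy-atom
  distance with a proton-transfer distance.
* `four_state_2d` — a sextic triple well whose *derivative* is a quintic
  with prescribed roots, so the three minima and two saddles sit exactly at
  chosen coordinates; energies follow from termwise integration of the
  polynomial. The default arrangement mimics a
  reactant → tetrahedral-intermediate → acyl-enzyme profile
  (RC → TS1 → TI1 → TS2 → EAM).

What the surrogates emulate: multi-basin topology on bond-distance
coordinates, barrier heights in the 5–30 kcal mol⁻¹ range, Boltzmann
statistics under harmonic restraints at 310.15 K. What they do not: rugged
high-dimensional orthogonal degrees of freedom, slow conformational
relaxation between windows, sampling correlation structure of real MD, and
any actual chemistry. Tests passing on these surfaces certify the
*estimators* (WHAM, path tracing, correction, screening bookkeeping), not
the quality of any molecular model.

## Window design and sampling

Window centres are generated by integer index from the range lower bound —
never by floating-point accumulation — with both endpoints included; fine
regions (default none, since where "near the transition state" begins is a
user decision) are tiled at the fine step and de-duplicated against coarse
centres within 10⁻⁹ Å. In 2D the window set is the Cartesian product of the
per-coordinate centre lists; the standard scheme over
[1.4, 2.5] × [1.0, 2.0] Å at 0.1 Å spacing gives 12 × 11 = 132 windows.

The per-window sampler is Metropolis Monte Carlo with Gaussian proposals on
U(x) + Σ_d ½k(x_d − c_d)². Only the stationary distribution matters to
WHAM, so a Markov chain is an adequate stand-in for restrained MD. The
proposal scale starts at 2.4/√d times the restrained harmonic width and is
re-tuned every 50 burn-in steps towards a 30–50 % acceptance rate, then
frozen (adapting after burn-in would break detailed balance). Burn-in is
the first 20 % of proposed steps, discarded and recorded. Proposals outside
the landscape domain are rejected, i.e. the target density is truncated to
the domain. Sample counts default to 5,000 per window — the desk-scale
analogue of a 50 ps window at 1 fs steps with 10× thinning — and all
randomness flows from explicit seeds: identical (landscape, window, seed)
triples reproduce output bit-for-bit, and multi-window runs derive
per-window substream seeds from one base seed.

A practical note on restraint strength: with 0.1 Å window spacing the
restraint must dominate the local curvature and slope of the underlying
surface, or windows on steep walls slide away from their centres and the
histograms stop overlapping. The escalation of the declared force constant
(200 → 1000 kJ mol⁻¹ Å⁻² and beyond) is therefore exposed per window and
per pipeline stage rather than hard-coded: surrogate barriers of 20–30
kcal mol⁻¹ over a 0.5 Å half-width are steeper than most real PMFs and need
the escalated values.

## WHAM

Histogram bins are half-open [lo, hi) with the final bin closed; a sample
exactly on an interior edge counts in the higher bin. The default bin width
of 0.02 Å matches the finest window spacing — finer bins add noise without
resolution, coarser ones blur the saddle region.

The self-consistent equations

* P(b) = Σᵢ nᵢ(b) / Σᵢ Nᵢ exp[(Fᵢ − Uᵢ(b))/k_BT]
* Fᵢ = −k_BT ln Σ_b P(b) exp[−Uᵢ(b)/k_BT]

are iterated with all sums accumulated in the log domain (stiff restraints
make exp[−Uᵢ(b)/k_BT] underflow otherwise), gauge-fixed by F₁ = 0,
normalised so Σ_b P(b) = 1 at every iteration, and stopped when
max |ΔFᵢ| < 10⁻⁶ kcal mol⁻¹ (well below any barrier of interest) or after
10⁵ iterations, with the iteration count and final residual recorded in the
result. The PMF is −k_BT ln P(b) shifted so the minimum over sampled bins
is 0 — barriers are relative quantities, so the offset is pure convention.
Unsampled bins are masked, never imputed: an imputed bin would silently
fabricate a pass through unexplored territory, whereas a masked bin makes
the downstream path tracer fail loudly. Disconnected histogram support
warns rather than fails (the PMF within each connected component is still
valid; only cross-component offsets are arbitrary).

Bootstrap errors resample each window's retained samples with replacement
(realised as a multinomial redraw of that window's histogram counts, which
is distributionally identical), re-solve WHAM warm-started from the base
solution, offset-align every replicate at the base global-minimum bin, and
report the per-bin standard deviation across replicates. The resampling
unit assumes approximately independent retained samples; for serially
correlated series a moving-block bootstrap over the raw time series is
available (`series` + `block_length`). The degenerate no-resampling mode
(all errors exactly zero) exists purely to validate the machinery.

## Stationary points and minimum-energy paths

Minima are unmasked bins strictly below all unmasked neighbours
(8-neighbourhood in 2D by default — diagonal moves approximate smooth paths
better on a square grid; 4-connectivity is available and cannot cut
corners). Exact plateau ties resolve by lexicographic node order,
documented and deterministic. Saddles are the peak nodes of
bottleneck-optimal paths between basin pairs, de-duplicated by node, and
are reported at bin-centre resolution — no sub-bin interpolation, since the
default spacing (0.02 Å) is already below any physically meaningful
feature.

The path between two basins minimises the maximum node energy (the
bottleneck or minimax criterion — the defining property of a
minimum-energy path on a grid), with ties broken by minimum total path
energy, then lexicographic order. It is computed as bottleneck Dijkstra
followed by a minimum-total-energy pass restricted to the sub-level set at
the bottleneck energy; the second pass makes the descent segments from the
pass down to each basin follow low-energy routes rather than arbitrary
bottleneck-feasible detours. Correctness is certified in the test suite
against an independent sub-level-set connectivity sweep on random grids up
to 12 × 12, and that sweep oracle is itself validated against genuine
all-simple-paths enumeration on tiny grids (full enumeration on a
12 × 12 8-connected grid is combinatorially impossible — the sweep is the
exact, tractable formulation of the same minimax quantity).

On *sampled* (noisy) grids, strict local minima include statistical
ripples. `find_stationary_points()` therefore takes a `min_prominence`
floor (kcal mol⁻¹): a minimum whose lowest pass to any deeper basin rises
less than the floor above it is merged away. The default is 0 (exact
behaviour on noise-free grids); the pipeline uses 1.0 kcal mol⁻¹ — roughly
an order of magnitude above typical per-bin bootstrap errors at the default
sampling depth, and far below any barrier the screen cares about. The
pipeline additionally restricts basins to the connected component of the
global minimum, since a reaction path cannot cross never-sampled territory.

## Dual-level correction

High-level (DFT-quality) energies are only affordable at a handful of
anchor structures along the path. The correction is a cubic spline S fitted
to the per-anchor difference ΔE = E_high − E_low, and the corrected profile
is E_corr = E_low + S(position). Decisions:

* **Boundary condition**: natural spline (zero second derivative at both
  ends) — the conventional default when nothing is known about the
  derivative of ΔE beyond the anchor span; recorded in the object. With two
  anchors it degrades to linear interpolation.
* **Progress coordinate**: the reaction-coordinate value for 1D profiles;
  cumulative Euclidean arc length for 2D paths (no canonical
  parameterisation exists for a grid path; arc length is the least
  arbitrary).
* **No extrapolation**: querying outside the anchor span is an error, never
  an extrapolation — a cubic beyond its data is fiction.
* **Anchor count/placement**: user input, default 11 evenly spaced path
  nodes.
* **Where barriers are read off**: at an anchor, E_corr = E_low + (E_high −
  E_low) = E_high exactly, so the low-level statistical noise cancels
  there; between anchors that noise passes through unchanged. The pipeline
  therefore evaluates corrected step barriers on the anchor set itself —
  the corrected barrier inherits the (smooth) high-level surface's
  discretisation at anchor spacing instead of the low-level sampling noise.
  Denser anchors trade cost for resolution, exactly as in the real
  protocol. Correction is applied along the traced path only; off-path
  correction of a whole 2D map would require an anchor parameterisation the
  method does not define.

## Screening

A reaction profile holds per-transition-state barriers for one conjugate
and phase (acylation: TS1, TS2; deacylation: TS3, TS4). The rate-limiting
step is the largest barrier, ties broken towards the later step (the step
nearest product). Viability is strict: ΔG‡ < 25.0 kcal mol⁻¹; a barrier
exactly at the threshold is *not* viable, since the threshold is defined as
the onset of biological irrelevance. Viable conjugates are ranked 1..n
ascending in rate-limiting ΔG‡. Barrier/rate interconversion uses the
Eyring equation with unit transmission coefficient; the pair is exactly
self-inverse. Per-TS barriers are stored as given and never recombined into
absolute state energies — whether a published TS2 barrier is referenced to
TI1 or to RC varies, so the screen compares like with like and nothing
more. Acylation and deacylation are screened separately; the pipeline runs
a cheap 1D pass over all candidates and promotes only sub-threshold
candidates to the ~100× more expensive 2D landscape pass.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use 5 windows × 20,000 samples
for harmonic PMF recovery (RMS against the closed form evaluated over the
central 80 % of the domain, with the free additive constant aligned by
least squares — a PMF is defined only up to a constant), 19 windows × 5,000
samples for the double-well pipeline, 25 random grids up to 12 × 12 for the
minimax certificate, and 50,000–100,000-sample chains for the sampler's
distributional checks. These sizes give comfortable statistical margins at
desk scale; all are configurable upward.

## Known limitations

* The sampler is a stand-in: it reproduces biased Boltzmann statistics, not
  MD kinetics; autocorrelation structure differs from real trajectories,
  which matters only to the bootstrap's independence assumption (use the
  block bootstrap for correlated input).
* WHAM here is histogram-based; no MBAR-style binless generalisation and no
  automatic autocorrelation-time estimation.
* Path analysis is grid-based (no string method or nudged elastic band);
  saddle resolution equals the bin width.
* The screen is bookkeeping on barriers: no kinetic time-course of enzyme
  turnover, no docking, and no claim about real hCE2 chemistry beyond what
  the supplied barrier sets encode.
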