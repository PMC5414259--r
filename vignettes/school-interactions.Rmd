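---
title: "Inferring school interactions: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring school interactions: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pmfish` couples a self-propelled particle (SPP) model of schooling fish in
a circular arena with the statistical-mechanics machinery needed to go the
other way: from stationary positional data back to an effective pair
interaction. This vignette documents the model and its assumptions, the
estimators, the numerical choices, and what the validation suite does and
does not establish.

## The model

N point particles move in discrete time (`dt = 1` step) inside a circular
arena of radius R (default 380 length units; one unit corresponds to 1 mm).
Each step is synchronous — all updates are computed from the previous
frame — and per particle proceeds as:

1. **Desired heading.** If any neighbour lies strictly inside the zone of
   repulsion (`zor_radius`), collision avoidance takes absolute priority:
   the heading is the negated, normalized sum of displacement vectors to
   those neighbours. Otherwise the particle aligns with the normalized sum
   of the velocities of all particles inside the zone of alignment
   (`k * zoa_radius_base`), itself included — the Vicsek convention, which
   also makes an isolated particle keep its own heading. A velocity sum
   that cancels exactly leaves the current heading unchanged; we prefer
   this to injecting unmodelled randomness into a measure-zero case.
2. **Speed.** v = v0 ψ^γ, where ψ is the magnitude of the mean heading
   unit vector over all particles inside the behavioural zones (the
   repulsion zone is a subset of the alignment zone, so "both zones" is the
   alignment disc). Zero-speed neighbours contribute their stored heading:
   a particle always carries a heading, even when momentarily stopped. An
   isolated particle has ψ = 1 and moves at full speed.
3. **Noise, then wall.** The heading is rotated by a Gaussian angle of
   standard deviation η, then by the wall-avoidance angle
   θ = v0 φ / d, where d is the distance to the forward impact point of
   the heading ray on the arena circle and φ the angle between the heading
   and the boundary normal there. For a forward impact φ ∈ [0, π/2), so
   the turn is damped far from the wall and for head-on approaches; the
   sign rotates the heading toward the inward normal. The two rotations
   are applied in this order; the wall angle is evaluated on the
   post-noise heading.
4. **Streaming and containment.** Positions advance by r + V dt. Because
   a head-on approach has φ = 0 and hence no wall turn, the turning rule
   alone cannot guarantee confinement; a specular reflection at the
   boundary (position and velocity mirrored about the local tangent) is
   applied to any particle that would exit. A `clamp` mode (radial
   projection onto the boundary) is available for sensitivity checks. The
   wall turn is capped at π/2 per step so that d → 0 cannot produce
   unbounded rotations.

There is no explicit attraction rule and no inertia: cohesion emerges from
alignment plus the wall interaction, which is precisely what the Boltzmann
inversion then detects as an effective attraction.

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `arena_radius` | 380 | length | arena radius (1 unit ≈ 1 mm) |
| `zor_radius` | 7.5 | length | repulsion zone, one small-fish body length; size-independent |
| `zoa_radius_base` | 75 | length | alignment zone of the smallest class (ten body lengths) |
| `k` | 1 | — | body-size scale of the alignment zone: 1, 1.73, 3.07 for body lengths 7.5, 13, 23 mm |
| `v0` | 5 | length/step | maximal speed; `calibrate_v0(b, v_exp)` = b·v_exp with reaction time b = 0.05 s |
| `gamma` | 1 | — | sharpness of the order–speed coupling |
| `eta` | 0.1 | rad | heading-noise strength |
| `n_steps` | 2×10⁴ | steps | run length; `burn_in` defaults to the first half |

The zone radii are calibration parameters: they are not fixed by any
printed quantity, and the defaults (one and ten body lengths of the
smallest class) encode the usual zonal-model rule of thumb. The default
speed corresponds to a 100 mm/s cruising speed converted by the 0.05 s
reaction time. `size_class_params()` scales **both** the alignment zone
(factor k from the body-length ratio) and the speed (v0 ∝ k) across the
three size classes: the model's unit of time is set by v0 = b·v0e with v0e
the average experimental speed of the class being simulated, and cruising
speed scales roughly linearly with body length. This joint scaling matters:
with a single common speed the first peak of g(r) is pinned by the
size-independent repulsion zone and does not move across classes, whereas
class-scaled speeds shift the preferred spacing outward for larger fish —
the behaviour the inversion is meant to detect.

Burn-in of half the run is a conservative steady-state allowance; the
polarization of a 30-particle run equilibrates within a few thousand steps
at these parameters.

## The inversion chain

The pair distribution function accumulates all ordered pair separations
over frames into bins of width `bin_width` (default 1). Two normalizations
are provided:

- `shell`: divide by the annulus measure 2πr dr / (πR²) — the textbook
  expression. In a bounded arena this decays below 1 at large r even for an
  ideal gas, because part of the annulus lies outside the wall.
- `edge_corrected` (default): divide by the **exact** expected ideal-gas
  pair count per bin, obtained by integrating the closed-form pair-distance
  density of two uniform points in a disc ("disk line picking") over each
  bin. A uniform ensemble then gives g ≡ 1 at every separation, which is
  the property the Boltzmann step U = −k_BT ln g relies on. We use the
  analytic density rather than Monte-Carlo resampling of the arena: it is
  exact, deterministic, and removes one source of noise from the
  normalization; the validation against uniform ensembles remains an
  independent Monte-Carlo check.

g is smoothed by a centred moving average (default 5 points, shrinking
symmetrically at the edges; counts propagate by summation) *before*
inversion, and U and F inherit the smoothing. The additive constant of U —
the partition function of the assumed Boltzmann distribution — is fixed by
rescaling the large-r plateau of g to 1 (`normalize_plateau()`, mean over
the last quartile of bins with positive g). For compact simulated schools
whose g falls to zero well inside the arena there is no meaningful plateau;
the analyses that only need the *location* of features (e.g. the U
minimum) therefore run with `rescale = FALSE`, since additive constants do
not move extrema.

Bins with g = 0 are undefined under the logarithm; they break U into
segments, and the mean force F = −dU/dr is differenced per segment
(central differences inside, one-sided at segment ends, never across
gaps). Central differences are exact for quadratic U and second-order
accurate otherwise. Peak features use a smallest-radius tie-break, and the
half-radial width is the largest down-crossing of g = 1 beyond the main
peak, linearly interpolated between bin centres. Where U has a flat
minimal basin, `u_min_radius()` reports the centre of the basin of bins
within 0.05 k_BT of the minimum instead of a noise-dominated argmin.

kBT is set to 1 throughout: the inverse temperature here is a bookkeeping
constant for fluctuation scale, not a thermodynamic temperature, and the
inferred U is only defined up to this scale.

## Synthetic ensembles and what the tests show

Every estimator is validated against ensembles with known structure:

- `uniform_disc()` — the ideal-gas null. Edge-corrected g must be 1 within
  3 standard errors on every well-sampled bin. The per-bin SE is estimated
  empirically across 50 frame blocks: pairs sharing a particle are
  positively correlated, so a Poisson count model understates the
  variance.
- `fixed_pair()` — rigid pairs at an exact separation; g has single-bin
  support.
- `aligned_group()` — polarization exactly 1; reversed halves give 0.
- `metropolis_pair()` — two-particle configurations drawn from
  exp(−U*/k_BT) by a Metropolis chain with uniform displacement moves. The
  step size is auto-tuned to a 30–50% acceptance band; the chain is
  thinned by five integrated autocorrelation times of the pair distance
  (Geyer initial-sequence estimate from a pilot run), so retained frames
  are approximately independent; everything is seed-reproducible.

The end-to-end recovery test draws 10⁵ retained configurations under a
truncated harmonic well and requires the full chain (pair distribution →
smoothing → inversion, constant aligned on the outer quartile of sampled
bins) to recover U* within 0.1 k_BT on all bins with at least 500 raw pair
counts. The well used — centre 60, half-width 150, depth 1.5 k_BT, with
4-unit bins — is chosen so that the fixture does not defeat the estimator
for reasons unrelated to its correctness: a much deeper well makes
well-to-plateau exchanges rare (correlated noise on plateau bins), and a
steeper truncation slope turns the moving average's corner bias at the
truncation radius into the dominant error. Those are properties of the
fixture, not of the inversion.

What passing these tests does **not** show: real tracking data are
anisotropic (fish have heading-dependent neighbourhoods), temporally
correlated, and subject to identity loss; the inversion assumes a
stationary, isotropic, Boltzmann-distributed ensemble. The recovered U is
an *effective* potential — it folds in multi-particle correlations and the
wall — and is useful for qualitative comparison, not as an equilibrium
pair potential.

## Problem sizes

The validation suite runs the study conditions at full size: 200 particles
× 500 frames for the ideal-gas null, 10⁵ retained Metropolis frames for
the recovery test, and 5 replicate runs × 2×10⁴ steps at N = 10–60 for the
size- and group-size trends, with pair statistics computed on every tenth
retained frame (consecutive frames are strongly autocorrelated). Replicate
runs are pooled with `bind_trajectories()` before locating U minima.

## Known limitations

- Interactions are metric and isotropic; no blind angle, no body shape,
  no three-dimensional motion.
- The wall rule plus specular fallback guarantees containment but makes
  the boundary layer's details (reflection vs. clamp) a modelling choice;
  both modes are provided.
- Direct (non-iterative) Boltzmann inversion is single-shot: it does not
  self-consistently correct for density effects the way iterative schemes
  do, and recovered potentials are state-dependent.
- The Metropolis generator samples two-particle ensembles only; it
  validates the pair-level inversion, not many-body closures.
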