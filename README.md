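# pmfish

Self-propelled particle schools in a circular arena, and inference of the
effective interactions between the fish from their positions alone, by
direct Boltzmann inversion.

## The problem

Schooling fish interact through short-range collision avoidance and
longer-range alignment, and both the strength of these interactions and the
resulting spatial organization change as fish grow. Reconstructing the
interactions from tracking data is an inverse statistical-mechanics
problem: given stationary configurations of a group, what effective pair
potential would produce them? `pmfish` implements both directions of this
programme for a school of *Pseudomugil signifer*-like agents confined to a
shallow circular arena:

- **Forward (simulation).** A Vicsek-class model of N point particles with
  discrete-time dynamics. Each particle turns away from neighbours inside a
  zone of repulsion (radius `zor`, absolute priority), otherwise aligns with
  the summed velocity of neighbours inside a zone of alignment (radius
  `k * zoa_base`, with k the body-size scale factor). Its speed is
  v_i = v0 ψ^γ, where ψ is the local polar order inside the behavioural
  zones, so disordered neighbourhoods slow a fish down. The heading is
  perturbed by Gaussian noise of strength η and by a wall-avoidance turn
  θ = v0 φ/d damped with the distance d to the heading ray's impact point on
  the wall and the approach angle φ. Positions then stream by
  r(t+Δt) = r(t) + V Δt. There is *no explicit attraction rule*: cohesion
  emerges from alignment plus the wall.

- **Inverse (analysis).** From trajectories (simulated or tracked): group
  area by convex hull, number density ρ = N/A, packing fraction a = A_f/A,
  the polar order parameter φ = ⟨|Σ_j e^{iθ_j}|/N⟩, the radial pair
  distribution function g(r) — with an exact edge correction for the bounded
  arena, so that a uniform ideal gas gives g ≡ 1 — the potential of mean
  force by direct Boltzmann inversion U(r) = −k_BT ln g(r), and the mean
  interaction force F(r) = −dU/dr (positive = repulsive).

Synthetic ensemble generators (uniform disc, rigid pairs, perfectly aligned
groups, and a Metropolis sampler drawing two-particle configurations from
exp(−U*/k_BT) for a known U*) give every analysis step an exact oracle, so
the whole chain is validated without any experimental data.

## Worked example

Simulate a school of 30 medium-sized fish (body length 13 mm, alignment
zone and speed scaled accordingly) and invert its pair structure:

```r
library(pmfish)

params <- size_class_params("medium", n_particles = 30, n_steps = 2e4, seed = 1)
traj   <- spp_run(params)

group_stats(traj, body_length = 13)
#>       area density packing_fraction polar_order
#> 1 9470.887  0.0032           0.0841      0.9814

res <- school_analysis(traj, analysis_params(bin_width = 4, r_max = 600),
                       rescale = FALSE)
ft <- profile_features(res$g_smooth)
sprintf("g peak %.1f at r = %.0f; U minimum at r = %.0f",
        ft$peak_value, ft$peak_radius, u_min_radius(res$U))
#> [1] "g peak 29.0 at r = 22; U minimum at r = 22"
```

Read: the school covers ~9500 mm² (density 0.0032 fish/mm², packing
fraction 0.084 — gas-like), is strongly polarized (φ = 0.98), and the local
density around a fish peaks 29× above the arena average at a separation of
22 mm, which is where the inferred potential of mean force has its minimum
— the preferred nearest-neighbour spacing that emerges from repulsion,
alignment and the wall, with no attraction rule in the model.

A command-line interface wrapping the same functions ships in
`inst/cli/pmfish` (subcommands `simulate`, `analyze`, `invert`,
`fixtures`); every run writes a `manifest.json` with the full parameter set
and seed needed to reproduce it.

## Layout

- `R/`, `src/` — model rules, compiled step/Metropolis loops, statistics,
  synthetic generators, I/O.
- `tests/testthat/` — unit, property and end-to-end validation tests.
- `vignettes/school-interactions.Rmd` — model, assumptions, estimator
  choices and limitations.
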