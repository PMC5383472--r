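---
title: "Simulating cumulative sound exposure risk for marine mammals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cumulative sound exposure risk for marine mammals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

selrisk estimates how many marine mammals are likely to be harmed by an
intense underwater sound source — naval sonar, pile driving, a seismic
survey — by simulating the movement and sound exposure of thousands of
animal agents.  This vignette is the package's account of the model: what
each component assumes, which parameters matter, and what the idealized
test scenarios can and cannot tell you about real assessments.

## The model

Risk decomposes into *vulnerability* (will an animal be exposed?) and
*sensitivity* (what does the exposure do to it?).  The simulation chains
six components:

1. **Seeding.** Agents are placed by sampling a gridded density surface
   (animals/km², with a per-cell CV) with probability proportional to
   density × cell area, uniformly within the chosen cell
   (`sample_positions()`).
2. **Movement.** Each time step every agent draws a heading from a
   wrapped normal distribution and swims `speed · dt` along it.  The
   distribution's mean is either the agent's previous heading (a natural
   correlated random walk) or, for responsive movement, the bearing
   pointing directly away from the source, recomputed every step.  The
   SD σ controls directionality: σ = 0 is straight-line travel, σ = 10
   rad is effectively a uniform circular distribution (mean resultant
   length e^(−σ²/2) ≈ 0), and intermediate values grade between fleeing
   and diffusing.  A triangular dive cycle (descend/ascend over the dive
   duration, then a surface interval) keeps depth within both the
   species' maximum dive depth and the local seafloor.
3. **Sound field.** The received level at horizontal range r is
   `RL = SL − k·log10(max(r, r_ref)/r_ref) − α·r`, geometric spreading
   with k dB per decade (15 by default, between cylindrical 10 and
   spherical 20) and optional absorption α (default 0).  Fields can be
   precomputed on a grid and queried by bilinear interpolation
   (`precompute_field()`, `field_level()`), mirroring the practice of
   building a sound-field library per scenario.
4. **Duty cycle.** Sources are rarely continuous.  A duty cycle d means
   each step contributes `d · dt` seconds of active exposure — a
   deterministic energy fraction rather than an explicit ping schedule.
   For steps much longer than a ping period the cumulative energy is
   identical, and it makes the final SEL independent of dt (tested to
   10⁻⁶ dB).
5. **Weighting and accumulation.** The received level is
   frequency-weighted for the species' hearing and accumulated as
   energy: SEL_new = 10·log10(10^(SEL/10) + 10^((RL+W)/10)·seconds), in
   dB re 1 μPa²·s.  A "no exposure yet" sentinel (`NA`) avoids −∞ dB
   arithmetic.
6. **Risk.** Final SELs are compared against PTS/TTS criteria — a hard
   threshold (exceedance fractions, `fraction_exceeding()`) or a
   logistic dose–response curve (expected affected counts,
   `expected_tts_count()`; probability any agent is affected,
   `any_effect_probability()`) — and can be mapped back to the seeding
   grid (`risk_map()`).

## Auditory weighting and effect criteria

Two weighting schemes are supported, and the choice matters more than
any other input:

- **M-weighting** (`m_weighting()`): a band-pass filter per functional
  hearing group, `W_M(f) = K + 20·log10(f_h²f²/((f²+f_l²)(f²+f_h²)))`,
  with K chosen in closed form so the maximum is exactly 0 dB.  Band
  edges per group are packaged as a fixture table
  (`functional_groups()`).  At 1 kHz the weighting is effectively zero
  for both packaged species.  It pairs with the recommended group
  criteria for nonpulsed sound: PTS at 203 dB (pinnipeds in water) and
  215 dB (cetaceans) cumulative weighted SEL.
- **A-weighting** (`a_weighting()`): the audiogram-derived weighting
  `W_A(f) = −H(f)`, so a weighted level is a sensation level on the SEL
  scale.  This normalization is the package's design choice: it is the
  only convention under which the audiogram-appropriate threshold rule —
  PTS at `H(f) + 95` dB (`pts_threshold(..., "A")`) — and the tens-of-dB
  separation between M- and A-weighted exposure curves are mutually
  consistent.  Audiograms are interpolated linearly in log10(f) and
  never extrapolated.

The packaged TTS dose–response curve (`tts_curve()`) is a logistic in
SEL anchored so that P(195 dB) = 0.185, inside the 0.18–0.19 band that
summarizes the experimental TTS-onset literature.  Only that anchor is
empirically pinned; the 4-dB scale is a documented free choice (the
underlying fitted curve is not published), and users can supply any
`dose_response_curve()`.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| source level SL | 240 | dB re 1 μPa²/s @ 1 m | loud pile-driving/sonar class source |
| frequency | 1 | kHz | inside both species' hearing range; M ≈ 0 there |
| duty cycle d | 0.1 | — | typical intermittent industrial activity |
| spreading k | 15 | dB/decade | intermediate spreading in shallow water |
| time step dt | 60 | s | resolves the dive cycle; 10-day × 10⁴-agent runs stay desk-scale; SEL is dt-invariant by construction |
| agents | 10⁴ (study), 2×10³ (tests) | — | binomial SE on a 1% exceedance at 2×10³ agents is ~0.2 pp |
| aversion σ sweep | 10, 1, 0.5, 0.1, 0.05 | rad | spans directionless movement to directed fleeing |
| boundary radius | 75 or 100 | km | site-fidelity surrogate (hard reflecting wall) |

Heading SDs are taken to be radians (the natural unit of the wrapped
normal; the sweep values are dimensionless in their original usage).
Aversion is always-on while a responsive scenario runs — no
received-level trigger — because no response threshold is stated for
these scenarios; a dose-triggered response would mainly matter for
agents far from the source, whose exposure is small either way.  All
movement uses the species' typical swim speed: aversion biases the
heading distribution, it does not change gait.  For the
weighting-comparison scenario, which does not specify movement, both
packaged species are flagged as noise-responsive and use their default
aversion SDs (1.0 rad gray seal, 0.5 rad harbor porpoise — porpoises
show strong documented avoidance of industrial noise).

## The synthetic fixture and what it does (not) emulate

`disc_scenario()` builds the reference environment: a uniform-density
disc (0.05 animals/km², CV 0.3, radius 100 km, 5-km cells) centered on
the source over a flat 50-m seabed.  This reproduces the *idealized*
study conditions — uniform bathymetry, unbounded open water, a
population surrounding the source — and makes closed-form oracles
available (a stationary agent at 10 km accumulates exactly
180 + 10·log10(360) ≈ 205.56 dB in an hour at 10% duty).

It deliberately does **not** emulate: real density surfaces (which are
patchy, asymmetric, and extend over scales set by habitat, not by the
scenario); coastlines; depth-structured sound fields; or survey-driven
density estimation (density grids are inputs here, never estimated).
Consequences worth stating plainly:

- Absolute exceedance percentages depend strongly on the seeded
  surface.  On the 100-km uniform disc, M-weighted exceedance saturates
  far higher than assessments seeded from realistic, spatially extensive
  density maps; only orderings and zero rows are transferable.
- A hard boundary placed at the seeded disc's own edge barely binds for
  directionless movement (diffusion moves agents only ~11 km RMS in 10
  days at 1.5 m/s and dt = 60 s), so constrained-vs-unconstrained
  contrasts on this fixture are structurally smaller than when the
  unconstrained population extends far beyond the boundary.  The
  packaged audiograms are likewise synthetic, literature-shaped curves
  anchored at H(1 kHz) = 71/80 dB; filenames carry `_synthetic`.
- Because the sound field is range-only, diving affects realism but not
  SEL; the dive model is exercised and constrained (never below the
  seafloor) but contributes nothing to exposure totals.

Passing tests on this fixture therefore demonstrate the *mechanics* —
accumulation identities, propagation, weighting offsets, movement
statistics, paired-arm orderings and magnitudes of the movement effects
— not the absolute risk numbers any real assessment would produce.

## Numerical choices

- **Energy-domain accumulation with an NA sentinel**: avoids undefined
  dB arithmetic before first exposure; incremental accumulation matches
  a brute-force end-of-run energy sum to 10⁻⁹ dB.
- **Population curves average SELs in the dB domain**, and the shaded
  band is the empirical central 95% of agents (order statistics, a
  prediction band).  Averaging in the linear domain would shift curve
  levels by a dB or two but leaves paired differences essentially
  unchanged.
- **Reflection** at the hard boundary is specular in the radial
  component (range 2B − r, same bearing; heading mirrored about the
  local tangent).  Land proposals get up to 8 heading re-draws, then a
  reversed heading with no displacement.  Seeding respects boundary and
  land exactly (sub-cell jitter is reflected/recentered).
- **Snapshot thinning**: per-agent state is stored on a configurable
  `record_hours` grid (default 1, 6, 12, 24, 48, 96, 168, 240 h); the
  running accumulator is exact regardless.
- **Paired seeds**: arms of a comparison share the RNG seed and consume
  identical draw counts per step, so agents far from any constraint are
  *identical* across arms and dB differences carry far less Monte-Carlo
  noise than arm means (the sweep differences move by <0.1 dB across
  seeds at 2000 agents).
- **Near-field clamp**: ranges below the 1-m reference are clamped, so
  RL never exceeds SL.
- **Uncertainty intervals** (`risk_with_uncertainty()`) resample the
  density surface per cell from a mean-preserving lognormal
  (sdlog² = log(1+CV²)) and reseed agents with fresh derived seeds;
  CIs are 2.5/97.5 order statistics across realizations.  Movement and
  hearing parameters are held fixed — an extension hook, not a claim
  that they are certain.

## Problem sizes

The test suite runs most properties at 10²–10³ agents over hours; the
full study conditions (2000 agents, 240 h, dt = 60 s, paired seeds) are
exercised in the acceptance suite and by `scripts/acceptance.R`, where
each 10-day arm takes seconds to tens of seconds on one CPU.  The
default 10⁴-agent configuration matches the study scale and remains
desk-scale (minutes).

## Known limitations

Single fixed source and single tone (no multi-band accumulation, no
moving sources); no behavioral dose–response severity scaling beyond the
generic curve object; no pulsed-sound criteria or in-air pinniped
criteria; no population-consequence modelling; confidence intervals
propagate density and seeding uncertainty only.  These are scope
boundaries, not TODOs: each sits behind a small, documented interface
(`dose_response_curve()`, `sound_source()`, `risk_with_uncertainty()`)
where extensions can attach.

```{r example}
library(selrisk)
gs <- example_species("gray seal")
env <- disc_scenario()
cfg <- scenario_config(gs, env, n_agents = 2000, duration_h = 240,
                       scheme = "M", seed = 1)
sim <- run_simulation(cfg)
glance(sim)
autoplot(sim, threshold_db = pts_threshold(gs, "M"))
```
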