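---
title: "Models, mechanics and design choices in vesselgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, mechanics and design choices in vesselgame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselgame)
```

## The experiment this package mechanises

Keyhole surgery forces the surgeon to work from a small moving window onto
the anatomy. To measure how much a restricted field of view (FOV) by itself
costs in task performance, the underlying experiment uses an abstract
vessel-cutting game: locate the one vessel band marked by two black
endpoint circles and transect it with a short cut line, either with the
whole scene visible or through a circular spotlight that follows the
cursor. Seven fixed levels ramp difficulty (more vessels, intertwining,
limited FOV); levels 4/5 and 6/7 differ *only* in FOV, so their contrast
estimates the FOV effect. The measured outcomes are completion time
(timer runs from level start to the successful cut) and attempts (every
press–drag–release increments the counter, including the successful one).

This package implements the whole loop headlessly: scene generation, the
event-driven game mechanics, a simulated cohort, and the analysis pipeline.

## Scene generation

A vessel is a centerline stroked into a band:

* **Centerline** — `n_waypoints` (default 6) waypoints at equally spaced x
  positions spanning the full width; waypoint y = a common uniform base
  level plus uniform jitter (default half-width 35% of the vertical band),
  interpolated by a natural cubic spline sampled at 100 points and clamped
  to the band. With zero jitter the curve degenerates to a straight
  horizontal line, which the tests exploit.
* **Band** — offset the centerline by half the vessel width along normals
  from central differences, close with flat end caps. Because the caps pass
  through the centerline endpoints (the straight-segment stroke is exactly
  the bounding rectangle), the endpoints lie *on* the boundary; strict
  interiority of the centerline therefore holds for interior points only.
* **Intertwining** — formalised as the number of transversal centerline
  crossings. Intertwined levels rejection-sample full-band splines until
  every pair crosses at least `k_min = 2` times and every stroked ring is
  simple, capped at 200 retries (a cap breach raises a generation-failure
  error and signals an infeasible configuration). Non-intertwined levels
  with several vessels get disjoint horizontal bands, which guarantees zero
  crossings by construction.

Nothing about canvas size, vessel width, marker radius or spotlight radius
was ever published; the defaults (800×600 units, width 14, radius 8,
spotlight 100) were chosen once so that the one published constant — the
45-unit cut cap — comfortably transects a single vessel, and all are
configurable through `run_config()`. Colours are deliberately low-contrast
reds (a design feature of the original, emulating poor illumination); the
palette is a parameter, not an invariant, since display tuning is an open
question in the source experiment.

All randomness flows from the single `seed` argument; the same
`(level, seed)` serializes to byte-identical JSON.

## Game mechanics

`apply_event()` consumes time-stamped pointer events. `move`/`drag` move
the cursor (and the spotlight, whose centre the cursor is); `press` opens a
line; `drag` extends it, with the end pulled back onto the 45-unit circle
around the start whenever the gesture overshoots (clamping rather than
rejecting keeps success reachable mid-gesture); `release` closes the line,
increments the attempt counter, and evaluates the cut. On success the timer
freezes; later events are ignored rather than rejected, matching a human
finishing a gesture after the win message appears.

**Cut semantics.** A line cuts a vessel iff both endpoints are strictly
outside the band polygon and the open segment passes through its interior
— the "entered and exited" reading of completely intersecting both sides.
The implementation computes exact crossing parameters against the polygon
edges and classifies inter-crossing midpoints by even-odd point-in-polygon;
the test suite checks it against an independent winding-number
rasterisation oracle on 2,000 random band/segment cases. Whether the
original game counted a cut exiting through a vessel's flat *end cap* is
unknown; by default it counts (`strict_sides = FALSE`), and
`strict_sides = TRUE` additionally requires crossings of both long sides.

Attempts count every release, including the successful one — the published
mean attempt counts are all ≥ 1, which supports that reading. Wrong-vessel
cuts are recorded (`cut_vessel_index`) but carry no penalty beyond the
failed attempt; negative scoring is explicitly future work in the source
experiment. A minimal "paint" mode (`reveal()`) emulates computational
mosaicking by making previously seen discs permanently visible.

## The simulated cohort

The paper contains no behavioural model, so the generator is the simplest
structure that reproduces its two findings:

$$\log T_{pl} = \alpha_{l} + \beta_{fov}\,[\text{limited}] + u_p +
\varepsilon_{pl}, \qquad u_p \sim N(0, \tau^2),\
\varepsilon_{pl} \sim N(0, \sigma^2)$$

with attempts \(1 + \mathrm{Poisson}(\lambda)\), independent of FOV.
Defaults, fixed once:

| parameter | default | rationale |
|---|---|---|
| `alpha_level` | calibrated | noiseless means equal the published per-level means (5.7, 3.3, 7.2, 6.4, 12.5, 9.8, 16.4 s) |
| `beta_fov` | log(12.5/6.4) ≈ 0.669 | log ratio of the matched pair 4/5 |
| `sigma` | 0.35 | published per-level CVs of ~0.4–0.7 imply a total log-SD near 0.46; split with `participant_sd` |
| `participant_sd` | 0.30 | between-participant share of that spread |
| `lambda_err` | 0.5 | mean attempts 1.5, inside the published 1.2–1.8 range |

Poisson (shifted by one) was preferred over geometric for attempts purely
for simplicity. What the generator deliberately does **not** model: the
learning effect the study observed between levels 1 and 2, fatigue, or any
FOV effect on attempts. A green simulation test therefore establishes that
the pipeline recovers effects from this stated world — not that human data
look like this in every respect.

`estimate_fov_effect()` estimates β from the matched pairs as the
per-participant mean of log-time differences (limited − full), with a
one-sample t interval. That estimator is unbiased only when paired levels
share the same baseline apart from FOV; note the *published* pair means do
not satisfy this for 6/7 (16.4/9.8 exceeds the 4/5 ratio), so the
parameter-recovery tests generate cohorts with matched baselines
(α₄ = α₅, α₆ = α₇) — the design intent of the pairs — rather than the
Table-calibrated defaults.

The mechanistic `agent_play()` produces event streams that replay to
success: under full FOV it moves straight to a planned transection; under
limited FOV it sweeps the scene boustrophedon with row stride below the
spotlight radius until both black markers have been seen, so its locate
time scales with scene area over spotlight area. Its motor parameters
(speeds, reaction time, aim noise) are configuration, not science.

## Statistics

* Summaries: mean, sample SD (n−1), t-based 95% CI; report formatting
  rounds to 1 dp, matching the published tables (the CI uses the t
  quantile, not z — this is what reproduces the printed bounds).
* Welch test from summary statistics with Satterthwaite df; two-sided p
  throughout. No multiple-testing correction, mirroring the two planned
  comparisons of the source study.
* Cohen's d uses the equal-n pooled denominator √((s₁²+s₂²)/2); the source
  never states its formula, and this choice reproduces its printed 0.79
  for levels 6/7 to within rounding of the printed inputs.
* `required_n()` searches n upward using the exact noncentral-t power of
  the two-sided two-sample t test. For d = 0.79 at 80% power it returns
  27: the non-integer solution is 26.14, and the smallest integer n whose
  exact power reaches 0.80 is 27 (power at 26 is 0.7977). Simulated power
  at the returned n confirms ≥ 0.80.
* p values format journal-style (".009", "<.001" below 0.001).

Known irreproducibilities, documented rather than reconciled: the source's
printed d = 1.19 and p = .009 were evidently computed from raw
(unpublished) data — the printed summary statistics give 1.31 and .0096 —
and its abstract quotes a 13.6 s mean matching no table row. The package
asserts only quantities that are arithmetic on the printed summaries.

## Numerical choices and edge cases

* Geometry tolerances: 1e-9 for degeneracy (parallel segments, duplicate
  points), 1e-7 for strict inside/outside classification against polygon
  boundaries. Zero-length cut lines cut nothing.
* Crossing counts use orientation tests with a bounding-box prefilter; the
  brute-force oracle in the tests solves each segment pair's 2×2 system
  instead.
* Degenerate inputs raise typed conditions (`vg_invalid_level`,
  `vg_degenerate_geometry`, `vg_protocol_error`, `vg_config_error`,
  `vg_schema_error`, `vg_validation_error`, ...), so callers and tests can
  match on class rather than message.
* Scene/event/report serialization uses full-precision JSON
  (`digits = NA`); determinism tests compare bytes.
* Trial CSVs store seconds at full precision; reports round only at the
  formatting layer.

## Limitations

* The procedural vessel shapes match the published screenshots only in
  character (wavy, window-spanning, intertwined), not in detail.
* The agent is a test instrument, not a cognitive model; its times should
  be compared between FOV conditions, not to human seconds.
* The interactive front end is out of scope; the engine's event API is the
  integration point for one.
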