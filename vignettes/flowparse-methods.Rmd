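---
title: "Model and methods: competitive-dynamics flow parsing in MT/MST"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: competitive-dynamics flow parsing in MT/MST}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model, its assumptions, the parameters that matter, the numerical
choices, and what the simulations do and do not show.

## The computational problem

A translating observer sees a radial optic-flow field whose singularity
(the focus of expansion, FOE) marks the heading. The retinal motion of an
independently moving object is the vector sum of its world-relative motion
and the local self-motion flow; recovering the world-relative motion
requires estimating the global pattern and discounting its local
contribution — *flow parsing*. Because motion parallax ties retinal speed
to depth, the amount to discount depends on the scene's depth structure,
which is exactly what the three simulated stimulus families vary:
a frontoparallel dot plane (no depth variation, monocular), a ground plane
(continuous monocular parallax), and a stereo wire-frame cloud (parallax
plus binocular disparity).

The psychophysical reference experiments place the probe so that its
object component is perpendicular to its self-motion component, and report
the flow-parsing gain, the fraction of the self-motion component removed
from the perceived direction. `flow_parsing_gain()` converts a decoded
angular shift into that gain through the residual-component formula; a
gain of 1 corresponds to a shift of `atan(c/o)`.

## Architecture

The pipeline per input frame is:

1. **Stimuli** (`gen_frontoparallel()`, `gen_ground()`, `gen_cloud()`,
   `rasterize()`). Stimuli are parameterized directly by the printed
   retinal quantities (component speed at the probe, eccentricities,
   optical speeds) rather than by screen geometry, so those values hold
   exactly. Dots are limited-lifetime texture elements: fixed positions
   sampling a stationary analytic velocity field. The field is rasterized
   to a 64×64 grid (cell = FOV/64 = 0.625°) by nearest-cell assignment
   with within-cell averaging; the probe occupies the cells within its
   1° diameter.
2. **MT Layer 4/6** (`mt_encode()`): separable circular-Gaussian direction
   tuning (24 preferences, σ = 45°), log-Gaussian speed tuning (5
   preferences, σ = 1 octave) and Gaussian disparity tuning (5
   preferences spanning the display's disparity range), multiplied, with a
   binocular response gain decreasing from 2.2 (nearest preference) to 1.6
   (farthest); 1 for monocular input.
3. **MT+ and depressing synapses** (`mt_plus_drive()`, `mt_plus_step()`,
   `depress()`): Gaussian receptive-field integration of like-tuned
   activity (radius 2 cells, unit centre weight, unnormalized — coherent
   full-field motion drives MT+ above the single-cell response), a leaky
   integrator (α = 20/s), and per-connection efficacy with recovery
   τ = 0.5 s and depletion rate 0.3, which attenuates tonic signals.
4. **MSTd templates** (`template_bank()`, `feedforward_drive()`): radial
   templates `Π = (x−i, y−j)` at every fourth grid position (16×16
   singularities), distance-weighted by `1/(1 + r/r0)` with `r0 = 32`
   cells; band-pass units keep one speed channel, speed-summating units
   average channels, gradient units couple eccentricity-ring quintiles to
   speed preferences (increasing and decreasing variants), and ground
   units use the half-field pattern `|y−j|·(x−i, y−j)` with speed
   quintiles of the ground pattern. Template matches are normalized
   cross-correlations over the stimulated cells, which makes the drive a
   per-input match quality, invariant to dot density and grid resolution
   (the ground family is normalized by its expected mass at the display's
   occupancy rate, so an empty region below a candidate horizon counts
   against it, and the horizon constraint — stimulation *above* a
   candidate horizon, or *upward-moving* stimulation below it, neither of
   which ground flow can produce — vetoes the ground interpretation in
   proportion to `ground_veto`).
5. **Recurrent competition** (`recurrent_step()`): shunting network with
   broad divisive inhibition (population mean scaled by ω = 30) and a
   faster-than-linear recurrent term `β A²` (β = 60) gated by an
   engagement threshold on the unit's feedforward input
   (`theta_eng = 1.15` per unit input gain). Every activity is bounded by
   the ceiling `B = 1`; engaged winners approach it.
6. **Feedback** (`compose_feedback()`): the single most active MSTd unit
   suppresses MT−/MSTv units that locally match its template: Gaussian
   mismatch weights in direction (σ = 45°) and log speed (σ = 1 octave)
   around the locally prescribed motion, a Gaussian distance falloff
   (σ = 5 cells) from the winner's singularity, scaled by the winner's
   activity (gain 500 to MT−, 1/20 of that to MSTv). The prescribed speed
   is the winner's mean-pattern-speed estimate (the activity-weighted mean
   of the band-pass column at its singularity, or its own preference)
   scaled by the template's eccentricity profile; in stereo runs the
   prescribed speed follows the congruent speed–disparity diagonal of
   motion parallax, so slow-and-far combinations are suppressed more than
   slow-and-near ones.
7. **MT−/MSTv and readout** (`mt_minus_step()`, `mstv_step()`,
   `population_vector()`): on-centre/off-surround shunting with
   feedforward surround inhibition from similarly tuned Layer 4/6
   neighbours (strength 4, radius 3 cells), speed-summating pooling into
   MSTv, and a population-vector decode over the probe's cells. The run
   continues with the final input held until the decoded direction stays
   within 1° for five frames (`stabilization_check()`), with a 3 s cap.

## Numerical scheme

Each input frame is integrated for ten Euler substeps (≈3.3 ms at
30 frames/s). The shunting updates use the semi-implicit (Patankar) form
of the Euler step — gain terms explicit, loss terms implicit — which has
the same fixed points as the explicit update and is unconditionally
stable; with the calibrated feedback strengths the explicit form would
need a far smaller step. The MSTd feedforward matching is evaluated once
per frame and held across that frame's substeps (its inputs change on the
MT+ integrator's 50 ms timescale, much slower than a substep). MT−/MSTv
are integrated on a probe-centred patch; this is exact because their
dynamics are per-cell feedforward given the (full-field) Layer 4/6 and
MSTd signals. Template inner products and the MT+/depression substeps are
compiled (Rcpp); everything else is vectorized R.

Degenerate inputs: cells without stimulus have zero activity everywhere;
zero-speed vectors have undefined direction and produce no response; the
template vector vanishes at the singularity (and along a ground template's
horizon row), so those cells neither drive templates nor receive
prescribed suppression. Winner ties break to the lowest linear index
(band-pass, speed-summating, gradient increasing/decreasing, ground; then
row-major singularity position).

## Calibration and the free parameters

The tuning-curve families, the shunting form of the dynamics and the
Euler-with-substeps scheme are fixed by the model family; the constants
are calibration parameters exposed in `fp_control()`. They were fitted
once against the published human benchmarks (ground-plane gains of 84%
and 72% at 2° and 4° probe eccentricity, frontoparallel gains declining
into a 0.30–0.40 band at fast self-motion speeds, a ground-plane MSTd
peak ≈33% above the best frontoparallel peak, and a stereo shift
trajectory plateauing near 150 ms) and then frozen as package defaults.
The qualitatively load-bearing choices:

* **Engagement threshold** (`theta_eng`): set so that only the stereo
  cloud — through the disparity-dependent gain — recruits the recurrent
  mechanism; disabling `stereo_gain` reverts the cloud to the monocular
  outcome. The ground family's threshold carries a 1.6 ceiling factor
  because its expected-mass normalization runs hotter per unit gain.
* **Feedback speed falloff** (`fb_speed_sigma_oct = 1`): the knob that
  governs the decline of frontoparallel gains with self-motion speed. At
  fast speeds the winner's mean-speed estimate saturates at the top of
  the MT speed-preference range, the prescribed speed underestimates the
  true component, and suppression misses the probe's speed channels.
  A broader falloff removes the decline; a narrower one collapses the
  slow conditions.
* **Feedback distance falloff** (`fb_dist_sigma = 5` cells): produces the
  2°-versus-4° eccentricity ordering of the ground-plane gains.
* **MSTv feedback share** (`fb_gain_v = fb_gain/20`): the direct
  MSTd→MSTv field is speed-averaged, hence unselective; giving it a large
  share washes out the speed selectivity of the suppression.
* **Ground speed preferences**: matched to the quintile medians of the
  ground-flow speed distribution (geometric mean over the two translation
  speeds), so the eccentricity rings of a true-horizon template are
  congruent with the speed preferences; without this the estimated
  horizon drifts upward.

## What the simulations show — and what they do not

The synthetic displays reproduce the *retinal* content of the reference
experiments (component speeds, eccentricities, depth ranges, masks,
probe timing) under idealized conditions: noise-free analytic flow,
point-sampled texture, no eye movements or rotational flow, no
accommodation or vergence cues, a fixed 40° field. Passing tests
therefore show that the mechanism — selectivity-dependent feedback
suppression — accounts for the pattern of human gains across depth-cue
conditions; they do not show robustness to measurement noise, natural
image statistics, or combined translation–rotation flow, all of which are
outside the model's scope. Model runs are deterministic single runs; the
only randomness is dot placement, and the reported quantities are stable
across placement seeds at the default dot counts (300 dots; 60 cubes ×
8 vertices).

Known limitations: the frontoparallel 2 deg/s-object conditions
overestimate the shift at moderate speeds (the documented over-suppression
of much-slower-speed channels); the monocular gains at the slowest speeds
run below the human means while the orderings and the graded quantities
are preserved; and the Table-style unit counts treat the
increasing/decreasing gradient variants as sharing the per-position
budget. The reduced 32×32 mode (with proportionally scaled radii) is for
fast testing; calibrated quantities are evaluated at 64×64.
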