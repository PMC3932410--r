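---
title: "Dynamic form analysis by reliability-weighted cue integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic form analysis by reliability-weighted cue integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynform)
```

## The model in brief

`dynform` simulates direction discrimination of two sparsely sampled dynamic
forms — an articulated point-light-style walker (leftward/rightward) and a
rigid rotating square (clockwise/counter-clockwise) — and explains the
percept with a two-module probabilistic template-matching observer.

Stimuli are *element tables*, not pixels: on every frame, a handful of
oriented Gabor elements is sampled afresh along the figure's segments
(one-frame limited lifetime), so local motion energy is uninformative and
only sequential form remains. Element orientation can be **congruent** with
the sampled segment, **incongruent** (taken from the nearest segment of the
opposite-motion stimulus), or **randomized**.

The observer stores K probabilistic key-frame templates per hypothesis with
position spread `sigma_Tp` and orientation spread `sigma_Ttheta`. Per frame,
a position module and an orientation module each select their MAP template
within every hypothesis, produce a posterior over the two hypotheses, and
are combined by Bayesian model averaging with weights

$$w_p = \frac{\alpha\,\sigma_p^{-2}}{\alpha\,\sigma_p^{-2} + \sigma_\theta^{-2}},
\qquad w_\theta = 1 - w_p,$$

where $\sigma_p$ and $\sigma_\theta$ are the observer's low-level cue
reliabilities and $\alpha$ — the ratio of module prior probabilities — is
the single free parameter, fitted to behavioral proportions by least squares
(`fit_alpha()`). Walker decisions sum integrated posteriors over frames;
square decisions weight MAP-index transitions by their consistency with each
rotation order (Gaussian sequence weight, SD `sigma_s`, default
$\sqrt{3.6}$ index units).

The weight formula is a reconstruction: we read "reliability determines the
likelihood terms" plus "prior biases favor position cues" as inverse-variance
weighting with $\alpha$ multiplying the position precision. It reproduces
every qualitative constraint of the behavioral pattern (spatial-frequency,
element-count and envelope-size effects) and makes $\alpha$ absorb the unit
mismatch between the two reliability scales, which is what lets the fitted
values land in the plausible 4–8.5 range.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `alpha` | — | fitted (4.25–8.5 plausible) | prior bias toward the position module |
| `sigma_p` | task units | per condition (1.6–8.5) | position cue reliability from the low-level task |
| `sigma_theta` | degrees | per condition (1.7–13) | orientation cue reliability |
| `position_unit` | deg/unit | 0.05 | converts position reliabilities to degrees for encoding/matching |
| `sigma_s` | template indices | `sqrt(3.6)` | sequence-selectivity bandwidth (square only) |
| `prior` | probability | 0.5 | direction prior |
| `K` | templates | 8 | key frames per bank (robust 4–16) |
| `sigma_floor` | degrees | `1e-3` | lower bound on template spreads |

**The position-unit decision.** The position-discrimination task reports
spread parameters of 1.6–8.5 although its offsets span only ±0.67°, so those
values cannot be degrees; they behave like display pixels (~20 px/deg at a
35 cm viewing distance, i.e. 0.05 deg/unit — on that conversion the stored
template spread of "8 pixels" also lands near our recomputed walker value).
We therefore use the raw task-unit values inside the integration weights,
where $\alpha$ absorbs any residual scale error, and convert by
`position_unit` wherever a physical magnitude is needed: encoding noise
injected into observed positions and the likelihood width
`sigma_Tp^2 + sigma_p^2`. This is a deliberate split, not an oversight; it
keeps fitted $\alpha$ values on the scale on which they are interpretable.

**Template spreads are data-driven.** `sigma_Tp` is the largest directed
point-to-shape distance between cyclically neighbouring templates (100
sample points per segment, endpoints included — resolution far below any
decision-relevant scale); `sigma_Ttheta` is the largest orientation change
of corresponding segments. With the default sequences these come out at
`r round(build_template_bank(make_walker_sequence(), 8)$sigma_tp, 2)`° /
`r round(build_template_bank(make_walker_sequence(), 8)$sigma_ttheta, 1)`°
for the walker and
`r round(build_template_bank(make_square_sequence(), 8)$sigma_tp, 2)`° /
`r round(build_template_bank(make_square_sequence(), 8)$sigma_ttheta, 0)`°
for the square.

**Symmetry and the square's template bank.** A square is invariant under
quarter turns, so a 360° rotation shows the same image four times. Template
banks therefore subsample one *symmetry period* (15 frames at 6°/frame),
never the full rotation: sampling the full cycle would store four duplicates
of each image, make the MAP template index ambiguous among them, and destroy
sequence selectivity outright (we verified this empirically — every square
condition collapses to chance). With period-based banks the 8 templates are
11.25° apart and the orientation spread computes to 12°, which is also the
only reading consistent with the stored-template spread reported for this
class of model. Orientation changes across the period wrap are folded by the
square's 90° orientation symmetry for the same reason. The walker has no
such symmetry; its period is the full gait cycle.

## The synthetic-data generator

The generator is the package's study design, not a test dial:

- **Stimuli.** 60-frame cycles, ~9° vertical extent; walkers sample 2/4/6
  distinct limb segments per frame (uniformly without replacement, uniform
  position along each limb), squares 4/6/8 points on edges with
  replacement — matching the different sampling rules of the two stimulus
  classes. Condition grids: 3 orientation conditions × 3 spatial frequencies
  × 3 element counts (single-kind design) and the 4 × 3 × 2 × 2 = 48-cell
  incongruent design with carrier frequency doubled in the half-size
  envelope so orientation bandwidth (hence `sigma_theta`) is equated.
- **Walker kinematics.** In place of motion capture, a sinusoidal joint-angle
  model (per-joint mean, amplitude, phase, integer harmonic — guaranteeing
  exact periodicity) drives the standard 9-segment stick figure: upper/lower
  arms and legs plus a mid-shoulder-to-head torso, 11 joints in all. The
  hip stays at x = 0, so the walker steps in place; the rightward walker is
  the exact mirror of the leftward one. A CSV joint-trajectory loader
  (`read_joint_trajectories()`) accepts real motion-capture traces.
- **Observers.** The packaged reference table provides seven observers'
  reliabilities (orientation spread decreasing in sf; position spread
  smaller for the small envelope) and their fitted biases; synthetic cohorts
  mirror those rows. Every generated dataset carries a ground-truth sidecar
  (`truth.json`) with all generating parameters, and identical specs yield
  byte-identical files.
- **Low-level tasks.** 2AFC simulators draw `offset + N(0, sigma^2) > 0`
  with eight offset levels within ±20° (orientation) or ±0.67° (position);
  by default offsets adapt to the noise level (±2.5 sigma, clipped), the
  same design logic as adapting offsets per spatial-frequency condition.

What the generator does *not* emulate: lapses, learning, sequential
dependencies, pixel-level rendering, or biomechanically realistic gait.
Passing tests therefore show that the pipeline is internally consistent and
that the estimator recovers known parameters under the model's own
assumptions — not that the model fits any particular human dataset.

## Numerical choices

- All scoring runs in the log domain; the two-hypothesis posterior is a
  stable logistic of the MAP score difference. Within each hypothesis the
  MAP template (not a sum over templates) carries the evidence, and
  probability-sum (not log-sum) temporal pooling is the default.
- Cyclic quantities use signed shortest displacements: template-index steps
  fold into `(-K/2, K/2]`, orientations into `[0, 90]` after mod 180.
- The square's sequence weight multiplies the *mean* of the two flanking
  frames' max integrated posteriors. Weighting only the current frame would
  break exact time-reversal antisymmetry (the step looks backwards, the
  multiplier forwards); the symmetric form makes a time-reversed trial swap
  the two aggregates to machine precision, which is the behavior the
  symmetry suite asserts.
- Exact decision ties flip a fair coin from a dedicated seeded stream; every
  stochastic component (sampling, orientation offsets, encoding noise, truth
  assignment, tie-breaks) draws from its own stream derived from one master
  seed, so element positions are identical across orientation conditions
  built from the same sampling draw.
- Degenerate inputs fail loudly with classed errors: non-periodic gaits,
  oversampled walkers (n > 9), empty frames, sub-2-frame square decisions,
  offsets beyond the task ranges, non-positive reliabilities, missing
  profile entries. Identical templates floor their spread at `sigma_floor`;
  degenerate psychometric data (separation, flat responses) are flagged and
  clamped, never silently fit.
- `fit_alpha()` evaluates a deterministic objective: per-cell module
  evidence is simulated once at a fixed derived seed and cached (alpha only
  enters through the weights), then a log-spaced grid (2^-2..2^5) with local
  refinement minimizes the summed squared discrepancy. Common random numbers
  keep least squares meaningful on a simulated objective.

## Problem sizes

The test-suite and acceptance-script sizes are the package's validation
design: trade-off curves at 1000 trials per cell over the 48-cell grid;
bias recovery at 200 observed and 400 simulated trials per cell, five
replicates per generating value (4.25, 6.25, 8.5), using the reference
observer whose reliability ratios `(sigma_p/sigma_theta)^2` span 0.16–14 and
therefore bracket the whole plausible alpha range (the most informative
design for identifiability); psychometric closed loops at 24 and 200 trials
per level. Recovery errors run about 2–5% at these sizes, far inside the
±20% validation band.

## Known limitations

- Proportions in many walker cells saturate at 0 or 1: with 60 frames of
  independent resampling, the aggregate posterior concentrates, so the
  model's psychometric surface is steep in alpha near each cell's
  `(sigma_p/sigma_theta)^2` threshold and flat elsewhere. Identifiability
  comes from cells whose thresholds straddle the fitted value — another
  reason the validation design uses the observer with the widest threshold
  spread.
- The walker's gait is stylized; only its articulated, semi-rigid, periodic
  character matters to the model, not biomechanical fidelity.
- Orientation mirror arithmetic (`180 - theta` mod 180) is exact only to
  floating-point rounding of the subtraction, so mirrored decisions are
  asserted as exact flips of the discrete choice, not of the real-valued
  aggregates.
- Human-data quantities (ANOVA effects, the human-model correlation) are
  out of scope: they require behavioral data this package does not ship.
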