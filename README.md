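# dynform

Bayesian integration of position and orientation cues in dynamic form
analysis.

## The scientific problem

When a moving shape — a point-light walker or a rotating square — is shown
only as a sparse, flickering cloud of oriented Gabor patches, two form cues
carry the percept: the **positions** of the elements (where the shape's
boundary was sampled) and their **orientations** (the local tangent the
carrier grating implies). With one-frame limited-lifetime sampling, element
positions are redrawn on every frame, so local image motion is useless and
perception must rest on sequential global form. When the two cues are put in
conflict — element positions sampled from a leftward walker but orientations
taken from the nearest limbs of the rightward (mirrored) walker — observers
trade off between them according to the *reliability* of each cue: high
carrier spatial frequency makes orientation dependable and flips the percept
toward the orientation-defined direction; small Gabor envelopes make position
dependable and pull it back.

`dynform` implements, end to end, an ideal-observer account of that
trade-off, for both a biological stimulus (an articulated walker) and a
non-biological one (a rigid rotating square), with tools to simulate the
psychophysics, fit the model's one free parameter, and validate everything
against synthetic data with known ground truth.

## The model

Each dynamic form is stored as K = 8 probabilistic key-frame templates with
Gaussian spread: position templates `T_p ~ N(C_p, sigma_Tp^2)` and
orientation templates `T_theta ~ N(C_theta, sigma_Ttheta^2)`, the spreads
estimated from the largest change between neighbouring templates. Two
modules score every stimulus frame against every template:

- **position module** — for elements at observed positions `x_p`, each
  template k scores `sum_i log N(d_ik; 0, sigma_Tp^2 + sigma_p^2)` where
  `d_ik` is the distance from element i to the nearest point of template k's
  segments;
- **orientation module** — each element is associated with the positionally
  nearest template segment and scores the folded circular difference
  `delta_ik` between observed and template orientation under
  `N(0, sigma_Ttheta^2 + sigma_theta^2)`.

Within each module the MAP template per direction hypothesis yields a
posterior over the two directions (prior `P(L) = 0.5`), and the module
posteriors are combined by Bayesian model averaging,

```
P_int(L) = w_p P_p(L) + w_theta P_theta(L),
w_p = alpha sigma_p^-2 / (alpha sigma_p^-2 + sigma_theta^-2),
```

where `sigma_p, sigma_theta` are the observer's low-level cue reliabilities
(measured with 2AFC position/orientation discrimination tasks fitted by
cumulative Gaussians) and `alpha`, the ratio of module prior probabilities,
is the model's **single free parameter**. Walker decisions sum `P_int`
across the 60 frames. Square decisions add sequence selectivity: both
rotation directions share one template bank, so each transition of the MAP
template index is weighted by `exp(-(step -/+ 1)^2 / (2 sigma_s^2))`
(`sigma_s^2 = 3.6`) before aggregation, selecting the hypothesis whose
temporal order the index sequence follows.

`fit_alpha()` estimates `alpha` by least squares between model and observed
position-consistent proportions over the 48-cell design (4 spatial
frequencies x 3 element counts x 2 envelope sizes x 2 stimulus kinds,
incongruent cues), using common random numbers so the objective is
deterministic.

## Worked example

```r
library(dynform)

profile <- fixture_profile(3)        # reference observer 3's reliabilities
profile
#> <reliability_profile> (fixture)
#>   sigma_theta (deg): low=12.2 med-low=6.2 med-high=3.34 high=2.27
#>   sigma_p (task units): large=8.49 small=4.86

# at high sf this observer weights orientation strongly even with alpha = 6
integration_weights(observer_params(alpha = 6, sigma_p = 8.49, sigma_theta = 2.27))
#>       w_p   w_theta
#> 0.3001762 0.6998238

# ... and the percept reverses: no responses follow the position direction
grid <- condition_grid(2)
cond <- grid[grid$kind == "walker" & grid$sf_level == "high" &
             grid$n_elements == 2 & grid$size_level == "large", ]
run_condition(cond, observer_params(alpha = 6), profile, n_trials = 200, seed = 1)
#>     kind orientation_condition sf_level n_elements size_level n_trials
#> 1 walker           incongruent     high          2      large      200
#>   prop_position_consistent se
#> 1                        0  0

# closed loop: synthesize behavior at alpha = 6.25, then refit alpha
spec <- synthetic_observer(profile, alpha = 6.25, n_trials = 100, seed = 1)
dat  <- generate_behavioral_dataset(spec)
fit  <- fit_alpha(dat$summary, observer_params(alpha = 1), profile,
                  n_sim_trials = 200, seed = 2)
summary(fit)
#> Position-bias fit (two-module Bayesian observer)
#>   alpha = 6.392   RMS = 0.0314   (48 conditions, 200 sim trials/cell)
#>   model-observed correlation r = 0.998
#>   per-kind RMS: square=0.0145  walker=0.0419
```

The fitted `alpha = 6.39` recovers the generating 6.25 to within ~2%; the
RMS of 0.031 sits at the binomial noise floor of 100-trial cells. `plot(fit)`
shows the least-squares objective over the alpha grid and the
observed-versus-predicted proportions.

## Package layout

- `R/sequences.R`, `R/templates.R` — walker/square segment sequences,
  opposites, probabilistic template banks.
- `R/sampling.R` — limited-lifetime Gabor sampling, cue conditions,
  encoding noise.
- `R/observer.R` — the two-module Bayesian observer; `src/score_kernel.cpp`
  holds the frame-scoring kernel.
- `R/psychometrics.R` — cumulative-Gaussian fits, 2AFC task simulators,
  reliability profiles (reference observers in `inst/extdata/`).
- `R/experiment.R` — condition grids, batch simulation, `fit_alpha()` and
  its methods, fit metrics.
- `R/synthetic.R` — ground-truth synthetic datasets and cohorts.
- `vignettes/dynamic-form-analysis.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical decisions, limitations.
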