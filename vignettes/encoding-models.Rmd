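---
title: "Bimanual curl-field adaptation: simulation, metrics and encoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bimanual curl-field adaptation: simulation, metrics and encoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(curladapt)
library(dplyr)
```

## The paradigm

curladapt analyses (and simulates) a class of bimanual force-field
adaptation experiments. A participant makes simultaneous planar reaching
movements with both hands. The left hand is perturbed by a
velocity-dependent curl force field — but the field is driven by the
velocity of the *right* hand:

$$
\begin{pmatrix} F_x \\ F_y \end{pmatrix}
= \begin{pmatrix} 0 & -B \\ B & 0 \end{pmatrix}
\begin{pmatrix} \dot x_\mathrm{right} \\ \dot y_\mathrm{right} \end{pmatrix},
\qquad B = 13\ \mathrm{N\,s/m}.
$$

For a forward reach ($\dot y > 0$) the field pushes the left hand leftward.
Adaptation is probed with interleaved *error-clamp* (channel) trials: a
stiff virtual wall (stiffness 6000 N/m, damping 20 N s/m) confines the left
hand to a straight path, and the lateral force the participant presses into
the wall is the feedforward, predictive compensation they have learned.

Each hand's reach is *slow*, *medium* or *fast* — 15, 20 or 25 cm in the
same nominal 700 ms, so desired peak speeds are 45, 60 and 75 cm/s with a
±10% compliance band. Crossing the three left-hand with the three
right-hand speed classes gives nine bimanual conditions (`b_sf` = slow
left, fast right, …); three unimanual conditions (`u_s`, `u_m`, `u_f`)
move only the left hand. Two training regimes differ in what they reveal
about the field: the **evident** group trains on `b_sf`, `b_mm`, `b_fs`
(mismatched hand speeds expose the dependence on the right hand), the
**ambiguous** group on `b_ss`, `b_mm`, `b_ff` (matched speeds hide it).

The question the analysis answers is: *which state did the motor memory
get keyed to* — the velocity of the perturbed (left) hand, of the driving
(right) hand, or a mixture?

## The encoding models

On channel trials the measured lateral force $F(t)$ is regressed, by least
squares, against four candidate encodings of the two hands' forward
velocities, each scaled by the field gain $B$:

* **right**: $F = \alpha\, B\, \dot x_\mathrm{right}$
* **left**: $F = \alpha\, B\, \dot x_\mathrm{left}$
* **average**: $F = \alpha\, B\, (\dot x_\mathrm{left} + \dot x_\mathrm{right})/2$
* **weighted**: $F = \alpha\, B\, \big(\omega\, \dot x_\mathrm{right} +
  (1-\omega)\, \dot x_\mathrm{left}\big)$

$\alpha$ is the compensation gain (1 = full adaptation) and $\omega$ the
encoding weight (1 = pure right-hand encoding, 0 = pure left-hand,
0.5 = average). $\omega$ starts at 0.5 and is unrestricted in the
optimization; $\alpha$ starts at 1. The one-parameter models have exact
through-origin solutions; the weighted model is minimized with BFGS and
analytic gradients (relative objective tolerance 1e-8).

Model evidence uses the Gaussian least-squares BIC,
$n \ln(\mathrm{SSE}/n) + k \ln n$, reported as the improvement over a
zero-parameter reference model. That reference is a fixed gain — the mean
fitted $\alpha$ across the four parametric models and all participants —
applied to the right-hand velocity. The functional form of this reference
is a design choice of this package: the right-hand encoding is the true
force-field relation, so a fixed-gain version of it is the natural
"no-free-parameters" baseline (a published pooled gain of 0.822 can be
supplied as an override via `nonparametric_reference(alpha = )`). $R^2$ is
computed per fit as $1 - \mathrm{SSE}/\mathrm{TSS}$ (TSS about the mean)
and summarised per participant, then averaged.

Fits are per participant on **condition-averaged** aligned profiles (one
mean profile per trained condition in the generalization phase). This
matches the convention of averaging channel-trial forces within condition
before comparing them with predictions; per-trial fitting is available by
passing un-averaged profiles (e.g. `fit_weight_trajectory()` fits per-trial
profiles in 96-trial windows).

### Identifiability

When the two hands' velocity profiles coincide (the ambiguous group's
trained conditions), all four models span the same force predictions and
$\omega$ is unidentifiable. The weighted fit detects this by profiling the
optimal-gain SSE over $\omega \in [0, 1]$: if the relative change is below
1e-6 (measured against the larger of the SSE level and a round-off floor
proportional to signal power), the fit is returned with an
`identifiable = FALSE` flag and a classed warning. In practice even
"matched" conditions carry a little identifying signal — a small temporal
lead of the dominant hand and trial-to-trial speed variability — which is
exactly what lets a weighted fit on ambiguous-group data move off 0.5.

## Signal conditioning

Channel-trial forces are processed the way force-channel studies
conventionally do:

1. **Filtering**: 5th-order Butterworth low-pass, 40 Hz cut-off, applied
   forward and backward (zero phase). The implementation pads the series by
   odd reflection (up to 500 samples) before the two filter passes so that
   edge transients from uninitialised filter states do not leak into the
   window of interest; DC gain is 1 to within 1e-9.
2. **Drift correction**: the mean lateral force from 200 to 150 ms before
   movement onset is subtracted. Onset is the first sample at which left
   hand speed exceeds 5% of the trial's peak speed (the threshold is a
   package choice, configurable).
3. **Alignment**: the force profile is clipped to ±400 ms around the
   reference hand's peak speed — the right hand in bimanual trials, the
   left hand in unimanual trials (801 samples at 1 kHz). Ties in peak
   speed break to the earliest sample. Windows that overrun the recording
   are padded with the boundary value and flagged; fits exclude padded
   samples.

**Peak force** is the mean force over a 20 ms window around the profile
centre. We read "a window of 20 ms around peak velocity" as a *total*
width of 20 ms (±10 ms); the ±20 ms alternative is available through
`peak_force(window_ms = 40)`.

**Force compensation** is 100 × the slope of a regression of measured
force on the perfect-compensation profile $+B\,\dot y_\mathrm{right}(t)$.
The regression is through the origin by default — drift has already been
removed, and an intercept would absorb residual offsets into the gain —
with a with-intercept variant behind `intercept = TRUE`. Because no field
is ever applied in unimanual trials, the compensation target there is
undefined and `fc_table()` covers bimanual clamp trials only; unimanual
transfer is quantified through peak forces.

**Maximum perpendicular error** (MPE) is the signed largest deviation of
the left-hand path from the straight start–target line, positive =
leftward of the direction of travel (the direction the field pushes).

## The synthetic-experiment generator

The simulator exists so that every stage of the analysis is exercisable
without human data. Its defaults are the study conditions of the paradigm;
they are not tuning knobs.

**Schedule.** Three phases, 46 blocks of 48 trials, 2208 trials: baseline
288 (blocks 1–5: every condition 3× null + 1× clamp; block 6: trained
conditions only, 14× null + 2× clamp), exposure 960 (per trained
condition 14× force-field + 2× clamp per block), generalization 960 (12×
force-field per trained condition + one clamp for each of the 12
conditions per block). Order within a block is a uniform shuffle from a
seeded stream; nothing prevents consecutive clamp trials (the design is
silent on this, so the simplest rule is used).

**Kinematics.** Reaches are minimum-jerk and straight along $+y$. Peak
speed — not duration — is the controlled quantity: a pure 700 ms
minimum-jerk reach of 25 cm would peak at $1.875 d/T \approx 67$ cm/s,
outside the 75 ± 7.5 band, whereas measured reaches comply with the peak
speed bands. Durations therefore rescale to $1.875\,d/v_\mathrm{peak}$
(625 ms for all three classes). Per trial and hand, peak speed is
multiplied by a Gaussian draw centred on 1 with CV 0.05, which keeps ~95%
of reaches inside the ±10% band; the draw preserves reach distance by
rescaling duration. The right hand leads the left by 20 ms in bimanual
trials — the lead is reported qualitatively in this paradigm without a
magnitude, so 20 ms is a package default, configurable via
`kinematics_config(right_lead_ms = )`. Each trial records 1400 ms at
1 kHz with movement onset at 300 ms, leaving room for the drift-correction
window and the full ±400 ms alignment window.

**Learner.** A single-rate state-space learner: on every force-field trial
the compensation gain updates as
$\alpha_{t+1} = a\,\alpha_t + b\,(1 - \alpha_t)$, approaching
$\alpha_\infty = b/(1 - a + b)$. Defaults $a = 0.99$, $b = 0.04$ give
$\alpha_\infty = 0.8$, matching the ~80% late-exposure force compensation
typical of curl-field adaptation, with most learning inside the first
exposure block. Clamp trials do not update the gain (the channel clamps
the error to ~0); a partial-update variant is available via
`learner_config(clamp_update = TRUE)`. The learner's predictive lateral
force is $\alpha_t B (\omega v_R + (1-\omega) v_L)$ plus white execution
noise (0.3 N per sample before filtering); $\omega$ is the ground-truth
encoding weight, fixed per participant by default (group defaults 0.9
evident, 0.4 ambiguous) with an optional linear drift across exposure
(`omega_start`) to mimic a developing encoding.

**Plant.** Trajectory errors on force-field trials, needed only for MPE
analyses, come from an optional lateral point-mass plant
($m = 1.5$ kg, viscous damping 50 N s/m, no stiffness): net lateral force
= field + predictive compensation, integrated at 1 kHz. This produces the
qualitative MPE signature — leftward error early in exposure shrinking as
$\alpha_t$ grows — not calibrated error magnitudes, since a human's
impedance control is far richer than a damped point mass.

**What the generator does not emulate**: feedback corrections within a
trial, co-contraction and limb impedance, curved baseline trajectories,
fatigue or attention drifts, and use-dependent biases. Passing tests
therefore show that the *pipeline* is correct (parameters generated under
the model are recovered, invariants hold), not that these defaults
reproduce any particular human dataset.

## A worked run

A small end-to-end run (1 participant per group; analyses use the
generalization-phase clamp trials):

```{r pipeline, eval = FALSE}
cfg <- run_config(n_participants = 1, seed = 1)
run <- run_pipeline(cfg)

# late-exposure adaptation level
run$fc |>
  filter(phase == "exposure", block > 15) |>
  summarise(fc = mean(fc), .by = group)

# fitted encoding weights and model ranking
run$fits |> filter(model == "weighted") |> select(group, alpha, omega)
run$bic |> summarise(delta_bic = mean(delta_bic), .by = c(group, model))
```

With the defaults this recovers force compensation near 80%, a weighted
$\omega$ near 0.9 (evident) and 0.4 (ambiguous), and the weighted model
with the largest BIC improvement — the qualitative signature the package
is built to measure. `plot_learning_curve()`, `plot_force_profiles()`,
`plot_generalization()` and `plot_weight_trajectory()` draw the standard
figures from these tables.

## Numerical and design choices

* **Units**: SI internally (m, s, N); the speed-class table carries cm for
  readability and is converted at the boundary. $B$ is 13 N s/m, i.e.
  0.13 N per cm/s.
* **Degenerate inputs** raise classed errors rather than returning
  nonsense: a zero perfect-compensation profile (FC undefined), an
  all-zero speed series (no onset), a zero-length start–target line (MPE
  undefined), unknown groups/conditions, a zero SSE passed to the BIC
  (a noise-free fit has no likelihood scale — callers skip the BIC or add
  noise).
* **Weight trajectories** tile exposure + generalization into 96-trial
  windows anchored on the block grid (96 = two schedule blocks), fitting
  the weighted model to the clamp trials of each window; windows without
  clamp trials yield flagged missing values.
* **Reproducibility**: every stochastic function takes or derives a seed;
  per-participant sub-seeds are derived from the experiment seed, and the
  global RNG state is restored on exit. The same configuration and seed
  reproduce schedules, datasets and result tables byte-for-byte.
* **Problem sizes**: the package's own test battery runs single-participant
  experiments for unit checks and an 8 + 8-participant two-group
  experiment for the end-to-end recovery check; fits there use 3 trained
  conditions × 801 samples per participant. These sizes give group-mean
  recovery of $\omega$ to well within ±0.05 while keeping a full run in
  the order of minutes.

## Limitations

* The non-parametric reference's functional form (fixed gain × right-hand
  velocity) is an assumption; with matched-speed data all encodings
  coincide, so it only matters for generalization-phase comparisons.
* $R^2$ is computed per participant and then averaged; pooled-variance
  alternatives would differ slightly.
* Condition-averaged fitting discards trial-to-trial amplitude
  variability, which is itself identifying information; per-trial fitting
  recovers it at the cost of noisier estimates.
* The simulator's learner has one rate; dual-rate phenomena (spontaneous
  recovery, savings) are out of scope, as are all inferential statistics —
  the pipeline emits tidy per-participant tables ready for any stats
  package.
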