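# curladapt

Simulation and analysis of bimanual curl-field adaptation experiments.

## The problem

In a bimanual force-field paradigm, a participant reaches with both hands
while the left hand is perturbed by a velocity-dependent curl field that is
driven by the **right** hand's velocity:

```
[Fx]   [ 0  -B ] [vx_right]
[Fy] = [ B   0 ] [vy_right],      B = 13 N·s/m
```

Interleaved error-clamp (channel) trials confine the left hand to a
straight path and measure the lateral force the participant presses into
the channel — their learned, predictive compensation. The scientific
question is what state the motor memory is keyed to: the velocity of the
perturbed (left) hand, of the driving (right) hand, or a weighted mixture.
That is answered by regressing measured channel forces against four
encoding models of the hands' forward velocities,

```
right:     F = alpha * B * v_right
left:      F = alpha * B * v_left
average:   F = alpha * B * (v_left + v_right) / 2
weighted:  F = alpha * B * (omega * v_right + (1 - omega) * v_left)
```

and comparing them by BIC against a fixed-gain reference model. The weight
`omega` (1 = right-hand, 0 = left-hand, 0.5 = average encoding) is the
headline quantity; its generalization to untrained speed combinations and
its transfer to unimanual reaches (where `v_right = 0`) diagnose the
encoding.

`curladapt` implements the full pipeline for experimentalists and
modellers working with this kind of data:

* **design** — the 12-condition grid and the block-randomized, three-phase
  2208-trial schedule (`condition_grid()`, `build_schedule()`);
* **simulation** — synthetic participants: minimum-jerk kinematics with
  peak-speed noise, coupled curl-field / channel dynamics, and a
  single-rate adaptive learner with a ground-truth encoding weight
  (`simulate_experiment()`);
* **preprocessing** — zero-phase Butterworth filtering, drift correction,
  peak-velocity alignment (`align_profiles()`);
* **metrics** — force compensation, peak forces, signed maximum
  perpendicular error, trial binning (`fc_table()`, `peak_force()`,
  `mpe_table()`);
* **models** — least-squares encoding fits, BIC comparison, generalization
  and unimanual-transfer predictions, encoding-weight trajectories
  (`fit_encoding_models()`, `bic_improvement()`,
  `predict_generalization()`, `fit_weight_trajectory()`).

Everything is data-frame-in / tibble-out and pipe-friendly; fitted models
support `tidy()`/`glance()`, and `plot_*()` helpers draw the standard
figures. See the vignette (`vignettes/encoding-models.Rmd`) for the
methods in full.

## Worked example

Simulate one participant per group (evident group trained on mismatched
hand speeds, ground-truth `omega = 0.9`; ambiguous group on matched
speeds, `omega = 0.4`) and run the whole analysis:

```r
library(curladapt)
library(dplyr)

cfg <- run_config(n_participants = 1, seed = 1)
run <- run_pipeline(cfg)

run$fc |>
  filter(phase == "exposure", block > 15) |>
  summarise(fc = mean(fc), .by = group)
#>   group        fc
#> 1 evident    80.6
#> 2 ambiguous  80.0

run$fits |> filter(model == "weighted") |> select(group, alpha, omega)
#>   group     alpha omega
#> 1 evident   0.800 0.897
#> 2 ambiguous 0.801 0.399

run$bic |>
  summarise(delta_bic = mean(delta_bic), .by = c(group, model)) |>
  arrange(group, -delta_bic)
#>   group     model    delta_bic
#> 1 ambiguous weighted   11965.
#> 2 ambiguous average     8061.
#> 3 ambiguous left        1919.
#> 4 ambiguous right         21.2
#> 5 evident   weighted    9205.
#> 6 evident   right        195.
#> 7 evident   average    -6355.
#> 8 evident   left      -10165.
```

Reading the output: both simulated groups adapt to ~80% force
compensation by late exposure; the weighted fit recovers each group's
ground-truth encoding weight (0.897 vs 0.9; 0.399 vs 0.4); and the
weighted model has the largest BIC improvement over the fixed-gain
reference in both groups, with the runner-up being right-hand encoding for
the evident group and average encoding for the ambiguous group — the
signature pattern this analysis is designed to detect.

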