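# pwvflow

Pulse wave velocity (PWV) — the speed at which the systolic wavefront
travels along the aorta — is the standard surrogate marker for arterial
stiffness.  With phase-contrast MRI it is measured from two
single-cardiac-cycle flow or velocity curves, one in the ascending aorta
and one downstream, as

```
PWV = Δd / Δt        [mm / ms = m/s]
```

where `Δd` is the centerline traveling distance between the two flow
planes and `Δt` the transit time of the waveform between them.  How `Δt`
is detected, how the baseline is corrected, and how finely the cycle is
sampled all change the resulting PWV — which is why these methodological
choices need tools that make them explicit and testable.

`pwvflow` is aimed at researchers working on PWV methodology in young
populations (neonates through adolescents).  It implements the full
measurement chain:

* **Transit-time estimators** (`transit_time()`): time-to-foot (TTF, the
  tangent through the maximum-upslope point intersected with the
  baseline), maximum upslope, and time-to-peak — with circular Gaussian
  smoothing (`smooth_curve()`, SD 0.025 of the cycle) and baseline
  correction (`baseline_correct()`: none, automatic over the 80–95 %
  late-diastolic segment, or a manual pre-upslope window).
* **A temporal-resolution computer phantom**
  (`phantom_spec()`, `run_resolution_experiment()`,
  `find_required_frames()`): a 10,000-frame curve pair with known
  reference PWV is downsampled to 20–60 timeframes per cycle to find the
  minimum number of timeframes needed for accurate PWV.
* **A synthetic waveform generator** (`generate_waveform()`,
  `generate_cohort()`): parametric neonatal / adolescent aortic
  waveforms and cohorts with known ground-truth PWV, for validating
  every downstream stage.
* **Centerline geometry** (`centerline_length()`): `Δd` as the arc
  length of ordered 3D points in mm.
* **Agreement statistics** (`bland_altman()`, `summarize_methods()`):
  bias, SD and 95 % limits of agreement for method comparisons.
* **I/O and pipelines** (`read_curve()`, `write_curve()`,
  `analyze_manifest()`, `run_pipeline()`) plus a thin command-line
  wrapper in `inst/scripts/pwvflow-cli.R` with `simulate`, `analyze`,
  `phantom`, `length` and `agreement` subcommands.

## Worked example

Build a neonatal pair whose descending curve is the ascending curve
delayed by 15 ms and scaled by the 0.6 blood-diversion factor, sampled at
the clinical 44 timeframes per cycle, and estimate PWV by TTF with
automatic baseline correction:

```r
library(pwvflow)

p    <- waveform_params("neonate")          # 138 bpm, 434.8 ms cycle
asc  <- generate_waveform(p, 44)
desc <- shift_curve(asc, 15)                # 60 mm at 4 m/s -> 15 ms
desc$values <- 0.6 * desc$values
est <- transit_time(curve_pair(asc, desc, 60), "ttf",
                    baseline_spec("automatic"))
est
#> <transit_estimate> ttf (baseline: automatic)
#>   landmarks: asc 41.114 ms, desc 55.734 ms -> delta-t 14.621 ms
#>   PWV = 60.0 mm / 14.621 ms = 4.104 m/s
```

The true construction delay is 15 ms; at 44 timeframes per cycle
(temporal resolution `temporal_resolution_ms(138, 44, rounded = TRUE)` =
10 ms) the TTF estimate lands at 14.62 ms, i.e. a PWV of 4.10 m/s versus
the true 4.00 m/s — a +2.6 % discretisation error.  The phantom module
quantifies exactly this error as a function of timeframes per cycle:

```r
grid <- run_resolution_experiment(
  phantom_spec(profile = "neonate", vessel_length_mm = 25))
grid
#> <error_grid> neonate profile, vessel length 25 mm
#>   5 reference PWV x 41 frame counts (20-60)
#>   cut-off: 51 timeframes/cycle (|error| <= 10%), error range -7.92 to 8.71%
```

For the shortest neonatal aortic arch (25 mm), every reference PWV
between 2 and 10 m/s stays within ±10 % only from 51 timeframes per
cycle upward — short vessels and high PWV are the demanding corner, since
the transit time shrinks toward the frame duration.  Agreement between
two measurement series is summarised the standard way:

```r
bland_altman(c(4.1, 3.8, 4.5, 5.0, 2.9), c(4.0, 4.0, 4.3, 4.8, 3.2))
#> <agreement_summary> n = 5 (difference = first minus second argument)
#>   bias -8.881e-17 +/- 0.2345, 95% LoA [-0.4597, 0.4597]
```

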