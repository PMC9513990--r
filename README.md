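# ulbench — benchmarking upper-limb motor capacity

`ulbench` is an R toolkit for standardized, sensor-based assessment of
upper-limb motor capacity in neurological disorders (stroke and related
conditions), with or without a rehabilitation robot. It implements a unified
benchmarking scheme as reusable code:

* a **taxonomy** of six motor primitives (idle, stabilize, point-to-point
  reach, reach for grasp, transport, reposition), six standardized motor
  skills built from them, ten motor abilities, and a registry of ~50
  kinematic and surface-EMG performance indicators (PIs), seven of which are
  mandatory;
* an **8-DOF upper-limb kinematic model** in the ISB convention (trunk
  flexion q0; shoulder plane of elevation, elevation, axial rotation q1–q3;
  elbow flexion and pronation q4–q5; wrist q6–q7), with forward kinematics
  and the conversion between the robotics shoulder convention
  (flexion/extension, horizontal adduction/abduction, humeral rotation) and
  the ISB Y–X′–Y″ angles;
* taxonomy-driven **trial segmentation** (speed-threshold onset/offset
  detection with boundary refinement, the strict 1-s stability rule, the
  strict 20° trunk-compensation validity rule);
* the full **performance-indicator suite**: accuracy, efficacy, efficiency,
  movement amplitude, intra-limb coordination, planning predictability,
  smoothness (velocity peaks, MAPR, normalized dimensionless jerk, SPARC),
  speed, and the EMG side (time/frequency features, TKEO muscle onset,
  co-contraction index, intermuscular coherence, muscle synergies by NMF);
* the **assessment protocol**: a validated machine-readable worksheet, the
  A–E target layout at complete elbow extension, PI selection and a
  deterministic benchmark report;
* a **synthetic-trial simulator** (minimum-jerk reaches, tunable impairment,
  amplitude-modulated band-limited EMG) with ground-truth labels, so the
  whole pipeline is testable without any recorded patient data.

## The core quantities

Movements are compared against the idealized reach: a straight chord
traversed with the minimum-jerk profile
`p(τ) = p0 + (p1 − p0)(10τ³ − 15τ⁴ + 6τ⁵)`, whose peak speed is
`1.875·L/D` for length `L` and duration `D`. Smoothness is quantified,
among others, by the normalized dimensionless jerk

    NDJ = ∫ ‖p⃛(t)‖² dt · D⁵ / L²     (NDJ = 720 for a pure minimum-jerk reach)

and by the spectral arc length (SPARC), the negative arc length of the
magnitude-normalized Fourier spectrum of the speed profile. Onsets use the
10%-of-peak-speed convention; stability requires holding position for
strictly more than 1 s; a trial is invalid if trunk lean exceeds 20° in the
sagittal or frontal plane. Co-contraction uses the envelope-overlap form
`CCI = 100 · 2Σmin(e₁,e₂)/Σ(e₁+e₂)`; synergies are extracted by
non-negative matrix factorization with a variance-accounted-for (VAF) rank
rule.

## Worked example

Simulate one protocol trial of anterior reaching at rest height for a
0.55 m arm, segment it, and compute the indicators:

```r
library(ulbench)

g   <- arm_geometry(0.30, 0.25)                    # upper arm + forearm, m
lay <- build_target_layout(g, shoulder_height_m = 0.30)
lay
#> Target layout (rest_height): reach 0.4610 m
#>   A: (0.000, 0.000, 0.000)
#>   B: (0.461, 0.000, 0.000)
#>   C: (0.326, 0.000, -0.326)
#>   D: (0.326, 0.000, 0.326)
#>   E: (0.150, 0.550, 0.000)

tr  <- synth_emg(synth_trial("anterior_reaching_rest_height", lay, g,
                             impairment_params(n_submovements = 2, seed = 42)))
seg <- segment_trial(tr)
seg
#> Primitive segmentation (anterior_reaching_rest_height): 7 segments
#>   step            primitive start_s end_s waypoint_from waypoint_to reached
#> 1    1                 idle    0.00  1.49             A           A    TRUE
#> 2    2 point_to_point_reach    1.49  2.63             A           B    TRUE
#> 3    3           reposition    2.96  4.10             B           A    TRUE
#> ...
```

The reach distance is `sqrt(0.55² − 0.30²) = 0.461 m` (complete elbow
extension at rest height), and the lateral targets C/D sit at exactly 45°.
The indicator table for the first reach shows the impairment: two
sub-movements produce two velocity peaks and inflate the dimensionless jerk
far above the minimum-jerk value of 720, while the path stays straight
(path length ratio 1):

```r
pis <- compute_kin_pis(tr, seg)
subset(pis, step == 2 & ability %in% c("efficiency", "smoothness", "speed"))
#>     ability                            pi         value    units    status
#>  efficiency             path_length_ratio     1.0000000    ratio mandatory
#>  smoothness      number_of_velocity_peaks     2.0000000    count mandatory
#>  smoothness  movement_arrest_period_ratio     0.7130435 fraction recommended
#>  smoothness normalized_dimensionless_jerk 22581.4317815        1 recommended
#>  smoothness           spectral_arc_length    -2.6193769        1 recommended
#>       speed                 mean_velocity     0.4024417      m/s mandatory
```

An end-to-end run over a full 8-repetition dataset (worksheet validation,
validity checks, segmentation, kinematic and EMG indicators, JSON report and
run manifest):

```r
dir <- tempfile()
simulate_dataset(dir, n_repetitions = 8, impair = impairment_params(seed = 1))
res <- run_benchmark(file.path(dir, "worksheet.json"),
                     kin_paths = file.path(dir, sprintf("rep%02d_kin.csv", 1:8)),
                     emg_paths = file.path(dir, sprintf("rep%02d_emg.csv", 1:8)),
                     out_dir = file.path(dir, "out"))
res$report
#> Benchmark report
#>   environment: gravity | repetitions: 8 (8 valid)
#>   indicators aggregated: 56 rows (mean +/- SD over valid repetitions)
```

A thin command-line front end with the verbs `simulate`, `validate`,
`layout` and `run` is installed at `inst/cli/ulbench.R`. An example
worksheet ships in `inst/extdata/example_worksheet.json`.

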