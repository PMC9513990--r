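---
title: "Methods: models, parameters and design choices in ulbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in ulbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulbench)
```

# The benchmarking scheme

`ulbench` operationalizes a standardized assessment of upper-limb capacity.
Six *motor primitives* — idle, stabilize, point-to-point reach, reach for
grasp, transport, reposition — compose six protocol *motor skills*
(anterior reaching and moving objects, each at rest and at shoulder height,
and hand-to-mouth with and without an object). The primitive flows are fixed
templates of 7, 7, 12, 12, 4 and 6 steps; every flow starts with idle at the
rest position A and ends with a reposition back to A. Ten *motor abilities*
(accuracy, efficacy, efficiency, movement amplitude, muscular effort,
intra-limb coordination, planning predictability, power, smoothness, speed)
are quantified by a registry of performance indicators split between the
kinematics and surface-EMG domains. Seven indicators are mandatory — one per
ability for efficacy, efficiency, movement amplitude, muscular effort,
planning predictability, smoothness and speed; accuracy, intra-limb
coordination and power carry none because the evidence linking a single
indicator to clinical scales is insufficient there.

Primitives are classified along two axes. *Function*: stability requires
holding the arm location unchanged for strictly more than 1 s (the mean
duration of upper-limb activities of daily living); anything else is
transport. We operationalize "location unchanged" as end-effector speed
below 2 cm/s (configurable); the hold is measured on the hand, not the
object. *Environment*: micro-gravity when the arm's weight is externally
supported (suspension, table sliding, or a robot in an assistive mode),
gravity otherwise. With a robot, the patient-in-charge, transparent and
resistive training modalities keep the gravity label; all other modalities
of the eight-member enumeration imply micro-gravity, and any passive-DOF
gravity compensation above a threshold (default 0, i.e. any compensation at
all) forces micro-gravity with a flag in the output — the scheme does not
state how partial compensation should be read, so the threshold is exposed.

# Kinematic model

The arm is a rigid chain with eight DOFs: trunk flexion/extension (q0),
a glenohumeral ball-and-socket (plane of elevation q1, elevation q2, axial
rotation q3; ISB Y–X′–Y″ sequence), elbow flexion/extension (q4),
pronation/supination (q5) and two wrist rotations (q6, q7). The shoulder is
deliberately simplified to the glenohumeral joint — valid for arm elevations
up to about 90°, which covers the protocol. The hand is out of scope, so
the end-effector coincides with the wrist point. The ground frame is ISB:
X anterior, Y up, Z lateral toward the evaluated side; left-arm data are
mirrored about the sagittal plane at load time so all indicators are
side-agnostic. The zero posture for q1–q3, which the scheme leaves open, is
ISB neutral (arm hanging, palm medial); every report should state this.

The robotics shoulder convention (flexion/extension, horizontal
adduction/abduction, humeral rotation) is related to the ISB angles by
composing the rotation matrix in one convention and decomposing it in the
other (Y–Z′–Y″ vs. Y–X′–Y″ Euler sequences). The conversion is exact away
from the elevation singularity; at `sin(q2) ≈ 0` the plane of elevation is
undefined and set to 0 with a `singular` flag. Round trips on nonsingular
poses are identity to within 1e-6 rad (property-tested on 100 random
poses).

Angles are radians internally and degrees at every I/O boundary, matching
the degree-valued protocol rules.

# Signal processing

* **Kinematics**: zero-phase 4th-order Butterworth low-pass at 6 Hz
  (configurable; the protocol prescribes none) before central-difference
  differentiation. Forward–backward filtering uses odd-reflection end
  padding so that edge transients fall outside the data. Endpoint
  derivatives use one-sided second-order stencils.
* **Jerk**: the normalized dimensionless jerk integrates the squared third
  derivative, which peaks exactly at the movement boundaries; repeated
  one-sided stencils are badly conditioned there, so the third derivative
  is taken with a Savitzky–Golay filter (order 5, window 9), whose endpoint
  filters are exact for the minimum-jerk quintic. On a sampled minimum-jerk
  reach the implementation reproduces NDJ = 720 to 0.1%.
* **SPARC**: FFT zero-padded to four times the next power of two, 20 Hz
  frequency cutoff, 0.05 adaptive amplitude threshold on the normalized
  magnitude spectrum. These constants are echoed into every report.
* **EMG**: band-pass 20–450 Hz (Butterworth 4, zero-phase; upper edge
  capped below Nyquist), optional 50 Hz harmonic notches, full-wave
  rectification and a 5 Hz low-pass for the linear envelope, peak-of-trial
  normalization by default (MVC normalization when an MVC recording is
  supplied). Rates below 1000 Hz are recorded as warnings. Welch spectra
  use Hann windows, 512-sample segments and 50% overlap; the frequency
  ratio splits at 20–60 / 60–450 Hz and the power-spectrum ratio integrates
  ±10 Hz around the spectral peak — both configurable, since the scheme
  names the quantities but not the bands.
* **Muscle onset**: Teager–Kaiser energy `ψ[i] = x[i]² − x[i−1]x[i+1]`,
  smoothed with a *causal* 50 ms moving average (a centered window leaks
  burst energy backwards and biases onsets early), thresholded at the
  pre-cue baseline mean of the smoothed trace plus 3 SD of the *raw*
  energy (the raw SD suppresses chance excursions of the autocorrelated
  smoothed series), sustained for 25 ms. On injected bursts this recovers
  latencies within ±15 ms.

# Segmentation

Movement onset is the first time after the go cue at which speed crosses
10% of the post-cue peak upward and stays above it for 50 ms; offset is
symmetric. Segment boundaries are then refined by walking from the crossing
to the nearest speed minimum, which places boundaries at the true movement
edges rather than at the 10% crossing (for a 1-s minimum-jerk reach the
crossing sits ~87 ms after the true start; the refined boundary is within a
sample or two). Sub-threshold gaps strictly longer than the 1-s stability
threshold are holds and are matched to idle/stabilize template entries;
shorter gaps within a movement are within-movement arrests. When more
supra-threshold intervals are found than the template expects, intervals
separated by sub-stability gaps are merged smallest-gap-first; with fewer,
a partial segmentation is returned with an `incomplete` flag (severely
impaired users may not complete a flow). Waypoint arrival uses a 3 cm
capture radius (configurable; the protocol states no radius). Boundary
strictness follows the protocol's wording everywhere: *more than* 1 s,
*higher than* 20°.

Reaction time deserves a note: the indicator is defined against the
10%-of-peak onset, so the generator's ground truth records, for each
movement, the analytic time at which the ideal profile crosses 10% of the
trial's peak speed. Recovery tests compare the detector against that
analytic crossing (≤ 15 ms), not against the commanded movement start —
the two differ by construction, and conflating them would make the 10%
convention look biased when it is not.

# Indicator conventions that the scheme leaves open

* The *ideal trajectory* is the straight chord with a minimum-jerk speed
  profile over the segment's duration and length.
* The *area index* is the unsigned shoelace area between the path and its
  chord; 3-D paths are projected onto their best-fit (SVD) plane first,
  since an enclosed area is only defined in a plane.
* *Trunk compensation* uses the ground-frame sagittal (X–Y) plane; the
  trunk marker's peak planar excursion is divided by the hand's.
* *Normalized reaching area* is a distance ratio (maximum reached distance
  over arm length), following the registry's description rather than its
  name.
* The *variable error* is the SD of end-point errors across repetitions; it
  is pooled across target directions in the report (per-direction values
  are recoverable from the per-repetition table).
* Velocity peaks are maxima above 10% of the movement's peak speed with a
  100 ms minimum separation (smaller peak dropped); MAPR shares the same
  10% constant with onset detection deliberately, so one threshold governs
  "moving vs. arrested" throughout.
* The *co-contraction index* uses the envelope-overlap (Falconer–Winter)
  form, `100 · 2Σmin(e₁,e₂)/Σ(e₁+e₂)`; the default agonist/antagonist pair
  is biceps/triceps brachii (the reaching pair), remappable per worksheet.
* Degenerate inputs yield explicit not-computable results, not silent
  zeros: zero-chord movements (path length ratio), constant joint traces
  (correlations), single repetitions (variable error), all-zero envelope
  pairs (CCI), zero attempts (success rate).

# Protocol and worksheet

The worksheet is a JSON/YAML document validated with field-path messages:
actuated-DOF assistance in [−1, 1] (−1 full resistance, 0 transparent, +1
robot-in-charge), passive-DOF gravity compensation in [0, 1], seatback tilt
in [100°, 110°] when given, repetitions ≥ 1 with default 8 (the protocol's
"at least eight": the minimum is enforced and also the default). The
worksheet form lists hand-to-mouth undivided; the loader expands it via an
`object_present` flag. The eight training modalities follow the established
robot-training taxonomy; the scheme names patient-in-charge,
robot-in-charge, transparent and resistive explicitly, and the remaining
four members (assistive, corrective, path guidance, error augmentation)
complete the assistive class.

The target layout places B anterior of the rest point A at horizontal reach
`r = sqrt(arm² − h²)`, where `h` is the vertical drop from the shoulder to
the target height (zero in shoulder-height mode, so `r` equals the arm
length). C (contralateral) is rotated 45° toward the midline and D
(ipsilateral) 45° lateral — the scheme never states the signs; we take
contralateral = medial and mirror for left-arm evaluation. The 45° angles
hold exactly in the horizontal plane (the protocol draws them on the table
surface). The mouth point E defaults to 0.15 m anterior of and 0.25 m above
the sternal notch (taken at shoulder height), subject-overridable — the
scheme gives E no coordinates. The object for the drinking task sits 6 cm
anterior of A, so the grasp and the final reposition are distinct, real
movements. Whether table-sliding executions of skills 1 and 3 force the
micro-gravity label is left to the worksheet (with the classification note
attached), since the protocol presents sliding as an option, not a rule.

# The synthetic-trial generator

The simulator is the package's test bed: it emulates protocol-conformant
executions, not patients. Defaults define the study conditions: movement
duration 1.0 s (self-selected speed; optional Gaussian jitter, default 0),
idle/stabilize dwells of 1.5 s (strictly above the 1-s stability rule),
0.35 s pauses between chained movements (below it), kinematics at 100 Hz,
EMG at 1000 Hz. Impairment knobs: sub-movement count (each reach splits
into that many minimum-jerk bumps, ≥ 250 ms each, separated by 120 ms
arrests; micro grasp-reaches under 15 cm are never fragmented — sub-movement
decomposition is a property of full reaches), reaction delay, trunk lean
(which displaces the shoulder but not the task path, as trunk compensation
does), lateral path curvature (a bell-shaped `sin²` bump with zero end
slope, so onsets stay crisp), and speed scaling. Joint angles are produced
by inverse kinematics with an elbow-down swivel; because the targets sit at
complete elbow extension, impairment deviations may nudge points marginally
past the reachable sphere — up to 2% of arm length is projected back, more
is an error.

EMG synthesis is phenomenological: smooth raised-cosine activation bursts
(20 ms rise) aligned to movements modulate band-limited (20–450 Hz)
Gaussian carrier noise at 0.5 mV, over a 5% resting baseline. Antagonists
mix an in-phase burst scaled by the co-contraction gain with an off-phase
braking burst, so gain 1 duplicates the agonist envelope (CCI = 100) and
gain 0 makes the supports disjoint. This exercises every EMG indicator but
is *not* a motor-unit model: firing statistics, fatigue-driven spectral
compression, crosstalk and electrode artifacts are absent, so passing tests
demonstrate correctness of the computations, not robustness to real
recording conditions.

Disturbances: a payload stretches transport durations by 10% and scales
anti-gravity muscle amplitudes with mass (an explicitly toy model); a motor
perturbation adds the specified waveform to the end-effector path (joint
angles recomputed by IK); cognitive disturbances are metadata. Every
disturbance must be quantitatively specified before use.

Determinism: all randomness flows from the impairment seed; identical seeds
give bit-identical trials, EMG and reports.

# Problem sizes and verification

The test suite builds all fixtures in code: canonical 100 Hz minimum-jerk
reaches, 20 seeded trials across the six skills with graded impairment for
parameter recovery (boundaries ≤ 50 ms, onsets ≤ 15 ms against the analytic
crossing, exact per-movement peak counts, co-contraction ordering with
Spearman ρ = 1), rank-2 synergy fixtures (9 muscles × 400 samples, 20 NMF
restarts, matched cosine ≥ 0.95), and tiny hand-computable signals for every
feature family. `scripts/acceptance.R` re-runs the same computations from a
command-line seed, including a full 8-repetition benchmark. These sizes keep
the whole suite around a minute on one core while leaving every code path
exercised.

# Known limitations

Hand and grasp kinematics, bimanual tasks, tremor metrics and kinetic
(force) outcomes are out of scope, as in the scheme itself. C3D motion
files are not read — kinematic input is CSV (joint angles or markers) with
a JSON sidecar; converting C3D to CSV is left to external tools. The
scapulothoracic rhythm is not modeled (glenohumeral simplification), so
shoulder angles above ~90° elevation lose anatomical fidelity. Synergy
extraction is deterministic given the seed but, like all NMF, only locally
optimal; restarts mitigate this on the scales used here.
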