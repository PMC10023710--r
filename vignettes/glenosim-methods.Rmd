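---
title: "glenosim: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glenosim: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glenosim)
```

# What glenosim simulates

glenosim is a software-in-the-loop counterpart of a muscle-actuated in-vitro
shoulder simulator. The physical apparatus drives a cadaveric glenohumeral
joint through six cables representing the three deltoid heads (anterior,
middle, posterior: AD, MD, PD) and the rotator cuff (subscapularis SSC,
infraspinatus/teres minor ISP/TM, supraspinatus SSP), each routed through a
low-friction guide that fixes its line of action, and closes the loop with
optical tracking of the humerus relative to the scapula. This package
replaces the cadaver and the hydraulics with a rigid-body virtual specimen
and reimplements the three-loop muscle-force control algorithm and the full
evaluation pipeline, so that the control and analysis machinery can be
studied, stress-tested and extended without tissue.

# Kinematic conventions

Glenohumeral orientation is parameterized by the Cardan sequence **XZY**:
abduction about the scapular X axis, flexion(+)/extension(-) about Z, then
internal(+)/external(-) rotation about the (humeral) Y axis. The Y-first
sequence recommended for the shoulder is singular at zero elevation, exactly
where abduction trials begin; XZY moves the singularity to +/-90 degrees of
flexion, far outside the protocol workspace, and `decompose_orientation()`
refuses the singular branch explicitly. All interfaces use degrees;
internals are radians. Translations of the humeral-head centre of rotation
are expressed in the scapular frame as anterior/posterior (AP),
superior/inferior (SI) and medial/lateral (ML) components in mm.

The centre of rotation is estimated as the "least-moving point" of a passive
mobilization recording, formulated as a linear pivot calibration: the pair
of points (fixed in the humerus frame, fixed in the scapula frame)
minimizing the summed squared discrepancy `|R_i p_h + t_i - p_s|^2` over all
recorded poses, solved by stacked linear least squares with an explicit
rank-deficiency guard (pure translations, or single-axis motion, cannot
constrain the pivot). The test suite checks this estimator against a
brute-force nonlinear least-squares oracle.

# The virtual specimen

The plant is deliberately simple, because no cadaver geometry is published
for this class of rig; every number in `reference_specimen()` is a
documented invention chosen for physiological plausibility:

* **Rigid body, 3 rotational DOF.** Dynamics are integrated in
  Cardan-angle space: `I th'' = J(th)^T (tau_muscle + tau_gravity)
  - k (th - th_rest) - c th'`, where `J` maps Cardan rates to angular
  velocity. The generalized gravity force is computed exactly as
  `J^T (r x m g)`, which equals the gradient of the gravitational
  potential, so with the linear capsule stiffness `k` and damping `c` the
  passive plant is exactly dissipative -- the energy test asserts that
  mechanical energy never increases under zero muscle force. The
  generalized inertia is a constant diagonal (0.09, 0.09, 0.004) kg m^2,
  consistent with a ~2 kg humerus segment plus the 3 kg forearm-replacement
  mass (3.2% body weight) on a 15 cm lever.
* **Cables.** Each muscle is a straight line from its humeral insertion to
  a scapula-fixed guide point (no wrapping surfaces -- the single-line-of-
  action simplification of the physical rig). Torque is `r x (F u)` with
  `u` the insertion-to-guide unit vector; cables only pull. Insertions and
  guides were placed so each muscle's moment-arm signs match its anatomical
  action (MD/SSP abduct, AD flexes, PD extends, SSC rotates internally,
  ISP/TM externally) and so that steady prime-mover forces land in the
  range reported for muscle-driven simulators (MD on the order of
  100-180 N near 60 degrees abduction).
* **Scapular pose and resting equilibrium.** The scapula is tilted 10
  degrees forward, applied as a constant rotation of gravity into the
  scapular frame about the abduction axis; together with the capsule rest
  angles this places the passive pretension equilibrium near 10 degrees of
  abduction with the humeral head centred to within 1 mm, matching the
  mounted-specimen state the protocols start from.
* **Translations.** The humeral head translation has two parts: an elastic
  deflection of the net joint force with anisotropic stiffness (AP 12,
  SI 18, ML 35 N/mm -- the capsule is most compliant anteriorly, stiffest
  against medial compression into the glenoid), plus the kinematic
  excursion of the articular head centre, which sits a few millimetres
  away from the kinematically identified pivot (offset (3, 4, -4) mm) and
  therefore rides with the rotation. Both are measured from the seated
  resting pose. Without the kinematic term a fixed-pivot model produces
  sub-millimetre translations, an order of magnitude below the several-mm
  excursions real specimens show.
* **Integrator.** Fixed-step RK4 at dt = 5 ms, muscle forces held over the
  step; the controller runs every plant step. Halving dt changes an 80 s
  trajectory endpoint by less than 1e-3 degrees (tested). Trials abort
  with a dislocation error if any translation component exceeds 22 mm and
  with an instability error above 120 deg/s.

## Synthetic specimens

`generate_specimen(seed, variability)` emulates inter-specimen variability:
geometry points receive isotropic Gaussian offsets scaled by their distance
from the joint centre, and masses, inertia, stiffnesses, damping and the
head-centre offset receive multiplicative factors with fractional SD
`variability` (default 0.10). A sampled specimen must pass rejection
checks -- moment-arm signs, moment-arm *magnitudes* across the protocol
workspace, gravity-demand feasibility against the AD/PD constraint, resting
equilibrium near 10 degrees with a centred head -- and is resampled from a
derived child seed otherwise, just as an experimenter would re-route an
unusable cable. The generator is deterministic per seed.

What the generator does *not* emulate: scapulothoracic rhythm (the scapula
is rigidly mounted), wrapping of muscle bellies, viscoelastic creep and
hysteresis of real soft tissue, and tracking artefacts beyond additive
Gaussian noise. Passing tests therefore demonstrate that the *control and
evaluation machinery* behaves correctly on a plausible plant, not that any
particular cadaver would produce the same numbers.

## Sensor noise

Recorded angles, translations and forces receive additive Gaussian noise
(SD 0.1 deg, 0.1 mm, 0.5 N by default) emulating the optical tracker and
load cells. The noise is observational: the controller always sees the
clean process variable, and repeats differ only in their noise stream
(repeats fully re-zero the plant, resolving an ambiguity in the procedure
in favour of independence between repeats). These SDs were chosen once, at
the level of the instrumentation used by such rigs, so that repeatability
statistics are non-degenerate.

# The control algorithm

Three independent loops (abduction, F/E, IR/ER) regulate muscle forces; the
rotational setpoints are the SP, the tracked angles the PV, and the cable
forces the CV. Each PID uses the time-constant form
`u = Kc (e + (1/Ti) int e dt + Td de/dt)` with `Ti`, `Td` in **minutes**
(the convention the shipped gain table was tuned in; the conversion is
explicit and tested). Anti-windup is conditional integration: the
accumulator freezes while the output is clamped and the error pushes
further into the clamp. The derivative acts on a first-order-filtered error
(time constant `max(4 dt, Td/8)`); only the constant-mode abduction row has
a nonzero `Td`.

Two operating sequences (selected per protocol by `select_mode()`):

* **Cascade (active abduction).** The abduction activation controller
  drives MD; SSP is slaved through the abduction-dependent prior ratio
  (0.99 at 10 deg, 0.52 at 30 deg, 0.30 at 60 deg, linearly interpolated
  with end clamping); the AD+PD couple total is 0.60 x MD and the
  SSC+ISP/TM total 1.00 x MD (prior loading ratios 0.43/0.17 and
  0.22/0.78); distribution controllers split each total.
* **Parallel (active F/E, rotation, or both).** Each couple total comes
  from its own activation controller; the abduction loop holds its
  constant setpoint through MD (constant-mode gains), with SSP still
  slaved (a deliberate interpretation -- the alternative is one flag away).

Distribution controllers output an antagonist share clamped to 5-95% of
the couple total, so no cable is ever unloaded; a force floor of 10 N (the
lower end of the 10-20 N centering pretension) applies everywhere, and each
muscle is capped at its kinetic constraint, pCSA x 25 N/cm^2 rounded half
up (MD 241, AD 118, PD 136, ISP/TM 308, SSC 390, SSP 132 N, with 254 N
enforced as the AD+PD couple cap).

Three aspects are underdetermined by the published description of such
controllers and are resolved here as explicit design choices:

1. **Actuator scaling.** The gain table is dimensionless (percent-of-range
   hydraulic controllers); mapping a PID output unit onto newtons is a
   property of the actuation hardware. The shipped config uses 2 N/unit
   for the abduction activation, 350 N/unit for the couple activations and
   0.45 share/0.15 unit for the distributions, chosen so the verbatim gain
   table tracks all six protocols on the reference plant.
2. **Couple activation error.** In profile mode the activation error is
   signed by the commanded motion direction (a negative-going extension
   ramp must still *raise* the couple total); in hold mode it is the error
   magnitude, so the co-contraction envelope rises whichever way the hold
   is disturbed, and the distribution controller picks the direction.
3. **Constraint handling.** The couple total is capped at
   `min(couple cap, mvc_agonist/share, mvc_antagonist/(1-share))`;
   without this, conservation of the split would dump an agonist's
   overflow onto its antagonist and actively oppose the motion.
   Mode and gain-row switches are bumpless (the incoming controller's
   accumulator is initialized to reproduce the outgoing output).

Every trial runs the same phase schedule as the physical protocol: a
cascade loading ramp from the resting posture to the start configuration at
0.5 deg/s, a 10 s settling hold for the constant-mode loops, the scored
ramp(s), and a short tail hold.

# Motion protocols

Six built-ins at 0.5 deg/s, three repeats each: abduction 20-60 deg (F/E
and IR/ER at 0); flexion 0-30 and extension 0 to -30 at 50 deg abduction;
internal rotation 0-45 and external rotation 0 to -45 at 30 deg abduction;
and the non-planar extension 0 to -30 coupled with internal rotation 0-30
at 40 deg abduction, both ramping at 0.5 deg/s (equal spans, so they finish
together). Ramps are velocity-exact by construction and secondary setpoints
exactly constant.

# Evaluation pipeline

Scored segments are linearly interpolated onto the integer-degree grid of
the profiled DOF's setpoint (`resample_by_angle()`, 1 deg increments;
descending grids for negative-going ramps; for the coupled motion the
extension setpoint parameterizes the grid). Translations are referenced to
the 20-degree-abduction pose of the loading phase -- the point at which
initial muscle loading is complete -- averaging a ~1 s window around the
crossing to keep the reference from inheriting a single noisy sample.

* **Accuracy**: the across-trial mean of (achieved - setpoint) per grid
  point; the reported *maximum mean deviation* is the largest absolute
  value of that curve, and the RMSE pools squared deviations over grid
  points and trials. The two differ in informative ways (two trials offset
  +1 and -1 deg have zero mean deviation but unit RMSE), which the tests
  pin down.
* **Repeatability**: the sample SD across the three repeats per grid
  point, summarized as its maximum and grid average, computed per specimen
  and reported as the worst specimen.
* **Reliability**: ICC(A,1) -- single-measurement, absolute-agreement,
  two-way model -- for each muscle force and translation axis, with rows
  the 1-degree grid points pooled across specimens (the per-specimen
  alternative is an option) and columns the repeats, and the 95% CI by the
  F-based method of McGraw & Wong (1996). Absolute agreement is the right
  flavour here because a constant offset between repeats is a real
  repeatability failure; the tests verify that a column offset lowers
  ICC(A,1) while leaving the consistency form unchanged, and check the
  estimator against an independent `aov()`-based oracle and an external
  reference implementation. Interpretation bands: < 0.5 poor, 0.5-0.75
  moderate, 0.75-0.9 good, >= 0.9 excellent.

# Default campaign and what it shows

The standard campaign -- 3 generated specimens x 6 protocols x 3 repeats,
dt = 5 ms, default gains and noise (~54 trials of 100-160 s simulated time
each, a few seconds of wall time) -- tracks all motions with a maximum mean
deviation below ~2.2 deg and RMSE below ~0.9 deg across seeds, with
repeatability SDs at the sensor-noise floor and reliability generally
excellent: typically 32-36 of 36 muscle-force instances and 12-14 of 15
planar translation instances with the ICC CI lower bound above 0.90. The
weakest instances mirror the physical system's weakest ones: SSP (slaved,
small force range in F/E protocols) and the translation axes with little
true excursion. One known limitation: the SI translation of the coupled
extension+internal-rotation motion has almost no genuine excursion in this
plant, so its ICC is only moderate, whereas a real joint (and the physical
rig) shows excursion there.

# Reproducibility

All randomness (specimen generation, noise streams) derives from a single
root seed through a documented splitting rule; a campaign is bit-identical
for a fixed seed and config, and `run_simulation()` persists the config and
seeds in its manifest. `scripts/acceptance.R` re-runs the standard campaign
from scratch for any seed and writes the headline metrics as JSON.
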