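---
title: "Occiput-reaching kinematics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occiput-reaching kinematics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headreach)
```

This vignette is the package's own account of its science: the motion model
behind the synthetic cohort, the kinematic extraction chain, the inferential
chain, the clustering machinery, and — most importantly — the choices we had
to make where the underlying analysis protocol is under-specified, with the
reasoning for each.

## 1. The task and the data model

A seated participant starts with the arm hanging (elbow extended, forearm in
mid-position), reaches to touch the centre of the external occipital ridge
with the palm, holds briefly, and returns. Optical capture at 100 Hz records
reflective markers on the acromion, olecranon, radial/ulnar wrist
eminences, second metacarpal head, manubrium (CLAV), C7, and the posterior
head (BHD), for each limb. The analysis contrasts the paralyzed limb with
the participant's own non-paralyzed limb — the clinically available
reference — over ten participants with five trials per side.

A `trial_recording` holds named marker series (mm, lab frame: x anterior,
y left, z up), the sampling rate, side and limb labels, and participant
covariates. TRC and long-CSV readers/writers (`write_trc()`,
`read_trial_files()`) round-trip this container.

## 2. The synthetic-motion generator

`simulate_trial()` drives shoulder flexion, shoulder abduction and elbow
flexion along **minimum-jerk profiles** from rest to a per-trial end pose at
the occiput and back. Minimum-jerk is the standard model of smooth
point-to-point reaching; its closed-form peak velocity, $1.875\,\Delta\theta/T$,
anchors several tests. The occiput contact is realized as a fixed end pose
(abduction ≈ peak, elbow flexion ≈ peak) rather than a contact simulation,
because only joint-space features enter the analysis.

Per-trial parameters are drawn from truncated normal distributions whose
means and SDs are the generator's defaults per side
(`default_motion_params()`):

| parameter | paralyzed | non-paralyzed | unit |
|---|---|---|---|
| outward motor time | 2.3 ± 0.7 | 1.3 ± 0.3 | s |
| return motor time | 2.3 ± 0.7 | 1.5 ± 0.3 | s |
| peak shoulder flexion | 48.9 ± 15.4 | 42.3 ± 11.2 | deg |
| peak shoulder abduction | 117.5 ± 16.7 | 118.9 ± 6.2 | deg |
| peak elbow flexion | 134.2 ± 8.0 | 140.0 ± 6.1 | deg |

These are the study conditions of the clinical cohort this package
emulates; they are fixed defaults, not tuning knobs. Truncation uses wide
anatomical bounds (flexion < 88°, abduction < 168°, elbow < 149.5°, motor
time ∈ [0.9, 8] s) rather than the observed min/max, which would bias the
means; 0.9 s is the fastest observed motor time in the task and sub-0.9 s
draws are physiologically implausible. Trunk (C7/CLAV) and head (BHD)
clusters sway as a 0.3 Hz sinusoid of 2–6.4 mm amplitude — sway enters the
analysis only as a displacement covariate, so it is applied to those
markers and not to the arm chain. White marker noise (default 0.05 mm per
coordinate) is added everywhere.

**Motor time is defined as the rule-detected duration.** The segmentation
rule (below) cannot see the sub-threshold tails of a smooth velocity
profile, and the low-pass filter rings briefly after an abrupt stop; both
shift the detected duration relative to the profile duration by
0.05–0.1 s. Published motor times are themselves rule-detected, so the
generator calibrates each trial: a noise-free pass measures the detected
duration at the default 5 mm/s threshold and stretches the profile
(fixed-point, ≤ 3 iterations) until detection returns the sampled motor
time. Noiseless round trips then recover configured times to about one
frame.

**What the generator does *not* emulate.** Peak angular velocities are
emergent, not configured: under minimum-jerk they scale as
amplitude/duration, so the slower paralyzed side always shows *lower* peak
velocities. Clinical cohorts can show the opposite on the return phase
(spasticity-driven velocity bursts), a control-quality effect outside this
model. Velocity-based discrimination results on synthetic cohorts therefore
exercise the machinery but do not reproduce clinical directions. Likewise
absent: synergy coupling between joints, movement decomposition
(multi-peaked velocity profiles), marker soft-tissue artefact, and the full
35-marker body model. Passing tests demonstrate correctness of the
pipeline, not clinical generalization.

## 3. Kinematic extraction

**Filtering.** Zero-phase 4th-order Butterworth low-pass at 6 Hz before any
differentiation — the conventional choice for 100 Hz capture. The series is
detrended by its endpoint line and odd-reflection padded so constants pass
exactly. `filter_cutoff = NULL` disables filtering for noiseless data.

**Segmentation.** Phase onset: first frame beginning a run of ≥ 0.2 s with
3D index-finger speed > ε; phase end: first subsequent frame beginning a
run of ≥ 0.2 s with speed ≤ ε. Literal sample equality ("the position
records the same value") never happens in real data, so "same value" is
operationalized with the threshold; ε defaults to 5 mm/s and is
configurable. With per-frame differentiation at 100 Hz, sub-millimetre
noise multiplies by the rate: the 5 mm/s default assumes a post-filter
noise floor around 0.05 mm. For noisier captures raise ε proportionally
(the detected time is calibrated against ε = 5 in the generator; a mismatch
of a few mm/s costs a few hundredths of a second).

**Segment frames and angles.** The trunk frame takes the gravity vertical
as its longitudinal axis and the horizontal component of C7→manubrium as
anterior. (Taking the raw C7→manubrium direction as anterior would tilt the
frame by the manubrium's natural droop, ~20°, and break the zero-pose
convention; gravity is a physically fixed reference for a seated task, at
the price that lab-rotation invariance holds for rotations about the
vertical only.) The upper-arm long axis runs olecranon→acromion; the
in-plane axis comes from the forearm, falling back to the trunk anterior
axis when the elbow is extended and the arm/forearm plane is undefined —
only the (unreported) axial rotation depends on that axis. Shoulder angles
are the Euler sequence flexion → abduction → axial of the upper-arm frame
relative to the trunk frame; flexion is positive anterior, abduction
positive away from the trunk, elbow flexion 0 at full extension. Abduction
must exceed 90° in this task, so it is recovered as
$\mathrm{atan2}(\sin a,\; R_{13}\sin f + R_{33}\cos f)$ rather than by an
asin fold, giving the full (−180°, 180°) range; the branch with
|flexion| < 90° is selected. Round trips through `forward_kinematics()` are
exact to ~1e-12 deg, including through the |abduction| = 90° singularity.

**Features.** Per phase: motor time; peak (maximum) of each angle series;
peak angular velocity as the maximum *rate of change in the phase's
direction of travel* (outward +dθ/dt, return −dθ/dt); maximum displacement
of the manubrium and side-matched occiput markers from their phase-onset
positions. The phase-directed velocity sign is a deliberate choice: a
plain maximum of dθ/dt during a return (angle-decreasing) phase is ~0 by
construction and could not produce the large positive return-phase
velocities with occasional small negative minima that clinical tables
show; the directed rate reproduces exactly that sign pattern. A
`phase_average` velocity mode (net change / motor time) is exposed for the
alternative reading of "angle change divided by movement time". Trials are
never averaged within a participant.

## 4. Inferential chain

Per phase, the seven features (motor time, three peak angles, three peak
velocities) enter a multivariate linear model with covariates sex, age,
BMI, months post-onset, and the two displacement covariates, plus the side
factor. Wilks' Λ with Rao's F tests the side effect; trials are pooled as
observations (within-subject trial nesting is deliberately not modelled —
the reference analysis pooled trials, giving df [7, 86] at N = 100).
Univariate ANCOVA F and η² = SS(side)/SS(total) accompany each feature, and
a Shapiro–Wilk gate (α = 0.05) routes non-normal features to a
Kruskal–Wallis comparison. In small cohorts the participant-level
covariates collapse to a handful of distinct rows; `run_pipeline()` prunes
constant or collinear covariates with a warning instead of failing, and
degrades to a skipped multivariate test when the dependent variables exceed
the residual degrees of freedom.

Features separating the sides (univariate p < α) get a logistic fit
(`stats::glm` IRLS; deviance, AIC, McFadden R², overall χ² with df = number
of terms) and an ROC analysis. The ROC direction is fixed — "higher value
predicts paralyzed" — for every feature, so features on which the paralyzed
side scores lower (elbow flexion) report AUC < 0.5 rather than being
silently flipped; the cutoff maximizes Youden's J with ties broken toward
the lowest threshold; the AUC is the trapezoid over observed thresholds
(equal to the Mann–Whitney U statistic with half-credit ties). DeLong's
placement-value test compares each feature's AUC against the motor-time
AUC on the same trials. `binomial_min_n()` performs the exact one-sample
binomial power search; one-sided allocation is assumed, which uniquely
reproduces the study-design minimum of n = 8 (a two-sided allocation gives
power 0.43 at n = 8) — recorded as an assumption.

## 5. Random-forest clustering

The clustering variables are motor time and the three joint angles, per
side × phase condition. Rows default to one per trial (50 per condition at
the default design); a frame-level construction (per-frame angle samples
joined to the trial's motor time, subsampled by `frame_stride`) is
available via `row_unit = "frame"` for cohorts where frame-level
observations are wanted — the proximity matrix is O(N²) in memory, which
rules it out as a default at frame-level N in the tens of thousands.

`fit_unsupervised_forest()` builds the synthetic contrast class by
independently permuting each z-scored feature column (destroying joint
structure, preserving marginals), grows `randomForest` trees on the
real-vs-permuted labels (largest Gini information gain among `mtry`
features per split; `gini_impurity()` and `information_gain()` expose the
split mathematics), and reads the proximity of real observations off the
forest. `cluster_from_proximity()` runs k-medoids (`cluster::pam`, plus
seeded random restarts keeping the best objective) on √(1 − proximity).
`elbow_select_k()` computes the feature-space WSS per candidate k, picks
the knee as the largest second forward difference of the curve, reports
AIC = WSS + 2kp and BIC = WSS + ln(n)kp alongside, and flags the choice
low-confidence when the knee does not at least halve the WSS — continuous
clinical data rarely has a razor-sharp knee, and the flag keeps that
honest. Monotonicity of the returned WSS curve is guaranteed: if the
k-medoids solution for k would raise the feature-space WSS over the k−1
solution, the heaviest cluster of the k−1 solution is split instead (a
split can only lower WSS). `cluster_profiles()` reports per-cluster mean
and spread of the z-scored variables and R² = 1 − WSS/TSS.

**Terminal-node size sets the proximity resolution.** Two observations can
only be proximal if they share leaves, so with leaves of 5 observations a
25-member cluster caps its within-proximity near 0.17 even when trees
split it perfectly from the rest. For clustering use, a `min_leaf` near
half the expected cluster size gives much cleaner proximity contrast; the
package default stays at the conventional 5, and the blob-recovery tests
configure `min_leaf = 20` for 25-point clusters on exactly this ground.

## 6. Numerical choices and degenerate inputs

- Segmentation ε = 5 mm/s, window 0.2 s, both configurable; near-zero ε is
  valid for noiseless data.
- Gimbal handling: frames within 1° of the decomposition singularity take
  flexion from the first basis axis (axial rotation set to 0) and are
  flagged; interior flagged frames are smoothed from neighbours.
- Collinear arm/forearm markers (extended elbow) use the documented
  fallback axis; coincident markers (zero-length segments) raise a
  degenerate-frame error with the frame index.
- Logistic fits near complete separation (motor time separates the sides
  almost perfectly) converge to large coefficients; a warning flags
  |coefficient| > 15 or non-convergence instead of failing, since the
  reference analysis reports exactly such fits.
- k-medoids ties and restarts: the deterministic build+swap solution is
  kept unless a seeded restart strictly improves the objective, so runs are
  reproducible under a seed.
- Elbow knee needs k_max ≥ 3 interior points; k = 1 is the trivial
  partition and anchors R² = 0.

## 7. Problem sizes

The shipped tests and the acceptance script use the study-design cohort
(10 participants × 2 sides × 5 trials, ~6 s of 100 Hz data per trial), 100
seeded cohort replicates for the parameter-recovery check, forests of
80–500 trees, and blob fixtures of 75–100 observations — sizes chosen so
the full validation chain represents the study design faithfully while a
complete run stays in the minutes range on one CPU.

## 8. Known limitations

- The paralyzed/non-paralyzed contrast is within-participant; the package
  does not model healthy-control asymmetry, so "non-paralyzed" is a
  pragmatic, not a normative, reference.
- Trial nesting within participants is ignored by design (pooled trials);
  a mixed-effects extension is out of scope.
- No multiple-testing correction across features (none is applied in the
  reference chain).
- Wrist/finger kinematics and hand–occiput contact are not modelled or
  extracted.
- AIC/BIC for cluster solutions follow the WSS + penalty convention stated
  above; they are reported for curve reading, not as an absolute
  goodness-of-fit scale.
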