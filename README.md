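# headreach

Kinematic analysis of the seated *reach-to-the-occiput* task (touching the
back of the head with the palm) in mild post-stroke hemiplegia.

Reaching the occiput requires a wide range of motion and tight
shoulder–elbow coordination, which makes it a sensitive probe of residual
upper-limb impairment even when clinical scales hit their ceiling. Given 3D
marker trajectories of the task, this package answers three questions that
matter to rehabilitation planning:

1. **Which kinematic features separate the paralyzed from the non-paralyzed
   limb?** Motor time, peak joint angles and peak angular velocities per
   movement phase, compared with a covariate-adjusted multivariate model.
2. **At what value does a feature discriminate the two sides?** Binomial
   logistic fits and ROC cutoffs by Youden's index, with DeLong tests for
   AUC differences.
3. **What motion patterns exist within each side?** Unsupervised
   random-forest proximity clustering with elbow-method selection of the
   cluster count and z-value cluster profiles.

Because raw patient recordings are rarely shareable, the package includes a
first-class synthetic-motion module that simulates the task (minimum-jerk
joint trajectories, postural sway, marker noise, side-dependent parameter
distributions) and writes/reads standard TRC and long-CSV marker formats,
so every stage can be exercised end to end and validated by round trips.

## The methods in brief

- **Segmentation.** Phase onset is the first frame beginning a ≥ 0.2 s run
  in which the index-finger marker's 3D speed exceeds ε (default 5 mm/s);
  the phase end is the first subsequent frame beginning a ≥ 0.2 s run at or
  below ε. Applied twice this yields the outward (rest → occiput) and
  return (occiput → rest) phases; motor time is (end − onset)/fs.
- **Joint angles.** Per-frame segment frames (trunk from C7/manubrium +
  vertical; upper arm acromion→olecranon; forearm olecranon→wrist) and an
  Euler decomposition in the order flexion → abduction → axial rotation.
  Abduction is recovered with full (−180°, 180°) range; forward kinematics
  → extraction round trips are exact to ~1e-12 deg.
- **Side comparison.** Wilks' Λ with Rao's F on the 7 features per phase,
  adjusted for sex, age, BMI, months post-onset and trunk/head marker
  displacement (trials pooled as observations: df [7, 86] at N = 100), with
  a Shapiro–Wilk-gated Kruskal–Wallis fallback per feature.
- **Cutoffs.** ROC sweep with the fixed rule "higher value predicts
  paralyzed" (no direction flipping: features on which the paralyzed side
  scores *lower* report AUC < 0.5 as-is); cutoff at max *J* = sens + spec − 1.
- **Clustering.** A contrast class is built by independently permuting each
  feature column; a random forest separates real from permuted rows; the
  fraction of trees in which two trials share a terminal leaf is their
  proximity; k-medoids on √(1 − proximity) partitions the trials, with the
  cluster count at the sharp knee of the within-cluster sum-of-squares
  curve.
- **Design.** The exact one-sample binomial power search (`binomial_min_n`)
  reproduces the study-design minimum of n = 8 participants at p₀ = 0.5,
  g = 0.4, α = 0.05, power 0.8.

## Worked example

```r
library(headreach)

report <- run_pipeline(pipeline_config(seed = 1))
print(report)
```

```
<run_report> 100 trials x 2 phases, 10 participants
  outward: Wilks lambda 0.524, F[7,86] = 11.2, p 5.82e-10
    motor_time               cutoff     1.63  sens 0.90  spec 0.90  J 0.80  AUC 0.95
    peak_shoulder_flex       cutoff     45.6  sens 0.52  spec 0.70  J 0.22  AUC 0.58
    peak_elbow_flex          cutoff      149  sens 0.02  spec 1.00  J 0.02  AUC 0.26
    ...
  return: Wilks lambda 0.676, F[7,86] = 5.9, p 1.3e-05
    motor_time               cutoff     1.98  sens 0.78  spec 0.92  J 0.70  AUC 0.88
    ...
  clusters paralyzed_outward        k = 4 (n = 50, R2 = 0.45) [low confidence]
  clusters non_paralyzed_return     k = 4 (n = 50, R2 = 0.34) [low confidence]
```

Reading this: the simulated cohort (10 participants × 2 sides × 5 trials,
side-dependent motor times 2.3 ± 0.7 s vs 1.3 ± 0.3 s) shows a strong
multivariate side effect in both phases. Outward motor time discriminates
the sides at a cutoff of **1.63 s** (AUC 0.95, *J* = 0.80): a trial slower
than ~1.6 s most likely comes from the paralyzed limb. Peak elbow flexion
has AUC 0.26 — the *non-paralyzed* side flexes the elbow further, so under
the fixed ROC direction its AUC falls below 0.5. Each side × phase
condition partitions into 3–5 motion-pattern clusters explaining 34–45 % of
the z-space variance; the low-confidence flag warns that continuous
clinical data has no razor-sharp WSS knee.

Individual stages are ordinary functions: `simulate_trial()`,
`generate_cohort()`, `extract_features()`, `manova_rm()`, `logistic_fit()`,
`roc_analysis()`, `delong_auc_test()`, `binomial_min_n()`,
`fit_unsupervised_forest()`, `cluster_from_proximity()`,
`elbow_select_k()`, `cluster_profiles()`, plus TRC/CSV I/O
(`write_trc()`, `read_trial_files()`) and YAML configs
(`write_pipeline_config()`). See the methods vignette
(`vignettes/occiput-reaching-pipeline.Rmd`) for the model, parameter and
design discussion.

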