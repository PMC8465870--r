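---
title: "Two-level SOM clustering of postural sway: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level SOM clustering of postural sway: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swaysom)
library(dplyr)
```

# The problem

The modified Clinical Test of Sensory Interaction and Balance (mCTSIB) has
a standing subject hold four 30 s conditions that cross support surface
(firm / foam) with vision (eyes open / closed), progressively removing the
visual and proprioceptive contributions to balance.  A tri-axial
accelerometer worn on the lower back (near the iliac crest) records body
sway at 60 Hz.  This package quantifies how *distinguishable* each
degraded condition is from the reference condition (condition 1, all
sensory systems available), separately for the mediolateral (ML) and
anterior-posterior (AP) sway directions, by clustering subjects' sway
features and scoring the clusters against the known condition identity.
Small external scores mean the two conditions produce similar sway; large
scores mean the withdrawn sensory input changed sway enough for an
unsupervised method to tell the groups apart.

# From raw counts to sway features

1. **Unit conversion.** The sensor emits integer counts (LSB).  Dividing
   by the sensitivity scale factor (16,384 LSB/g for the ±2 g range)
   yields acceleration in g.
2. **Low-pass filtering.** Each axis is filtered with a causal
   second-order Butterworth low-pass at 4 Hz, the band that contains
   quasi-static postural sway.  The filter state is initialised at steady
   state for the first sample (implemented by padding with the first
   value for `8 * fs / cutoff` samples, which settles the start-up
   transient below 1e-12); without this, the gravity-dominated vertical
   channel would begin with a large artificial transient that corrupts
   the inclination-offset reference taken from the first sample.  A
   zero-phase two-pass variant exists behind `zero_phase = TRUE`, off by
   default because it doubles the effective order.
3. **Ground projection.** Under the inverted-pendulum view of quiet
   stance, the resultant acceleration `R = sqrt(ax² + ay² + az²)` defines
   direction cosines `cos α = ax/R`, `cos β = ay/R`, `cos γ = az/R`, and
   the centre-of-mass (COM) ground displacements are `dx = -L cos α`,
   `dy = -L cos β`, `H = L cos γ`, with `L` the COM height.  Only the
   direction of the acceleration vector matters, so the projection is
   invariant to the acceleration unit.  `L` is not measured directly; we
   default to the standard anthropometric fraction `L = 0.53 × height`,
   overridable per subject.
4. **Kinematics and features.** Per direction, the inclination offset is
   removed by subtracting the first displacement sample
   (`D_n = d_n − d_1`); velocity and acceleration follow by first
   differences with `T = 1/fs`.  Leading undefined samples are dropped
   rather than zero-padded, and each RMS normalises by its own valid
   length, so no artificial zeros bias the features.  The per-recording
   features are the RMS of position (cm), velocity (cm/s) and
   acceleration (cm/s²).

The device mounting convention is configurable (`axis_map`); the default
takes the sensor x axis as ML, y as AP.

# Feature screening

Across the cohort (rows pooled within a direction), the three RMS
measures are screened for collinearity: each feature's pooled sample is
Shapiro-Wilk tested (α = 0.05); a pair of features is correlated with
Pearson only if both pass, otherwise with Kendall's tau-b.  Pairs with
|coefficient| ≥ 0.85 are collinear and one member is dropped, strongest
pair first, until none remain.  Velocity and acceleration RMS are near
monotone transforms of one another for band-limited sway, so in practice
acceleration is removed and position + velocity remain.

Which member of a collinear pair to drop is a genuine design choice.  We
drop the *later-listed* (higher-order) kinematic measure: when two
measures carry the same ordering information the lower-order one is the
more directly interpretable, and derivatives amplify sensor noise.  An
alternative rule that drops the member with the larger mean absolute
correlation to all other candidates is available
(`drop_rule = "mean_abs_corr"`); note that for the typical correlation
pattern (velocity–acceleration very high, position–velocity slightly
above position–acceleration) that rule removes velocity, not
acceleration.

# The two-level clustering

**Level 1 — Kohonen self-organizing map.** A 10 × 10 hexagonal map (unit
spacing, link-distance neighborhoods) is batch-trained for 1000
iterations with initial neighborhood radius 3.  In a batch epoch every
neuron moves to the mean of all samples whose best-matching unit (BMU)
lies within the current radius (step-function kernel, the batch-toolbox
convention); neurons with empty neighborhoods keep their weights, and
the radius shrinks linearly to 1 over the first half of training, the
coarse-to-fine ordering phase.  Weights are initialised with small
uniform values in [0, 0.01], seeded.  Because batch updates are means,
the algorithm is independent of presentation order; we sort the input
rows canonically before summation so that invariance holds *exactly* in
floating point, not merely to rounding error.  The sequential rule
(`method = "sequential"`, Gaussian neighborhood, learning rate decaying
linearly to its floor) is provided for completeness but the pipeline
uses batch training.

Features are z-scored over the assembled 46-row pair matrix before
training (flag `scale` in `pair_matrix()`): position (cm) and velocity
(cm/s) live on different scales and an unscaled Euclidean BMU would be
dominated by one of them.

A numerical caveat worth knowing: with the radius floored at 1 the batch
update is a *smoothed* Lloyd step, and the quantization error typically
settles into a tiny period-2 limit cycle rather than decreasing
monotonically; only at radius 0 (exact Lloyd) is monotonicity
guaranteed.  The tests assert exactly that distinction.

**Level 2 — K-means over active prototypes.** Every neuron that wins at
least one sample becomes a prototype, taken as the *centroid of its
member samples* (the neuron's raw weight vector is available via
`type = "weight"`); this reading makes the later replacement of
centroids by their constituent data points exact.  The prototypes are
clustered with K-means (k-means++ seeding, Lloyd iterations, empty
clusters re-seeded at the farthest point, 10 restarts keeping the best
within-cluster sum of squares).

**Choosing K.** The Davies-Bouldin (DB) index is scanned over K = 2..30
on the reference pair (conditions 1 vs 4, where the largest sway
difference is expected).  For cluster scatters we use the
root-mean-square distance of members to the cluster mean — the natural
scalar "standard deviation of a cluster" for vector data — and each
cluster's ratio is maximised over *all* other clusters, the standard DB
definition.  Among the local minima of the mean-DB curve (global minimum
always included) the K with the highest mean F-measure wins, ties going
to the smaller K, and that K is reused for the other condition pairs.

# External evaluation

Data points inherit their prototype's cluster and are cross-tabulated
against condition identity.  Each cluster is labeled by its majority
condition (ties to the lower condition index, deterministically).  With
`n_ij` members of condition j in cluster i, `n_i = Σ_j n_ij`,
`m_j` the condition totals and `n` the grand total:

* per-cluster precision (= purity): `max_j n_ij / n_i`;
* purity: the size-weighted mean `Σ_i (n_i/n) prec_i`;
* precision and recall: *unweighted* cluster averages (their defining
  formulas carry no `n_i/n` weights — only purity does);
* per-cluster recall: `n_ij* / m_j*` for the majority condition j*;
* `F_i = 2 prec_i recall_i / (prec_i + recall_i)`, averaged over
  clusters.

For a balanced 23 + 23 design these measures have analytic bounds: the
purity and average precision floors are 0.5 (everything collapsed into
one cluster), the ceiling is 1 (pure and complete clustering), and the
minimum cluster-averaged recall over all assignments into exactly K
non-empty clusters is 1/K (0.5, 0.25, ≈0.17 for K = 2, 4, 6).
`min_bounds()` computes the recall floor exactly by minimising over all
integer compositions of per-cluster class counts via dynamic
programming, rather than trusting the 1/K shortcut; the tests check the
programme against a recursive enumeration on small instances.

The clustering is repeated 30 times with re-shuffled rows and fresh
SOM/K-means seeds, and medians with interquartile ranges are reported
per condition pair × direction.  Note that because batch SOM training is
order-invariant, repetition variability enters through the seeded weight
initialisation and the K-means restarts, not through the shuffle itself
(which is retained for protocol fidelity).  ML and AP values of each
measure, pooled across the three pairs, are compared with an
independent-samples t-test when both samples pass Shapiro-Wilk and a
two-sided Mann-Whitney U-test otherwise.

A `combined` direction mode concatenates the retained ML and AP features
per subject (four features when position + velocity are retained in
both) and z-scores after concatenation.

# The synthetic cohort

The subject recordings behind this kind of study are typically
restricted, so the package ships a generator whose output has the
statistical structure the analysis assumes, making every stage testable
from code alone.

* **Sway process.** Gaussian white noise through a second-order
  Butterworth low-pass at the sway bandwidth (default 1 Hz, well inside
  the 4 Hz analysis band), anchored at zero initial displacement and
  scaled so the sample RMS equals the condition target exactly.  The
  anchor reflects a subject starting upright and aligns the generator
  with the first-sample offset reference the kinematics subtract; a
  mean-centred path with a random first sample would instead inflate the
  recovered RMS by roughly √2 and make round-trip recovery meaningless.
* **Condition targets.** AP RMS 0.40 / 0.70 / 0.90 / 1.40 cm and ML RMS
  0.30 / 0.45 / 0.32 / 0.60 cm for conditions 1–4: sway grows from
  condition 1 to 4, the AP effect is larger than the ML one, and ML sway
  barely moves between the eyes-open conditions because vision
  stabilises the frontal plane.  No cohort-specific magnitudes are
  published for this design, so these are plausible stand-ins on the
  centimetre scale reported for quiet stance, not calibrated values.
* **Between-subject variability.** Two per-subject lognormal factors:
  σ = 0.15 on the RMS amplitude targets, and σ = 0.7 on the sway
  bandwidth (clipped to [0.2, 3] Hz to respect the analysis band).  The
  second factor matters: with amplitude jitter alone, position, velocity
  and acceleration RMS would be exactly proportional across subjects and
  the collinearity screen would collapse all three to one feature.  A
  frequency spread makes velocity ≈ amplitude × bandwidth and
  acceleration ≈ amplitude × bandwidth², reproducing the empirically
  observed pattern: velocity–acceleration strongly correlated (τ ≳
  0.85), position only weakly correlated with either.
* **Sensor model.** Quasi-static inversion at 1 g resultant
  (`ax = -dx/L`, `ay = -dy/L`, `az` completing the unit vector), which
  makes the generator analytically invertible by the projection;
  additive Gaussian noise (default 5 × 10⁻⁴ g, a low-pass-configured
  MEMS noise floor); scaling by 16,384 LSB/g; rounding; clipping to the
  two's-complement range [−32768, 32767].
* **Seeds.** One master seed; per-subject/condition/channel stream seeds
  derive from it by the counter scheme in `derive_seed()`
  (`(master mod 2²⁰)·2¹¹ + subject·2⁶ + condition·2³ + channel`), so any
  subset of the cohort reproduces exactly.

What the generator does **not** emulate: real postural control dynamics
(no inverted-pendulum ODE, no feedback), non-stationarity and fatigue
within a trial, gyroscope channels, sensor bias/drift, or inter-trial
carry-over.  Passing tests therefore certify the *pipeline* — unit
conversion, filtering, projection, screening, clustering and scoring —
under data that satisfy its assumptions, not clinical validity on real
cohorts.

# Numerical and protocol choices

* Filter: causal single pass by default (the stated order is the
  effective order); steady-state initialisation as above.
* Degenerate inputs: zero resultant acceleration raises an error naming
  the sample; constant samples are reported non-normal with a warning;
  coincident K-means centroids make the DB index error rather than
  return Inf; K values beyond the prototype count are clipped with a
  warning.
* Ties: BMU ties go to the lower neuron index; majority-label ties to
  the lower condition; equal-F K choices to the smaller K; collinear
  drop ties to the later-listed feature.  All deterministic.
* Problem sizes: the unit tests run reduced maps (3×3 to 6×6, tens of
  iterations) chosen to exercise every code path quickly; the acceptance
  suite runs the full default protocol once (23 + 23 subjects, 10 × 10
  map, 1000 iterations, 30 repetitions, three pairs, both directions),
  which completes in a few minutes on one core.

# A worked run

```{r study, eval = FALSE}
feats <- simulate_cohort(seed = 1) |> extract_sway_features()
ev <- run_study(feats, seed = 1)
ev
autoplot(ev)
```

On synthetic cohorts with the default effect sizes the study reproduces
the qualitative findings the pipeline is built to expose: AP measures
exceed ML measures (significantly over the 30 repetitions), the 1v4
contrast is at least as large as 1v2 in the AP direction, and when the
two eyes-open ML targets are set equal the ML 1v3 measures sit at their
0.5 floor.  Exact medians depend on the seed; the test suite computes
and checks them.

# Limitations

* The default effect sizes are stand-ins; absolute median measures on
  synthetic data should not be compared numerically against any real
  cohort.
* The quasi-static 1 g inversion ignores genuine COM accelerations; the
  forward analysis tolerates this, but the generator is not a dynamics
  simulator.
* The DB-guided K selection inherits the instability of internal indices
  on small prototype sets; the F-measure arbitration among DB minima
  mitigates but does not remove it.
* With strongly separated synthetic conditions the 30 repetitions often
  agree exactly (IQR 0); real cohorts produce more dispersion.
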