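---
title: "Learning surgeon-specific preoperative plans for total knee arthroplasty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning surgeon-specific preoperative plans for total knee arthroplasty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeplan)
```

## The problem

In 3D-planned total knee arthroplasty (TKA), the instrumentation manufacturer
derives a default preoperative plan (the MPP) from the patient's imaging using
fixed rules. Surgeons then revise it: implant sizes, resection depths,
rotations and translations are adjusted to their own alignment philosophy and
to the individual anatomy, producing the surgeon-corrected plan (SCP). These
revisions are frequent and time-consuming, and different surgeons revise
differently -- there is no consensus target alignment to encode in a fixed
rule set.

`kneeplan` treats plan revision as a supervised learning problem, *one model
per surgeon and per planning parameter*: given anatomy-derived features and
the default plan, predict the plan that this surgeon would approve. The
quality measure is operational rather than geometric: the number of discrete
correction steps (0.5 mm of translation or resection, 0.5 degrees of
rotation, or one implant size) still separating the predicted plan from the
surgeon's plan. These are exactly the increments planning interfaces expose,
so a correction count is the number of clicks a surgeon still has to make.

## Plan representation

A plan has 14 degrees of freedom (DOFs): per bone (femur, tibia) one ordinal
implant size plus coronal/axial/sagittal rotations and translations. All
continuous DOFs live on 0.5 mm / 0.5 degree grids; sizes are ordinal indices
into a catalog with monotone AP/ML dimensions. `snap_to_grid()` rounds half
away from zero (a deterministic, symmetric tie rule) and clamps sizes;
`count_corrections()` counts grid steps per DOF and sums them. A change of
two implant sizes counts as two corrections (ordinal distance); the
alternative -- counting any size change as one -- is defensible, but ordinal
distance preserves additivity and symmetry, and is what the per-step
definition of every other DOF implies.

## The synthetic data generator

No clinical planning data are publicly available, so the package ships a
fully synthetic generator that reproduces the *statistical structure* the
method relies on, layer by layer:

* **Anatomy.** A statistical shape model (SSM) per bone, trained on
  procedurally deformed template point clouds (ellipsoid-composite femur and
  tibia, roughly 160 and 110 points, with the 26 named landmarks as dedicated
  points so correspondence is free). Deformations vary overall size, ML/AP
  proportions, taper, bow and coronal tilt, with a shared per-knee size
  component; random rigid motions are removed again by the generalized
  Procrustes alignment. The alignment is deliberately *rigid* (no scale
  normalization): bone size is the single most informative predictor of
  implant size, so it must survive into the model's variation modes. New
  anatomies are drawn with independent normal mode coefficients at the
  model's per-mode variances (raw component scores, not SD units).
* **Default plans.** Deterministic sizing rules (smallest femoral size
  covering the AP depth -- no notching by construction; largest tibial size
  within the plateau width -- no overhang) plus fixed alignment defaults:
  neutral varus/valgus, 3 degrees femoral flexion and tibial slope, 9 mm
  resections (distal, posterior, proximal), zero displacements and axial
  rotations. The 9 mm femoral posterior resection is the package's own
  choice of a typical cut where the rule set needed one more default.
* **Surgeons.** A `surgeon_profile()` gives, per DOF: a gate probability
  (how often the surgeon touches the DOF at all), a linear preference over
  four interpretable anatomy features (ML width, AP depth, a joint-line
  varus proxy, the first femoral shape coefficient) plus an intercept, a
  noise SD, and an outlier term (rare large changes). The default profile
  generator calibrates effect sizes against the model population so that the
  systematic correction SD is 1.5 mm/deg (0.8 sizes) at a signal-to-noise
  variance ratio of 10, with gates open 90% of the time and 3% outliers of
  8 mm/deg SD -- a surgeon with strong, learnable, anatomy-driven habits.
  These defaults define the package's study conditions; pass other values to
  model timid or erratic surgeons.

What the generator does **not** emulate: real mesh geometry and cartilage,
inter-feature correlations beyond what the SSM induces, drift of a surgeon's
preferences over time, and intra-surgeon planning variability (a real
surgeon replanning the same knee does not reproduce their own plan exactly).
Passing tests therefore show the pipeline recovers the preference structure
it assumes; they cannot certify clinical performance.

## Features

Each case yields 149 features: 26 landmarks x 3 coordinates (expressed in
the anatomical frame of their own bone, making the vector rigid-invariant),
57 implant-fit measurements (notching distance, per-side over/underhang,
widths, depths, dimension ratios, and signed distances from the three
planned resection planes to every landmark of the cut bone), and the 14
default-plan DOFs as a baseline the models learn to correct. Fifteen SSM
coefficients per bone are also computable; the default `"paper149"` profile
excludes them from the assembled vector (the 78 + 57 + 14 accounting is
exact), while the `"full"` profile appends them (179 features). Extraction
is deliberately transform-free; standardization is a training-time concern.

## Feature selection

Three embedded, sparsity-inducing selectors operate on the standardized
design (zero-mean, unit-SD columns; constant columns flagged and forced to
zero; targets centered -- so the intercept is never penalized):

* **Lasso**, per target: `0.5 ||y - X b||^2 + lambda ||b||_1`.
* **Group Lasso**, per target: the l1 norm replaced by a sum of group l2
  norms with sqrt-group-size penalty factors; each landmark's three
  coordinates form one group, everything else is a singleton, so landmarks
  are selected whole.
* **Multi-Task Lasso**: one coefficient matrix for all 14 targets with an
  l2,1 penalty (sum of row norms), giving a single feature subset shared
  across targets.

All three are solved by (block) coordinate descent written for this package:
closed-form coordinate/row updates, block proximal-gradient steps for
coordinate triplets, full KKT verification on a freshly recomputed residual
each outer iteration, and warm-started geometric penalty paths with
sequential strong-rule screening (features enter only if already active or
passing the strong rule; excluded features are KKT-checked and pulled in if
they violate). The penalty is chosen by 10-fold cross-validated prediction
error over a path from `lambda_max` down three decades (50 points by
default; the planner uses 30), ties broken towards the sparser model, then
refit on all rows. CV path fits run at a relaxed KKT tolerance (1e-3,
relative to the penalty scale) since they only feed error ranking; the
final refit is solved to 1e-6 -- tight enough that coefficient error is far
below any 0.5-grid effect, and attainable even where near-exact collinearity
among landmark coordinates and plane-distance measurements makes coordinate
descent crawl below that.

## Regression

Two non-linear regressors with a Gaussian RBF kernel
(`exp(-||x - z||^2 / (2 sigma^2))`) compete on the selected features, both
fit on standardized inputs and targets:

* **eps-SVR**: the classical epsilon-insensitive dual QP, solved by libsvm's
  SMO decomposition (via `e1071`); the fitted model is kept as an explicit
  kernel expansion so predictions are transparent and testable.
* **LAD-SVR**: a robust kernel regressor minimizing
  `0.5 a'Ka + C sum_i huber_delta(y_i - (Ka)_i - b)`. The Huber threshold
  `delta` defaults to 1 on standardized targets. The objective is smooth and
  convex and is minimized by damped Newton iterations with backtracking line
  search -- fast at per-surgeon sample sizes (around a hundred cases), with
  a monotone objective trace and a gradient-norm exit criterion. Because
  large residuals are penalized linearly, a surgeon's occasional drastic
  correction barely displaces the fit; the squared-loss analogue chases it.

Hyperparameters are tuned by exhaustive grid search under 10-fold CV on
log-spaced values inside (1e-6, 1e6), jointly over the grid, with ties going
to smaller `C` then larger `sigma` (the more regularized model). The default
pipeline grids are deliberately small (C in {1, 10, 100}; sigma in
{1, 2} x sqrt(p), the natural length scale of a standardized p-dimensional
feature space; epsilon = 0.1; delta = 1); pass `planner_control()` a denser
grid for a slower, finer search.

## The per-surgeon planner

For each surgeon (trained only on their own cases) and each DOF, six
selector/regressor combinations plus an **MPP-copy baseline** enter a
contest scored by 10-fold cross-validated *mean correction steps* -- the
operational metric, not MSE -- on a shared fold split. The winner (ties:
baseline first, then Lasso < group Lasso < Multi-Task, LAD-SVR < SVR) is
refit on the full training set. The baseline guarantees non-inferiority: a
surgeon the models cannot predict gets their default plan back unchanged.

Nesting is deliberately single-level: the selector penalty and the regressor
hyperparameters are tuned once by CV on the full training set, and the
combo-level contest reuses those settings on shared folds, refitting only
the regressor per fold. Fully nested tuning inside every contest fold would
multiply the fit count roughly a hundredfold while leaving the
model-selection contract unchanged; with the small per-DOF hyperparameter
space the optimism this admits is limited, and the MPP-copy baseline bounds
the damage of any over-optimistic winner.

Prediction assembles the per-DOF winners, snaps to the grids and clamps
sizes. Evaluation counts corrections against the SCP for the default plan,
each fixed combination, and the assembled plan (APP), plus exact femoral and
tibial size-match rates.

## Statistical evaluation

The study-level summary follows the method-comparison conventions of the
field: per-surgeon mean corrections per method; improvement as the *mean of
per-surgeon percentage reductions* (not a pooled ratio -- the two disagree
whenever surgeons differ in volume or difficulty); a Friedman test across
the six learned combinations (tie-corrected chi-square, or the exact
within-row permutation distribution when `(k!)^n` is small enough to
enumerate); one-sided Wilcoxon signed-rank tests between methods (zeros
dropped by the Wilcoxon convention, exact signed-rank distribution when
there are no ties among at most 16 nonzero differences, otherwise the
normal approximation with tie and continuity corrections); Pearson
correlations; and a two-sample normal-approximation sample-size formula
`n_per_group = (z_{1-alpha/2} + z_power)^2 (s1^2 + s2^2) / (m1 - m2)^2`.
P-values are reported raw, without multiplicity correction, and the report
says so.

## Numerical choices and problem sizes

Tolerances: selector KKT 1e-8 (strict fits) / 1e-3 (CV path fits); LAD-SVR
gradient norm 1e-6; SVR SMO tolerance 1e-3 by default (1e-8 in
solver-equivalence tests); degenerate inputs (constant targets, constant
feature columns, boundary anatomies outside the catalog) all have defined,
tested behaviour rather than errors. All randomness flows from a single
master seed through named substreams, so every dataset, split, fold
assignment and fitted model is bit-reproducible.

The shipped experiments run at desk scale by design: shape models from 60
synthetic training knees with 20 modes; study datasets of 5-10 surgeons at
80-150 cases each with a 70/30 train/test split; the reduced hyperparameter
grids above. These sizes exercise every code path in minutes on one CPU
while leaving the learning problem genuinely hard (over a hundred correlated
features, a hundred training cases).

## Limitations

The feature set is static and bone-derived; soft tissue, kinematics and
cartilage are absent by construction. Selector interactions are not modelled
(main effects only). The generator's surgeons are linear-plus-noise; real
preference structure may be nonlinear or non-stationary. The planner is
per-surgeon only -- it needs tens of cases per surgeon before it can beat
the default plan, and shares nothing across surgeons.
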