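# kneeplan

Surgeon- and patient-specific preoperative planning for total knee
arthroplasty (TKA).

## The problem

3D TKA planning starts from a manufacturer's default plan (MPP): fixed rules
place a femoral and a tibial implant on the patient's bone models. Surgeons
then correct it — sizes, resection depths, rotations, translations — towards
the plan they are willing to approve (the SCP), one 0.5 mm / 0.5° / one-size
step at a time. Those corrections are frequent, surgeon-specific and
time-consuming. `kneeplan` learns them: for each surgeon, and for each of the
14 planning degrees of freedom (DOFs), it trains models that predict the
surgeon's corrected value from anatomy-derived features, and assembles the
best per-DOF models into an AI-based plan (APP) that needs fewer corrections.

The package is aimed at computational-orthopedics researchers and planning
-software engineers who want a complete, reproducible reference pipeline:
plan representation, synthetic data, feature extraction, sparse selection,
robust kernel regression, per-surgeon model selection and statistical
evaluation.

## The method

For a surgeon with cases `(x_i, y_i)` — feature vectors `x_i ∈ R^149`
(26 landmarks × 3 coordinates in anatomical frames, 57 implant-fit
measurements, 14 MPP DOFs) and plan targets `y_i` — each DOF is predicted by
the winner of a 7-way contest:

* **Feature selection** (per DOF, 10-fold CV over a penalty path):
  - Lasso: `min ½‖y − Xθ‖² + λ‖θ‖₁`
  - group Lasso: `min ½‖y − Xθ‖² + λ Σ_g √|g| ‖θ_g‖₂` (landmark coordinate
    triplets grouped)
  - Multi-Task Lasso: `min ½‖Y − XΘ‖²_F + λ‖Θ‖₂,₁` (one subset shared by
    all 14 DOFs)
* **Regression** on the selected features (10-fold CV grid search over
  log-spaced hyperparameters):
  - ε-SVR with a Gaussian RBF kernel, and
  - LAD-SVR: a robust kernel fit `min ½α'Kα + C Σ huber_δ(y_i − (Kα)_i − b)`
    solved by damped Newton iterations — outlier corrections are penalized
    linearly, so one drastic revision barely moves the fit.
* **An MPP-copy baseline** enters every contest, so a surgeon the models
  cannot predict gets the default plan back unchanged.

Candidates are scored by cross-validated **correction steps** — the number of
0.5 mm / 0.5° / one-size increments separating the snapped prediction from
the surgeon's plan — and evaluation on held-out cases reports mean
corrections per method, per-surgeon improvement percentages, implant-size
accuracies, Friedman and one-sided Wilcoxon signed-rank tests.

Because clinical planning data are proprietary, the package includes a
first-class synthetic generator: statistical-shape-model anatomies, rule-based
default plans, and parameterized surgeon behaviour (gate probabilities,
anatomy-linked preferences, noise, outliers). See the methods vignette
(`vignettes/planning-methods.Rmd`) for the model, its assumptions and its
limits.

## Worked example

```r
library(kneeplan)

model   <- build_synthetic_knee_model(seed = 42)       # SSM per bone
catalog <- default_catalog()                            # 8 + 8 implant sizes
surgeon <- sample_surgeon_profile(model, seed = 1)      # learnable habits
cases   <- generate_dataset(model, list(S1 = surgeon), cases_per_surgeon = 150,
                            catalog = catalog, seed = 9)

split <- split_dataset(cases, seed = 9)                 # 70/30 per surgeon
print(split)
#> S1: 105 train / 45 test

planner <- train_surgeon_planner(
  Filter(function(cs) cs$case_id %in% split$surgeons$S1$train, cases),
  catalog, seed = 5)

report <- evaluate_planner(
  planner,
  Filter(function(cs) cs$case_id %in% split$surgeons$S1$test, cases),
  catalog)
print(report)
#> Evaluation for surgeon S1 (45 test cases)
#>   MPP 41.04 (15.86) -> APP 17.53 (9.06) corrections
#>   size accuracy: femur 66.7% (MPP 35.6%), tibia 75.6% (MPP 37.8%)
```

Reading the output: on the 45 held-out cases this synthetic surgeon would
have to make 41.0 corrections on average to the manufacturer's default plan,
but only 17.5 to the learned plan (a 57% reduction), and the learned plan
gets the femoral implant size exactly right in 66.7% of cases versus 35.6%
for the default. `print(planner)` lists which selector/regressor combination
won each DOF, and `selected_feature_report(planner)` names the anatomical
features each winning model uses — the interpretability surface shown to
surgeons.

For multi-surgeon studies, `run_study()` wraps splitting, training and
evaluation and adds the cross-method statistics (Friedman test over the six
learned combinations, Wilcoxon APP-vs-MPP, improvement mean ± SD).

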