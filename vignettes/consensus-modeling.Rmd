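---
title: "Consensus bucket-of-models classification of task-fMRI activation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus bucket-of-models classification of task-fMRI activation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmribucket)
```

## The problem

Chronic fatigue syndrome (CFS) and Gulf War illness (GWI) present with
nearly identical symptom profiles, yet may involve different brain
physiology. During an n-back working-memory task, the 2-back > 0-back
contrast isolates working-memory load; per-subject t-statistic maps of that
contrast carry a spatial activation pattern that an ensemble of classifiers
can exploit to discriminate the two diagnoses. `fmribucket` implements that
discrimination pipeline end to end:

1. **Feature extraction** — voxels with *t* strictly exceeding a threshold
   (default 3.17, i.e. p < 0.001 uncorrected) are counted within each
   region of an integer-labelled anatomical atlas (117 regions in the AAL
   layout), giving a subjects × regions table of suprathreshold voxel
   counts.
2. **Collinearity screen** — Pearson correlations among all regions,
   computed on the training set, the testing set, and both combined; any
   pair with |R| ≥ 0.9 in any of the three is merged (counts are additive)
   until no pair is flagged.
3. **Bucket of models** — nine classifiers (k-nearest neighbours, linear
   SVM, decision tree, random forest, AdaBoost, Gaussian naive Bayes,
   regularized QDA, ridge logistic regression, a small multilayer
   perceptron) trained on a stratified 50:50 split, preceded by recursive
   feature elimination, and iteratively re-built: features with zero
   random-forest importance, or with an importance standard error larger
   than the importance itself, are pruned and the bucket refit until every
   model clears a 69% accuracy floor (or nothing is pruned, or an iteration
   cap is hit).
4. **Consensus statistic** — for each agreement threshold k = 1..9, the
   segment of test subjects predicted CFS by at least k models is scored:
   precision (fraction of selected subjects truly CFS), sensitivity,
   specificity and FDR = 1 − precision.
5. **Significance** — a full-pipeline label-shuffle permutation test: group
   labels are re-shuffled, the entire build re-run, and the observed
   minimum per-model accuracy compared with its null distribution using the
   add-one rule p = (1 + #{null ≥ observed}) / (reps + 1), with a
   Bonferroni-adjusted per-model threshold alongside.

Because the subject-level imaging data behind the reference results are not
publicly deposited, the package ships a synthetic cohort generator whose
defaults emulate the study design (38 CFS / 80 GWI, 117 regions,
demographics with the reported means), so every stage is testable without
any download.

## The synthetic cohort model

Per subject and region, a latent suprathreshold voxel count is drawn from a
negative binomial with mean $\mu_r$ (default 15) and size $\theta$ (default
8), so the variance is $\mu + \mu^2/\theta$ — counts of activated voxels
are overdispersed non-negative integers; no count distribution is
reported for the real data, so this is a stated assumption of the
generator, not an empirical claim. In the chosen *effect regions* the GWI mean is raised so
that the **pooled** standardized mean difference equals `effect_size`
exactly: because the negative-binomial variance grows with the mean, the
shifted mean is solved numerically from
$(\mu_b-\mu_a)/\sqrt{(v(\mu_a)+v(\mu_b))/2} = d$ rather than taken as
$\mu_a + d\,\mathrm{sd}_a$ (the naive shift undershoots the pooled SMD by
roughly 15% at $d = 1$). A calibration property test confirms the empirical
SMD is within three standard errors of nominal at 500 subjects per group.

In `"maps"` mode each subject receives a full 3-D t-map: exactly the latent
number of voxels per region is planted strictly above the threshold
(t ~ U(3.2, 8)) and all remaining voxels strictly below (t ~ U(−2, 3)), so
extraction at t > 3.17 reproduces the latent counts *exactly* — the round
trip is a bit-identity, tested at full study scale (118 subjects, 117
regions, 24³ grid). Latent counts are truncated at each region's voxel
capacity before planting so the identity cannot be broken by an
over-capacity draw. The default 24³ grid is a desk-scale choice; the grid
is configurable up to full MNI resolution, and the atlas is an ellipsoidal
"brain" mask partitioned into contiguous discrete Voronoi parcels.

Covariates follow the reported demographics: GWI age 46.9 ± 7.8, BMI
29.6 ± 5.6, 73.8% male; CFS age 47.74 ± 16.46, BMI 26.20 ± 4.52, 26.3%
male. Note that sex is therefore strongly confounded with group, exactly as
in the real cohort — residualizing features on age/sex/BMI (the default
covariate handling, matching the study protocol)
genuinely attenuates the planted group signal. Nine symptom-severity scores
(the 0–4 scale items of the study questionnaire; the scale bounds are
inferred from the reported means, max 3.5 ± 0.8) are generated as linear
combinations of z-scored region counts plus Gaussian noise, mapped around
the scale midpoint 2 and clipped to [0, 4].

What the generator does **not** emulate: BOLD time series, spatial
autocorrelation within maps, scanner drift, or any realistic anatomy.
Passing tests therefore demonstrate the *pipeline's* statistical behavior
(recovery, calibration, exactness of bookkeeping), not performance on real
fMRI data.

## Design choices in the model bucket

**Hyperparameters** are pinned for reproducibility (none are stated by the
reference): k = 3 neighbours; unit-cost linear SVM without internal
scaling; an unpruned seeded decision tree; a 100-tree random forest;
50-round discrete AdaBoost over depth-1 stumps; Gaussian naive Bayes;
regularized QDA; ridge logistic regression with λ = 1/n (the standard
default-regularization strength); and a one-hidden-layer perceptron of 10
units with weight decay 0.1 and 100 iterations. The perceptron is
deliberately small: a dense quasi-Newton optimizer over the ~12,000 weights
of a 100-unit layer at 117 inputs costs close to a minute per fit, which is
incompatible with an iterative rebuild loop wrapped in a permutation test;
10 units with decay gives a comparable decision boundary at desk scale. All
values are overridable through `bucket_config()`.

**Random-forest importances** are mean decreases in impurity. The forest is
fitted as seeded single-tree forests so that per-tree importances are
observable; the reported standard error is the per-tree standard deviation
divided by √(number of trees), and prediction is the majority vote over the
same trees (vote fraction as probability). Importances are normalized to
sum to one. The reference's printed importance table shows uniformly
*negative* values, which impurity importances cannot produce; the package
reports standard non-negative importances and ships the printed table
verbatim for bookkeeping only.

**Regularized QDA.** The classical QDA estimator is undefined whenever a
class has fewer observations than features — the study's actual regime (19
CFS training subjects, up to 117 features). Each class covariance is
therefore shrunk toward a scaled identity,
$\Sigma^{reg} = (1-r)\,\Sigma + r\,(\mathrm{tr}\,\Sigma/p)\,I$ with
r = 0.5, the classical regularized-discriminant midpoint. Weaker shrinkage
(r ≈ 0.1) leaves the smaller class's covariance near-singular and collapses
the classifier to majority-class predictions; r = 0.5 keeps it
well-conditioned and competitive.

**AdaBoost** is discrete two-class boosting over weighted decision stumps
(exhaustive threshold search per feature, both polarities); rounds stop
early at zero weighted error or when no stump beats 0.5.

**Recursive feature elimination** removes one feature per step, ranked by
the standardized coefficient magnitude of a ridge-logistic model. The
ridge penalty is chosen once by cross-validation on the full feature set
and held fixed along the elimination path: with 117 features and 59
training subjects a near-unpenalized coefficient ordering is dominated by
sampling noise (planted regions that rank 1–5 univariately can rank ~70th),
while the cross-validated shrinkage recovers a stable ordering. Subset
*sizes* are scored by stratified 5-fold cross-validated accuracy of the
prediction-grade (λ = 1/n) model — heavy shrinkage alone pushes all
predicted probabilities to the majority side and flattens the accuracy
curve, breaking size selection. Ties go to the larger subset.

**Where the accuracy floor is checked.** The reference protocol kept
rebuilding until each model reached 69% on data that also served as the
validation set, which leaks the test set into model selection. The default here evaluates the floor by stratified
cross-validation on the training set (`floor_eval = "train_cv"`); the
study-faithful behavior is one flag away (`floor_eval = "test"`).
Prediction ties (probability exactly 0.5) always break toward the positive
class (CFS). Models that fail to fit are logged, marked failed, and
excluded from the floor check rather than aborting the run.

**Consensus "accuracy".** Within a segment, accuracy is implemented as
precision — the fraction of selected subjects truly positive — which pairs
with FDR as precision = 1 − FDR, matching the arithmetic of the reference's
consensus figure. Specificity is computed as 1 − FP/N but should be read
with care at high agreement thresholds, where hardly anyone is selected and
specificity is mechanically inflated; the reference's own caption flags the
same artifact. The per-model accuracy summary uses a *population* (divide
by M) standard deviation, the convention that reproduces the printed
"75% ± 5%" and "79% ± 2%" rows from the printed per-model accuracies.

**Permutation statistic.** The default summary is the minimum per-model
final accuracy — significance requires every model to beat its shuffled
counterpart;
`"mean_accuracy"` is available. Each rep re-runs the *entire* build
(split-conditional screening is upstream; elimination and pruning are
re-threaded) on uniformly re-shuffled labels. The add-one rule keeps
p > 0. The default 200 reps is a desk-scale setting; 1000 reproduces the
reference protocol.

**Two scan days** are two independent pipeline runs over the same code
path (the pipeline's `day` field offsets the generator seed); the package
does not model within-subject correlation across days.

## Numerical conventions and degenerate inputs

* Thresholding is strict (`t > 3.17`): a voxel at exactly the threshold is
  excluded ("exceeding" read literally). Missing t-values count as
  subthreshold and are tallied in a warning.
* Atlas-to-map alignment uses nearest-neighbour label lookup in world
  space via the two affines (labels are categorical); voxel indices are
  0-based points under the NIfTI convention.
* Collinearity ties at exactly |R| = 0.9 are flagged (features must be
  *under* the threshold to pass). Constant columns yield missing
  correlations, are reported but not flagged — a constant feature carries
  no collinearity risk and dies later in importance pruning. Merged
  features are named by their members (`a+b`) and merging iterates to a
  fixed point; total count mass is conserved.
* Quartile binning (an optional transform, off by default, as in the
  reference where binned variables did not survive to the final model)
  codes by training-set boundaries persisted for test-set application;
  all-equal columns code as 1 with a warning.
* Empty consensus segments report missing precision/FDR rather than 0/0.
* If importance pruning would empty the feature list, the single
  top-importance feature is kept with a warning.
* All randomness is seeded; identical spec/config + seed reproduce
  cohorts, splits, builds and logs bit-identically (verified by test).

## Problem sizes used by the test-suite

The suite exercises the full study dimensions where exactness is the
point (the 118 × 117 map-mode round trip) and reduced dimensions where
only statistical calibration is being checked: the permutation-calibration
test runs 100 seeded 100-rep shuffle tests on a 32-subject, 6-region null
cohort with a lightened bucket (15 trees, 8 boosting rounds, 2-unit
perceptron, single iteration, test-set floor). Under label exchangeability
the permutation p-value is valid for *any* classifier configuration, so
the reduced setting checks the same property as a full-size run. The
parameter-recovery test uses the full 118-subject, 117-region cohort with
five planted regions at SMD 1.5 across 20 seeds.

## A worked run

```{r example, eval = FALSE}
bundle <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
glance(bundle$build)      # iterations, features, convergence
tidy(bundle$build$result) # nine per-model test accuracies
tidy(bundle$curve)        # consensus segments k = 1..9
autoplot(bundle$curve)
```

## Known limitations

* Synthetic regions are independent given group; real atlas regions are
  spatially and functionally correlated, so the collinearity screen almost
  never fires on synthetic data (consistent with the reference, where all
  117 regions passed).
* The generator plants mean shifts only; distributional-shape differences
  between groups are not modelled.
* Day-to-day dependence (same subjects scanned twice) is not simulated.
* The t-threshold's nominal p-value depends on unstated degrees of
  freedom; 3.17 is treated as a literal, configurable number.
* Specificity at high agreement thresholds is mechanically optimistic; use
  precision/FDR.
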