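---
title: "Classifying soybean lodging from canopy texture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying soybean lodging from canopy texture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soylodge)
```

## The problem

Lodging — stems bending or breaking until plants lean or lie flat — is scored
visually in soybean breeding nurseries on a 1–5 scale in 0.5 steps, and the
scores are grouped into four severity classes: NL (1.0–1.5), ML (2.0–2.5),
HL (3.0–3.5) and SL (4.0–5.0). Visual scoring of thousands of four-row plots
is slow and subjective, which motivates scoring plots from aerial (UAV) RGB
orthomosaics instead. The physical signal is textural: an erect canopy photographs
as a homogeneous, fine-grained surface, while a lodged canopy shows oriented
streaks of flattened stems and patches of exposed soil. `soylodge` implements
the full analysis from plot image to class label: canopy segmentation,
co-occurrence texture features, feature selection, class-imbalance treatment,
four classifier families, and a complete evaluation suite.

A central practical difficulty is imbalance. In a realistic nursery roughly
76% of plots are NL, 16% ML, 7% HL and under 1% SL (the package's reference
composition is 964/206/85/11 over 1266 plots). Untreated, every classifier
simply learns the majority class; the package therefore implements five
SMOTE-family treatments natively and evaluates each against four classifiers.

## The synthetic field generator

No public plot-imagery dataset accompanies this problem, so the package
ships a generator that produces orthomosaic-like fields with known ground
truth; every downstream stage is tested against it.

The texture model is deliberately minimal — the smallest model that realises
the homogeneous-vs-heterogeneous contrast the classification exploits. A plot
patch is built additively from:

* a flat canopy level (default 170 of 255) with Gaussian grain
  (`grain_sd`, 6→18 grey levels from NL to SL);
* a low-frequency brightness undulation (`base_amp`);
* an oriented sinusoid of random direction, wavelength 7–13 px
  (`streak_amp`, 0→40), standing in for combed-over stems;
* thresholded smooth-noise blobs of exposed soil (`soil_frac`, 0→30% of the
  patch; soil level 70), which also define the ground-truth canopy mask.

Severity is therefore encoded as a monotone increase in GLCM contrast, a
monotone decrease in angular second moment, and a shrinking canopy fraction
— and these monotonicities, verified over ≥20 seeds, are the generator's
contract, not incidental behaviour. What the generator does *not* emulate:
perspective and stitching artifacts, shadows, radiometric drift, plant-to-plot
geometry, or between-genotype variation in canopy colour. Passing tests on
synthetic fields demonstrate that the pipeline machinery is correct and that
the feature set separates textures with these statistics; they do not certify
accuracy on real nurseries.

Plots are laid out on a regular grid (64×48 px patches, 12 px gaps, 16 px
margin) with exact bounding boxes recorded per plot. `scaled_class_counts()`
scales the reference imbalance to any field size with a floor of 4 plots per
class, so stratified splitting and neighbour-based resampling remain defined
at the small sizes used in tests.

Tabular experiments use `generate_feature_table()`: class-conditional
Gaussians whose means sit on orthogonal indicator directions
(`feature_table_params()`), so a single `separation` parameter moves the
problem continuously from heavily overlapping (≈1.5, where imbalance
treatments matter) to essentially separable (≥4).

## Segmentation

Each plot ROI (the recorded bounding box plus a 6 px soil margin) is
segmented by a Chan–Vese active contour: the two-phase piecewise-constant
model that labels pixels canopy/background so as to minimise within-region
squared deviation from the two region means, plus a boundary-length penalty.
The minimiser here is a threshold-dynamics scheme: alternate (i) recompute
the two region means, (ii) diffuse the region indicator with a Gaussian of sd
`mu` pixels and re-threshold including the data terms. This converges in a
handful of sweeps, is exact on noise-free two-level images, and exposes the
length penalty through two interpretable knobs (`mu`, `mu_weight`). The
initial mask is a centred rectangle at 60% of the ROI; the iteration cap is
200; foreground is by convention the brighter phase. Components smaller than
25 px are removed (8-connected labelling). A collapsed contour (e.g. on a
constant ROI) is reported as an empty mask with a warning, never an error,
and such plots are skipped downstream with a log record.

These parameter values are package defaults, chosen once for the synthetic
imagery scale; none are claimed to be optimal for real orthomosaics, and all
are exposed.

## Texture features

Grey levels are quantized by equal-width binning into `Ng` levels
(default 16). For each of the four offsets (distance 1; 0°, 45°, 90°, 135°)
a symmetric co-occurrence matrix is accumulated over ordered pixel pairs that
both fall inside the canopy mask, normalized to sum 1, and the four matrices
are averaged — one matrix per plot, not a sliding kernel, since the analysis
needs one feature vector per plot. From the averaged matrix the 14 classical
Haralick statistics are computed: angular second moment, contrast,
correlation, variance, inverse difference moment, sum average, sum variance,
sum entropy, entropy, difference variance, difference entropy, two
information measures of correlation, and the maximal correlation coefficient.

Conventions, fixed package-wide:

* logarithms base 2, with 0·log 0 := 0 (required for the information
  measures' bounds);
* levels indexed 1..Ng, so the sum distribution runs over 2..2Ng;
* *variance* is the second moment about the grand mean level
  μ = Σᵢⱼ i·p(i,j);
* *sum variance* is centred on the sum-entropy value — the classical chained
  definition of that statistic, adopted here deliberately where the
  literature is ambiguous;
* *difference variance* is the literal statistical variance of the
  difference distribution;
* the maximal correlation coefficient is √(second-largest eigenvalue) of
  Q(i,j) = Σₖ p(i,k)p(j,k)/(pₓ(i)p_y(k)), with zero-marginal levels dropped;
* a constant image is degenerate: correlation is reported as 0 with a flag
  rather than raising.

Correctness rests on two independent oracles: exact rational values on a
hand-enumerable 4×4 image, and agreement with an established reference
implementation (frozen values) plus a naive double-loop oracle on random
matrices.

## Feature selection

`rf_rfe()` implements recursive feature elimination ranked by random-forest
Gini importance: score the current set by stratified 10-fold cross-validated
RF accuracy, drop the least important feature, repeat to one feature. Fold
assignment is fixed once per call so the score curve is comparable across
sizes; the chosen subset is the smallest attaining the curve maximum. One
feature is removed per iteration. The scoring estimator is a random forest
(500 trees by default; tests use fewer), and stratification is used although
plain k-fold would also be defensible — both choices are exposed.

## Imbalance treatments

All five composites are implemented natively from three primitives —
SMOTE interpolation, Tomek-link detection, and edited-nearest-neighbour
marking — because their interaction details (who gets removed, whether
counts equalize) are exactly what the package needs to control and test:

* **SMOTE**: each synthetic row is x + λ(y − x), λ ~ U[0,1], with y one of
  the k = 5 nearest same-class neighbours of x.
* **SMOTE-Tomek**: equalize all classes to the majority count, then remove
  majority members of mutual-nearest-neighbour opposite-class pairs.
* **SMOTE-ENN**: equalize, then remove (from *all* classes) every sample
  misclassified by the majority vote of its 3 nearest neighbours. Vote ties
  keep the sample. Output counts are unequal and the original majority
  typically shrinks most — the signature of this method.
* **Borderline-SMOTE** (variant 1): synthetic seeds restricted to "danger"
  minority points, i.e. at least half but not all of their k neighbours
  belong to other classes.
* **ADASYN**: per-point budgets proportional to the share of other-class
  neighbours, rounded per point, so totals only approximately equalize.
* **SMOTE-NC**: nominal columns enter the distance as a constant penalty
  (median sd of the continuous columns) and synthetics take the neighbours'
  modal nominal value; with zero nominal columns the code path *is* plain
  SMOTE.

Resampling is applied to the training partition only. Balancing before
splitting would leak synthetic copies of test points into training and
inflate every reported accuracy; the package keeps the test partition at the
natural class composition and marks every synthetic row in a `provenance`
column so the separation is checkable.

## Classifiers and tuning

Four families behind one contract (`fit_lodging()` / `predict()`): XGBoost
(multi-class softmax, single-threaded for determinism), random forest, a
natively implemented brute-force KNN (Euclidean distances, majority vote,
distance ties to the lowest training index, vote fractions as probabilities),
and a single-hidden-layer neural network with softmax output via `nnet`.
The network uses `nnet`'s logistic hidden activation — the standard R
single-hidden-layer implementation — rather than ReLU; at one hidden layer
the choice is immaterial to capacity and keeps the dependency standard.
Features are standardized (training mean/sd) for the distance and gradient
models only; trees are scale-invariant. Degenerate single-class training
yields an explicit constant classifier.

Tuning protocols (`tune_lodging()`): XGBoost by a tree-structured Parzen
estimator over rounds, learning rate, depth, subsampling, column subsampling
and minimum child weight, maximizing 5-fold CV accuracy; random forest by
grid search over six parameters with 5-fold CV; KNN fixed at k = 3 by
protocol; the network over hidden width and iteration cap. The pipeline runs
untuned by default (protocol defaults) because tuning multiplies runtime
twentyfold across the method × model grid; `tune = TRUE` switches it on.

## Evaluation

`evaluate_confusion()` computes, from a rows-actual confusion matrix:
overall accuracy OA = trace/N; Cohen's kappa (Po − Pe)/(1 − Pe) with Pe from
the marginals; misclassification rate defined as 1 − OA; and one-vs-rest
per-class precision, recall and F1 with zero denominators flagged rather than
propagated as NaN. With probabilities, one-vs-rest ROC (trapezoidal AUC over
tie-grouped thresholds) and precision-recall curves (step-wise average
precision) are added. Report display rounds half-up to two decimals, the
precision of the reference tables.

The package ships four reference confusion matrices (N = 527 each, SMOTE-ENN
test sets for XGBoost/RF/KNN/ANN) as CSV fixtures; recomputing every printed
metric from them at two-decimal precision is the package's primary regression
suite. One fixture is stored transposed back to the rows-actual convention
(documented in the fixture directory) because its source block was printed
with rows and columns swapped.

## Problem sizes and numerical choices in the test suite

The suites are sized for a single CPU: segmentation and monotonicity
properties use 20 seeds of 64×48 patches; resampler count contracts run once
at the full 1266-row reference composition; the RF-RFE noise-elimination
property runs 20 seeded repetitions at 160 rows, 12 signal features
(separation 4) plus 2 planted N(0,1) noise features, 100 trees; the
end-to-end pipeline check uses a 130-plot field crossing all 5 treatments
with all 4 models. The SMOTE-ENN-is-best observation is checked as a
tendency (mean accuracy at or above the methods' mean) on overlapping
Gaussians at separation 1.5, not as a strict ordering — with synthetic data
there is no guarantee any one treatment dominates.

## Known limitations

* The texture model is a stand-in; its validation is the stated
  monotonicities, not photographic realism.
* Chan–Vese parameters and the small-region threshold are package defaults,
  not fitted to real imagery.
* Real-data accuracies depend on an undeposited field dataset and are not
  reproducible here; the fixtures pin the evaluation arithmetic instead.
* ADASYN totals drift further from equality as classes shrink (per-point
  rounding), which is visible at small synthetic scales.
* Adjacent-severity confusions (NL↔ML, HL↔SL) dominate the residual error on
  synthetic fields, as they would in practice.
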