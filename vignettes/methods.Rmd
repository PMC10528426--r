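---
title: "Radiomic screening of AMD on ultra-widefield fundus images: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic screening of AMD: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Age-related macular degeneration (AMD) announces itself in the macula as
drusen — small homogeneous bright deposits — and as pigmentary abnormalities,
scattered dark clumps. Ultra-widefield fundus retinography (UWF-FRT) captures
the whole posterior pole in one shot, so a screening pipeline has to (i) find
the macula on a very large field, (ii) quantify the texture of a standard
region around it, and (iii) classify the eye while remaining explainable to a
clinician. `retinomics` implements that pipeline end to end: macula
localisation under a fixed circular-ROI contract, IBSI-style radiomic
features, stability-based feature selection, ensemble classification with
class rebalancing, and a per-case percentile/σ explanation report. A seeded
synthetic-fundus generator stands in for clinical images, which cannot be
redistributed, so every stage is testable.

## Geometry and the detector contract

Images are treated on an 8-bit grayscale scale with 0-based pixel coordinates
(x right, y down); a pixel belongs to a circular ROI iff the Euclidean
distance between pixel centres is at most the radius. These conventions are
fixed so that mask cardinalities — the |A| and |B| in the Dice similarity
coefficient DSC = 2|A∩B| / (|A|+|B|) — are exactly reproducible against
lattice-enumeration oracles.

At the native 3900 × 3072 resolution the macula centre concentrates around
(1971, 1588) with SDs (46, 52), so detection runs on a fixed square crop
(pixel ranges 901–2700 × 801–2600, i.e. [23 %, 69 %] × [26 %, 85 %] of the
image, whose bounds sit 18/10 and 10/15 SDs away from the mean nearest ROI
borders). For non-native resolutions the crop is applied fractionally. The
analysis ROI has a fixed 250 px radius (≈ 2 mm); detector-training
annotations are preprocessed by halving the radius and resampling to
300 × 300.

The detector itself is a *contract*: a function from an image to bounding
boxes with confidences. The shipped default is a matched filter — normalised
cross-correlation against a Gaussian-feathered dark-disc template, FFT-based,
peak correlation as confidence — because the macula is the darkest
disc-shaped structure on the field. The template radius is 1.5× the ROI
radius with a 25 % feather, matching the fact that the macular darkening
extends beyond the standard analysis circle; a narrower template flattens the
correlation peak over the plateau and degrades localisation. A trained
object detector can be plugged in unchanged. Detections below a configurable
acceptance threshold (default correlation 0.5; no production cut-off is
standardised) fall back to the mean position of the training ROI centres,
and the outcome records which path produced each ROI.

## Feature extraction

Preprocessing: grayscale conversion (Rec. 601 luma weights for RGB input),
2:1 down-sampling implemented as 2×2 mean pooling (deterministic and
anti-aliasing; the alternative — decimation — discards information), then
fixed-bin-number discretisation into 64 bins:
`level = min(64, 1 + floor(64·(x − min)/(max − min)))`, with a constant ROI
mapping to level 1. Fixed bin *number* (not fixed bin size) makes texture
features invariant to global intensity shifts, which matters on fundus
images with varying exposure.

The default catalogue has exactly 270 entries spanning eight families. The
composition is a versioned package choice (shipped as
`inst/extdata/feature_catalogue_v1.yaml`):

| block | entries |
|---|---|
| Intensity-based statistics | 18 |
| Intensity histogram (64 bins) | 23 |
| GLCM, 25 features × {per-direction averaged, merged} × distances {1, 2} | 100 |
| GLRLM, 16 features × {averaged, merged} | 32 |
| GLSZM, 16 features × {8-connected, 4-connected} | 32 |
| GLDZM, 16 features | 16 |
| NGTDM, 5 features × neighbourhood radii {1, 2, 3} | 15 |
| NGLDM, 17 features × α ∈ {0, 1} | 34 |

Numerical conventions, all oracle-tested on small grids: GLCM/GLRLM use the
four unique 2D directions at the stated pixel distance; "averaged" computes
features per direction then averages, "merged" sums the count matrices
first. Zones are 8-connected by default. GLDZM distances are city-block
steps to the nearest outside-mask pixel with minimum 1 (computed by a
distance transform; a padding ring makes the mask boundary count as
outside). NGLDM dependence counts use |Δlevel| ≤ α over the 8-neighbourhood
and index the matrix at count + 1, so entries sum to the pixel count. NGTDM
follows the standard definitions with sums over present levels; with fewer
than two present levels Contrast/Busyness/Strength are 0, and the
Coarseness/Strength denominators carry a machine-epsilon guard. 0·log 0 = 0
and logs are base 2 throughout; percentiles use R's default (type 7)
quantile rule. GLCM correlation of a single-level region is defined as 1.

One deliberate redundancy: the catalogue lists a family (GLDZM) that the
narrow preprocessing list would not predict, because the top-predictor
nomenclature used for reporting includes a distance-zone feature; the
catalogue therefore includes the full family rather than a single orphan
entry.

## Stability selection and univariate ranking

Features must survive segmentation perturbation: each case is re-extracted
under `n_variants = 5` seeded perturbations (rotation within ±15° about the
image centre, ROI centre jitter ±10 px, radius jitter ±10 % — magnitudes are
package defaults, config-exposed, since no standard magnitudes exist), and
per-feature reliability is summarised by the one-way random-effects
single-rater intraclass correlation ICC(1,1) = (MS_B − MS_W)/(MS_B +
(k−1)·MS_W). Features are retained when ICC > 0.80 (strict; exact-ICC-1
features survive any threshold ≤ 1); zero-variance ICCs are undefined and
conservatively dropped.

Retained features are ranked by a two-sided Wilcoxon rank-sum test (exact
for ≤ 25 cases per class without ties, normal approximation with tie
correction otherwise — the `stats::wilcox.test` defaults) with Bonferroni
correction over the number of features entering the screen, at the 0.05 and
0.005 levels; constant features get p = 1. Class medians carry seeded
2000-replicate percentile-bootstrap 95 % CIs. Ranking is by corrected p,
then by selection frequency in the classifiers (Fisher-screen selection
fraction for the SVM ensemble, trees-using-feature fraction for the random
forest). Corrected p-values below machine epsilon are treated as tied on
the primary key — the familiar "< 2.2e-16" reporting floor; beyond it the
normal approximation's tail carries no information and ordering by it would
just reward tie-heavy discrete features — so the frequency key decides
among saturated predictors.

## Classification

Two ensemble-of-ensembles models. Each consists of three independently
seeded sub-ensembles of 100 base classifiers with a majority vote over all
300; the three-way split mirrors the three ROC curves such systems report,
and since no mechanism distinguishing the three is standardised, independent
seeding (with per-base bootstrap resampling) is the design choice. The SVM
path screens features by Fisher discriminant ratio (μ₁−μ₂)²/(σ₁²+σ₂²)
keeping the top 20, projects onto PCA components capturing 95 % variance,
and fits a linear SVM with unit cost (hyperparameters config-exposed;
Fisher-then-PCA order is likewise exposed). The random-forest path uses
Gini-impurity trees, with each sub-ensemble realised as a 100-tree forest
whose individual trees are the base classifiers.

The minority class ("AMD") is rebalanced by ADASYN: the class deficit is
distributed over minority cases proportionally to the fraction of
majority-class neighbours among their k = 5 nearest neighbours (z-scored
feature space for the neighbour search), and each synthetic case is a convex
combination of a minority case and one of its k nearest minority
neighbours. Inside small training folds the neighbourhood adapts to
min(k, minority − 1). Rebalancing happens strictly inside training folds.

Evaluation uses nested stratified 10-fold cross-validation: outer folds give
internal-test predictions, an inner 10-fold within each outer-training set
gives validation predictions, and training metrics come from the refit on
the full outer-training set. Vote ties go to "AMD" — in a screening context
sensitivity carries more clinical weight than specificity. Metrics
(Accuracy, Sensitivity, Specificity, PPV, NPV, with "AMD" positive) are
aggregated over folds as mean with a 95 % t-interval; the pooled test
accuracy is additionally tested against the no-information rate with an
exact binomial test, and proportions get Clopper–Pearson CIs. ROC-AUC uses
the midrank statistic on vote fractions with a seeded bootstrap CI. The
model kind with the higher mean internal-test ROC-AUC is the winner.
Manual-vs-automatic ROI agreement uses linear-weighted Cohen κ (identical
to unweighted for binary labels — asserted in the tests) with a bootstrap CI.

## Explanation report

For each case, the top-ranked predictors are situated in the *predicted*
class's training distribution (training data only): an integer percentile by
the inclusive ≤-count convention — printed as e.g. "82°", with values
strictly outside the training range marked ">100°" or "<1°" — and the
deviation from the class mean in σ units rounded to 0.1 (undefined when
σ = 0). The percentile estimator is a documented package convention; no
standard fixes whether such reports use ≤ or < counts or interpolation. A
comparison against the true class can be requested when labels are known.
Distribution summaries (type-7 quartiles, Tukey whiskers) are exported as a
tidy table for violin/box visualisation.

## The synthetic generator

The generator emulates exactly the structure the pipeline relies on, at
native geometry by default (3900 × 3072, macula centre ~ N((1971, 1588),
(46, 52)²), radius 250): a bright retinal ellipse with low-frequency shading
on a black canvas, 2–6 dark curvilinear vessels as detector distractors
(kept clear of the macula), and a macular darkening drawn at 1.5× the ROI
radius with its flat core (1.125× the ROI radius) covering every ROI the
stability study perturbs, and its cosine feather outside — so the ROI
interior is a flat plateau plus N(0, 3) noise ("smooth texture"). AMD images
add 3–10 drusen-like bright blobs (+45 intensity) and 2–8 pigment-like dark
clumps (−45), anti-aliased feathered discs placed without overlap wholly
inside the macula. Contrasts are free modelling parameters chosen once so
that the pigment clumps occupy the lowest discretised levels (driving the
low-grey-level emphasis families up in AMD) and drusen the highest — the
directionality clinical readers associate with pigmentary abnormalities and
drusen. They are not claims about real lesion photometry, and passing tests
on synthetic data show pipeline correctness, not clinical performance: real
fundus texture (vessel crossings inside the macula, reflectance artefacts,
media opacity) is deliberately absent.

All randomness flows from explicit seeds through one derivation function;
identical (config, label, seed) triples give bit-identical images. A
`scale` parameter shrinks all lengths linearly; tests and worked examples
use 1/5 scale (780 × 614, radius 50) and 1/10 scale, which keep every stage
exact while making a full 145-image study (the 62 AMD / 83 Negative
composition) run on a desktop. The acceptance script runs at 1/5 scale with
nested 10×10-fold cross-validation over the full 270-feature catalogue.

## Known limitations

- The default detector is a matched filter, not a learned detector; it is
  adequate for the synthetic image class and for template-like maculae, and
  exists primarily to exercise the detector contract.
- ICC is the only stability criterion implemented; no additional
  distributional comparison across augmentation variants is made.
- The 270-entry catalogue is one defensible composition, versioned in the
  package; other compositions of the same families are equally valid.
- Bootstrap CIs (medians, AUC, κ) are percentile bootstraps; no BCa
  correction.
- RGB channels are collapsed to luma before analysis; per-channel radiomics
  is out of scope.
- On synthetic data the top of the univariate ranking is occupied by
  structure-presence features (run-length non-uniformity, zone percentage,
  inverse difference moment, intensity range): because Negative ROIs are
  smooth by construction, the mere presence of lesions separates the
  classes more reliably — completely, and with far lower within-class
  variance — than lesion mass or photometry does. The dark-structure
  (low-grey-level emphasis) families show the expected direction, higher
  in AMD, and also reach complete separation, but they do not displace the
  structure-presence features from the top ranks. On clinical data, where
  healthy maculae are richly textured, the ranking composition will
  differ; this was verified against generator variants with physiologic
  reflectance mottle and per-image lesion contrast, which weaken the
  dark-structure separation before they weaken the structure-presence
  features.
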