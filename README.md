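# nucmorph

Quantitative nuclear histomorphometry for predicting disease recurrence from
H&E tissue-microarray (TMA) spots, with survival analysis of the resulting
classifier — plus a seeded synthetic-spot generator so the entire pipeline is
testable without patient data.

## Who this is for

Computational pathology researchers who want a reproducible, fully tested R
implementation of the classical nuclear feature families — spatial-architecture
graphs, shape, orientation disorder, chromatin texture — and of the
selection/classification/survival machinery typically wrapped around them in
recurrence-prediction studies of early-stage solid tumors (the motivating
setting is early-stage non-small-cell lung cancer).

## What it computes

**242 named descriptors** per spot, from nuclear boundary polygons (and the
image, for texture):

| family | n | content |
|---|---|---|
| `graph_global` | 51 | Voronoi cell area/perimeter/chord, Delaunay edge/triangle, MST edge statistics (mean, SD, min/max ratio, disorder), k-NN distances, neighbor counts in 10–50 px, density |
| `graph_cluster` | 26 | mean-shift cell-cluster graph: degrees, eccentricity/diameter/radius, path length, clustering coefficients C/D/E, components, edge-length moments |
| `shape` | 100 | {mean, SD, median, min/max ratio} × 25 per-nucleus descriptors incl. area, perimeter, radii, compactness, solidity, bending energy, Fourier shape descriptors 1–10 |
| `orientation` | 39 | {mean, median, SD} × 13 second-order statistics of within-cluster nuclear-orientation co-occurrence |
| `texture` | 26 | {mean, SD} × 13 gray-level co-occurrence statistics over intranuclear pixels |

The *disorder* statistic used throughout is `1 − 1/(1 + σ/μ)`; co-occurrence
statistics include contrast energy/inverse moment/average/variance/entropy,
intensity average/variance/entropy, entropy, energy, correlation and both
information measures of correlation (base-2, `0·log 0 = 0`).

**Selection and classification**: top-3 features per category by a
minimum-redundancy maximum-relevance (mRMR, difference criterion) ranking →
15 candidates; exhaustive QDA search over all C(15,7) = 6435 subsets under 100
iterations of stratified 3-fold cross-validation (compiled inner loop); QDA,
LDA and polynomial-kernel SVM classifiers with lossless JSON serialization.

**Survival**: Kaplan–Meier + log-rank, Fisher exact and exact McNemar tests,
multivariable Cox models (gender, T/N stage, classifier call), and Cox risk
scores over the selected features with per-dataset median/tertile
stratification.

**Preprocessing**: monotone-spline (decile-matching) H&E color normalization
and watershed nuclear segmentation (fixed-vector color deconvolution, Otsu,
distance-transform markers with non-maximum suppression); external label masks
import through `mask_to_boundaries()` so any segmenter can feed the pipeline.

## Worked example

```r
library(nucmorph)

# a synthetic cohort: 120 patients, half with the recurrent-like phenotype
spec <- cohort_spec(n_patients = 120, seed = 11)
ct   <- cohort_feature_table(spec)     # 242 features + clinical per patient

y  <- ct$clinical$recurrence
set.seed(99)
tr <- c(sample(which(y), 30), sample(which(!y), 30))  # 60-patient training set
te <- setdiff(seq_len(120), tr)

sel <- select_features(ct$features[tr, ], y[tr], seed = 11)
sel$selected
#> [1] "graph_global.mst.edge_mean"
#> [2] "graph_global.density.neighbors_r10_mean"
#> [3] "graph_global.density.neighbors_r40_std"
#> [4] "graph_cluster.node_count"
#> [5] "graph_cluster.diameter"
#> [6] "graph_cluster.cluster_size_std"
#> [7] "shape.area.mean"

m  <- recurrence_classifier(ct$features[tr, ], y[tr], sel$selected, "QDA")
pr <- predict(m, ct$features[te, ])
evaluate_classifier(pr$call, pr$score, y[te])
#> <eval_report> n = 60
#>   confusion: TP 30  FP 0  FN 0  TN 30
#>   accuracy 1.000  recall 1.000  PPV 1.000  specificity 1.000  AUC 1.000

rk <- cox_risk_scores(ct$features[tr, ], sel$selected,
                      ct$clinical$rfs_months[tr], ct$clinical$event_observed[tr])
g3 <- stratify_scores(predict(rk, ct$features[te, ]))$group3
km_logrank(ct$clinical$rfs_months[te], ct$clinical$event_observed[te], g3)$p
#> [1] 5.246682e-07
```

The held-out AUC of 1.0 reflects the deliberately well-separated default
phantom presets (clustered/disordered/irregular/heterogeneous vs
regular/aligned/smooth/homogeneous); the tertile log-rank p-value shows the
risk score carries the planted survival contrast. Published worked examples
are reproduced exactly: a validation confusion matrix of TP 51 / FP 19 / FN 3
/ TN 46 gives recall 94.4%, PPV 72.9%, accuracy 82%, and the gender and
T-stage contingency tables of the 119-patient validation cohort give Fisher
exact p = 0.7151 and 0.5834.

## Conventions

Coordinates are 0-based pixels, `x` = column, `y` = row, origin top-left;
polygons are stored counter-clockwise and open. All distances are in pixels
(`microns_per_pixel` is recorded, never used). Boundary files are CSV
(`spot_id,nucleus_id,vertex_index,x,y` with an image-size header comment) or
JSON; feature tables are CSV with `spot_id` plus the 242 registry columns in
registry order; models are JSON. See the methods vignette
(`vignettes/nucmorph-methods.Rmd`) for the models, parameter meanings,
numerical conventions and the generator's scope and limitations.
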