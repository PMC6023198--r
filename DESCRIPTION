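Package: fetclust
Title: Voxelwise Time-Activity-Curve Clustering for Dynamic 18F-FET PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-based analysis of dynamic 18F-FET PET in gliomas:
    Z-score-template tumor segmentation, per-voxel time-activity-curve
    (TAC) z-normalization, dynamic-time-warping k-means clustering with
    elbow-based model selection, centroid-proportion and conventional
    kinetic features (TBR, TTP, late slope), and cohort statistics
    (group comparison, Kaplan-Meier survival stratification with an
    optimal-cutpoint scan). Includes a synthetic 4D brain phantom and
    cohort simulator so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp, RNifti, jsonlite, survival
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'fetclust-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'dtw.R'
    'cluster.R'
    'constructors.R'
    'segmentation.R'
    'tac.R'
    'features.R'
    'io.R'
    'pipeline.R'
    'stats.R'
    'synthetic.R'
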