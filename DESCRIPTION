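Package: densityatlas
Title: Density-Based Parcellation and Regional Quantification of Whole-Brain Cell-Type Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-brain cell-type distributions recorded as
    3D point clouds (one point per detected nucleus, in micrometres). Provides a
    synthetic-brain generator (toy label-volume atlases, multi-subject Poisson
    point clouds with known region-wise intensities, and nuclear-image stacks
    with ground truth), an unsupervised structure-tensor nuclei detector,
    assignment of points to atlas regions with region-by-cell-type density
    matrices (cells/mm^3) and max normalization, hierarchical clustering of
    regions by cell-type composition (correlation distance, Ward linkage), a
    percentile-thresholded DBSCAN spatial parcellation (neighbor counts at a
    fixed radius, per-cell-type percentile MinPoints sweeps, cluster-vs-region
    overlap scores), and a two-group density comparison with
    Benjamini-Hochberg false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    RNifti,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
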