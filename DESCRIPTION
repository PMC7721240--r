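Package: brainstab
Title: Sample-Size Stability of Voxelwise Brain-Behavior Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how sample size affects the stability of
    voxelwise brain-behavior correlation maps in task fMRI. Generates
    synthetic cohorts of per-participant contrast volumes with a known
    embedded correlation pattern and realistic covariate structure, draws
    non-overlapping (optionally age-stratified) subsamples of graded sizes,
    computes univariate correlation/t maps and single-measure behavioral
    partial least squares (salience map, permutation p value for the latent
    variable, bootstrap-ratio map) in each subsample, and quantifies
    cross-subsample stability with Spearman rho over unthresholded maps,
    Jaccard indices over thresholded maps, and penetration (overlap-count)
    maps. Reads and writes NIfTI-1 volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
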