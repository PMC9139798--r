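Package: naturalisc
Title: Inter-Subject Correlation and Semantic Similarity Analysis for
    Naturalistic Neuroimaging Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing group differences in responses to
    naturalistic stimuli. Implements voxelwise inter-subject correlation
    (ISC) of multi-run BOLD time series with Fisher-z run-length-weighted
    aggregation, a circular-shift resampling null with FDR control, and a
    cluster-based two-sample permutation contrast between groups, together
    with the preprocessing chain used for fast-TR fMRI (Savitzky-Golay
    detrending, nuisance-component regression against white-matter and CSF
    signals, DVARS, zero-phase band-pass filtering, spatial smoothing).
    A second analysis arm maps free-association word lists to semantic
    vectors via word-embedding sums and tests within-group cosine
    similarity per narrative segment with permutation tests and FDR.
    Includes synthetic-data generators with known ground truth for both
    arms so that every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    signal,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
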