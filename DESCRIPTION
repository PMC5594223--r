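Package: eegspect
Title: EEG Connectivity and SPECT Perfusion Classification for Amnestic Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-diagnosis pipeline combining multivariate autoregressive
    (MVAR) spectral connectivity of multichannel EEG with regional SPECT perfusion
    ratios. Fits MVAR models by the Vieira-Morf partial-correlation recursion,
    derives fourteen frequency-domain interaction measures (coherence, partial
    directed coherence, directed transfer function families, Geweke Granger
    causality and relatives) on a 2-80 Hz grid, averages them into canonical
    frequency bands, reduces connectivity matrices to global graph metrics, and
    classifies diagnostic groups pairwise with a linear 2-norm soft-margin support
    vector machine inside a three-layer nested cross-validation with greedy forward
    feature-subset selection. Includes a synthetic cohort generator with
    group-specific coupling structure and perfusion means, EDF and CSV input/output,
    and a full results report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
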