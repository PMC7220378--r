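Package: mlipharm
Title: Quantification of Pharmacological Effects on Calcium Signals in
    Cerebellar Molecular Layer Interneurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipelines for two-photon GCaMP calcium imaging and
    freeze-fracture immunogold electron microscopy of cerebellar molecular
    layer interneurons (MLIs). Implements delta-F-over-F normalization with
    background and neuropil compensation, beam-stimulation pharmacology
    (peak responses, drug/control ratios, Wilcoxon signed-rank statistics),
    an awake forced-locomotion drug-effect pipeline (rest normalization,
    75th-percentile locomotion fluorescence, exponential decay detrending,
    cross-session ROI registration and overlap matching, per-ROI effect
    classification, change-versus-baseline regression), and perisynaptic
    immunogold annulus-density profiling around postsynaptic density
    outlines. A synthetic-data module generates every pipeline input with
    known ground truth so that each stage is verifiable without
    experimental data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mgcv,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
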