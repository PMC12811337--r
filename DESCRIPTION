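Package: proxifilt
Title: Filtering and Quality Metrics for Proximity-Labeling Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Post-acquisition analysis of proximity-labeling (TurboID/BioID)
    pulldown mass-spectrometry experiments quantified at the protein level.
    Summarizes per-protein enrichment of bait strains against a no-ligase
    negative control (group means over detected replicates, fold changes,
    Welch tests with Benjamini-Hochberg correction, exclusive-detection
    categories, and a conservative fold-change estimator for proteins absent
    from the control), computes experiment-quality metrics (Up %, TurboID %,
    Carboxylase %, Epidermal %, replicate overlap and correlation), builds a
    non-specific-target reference from promiscuous-ligase control experiments,
    applies a two-step control-referenced filter with color annotation,
    analyzes concordance across technical and biological replicates, and
    generates fully synthetic studies with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
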