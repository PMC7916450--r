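Package: genofabric
Title: Genomic Fabric Analysis of Redundant-Spot Microarray Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the "genomic fabric" of a transcriptome from two-color
    microarray spot tables with redundant probing: spot-quality filtering and
    iterative median-gene normalization; per-gene average expression (AVE),
    chi-square mid-interval relative expression variability (REV) and pairwise
    expression correlation (COR) with redundancy-dependent significance
    cutoffs; variability-adjusted fold-change thresholds (CUT) with Welch
    t-tests, weighted individual (WIR) and pathway (WPR) regulation; gene
    commanding height (GCH) ranking and gene master regulators; coordination
    networks within and between pathway fabrics and activator/inhibitor
    sign-consistency evaluation. Includes a synthetic-experiment generator
    with planted fold-changes and coordination modules for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
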