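Package: peparray
Title: Label-Free MS1 Peptide Profiling for LC-MS Runs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A label-free peptide-profiling pipeline for LC-MS1 data: peak
    picking of centroid or profile scans, isotopic-cluster detection with
    averagine envelope validation and charge deconvolution to mono-isotopic
    MH+ values, elution-trace feature detection with a consecutive-scan rule
    and a rescue noise list, exponential retention-time drift alignment
    between runs, aggregation into a peptide profile matrix (PepArray) with a
    rolling redundancy-collapse rule, projection of mass lists onto a fixed
    ppm-spaced reference grid for overlap and Venn comparison, and two-group
    Wilcoxon-Mann-Whitney profiling with a label-randomization baseline. A
    synthetic Orbitrap-like LC-MS1 run generator provides ground-truthed data
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mzR,
    xml2,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
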