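Package: exoncgh
Title: Exon-Centric Targeted aCGH Simulation, Segmentation and Breakpoint
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the detection limit of intragenic deletions
    on exon-centric targeted array comparative genomic hybridization (aCGH)
    designs. Builds gene-targeted oligonucleotide probe manifests, simulates
    probe-level patient-versus-reference log2 ratios under a hybridization
    attenuation model (deletions, duplications, insertions interrupting probe
    footprints, and single-nucleotide variants under probes), segments
    profiles with circular binary segmentation, applies derivative log ratio
    quality control, threshold calling and manual-review escalation criteria,
    bounds breakpoints from probe evidence, plans in-silico walking primers,
    and characterizes deletion junctions (microhomology, inserted sequence
    origin, target-site duplications, repeat proximity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
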