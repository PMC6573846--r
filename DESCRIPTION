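Package: ecoassembly
Title: Null-Model Inference of Microbial Community Assembly Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the contributions of deterministic and stochastic
    ecological processes (homogeneous and heterogeneous selection, dispersal
    limitation, homogenizing dispersal, and undominated processes such as
    drift) to microbial community assembly from an OTU count table, a rooted
    phylogeny, and sample group metadata. Implements abundance-weighted mean
    nearest taxon distance (MNTD) and its standardized effect sizes (NTI,
    beta-NTI) against tip-shuffle null models, the Bray-Curtis-based
    Raup-Crick metric (RCbray) under an occupancy-weighted community
    reassembly null, and the threshold-based partition of sample pairs into
    assembly processes. Also provides the supporting diversity statistics
    (rarefaction, Chao1, Shannon, Simpson, Pielou evenness, Bray-Curtis
    dissimilarity, ANOSIM) and a synthetic-data generator that emulates
    seasonal two-group field designs with known ground-truth assembly
    scenarios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
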