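Package: azanome
Title: Single-Molecule Nucleosome Footprinting and Demethylation Dynamics
    After DNMT Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the chromatin consequences of passive DNA
    demethylation induced by DNMT inhibitors such as 5-Aza-2'-deoxycytidine.
    Implements single-molecule NOMe-seq (dual-enzyme bisulfite) footprint
    analysis of amplicon clone reads, including HCG/GCH/GCG site annotation,
    bisulfite strand inference, nucleosome-depleted-region calling, and
    strand-selective filters; Hpa II based hemimethylation deconvolution of
    unmethylated/hemimethylated/fully methylated duplex fractions; and
    genome-scale statistics for Infinium beta-value demethylation calling
    and SAM-style permutation tests of gene reactivation. A molecule-level
    simulator of semiconservative demethylation, methylation-conditional
    nucleosome remodeling, GpC methyltransferase footprinting and bisulfite
    conversion supplies ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
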