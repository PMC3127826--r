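Package: stripemeth
Title: Promoter Methylation Analysis for Striped Fruit Peel Phenotypes
Version: 1.0.0
Authors@R: person("stripemeth", "developers", role = c("aut", "cre"),
    email = "stripemeth@example.org")
Description: Tools for linking fruit peel pigmentation phenotypes to promoter
    DNA methylation. Implements McrBC methylation-sensitive qPCR percent
    methylation estimation with efficiency calibration and QC flags, amplicon
    bisulfite Sanger-clone analysis with CG/CHG/CHH cytosine-context
    classification, efficiency-corrected relative transcript quantification,
    promoter sequence-feature scanning (E-box motifs, McrBC recognition
    sites, pairwise identity), and a synthetic-data module that simulates
    methylation mosaics, bisulfite clone sets, McrBC-digested molecule pools
    and qPCR crossing-threshold measurements so the whole pipeline is
    testable without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
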