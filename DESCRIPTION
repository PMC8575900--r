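Package: screenfunnel
Title: Hit Calling and Candidate Integration for Arrayed RNAi Uptake Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide arrayed RNAi screens of
    receptor-mediated ligand uptake, such as fluorescent-LDL internalization
    screens for LDLR activity. Implements per-plate robust z-score
    normalization (plate median / MAD), cytotoxicity filtering on valid
    object counts, replicate-concordance primary hit calling, deconvolution
    validation with individual siRNAs, signed fold-change plus Student
    t-test classification of sterol-modulated genes from two-condition
    expression experiments, integration of functional hits with expression
    and GWAS evidence into a candidate funnel, and a synthetic screen
    generator with known ground truth for calibration and recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
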