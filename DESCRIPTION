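Package: refstab
Title: Reference-Gene Stability Analysis for RT-qPCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates candidate reference (housekeeping) genes for RT-qPCR
    normalization from cycle-threshold (CT) tables. Implements the four
    standard stability algorithms (geNorm, NormFinder, BestKeeper and the
    comparative delta-CT method), a RefFinder-style geometric-mean consensus
    ranking, the geNorm pairwise-variation rule for choosing how many
    reference genes to use, amplification-efficiency estimation from
    dilution standard curves, and 2^-ddCT target-gene validation with
    one-way ANOVA and Tukey compact-letter displays. Ships a seeded
    synthetic CT-data generator with known ground truth so every stage of
    the pipeline can be tested end to end without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite
Config/testthat/edition: 3
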