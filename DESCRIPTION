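Package: cystkit
Title: Phytocystatin Discovery, Inhibition Kinetics and Erosion-Protection Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for mining phytocystatins from assembled transcriptome
    contigs and characterising them downstream. Provides six-frame ORF
    extraction, a degenerate (PROSITE-style) motif engine with an ordered
    screening rule for the canonical cystatin motifs (N-terminal Gly-Gly,
    central QxVxG loop, C-terminal [PA]-W), group classification from the
    phytocystatin N-terminal helix signatures, molecular weight and
    isoelectric point computation, neighbor-joining clustering of screened
    proteins into groups, tight-binding competitive inhibition constant (Ki)
    estimation from fluorogenic assay slope series, and surface-microhardness
    erosion statistics (one-way ANOVA, Tukey HSD with compact letter display).
    Seeded synthetic-data generators with planted ground truth support
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    phangorn,
    seqinr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
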