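Package: choreseq
Title: ChIP-Seq and Expression Integration for Glucose-Responsive
    Transcription Factor Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for linking
    transcription-factor binding to glucose-regulated gene expression,
    modelled on ChIP-seq studies of the carbohydrate response element
    binding protein (ChREBP). Provides tag-pileup coverage and threshold
    peak calling with input normalization, peak-to-nearest-gene annotation
    with promoter/UTR/intron/intergenic categorization, position weight
    matrix scoring with exact p-value thresholds, bipartite ChoRE (tandem
    E-box) detection, ZOOPS expectation-maximization motif discovery,
    moderated-t differential expression with a beta-uniform mixture
    posterior (PPDE), and a running-sum Kolmogorov-Smirnov enrichment of
    binding targets within a ranked expression list. A synthetic-data
    module generates toy genomes, planted binding sites, ChIP/input tags
    and replicate expression matrices with known ground truth so that
    every stage can be validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
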