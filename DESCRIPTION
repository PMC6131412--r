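Package: introscan
Title: Transcriptome Scanning of Alien Chromosome Addition Lines
Version: 0.1.0
Authors@R:
    person("introscan", "maintainers", email = "introscan@example.org",
           role = c("aut", "cre"))
Description: Differential-transcription analysis for alien chromosome
    addition lines: TMM normalization and negative-binomial GLM testing of
    gene-level RNA-seq counts, sliding-window chromosomal metrics with
    PELT change-point segmentation to expose large deletions from
    expression loss, synteny-block based homeolog assignment and
    cross-genome transcriptional compensation scoring, and Parent-Child-Union
    GO-term enrichment. Includes a synthetic-data generator emulating a
    three-genotype (host, donor, addition line) replicated design so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
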