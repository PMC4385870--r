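Package: panelcall
Title: Multiplexed Amplicon ctDNA Mutation Detection with Spike-In Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of pooled amplicon sequencing data from a
    mutation-enrichment circulating tumor DNA (ctDNA) assay. Reads carrying
    inline sample barcodes are merged, demultiplexed and classified against a
    46-mutation hotspot panel; randomly barcoded internal positive control
    (IPC) molecules spiked into each sample are binned by their identifier
    sequences to estimate the per-mutation cluster yield, which converts
    mutant cluster counts into absolute input copies and allele fractions;
    mutations are called against per-mutation limits of detection derived
    from wild-type background runs (the greater of a single-copy allele
    fraction and mean plus three standard deviations of background). A
    built-in simulator emulates the wet-lab front end (limited-cycle
    error-prone PCR, differential mutant enrichment, paired-end sequencing)
    with full ground truth, so the whole pipeline is testable at desk scale.
    Reporting helpers assemble titration tables, assay-concordance summaries
    and longitudinal monitoring series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
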