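Package: paleokaryo
Title: Ancestral Karyotype Reconstruction Under Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs pre- and post-whole-genome-duplication (WGD)
    ancestral karyotypes for three related genomes that share one WGD and
    differ by a second, lineage-specific WGD.  Genomes are modelled as
    signed marker orders; rearrangement is measured with the
    single-cut-or-join (SCJ) distance, under which the genome median and
    the guided genome halving problems have exact majority-rule solutions
    once duplicated marker copies have been matched.  The package builds
    putative protogenes (pPGs) from ortholog graphs, detects conserved
    non-overlapping synteny blocks, matches duplicated block copies by
    minimising SCJ distance, reconstructs ancestors bottom-up, counts
    chromosome fissions and fusions against the reconstructed
    protochromosomes with z-tests for non-random placement, dates WGDs
    from Ks distributions with Gaussian mixtures, and normalises
    cross-species TPM expression.  A ground-truthed simulator of the
    two-WGD evolutionary scenario supports recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    igraph,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
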