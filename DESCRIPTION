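Package: transchimera
Title: Detection and Characterization of Intergenic Trans-Splicing Events
    from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for discovering intergenic trans-splicing
    events (chimeric mRNAs joining exons of two different genes) from
    paired-end RNA-seq data. Builds a between-gene exon-exon fusion junction
    library from a genome assembly and gene models, filters reads explained
    by the genome or canonical cis-splicing, aligns the remaining candidates
    to the fusion library, and calls events under four evidence criteria
    (non-redundant junction-spanning reads with a perfect match, 20 bp
    anchors on both arms, a bridging read pair, and removal of same-strand
    readthrough artifacts). Called events are classified by donor/acceptor
    gene organization, assembled into chimeric transcripts, translated into
    chimeric proteins with reading-frame analysis, and summarized into
    global-profile statistics. Protein homology screens (conserved events
    across species, resemblance to canonical genes, donor-acceptor paralogy)
    and a BTB-upstream-of-FLYWCH domain-configuration rule for mod(mdg4)-like
    genes are included, together with a fully specified synthetic-data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
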