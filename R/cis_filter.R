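# Removal of reads explained by the genome or by annotated cis-splicing.
# A read is cis-explained when it aligns end-to-end, ungapped, with at most
# `max_mismatches` mismatches (either orientation) to any genome sequence or
# any annotated spliced transcript. This conservative stand-in for the
# genome + transcriptome alignment rounds of a spliced aligner errs toward
# fewer candidate reads: no soft clipping, no indels, no novel cis junctions.

#' Build the cis index
#'
#' Indexes the genome chromosomes plus the spliced sequence of every
#' annotated transcript (in transcript orientation); reads are queried in
#' both orientations, so both genome strands are covered.
#'
#' @param genome a `genome_assembly`.
#' @param genes list of `gene_model` objects (may be empty).
#' @param k seed length used by the matcher.
#' @return A list of class `cis_index` with the indexed sequences and `k`.
#' @export
build_cis_index <- function(genome, genes, k = 20L) {
  tx_seqs <- character(0)
  for (g in genes) {
    for (tx in g$transcripts) {
      tx_seqs[[tx$transcript_id]] <- spliced_sequence(tx, genome)
    }
  }
  structure(list(seqs = c(genome$sequences, tx_seqs), k = as.integer(k)),
            class = "cis_index")
}

#' Partition read pairs into cis-explained and candidate pairs
#'
#' A pair is a candidate when at least one mate is not cis-explained;
#' per-mate explanation status travels with the candidates. Reads shorter
#' than the seed length are treated as cis-explained (uninformative).
#'
#' @param pairs QC-passed pairs (trimmed).
#' @param index a [build_cis_index()] result.
#' @param max_mismatches mismatch budget of the ungapped matcher.
#' @return A list with `cis` (fully explained pairs) and `candidates`
#'   (pairs with extra logical columns `mate1_cis`, `mate2_cis`).
#' @export
partition_reads <- function(pairs, index, max_mismatches = 2L) {
  if (nrow(pairs) == 0)
    return(list(cis = pairs, candidates = cbind(pairs, mate1_cis = logical(0),
                                                mate2_cis = logical(0))))
  explained <- function(seqs) {
    short <- nchar(seqs) < index$k
    hit <- .tc_match_any(seqs, unname(index$seqs), index$k,
                         as.integer(max_mismatches), TRUE)
    short | hit
  }
  e1 <- explained(pairs$seq1)
  e2 <- explained(pairs$seq2)
  both <- e1 & e2
  cand <- pairs[!both, , drop = FALSE]
  cand$mate1_cis <- e1[!both]
  cand$mate2_cis <- e2[!both]
  rownames(cand) <- NULL
  list(cis = pairs[both, , drop = FALSE], candidates = cand)
}
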