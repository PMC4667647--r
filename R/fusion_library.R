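# Between-gene exon-exon fusion junction library. Each junction fuses the
# spliced donor sequence ending at a donor exon's 3' boundary with the
# spliced acceptor sequence starting at an acceptor exon's 5' boundary. Arms
# are drawn from the mature (spliced) transcript, so a short exon's arm
# extends across its upstream/downstream cis junctions.

#' Evidence thresholds for event calling
#'
#' The four calling criteria: (i) at least `min_nonredundant_reads` distinct
#' junction-spanning read sequences, one a perfect match when
#' `require_perfect`; (ii) each spanning read anchored by at least
#' `min_overhang` bp on both arms; (iii) at least `min_bridge_pairs` read
#' pairs bridging the two flanking regions (fragment at most `max_insert`);
#' (iv) same-strand overlapping-or-neighbouring gene pairs removed as
#' readthrough. `neighbor_max_gap` bounds how far apart two same-strand
#' genes with no intervening gene still count as neighbours (default
#' unlimited).
#'
#' @param min_overhang bp anchor required on each arm.
#' @param min_nonredundant_reads distinct spanning read sequences required.
#' @param require_perfect require one mismatch-free spanning read.
#' @param min_bridge_pairs bridging PE pairs required.
#' @param max_mismatches mismatch budget for junction alignment.
#' @param neighbor_max_gap bp; see above.
#' @param max_insert largest plausible fragment length for a bridge (bp).
#' @return A list of class `evidence_thresholds`.
#' @export
evidence_thresholds <- function(min_overhang = 20L,
                                min_nonredundant_reads = 2L,
                                require_perfect = TRUE,
                                min_bridge_pairs = 1L,
                                max_mismatches = 2L,
                                neighbor_max_gap = Inf,
                                max_insert = 1000L) {
  stopifnot(min_overhang >= 1, min_nonredundant_reads >= 0,
            min_bridge_pairs >= 0, max_mismatches >= 0)
  structure(list(min_overhang = as.integer(min_overhang),
                 min_nonredundant_reads = as.integer(min_nonredundant_reads),
                 require_perfect = isTRUE(require_perfect),
                 min_bridge_pairs = as.integer(min_bridge_pairs),
                 max_mismatches = as.integer(max_mismatches),
                 neighbor_max_gap = neighbor_max_gap,
                 max_insert = as.integer(max_insert)),
            class = "evidence_thresholds")
}

# donor/acceptor boundary tables for one transcript: per exon, the arm
# sequence (clipped at transcript ends) and the genomic boundary coordinate
.boundaries_for_tx <- function(tx, genome, arm_length) {
  S <- spliced_sequence(tx, genome)
  lens <- exon_lengths(tx)
  cum <- cumsum(lens)
  n <- length(lens)
  left <- substring(S, pmax(1, cum - arm_length + 1), cum)
  cum0 <- c(0, cum[-n])
  right <- substring(S, cum0 + 1, pmin(nchar(S), cum0 + arm_length))
  d_coord <- vapply(seq_len(n), function(i) donor_site_coord(tx, i),
                    numeric(1))
  a_coord <- vapply(seq_len(n), function(j) acceptor_site_coord(tx, j),
                    numeric(1))
  list(donor = data.frame(exon = seq_len(n), arm = left, site = d_coord,
                          stringsAsFactors = FALSE),
       acceptor = data.frame(exon = seq_len(n), arm = right, site = a_coord,
                             stringsAsFactors = FALSE))
}

#' Build the between-gene exon-exon fusion library
#'
#' One junction per ordered (donor gene, donor exon boundary) x
#' (acceptor gene, acceptor exon boundary) pair over distinct genes.
#' Junctions with an arm shorter than `min_overhang`, or with more than
#' `max_n_fraction` N in their arms, are dropped. Identical fused sequences
#' are deduplicated; all contributing (junction, provenance) rows are kept in
#' the `provenance` attribute and each kept row carries the set of distinct
#' gene pairs its sequence could represent (used by the ambiguity rule).
#'
#' @param genes list of `gene_model` objects.
#' @param genome a `genome_assembly`.
#' @param arm_length arm length in bp; choose at least
#'   `read_length - min_overhang` so a fully embedded read can satisfy the
#'   two-arm rule (80 suits 100 bp reads).
#' @param isoform_mode `"representative"` (default; longest spliced
#'   transcript per gene) or `"all"`.
#' @param min_overhang junctions with arms shorter than this are dropped.
#' @param max_n_fraction maximum tolerated N fraction across the two arms.
#' @return A data frame of class `fusion_library`; one row per distinct
#'   fused sequence with donor/acceptor provenance, arm sequences, genomic
#'   boundary coordinates and the fused sequence.
#' @export
build_fusion_library <- function(genes, genome, arm_length = 80L,
                                 isoform_mode = c("representative", "all"),
                                 min_overhang = 20L, max_n_fraction = 0.2) {
  isoform_mode <- match.arg(isoform_mode)
  if (arm_length < min_overhang)
    stop("arm_length must be >= min_overhang")

  donors <- list()
  acceptors <- list()
  for (g in genes) {
    txs <- if (isoform_mode == "representative")
      list(representative_tx(g)) else unname(g$transcripts)
    for (tx in txs) {
      b <- .boundaries_for_tx(tx, genome, arm_length)
      donors[[length(donors) + 1]] <- cbind(
        gene = g$gene_id, transcript = tx$transcript_id, b$donor,
        stringsAsFactors = FALSE)
      acceptors[[length(acceptors) + 1]] <- cbind(
        gene = g$gene_id, transcript = tx$transcript_id, b$acceptor,
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(
    junction_id = character(0), donor_gene = character(0),
    donor_transcript = character(0), donor_exon = integer(0),
    acceptor_gene = character(0), acceptor_transcript = character(0),
    acceptor_exon = integer(0), donor_site = numeric(0),
    acceptor_site = numeric(0), left_arm = character(0),
    right_arm = character(0), fused = character(0),
    stringsAsFactors = FALSE)
  if (length(donors) == 0)
    return(structure(empty, class = c("fusion_library", "data.frame"),
                     arm_length = arm_length, provenance = empty))
  D <- do.call(rbind, donors)
  A <- do.call(rbind, acceptors)
  D <- D[nchar(D$arm) >= min_overhang, , drop = FALSE]
  A <- A[nchar(A$arm) >= min_overhang, , drop = FALSE]

  idx <- expand.grid(d = seq_len(nrow(D)), a = seq_len(nrow(A)))
  idx <- idx[D$gene[idx$d] != A$gene[idx$a], , drop = FALSE]
  if (nrow(idx) == 0)
    return(structure(empty, class = c("fusion_library", "data.frame"),
                     arm_length = arm_length, provenance = empty))
  lib <- data.frame(
    donor_gene = D$gene[idx$d], donor_transcript = D$transcript[idx$d],
    donor_exon = D$exon[idx$d],
    acceptor_gene = A$gene[idx$a],
    acceptor_transcript = A$transcript[idx$a],
    acceptor_exon = A$exon[idx$a],
    donor_site = D$site[idx$d], acceptor_site = A$site[idx$a],
    left_arm = D$arm[idx$d], right_arm = A$arm[idx$a],
    stringsAsFactors = FALSE)
  lib$fused <- paste0(lib$left_arm, lib$right_arm)

  n_frac <- (nchar(gsub("[^N]", "", lib$left_arm)) +
             nchar(gsub("[^N]", "", lib$right_arm))) /
    (nchar(lib$left_arm) + nchar(lib$right_arm))
  lib <- lib[n_frac <= max_n_fraction, , drop = FALSE]
  lib$junction_id <- sprintf("J%06d", seq_len(nrow(lib)))
  lib <- lib[, c("junction_id", setdiff(names(lib), "junction_id"))]

  # deduplicate identical fused sequences, remembering every provenance row
  grp <- match(lib$fused, lib$fused)
  provenance <- lib
  provenance$canonical_junction_id <- lib$junction_id[grp]
  keep <- lib[!duplicated(lib$fused), , drop = FALSE]
  pair <- paste(lib$donor_gene, lib$acceptor_gene, sep = "|")
  keep$n_gene_pairs <- vapply(
    split(pair, lib$junction_id[grp])[keep$junction_id],
    function(p) length(unique(p)), integer(1))
  rownames(keep) <- NULL
  structure(keep, class = c("fusion_library", "data.frame"),
            arm_length = arm_length, provenance = provenance)
}

#' Export a fusion library as FASTA
#'
#' Headers are structured as
#' `junction_id|donor_gene|donor_exon|acceptor_gene|acceptor_exon`.
#' @param library a `fusion_library`.
#' @param path output FASTA.
#' @export
export_fusion_library_fasta <- function(library, path) {
  set <- Biostrings::DNAStringSet(library$fused)
  names(set) <- paste(library$junction_id, library$donor_gene,
                      library$donor_exon, library$acceptor_gene,
                      library$acceptor_exon, sep = "|")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
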