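# Classification and molecular annotation of called events: organizational
# type, donor-acceptor distance, chimeric transcript assembly, chimeric
# protein prediction, reading-frame status and cis/trans splice-site sharing.

#' Classify an event by donor/acceptor gene organization
#'
#' DfChr: different chromosomes/scaffolds. DfStr: same chromosome, different
#' strands. SmDA/SmAD: same chromosome and strand, with "upstream" taken
#' along the shared transcription direction (on the minus strand the
#' genomically rightmost gene is upstream).
#'
#' @param donor,acceptor `gene_model` objects.
#' @return One of "SmDA", "SmAD", "DfStr", "DfChr".
#' @export
classify_event <- function(donor, acceptor) {
  if (donor$chrom != acceptor$chrom) return("DfChr")
  if (donor$strand != acceptor$strand) return("DfStr")
  donor_upstream <- if (donor$strand == "+") donor$start < acceptor$start
    else donor$start > acceptor$start
  if (donor_upstream) "SmDA" else "SmAD"
}

#' Distance between donor and acceptor genes
#'
#' Same-sequence events: the gap between the gene spans (0 when they
#' overlap). DfChr events between two unplaced scaffolds: the putative
#' distance obtained by orienting each scaffold so the donor transcribes
#' toward its 3' edge and the acceptor away from its 5' edge, then summing
#' the donor's distance to its scaffold edge and the acceptor's distance
#' from its edge. DfChr events involving a placed, named chromosome have no
#' defined distance (NA).
#'
#' @param donor,acceptor `gene_model` objects.
#' @param genome a `genome_assembly` (for scaffold lengths).
#' @param type event type from [classify_event()].
#' @param scaffold_pattern regex deciding which sequence names count as
#'   unplaced scaffolds.
#' @return Distance in bp, or NA for undefined DfChr distances.
#' @export
donor_acceptor_distance <- function(donor, acceptor, genome,
                                    type = classify_event(donor, acceptor),
                                    scaffold_pattern = "^(scaffold|scf|contig|ctg)") {
  if (type != "DfChr") {
    gap <- max(donor$start, acceptor$start) - min(donor$end, acceptor$end)
    return(max(0, gap))
  }
  is_scaf <- grepl(scaffold_pattern, c(donor$chrom, acceptor$chrom),
                   ignore.case = TRUE)
  if (!all(is_scaf)) return(NA_real_)
  dlen <- genome$lengths[[donor$chrom]]
  # distance from donor 3' end to the scaffold edge it transcribes toward
  d_tail <- if (donor$strand == "+") dlen - donor$end else donor$start
  # distance from the acceptor's 5'-edge to its gene start
  a_head <- if (acceptor$strand == "+") acceptor$start else
    genome$lengths[[acceptor$chrom]] - acceptor$end
  d_tail + a_head
}

#' Assemble the chimeric transcript of an event
#'
#' Concatenates donor exons 1..i and acceptor exons j..n (transcription
#' order, strand-corrected). The junction offset is the spliced length of
#' the donor part.
#'
#' @param donor_tx,acceptor_tx `transcript_model` objects.
#' @param donor_exon,acceptor_exon 1-based exon indices in transcription
#'   order.
#' @param genome a `genome_assembly`.
#' @return List with `sequence` and `junction_offset`.
#' @export
assemble_chimeric_transcript <- function(donor_tx, donor_exon, acceptor_tx,
                                         acceptor_exon, genome) {
  nd <- nrow(donor_tx$exons)
  na_ <- nrow(acceptor_tx$exons)
  if (donor_exon < 1 || donor_exon > nd)
    stop("donor exon index out of range: ", donor_exon)
  if (acceptor_exon < 1 || acceptor_exon > na_)
    stop("acceptor exon index out of range: ", acceptor_exon)
  dS <- spliced_sequence(donor_tx, genome)
  aS <- spliced_sequence(acceptor_tx, genome)
  d_keep <- sum(exon_lengths(donor_tx)[seq_len(donor_exon)])
  a_skip <- if (acceptor_exon > 1)
    sum(exon_lengths(acceptor_tx)[seq_len(acceptor_exon - 1)]) else 0L
  list(sequence = paste0(substr(dS, 1, d_keep),
                         substr(aS, a_skip + 1, nchar(aS))),
       junction_offset = d_keep)
}

#' Predict the chimeric protein of an assembled transcript
#'
#' Scans ATG codons starting before the junction in all three frames,
#' translates each to the first stop, and keeps ORFs whose complete codons
#' give at least `min_side_aa` amino acids on each side of the junction (a
#' codon straddling the junction counts to neither side). Among qualifying
#' ORFs the longest peptide wins, ties broken by the most 5' start.
#'
#' @param sequence chimeric transcript DNA.
#' @param junction_offset spliced length of the donor part.
#' @param min_side_aa minimum complete codons on each side.
#' @return NULL if no ORF qualifies, else a list of class `chimeric_protein`
#'   with `peptide`, `start` (0-based transcript offset of the ATG),
#'   `donor_aa`, `acceptor_aa`.
#' @export
predict_chimeric_protein <- function(sequence, junction_offset,
                                     min_side_aa = 10L) {
  starts <- gregexpr("ATG", sequence, fixed = TRUE)[[1]]
  if (starts[1] == -1) return(NULL)
  starts <- starts[starts - 1 < junction_offset] - 1L  # 0-based, in donor part
  if (length(starts) == 0) return(NULL)

  best <- NULL
  for (a in starts) {
    tail_len <- nchar(sequence) - a
    n_cod <- tail_len %/% 3L
    if (n_cod < 2) next
    orf <- substr(sequence, a + 1L, a + 3L * n_cod)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf),
                                             if.fuzzy.codon = "X"))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    pep <- if (stop_at > 0) substr(aa, 1, stop_at - 1) else aa
    P <- nchar(pep)
    if (P == 0) next
    donor_full <- (junction_offset - a) %/% 3L
    donor_aa <- min(P, donor_full)
    acceptor_aa <- max(0L, P - as.integer(ceiling((junction_offset - a) / 3)))
    if (donor_aa < min_side_aa || acceptor_aa < min_side_aa) next
    if (is.null(best) || P > nchar(best$peptide)) {
      best <- structure(list(peptide = pep, start = a, donor_aa = donor_aa,
                             acceptor_aa = acceptor_aa),
                        class = "chimeric_protein")
    }
  }
  best
}

# Spliced-coordinate offset of the annotated CDS start within a transcript,
# or NA if the transcript has no CDS.
.cds_spliced_start <- function(tx) {
  if (is.null(tx$cds) || nrow(tx$cds) == 0) return(NA_integer_)
  # 5'-most CDS base in transcription order
  cds5 <- if (tx$strand == "+") min(tx$cds[, 1]) else max(tx$cds[, 2])
  lens <- exon_lengths(tx)
  cum0 <- c(0, cumsum(lens)[-length(lens)])
  for (k in seq_len(nrow(tx$exons))) {
    s <- tx$exons[k, 1]
    e <- tx$exons[k, 2]
    if (tx$strand == "+" && cds5 >= s && cds5 < e)
      return(cum0[k] + (cds5 - s))
    if (tx$strand == "-" && cds5 > s && cds5 <= e)
      return(cum0[k] + (e - cds5))
  }
  NA_integer_
}

#' Reading-frame status of a chimeric ORF against donor and acceptor CDS
#'
#' The chimeric ORF is in frame with the donor (acceptor) when its codon
#' phase at the junction equals the donor (acceptor) CDS phase at the same
#' spliced coordinate. Phases are compared in spliced coordinates, so exons
#' of non-multiple-of-3 length are handled. Genes lacking an annotated CDS
#' give NA.
#'
#' @param protein a `chimeric_protein` (needs `$start`).
#' @param donor_tx,acceptor_tx `transcript_model` objects.
#' @param donor_exon,acceptor_exon exon indices defining the junction.
#' @param junction_offset spliced donor-part length.
#' @return List with logicals `in_frame_with_donor`,
#'   `in_frame_with_acceptor` (NA where CDS is missing).
#' @export
frame_status <- function(protein, donor_tx, acceptor_tx, donor_exon,
                         acceptor_exon, junction_offset) {
  s_d <- unname(.cds_spliced_start(donor_tx))
  s_a <- unname(.cds_spliced_start(acceptor_tx))
  a <- protein$start
  in_donor <- if (is.na(s_d)) NA else (a - s_d) %% 3L == 0L
  if (is.na(s_a)) {
    in_acceptor <- NA
  } else {
    lens <- exon_lengths(acceptor_tx)
    q0 <- if (acceptor_exon > 1) sum(lens[seq_len(acceptor_exon - 1)]) else 0L
    # junction maps to acceptor spliced coordinate q0
    in_acceptor <- (a - junction_offset + q0 - s_a) %% 3L == 0L
  }
  list(in_frame_with_donor = in_donor, in_frame_with_acceptor = in_acceptor)
}

#' Cis/trans splice-site sharing of an event
#'
#' The donor arm is shared when some cis intron of the donor gene uses the
#' event's donor-exon 3' boundary as a splice donor; the acceptor arm when
#' some cis intron of the acceptor gene uses the acceptor-exon 5' boundary
#' as a splice acceptor. All annotated transcripts of each gene are
#' considered.
#'
#' @param donor,acceptor `gene_model` objects.
#' @param donor_site,acceptor_site genomic boundary coordinates of the event
#'   (as carried by the fusion library).
#' @return "both_arms", "one_arm" or "neither".
#' @export
cis_sharing_status <- function(donor, acceptor, donor_site, acceptor_site) {
  donor_sites <- unlist(lapply(donor$transcripts, function(tx) {
    n <- nrow(tx$exons)
    if (n < 2) return(numeric(0))
    vapply(seq_len(n - 1), function(i) donor_site_coord(tx, i), numeric(1))
  }))
  acceptor_sites <- unlist(lapply(acceptor$transcripts, function(tx) {
    n <- nrow(tx$exons)
    if (n < 2) return(numeric(0))
    vapply(2:n, function(j) acceptor_site_coord(tx, j), numeric(1))
  }))
  d_shared <- donor_site %in% donor_sites
  a_shared <- acceptor_site %in% acceptor_sites
  if (d_shared && a_shared) "both_arms"
  else if (d_shared || a_shared) "one_arm"
  else "neither"
}

#' Annotate called events
#'
#' Adds to each called event: organizational type, donor-acceptor distance,
#' the chimeric transcript and its junction offset, retained exon counts,
#' cis-sharing class, and (where an ORF qualifies) the chimeric protein with
#' its frame flags.
#'
#' @param events a `trans_events` object or its `events` data frame.
#' @param genes,genome gene models and genome.
#' @param min_side_aa protein qualification rule (complete codons per side).
#' @param scaffold_pattern see [donor_acceptor_distance()].
#' @return Data frame of class `annotated_events`; one row per event with
#'   the added columns, including `peptide`, `donor_aa`, `acceptor_aa`,
#'   `in_frame_with_donor`, `in_frame_with_acceptor` (NA where absent) and
#'   `coding` (TRUE when a protein qualified).
#' @export
annotate_events <- function(events, genes, genome, min_side_aa = 10L,
                            scaffold_pattern = "^(scaffold|scf|contig|ctg)") {
  ev <- if (inherits(events, "trans_events")) events$events else events
  n <- nrow(ev)
  ev$type <- character(n)
  ev$distance_bp <- numeric(n)
  ev$chimeric_transcript <- character(n)
  ev$junction_offset <- integer(n)
  ev$retained_donor_exons <- integer(n)
  ev$retained_acceptor_exons <- integer(n)
  ev$cis_sharing <- character(n)
  ev$coding <- logical(n)
  ev$peptide <- NA_character_
  ev$orf_start <- NA_integer_
  ev$donor_aa <- NA_integer_
  ev$acceptor_aa <- NA_integer_
  ev$in_frame_with_donor <- NA
  ev$in_frame_with_acceptor <- NA

  for (r in seq_len(n)) {
    dg <- gene_by_id(genes, ev$donor_gene[r])
    ag <- gene_by_id(genes, ev$acceptor_gene[r])
    dtx <- dg$transcripts[[ev$donor_transcript[r]]]
    atx <- ag$transcripts[[ev$acceptor_transcript[r]]]
    ev$type[r] <- classify_event(dg, ag)
    ev$distance_bp[r] <- donor_acceptor_distance(
      dg, ag, genome, ev$type[r], scaffold_pattern)
    ch <- assemble_chimeric_transcript(dtx, ev$donor_exon[r], atx,
                                       ev$acceptor_exon[r], genome)
    ev$chimeric_transcript[r] <- ch$sequence
    ev$junction_offset[r] <- ch$junction_offset
    ev$retained_donor_exons[r] <- ev$donor_exon[r]
    ev$retained_acceptor_exons[r] <-
      nrow(atx$exons) - ev$acceptor_exon[r] + 1L
    ev$cis_sharing[r] <- cis_sharing_status(dg, ag, ev$donor_site[r],
                                            ev$acceptor_site[r])
    prot <- predict_chimeric_protein(ch$sequence, ch$junction_offset,
                                     min_side_aa)
    if (!is.null(prot)) {
      ev$coding[r] <- TRUE
      ev$peptide[r] <- prot$peptide
      ev$orf_start[r] <- prot$start
      ev$donor_aa[r] <- prot$donor_aa
      ev$acceptor_aa[r] <- prot$acceptor_aa
      fs <- frame_status(prot, dtx, atx, ev$donor_exon[r],
                         ev$acceptor_exon[r], ch$junction_offset)
      ev$in_frame_with_donor[r] <- fs$in_frame_with_donor
      ev$in_frame_with_acceptor[r] <- fs$in_frame_with_acceptor
    }
  }
  class(ev) <- c("annotated_events", "data.frame")
  ev
}

#' Donor and acceptor peptide segments of an annotated coding event
#'
#' Splits the chimeric peptide at the junction: donor segment = the codons
#' fully inside the donor part, acceptor segment = the codons fully after
#' the junction (the straddling codon, if any, belongs to neither).
#'
#' @param event one row of an `annotated_events` data frame.
#' @return List with `donor_peptide` and `acceptor_peptide` (NULL for
#'   non-coding events).
#' @export
event_peptide_segments <- function(event) {
  if (!isTRUE(event$coding)) return(NULL)
  pep <- event$peptide
  d <- event$donor_aa
  list(donor_peptide = substr(pep, 1, d),
       acceptor_peptide = substr(pep, nchar(pep) - event$acceptor_aa + 1,
                                 nchar(pep)))
}
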