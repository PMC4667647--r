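# Genome, annotation, read and alignment-flag input.
#
# Internal coordinates are 0-based half-open on the forward genome strand;
# GFF3's 1-based inclusive coordinates are converted on read and restored on
# write. Exons of every transcript are kept in transcription order (reverse
# genomic order on the minus strand); all strand logic is applied at
# sequence-extraction time.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome/scaffold name.
#' @param strand "+" or "-".
#' @param exons integer matrix with columns start, end (0-based half-open),
#'   rows in transcription order.
#' @param cds optional matrix of CDS spans in the same convention, or NULL.
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1) stop("transcript ", transcript_id, " has no exons")
  if (any(exons[, 1] >= exons[, 2]))
    stop("transcript ", transcript_id, ": exon with start >= end")
  gstart <- sort(exons[, 1])
  gend <- sort(exons[, 2])
  if (any(gend[-length(gend)] > gstart[-1]))
    stop("transcript ", transcript_id, ": overlapping exons")
  ord <- order(exons[, 1])
  if (strand == "-") ord <- rev(ord)
  if (!identical(ord, seq_len(nrow(exons))))
    stop("transcript ", transcript_id, ": exons not in transcription order")
  if (!is.null(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
    for (r in seq_len(nrow(cds))) {
      inside <- any(cds[r, 1] >= exons[, 1] & cds[r, 2] <= exons[, 2])
      if (!inside)
        stop("transcript ", transcript_id,
             ": CDS span not contained in any exon")
    }
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds),
            class = "transcript_model")
}

#' Construct a gene model from its transcripts
#'
#' The representative transcript is the one with the longest spliced length,
#' ties broken by lexicographically smallest transcript id.
#'
#' @param gene_id identifier.
#' @param transcripts list of [transcript_model()] objects sharing
#'   chromosome and strand.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcripts) {
  if (length(transcripts) < 1) stop("gene ", gene_id, " has no transcripts")
  chrom <- transcripts[[1]]$chrom
  strand <- transcripts[[1]]$strand
  for (tx in transcripts) {
    if (tx$chrom != chrom || tx$strand != strand)
      stop("gene ", gene_id, ": transcript ", tx$transcript_id,
           " differs in chromosome or strand from its gene")
  }
  lens <- vapply(transcripts, function(tx) sum(exon_lengths(tx)), numeric(1))
  ids <- vapply(transcripts, function(tx) tx$transcript_id, character(1))
  names(transcripts) <- ids
  rep_id <- ids[order(-lens, ids)][1]
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = min(vapply(transcripts, function(tx) min(tx$exons[, 1]),
                       numeric(1))),
    end = max(vapply(transcripts, function(tx) max(tx$exons[, 2]),
                     numeric(1))),
    transcripts = transcripts,
    representative_transcript_id = rep_id
  ), class = "gene_model")
}

#' Load a genome assembly from FASTA
#'
#' Sequences are uppercased; record names are the first whitespace-delimited
#' token of the header. Duplicate names, empty files and characters outside
#' A/C/G/T/N are hard errors.
#'
#' @param path FASTA file.
#' @return A list of class `genome_assembly` with elements `sequences`
#'   (named character vector) and `lengths` (named integer vector).
#' @export
load_genome_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1])
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN character in FASTA record: ", nm[bad][1])
  genome_assembly(seqs)
}

#' @rdname load_genome_fasta
#' @param sequences named character vector of uppercase DNA strings.
#' @export
genome_assembly <- function(sequences) {
  if (length(sequences) == 0) stop("genome has no sequences")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("genome sequences must have unique names")
  if (any(nchar(sequences) == 0)) stop("empty genome sequence")
  if (any(grepl("[^ACGTN]", sequences)))
    stop("genome alphabet must be A/C/G/T/N")
  structure(list(sequences = sequences,
                 lengths = stats::setNames(nchar(sequences),
                                           names(sequences))),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly:", length(x$sequences), "sequence(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Write a genome assembly to FASTA
#' @param genome a `genome_assembly`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Load gene models from GFF3
#'
#' Recognizes gene/mRNA/exon/CDS features case-insensitively (mRNA also as
#' "transcript"), linked by ID/Parent. Transcripts lacking a gene parent are
#' promoted to single-transcript genes; orphan exons (no Parent) are skipped
#' with a warning. Coordinates are converted from 1-based inclusive to the
#' internal 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @param genome optional `genome_assembly` used to validate that every exon
#'   lies within its chromosome.
#' @return A list of `gene_model` objects.
#' @export
load_annotation_gff3 <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,       # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = tolower(as.character(gr$type)),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    stringsAsFactors = FALSE
  )
  parents <- if (!is.null(gr$Parent)) gr$Parent else
    S4Vectors::List(replicate(nrow(df), character(0), simplify = FALSE))

  gene_rows <- which(df$type == "gene")
  tx_rows <- which(df$type %in% c("mrna", "transcript"))
  gene_info <- df[gene_rows, , drop = FALSE]
  rownames(gene_info) <- gene_info$id

  # transcript table; transcripts without a known gene parent become their
  # own single-transcript genes
  tx_info <- df[tx_rows, , drop = FALSE]
  tx_parent <- vapply(parents[tx_rows], function(p)
    if (length(p)) p[1] else NA_character_, character(1))
  tx_gene <- ifelse(!is.na(tx_parent) & tx_parent %in% gene_info$id,
                    tx_parent, tx_info$id)
  rownames(tx_info) <- tx_info$id

  exons <- vector("list", length(tx_rows))
  names(exons) <- tx_info$id
  cdss <- vector("list", length(tx_rows))
  names(cdss) <- tx_info$id

  n_orphan <- 0L
  for (r in which(df$type %in% c("exon", "cds"))) {
    pp <- parents[[r]]
    if (length(pp) == 0) {
      n_orphan <- n_orphan + 1L
      next
    }
    for (p in pp) {
      if (!p %in% tx_info$id) { n_orphan <- n_orphan + 1L; next }
      span <- c(df$start[r], df$end[r])
      if (df$type[r] == "exon") exons[[p]] <- rbind(exons[[p]], span)
      else cdss[[p]] <- rbind(cdss[[p]], span)
    }
  }
  if (n_orphan > 0)
    warning(n_orphan, " exon/CDS feature(s) without a usable Parent skipped")

  tx_objs <- list()
  for (tid in tx_info$id) {
    ex <- exons[[tid]]
    if (is.null(ex)) next
    strand <- tx_info[tid, "strand"]
    chrom <- tx_info[tid, "chrom"]
    gid <- tx_gene[match(tid, tx_info$id)]
    if (gid %in% gene_info$id && gene_info[gid, "strand"] != strand)
      stop("transcript ", tid, " strand differs from its gene ", gid)
    if (!is.null(genome)) {
      if (!chrom %in% names(genome$lengths))
        stop("transcript ", tid, " on unknown sequence ", chrom)
      if (max(ex[, 2]) > genome$lengths[[chrom]] || min(ex[, 1]) < 0)
        stop("exon of transcript ", tid, " outside sequence ", chrom)
    }
    ord <- order(ex[, 1])
    if (strand == "-") ord <- rev(ord)
    ex <- ex[ord, , drop = FALSE]
    cd <- cdss[[tid]]
    if (!is.null(cd)) {
      ordc <- order(cd[, 1])
      if (strand == "-") ordc <- rev(ordc)
      cd <- cd[ordc, , drop = FALSE]
    }
    tx_objs[[tid]] <- transcript_model(tid, gid, chrom, strand, ex, cd)
  }

  out <- list()
  for (gid in unique(tx_gene[tx_info$id %in% names(tx_objs)])) {
    txs <- tx_objs[tx_gene[match(names(tx_objs), tx_info$id)] == gid]
    out[[gid]] <- gene_model(gid, txs)
  }
  unname(out)
}

#' Write gene models to GFF3
#'
#' Inverse of [load_annotation_gff3()]: internal 0-based half-open spans are
#' converted back to GFF3's 1-based inclusive coordinates.
#'
#' @param genes list of `gene_model` objects.
#' @param path output file.
#' @export
write_annotation_gff3 <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, type = "gene", start = g$start + 1L, end = g$end,
      strand = g$strand, id = g$gene_id, parent = NA_character_,
      stringsAsFactors = FALSE)
    for (tx in g$transcripts) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom, type = "mRNA", start = min(tx$exons[, 1]) + 1L,
        end = max(tx$exons[, 2]), strand = tx$strand, id = tx$transcript_id,
        parent = g$gene_id, stringsAsFactors = FALSE)
      for (r in seq_len(nrow(tx$exons)))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = tx$chrom, type = "exon", start = tx$exons[r, 1] + 1L,
          end = tx$exons[r, 2], strand = tx$strand, id = NA_character_,
          parent = tx$transcript_id, stringsAsFactors = FALSE)
      if (!is.null(tx$cds))
        for (r in seq_len(nrow(tx$cds)))
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = tx$chrom, type = "CDS", start = tx$cds[r, 1] + 1L,
            end = tx$cds[r, 2], strand = tx$strand, id = NA_character_,
            parent = tx$transcript_id, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  attrs <- ifelse(is.na(tab$id),
                  paste0("Parent=", tab$parent),
                  ifelse(is.na(tab$parent), paste0("ID=", tab$id),
                         paste0("ID=", tab$id, ";Parent=", tab$parent)))
  lines <- paste(tab$chrom, "transchimera", tab$type, tab$start, tab$end,
                 ".", tab$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Load synchronized paired-end FASTQ files
#'
#' Read ids are stripped of trailing `/1` / `/2` suffixes and of anything
#' after the first whitespace; the two files must list the same ids in the
#' same order. Qualities are Phred+33.
#'
#' @param path_r1,path_r2 FASTQ files for mate 1 and mate 2.
#' @return A data frame of pairs with columns `read_id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`.
#' @export
load_reads_fastq <- function(path_r1, path_r2) {
  r1 <- Biostrings::readDNAStringSet(path_r1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path_r2, format = "fastq",
                                     with.qualities = TRUE)
  clean <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))
  id1 <- clean(names(r1))
  id2 <- clean(names(r2))
  n <- min(length(id1), length(id2))
  mismatch <- which(id1[seq_len(n)] != id2[seq_len(n)])
  if (length(mismatch) > 0)
    stop("paired FASTQ files desynchronized at record ", mismatch[1],
         ": ", id1[mismatch[1]], " vs ", id2[mismatch[1]])
  if (length(id1) != length(id2))
    stop("paired FASTQ files desynchronized at record ", n + 1L,
         ": unequal record counts (", length(id1), " vs ", length(id2), ")")
  q1 <- as.character(S4Vectors::mcols(r1)$qualities)
  q2 <- as.character(S4Vectors::mcols(r2)$qualities)
  s1 <- as.character(r1)
  s2 <- as.character(r2)
  if (any(nchar(s1) != nchar(q1)) || any(nchar(s2) != nchar(q2)))
    stop("sequence/quality length mismatch in FASTQ input")
  data.frame(read_id = id1, seq1 = unname(toupper(s1)), qual1 = unname(q1),
             seq2 = unname(toupper(s2)), qual2 = unname(q2),
             stringsAsFactors = FALSE)
}

#' Write a pair of FASTQ files
#' @param pairs data frame as returned by [load_reads_fastq()].
#' @param path_r1,path_r2 output files.
#' @export
write_fastq_pair <- function(pairs, path_r1, path_r2) {
  w <- function(seqs, quals, ids, mate, path) {
    lines <- as.vector(rbind(paste0("@", ids, "/", mate), seqs, "+", quals))
    writeLines(lines, path)
  }
  w(pairs$seq1, pairs$qual1, pairs$read_id, 1, path_r1)
  w(pairs$seq2, pairs$qual2, pairs$read_id, 2, path_r2)
  invisible(c(path_r1, path_r2))
}

#' Read ids of mapped records from a SAM/BAM file
#'
#' Returns the ids of records whose segment-unmapped FLAG bit (0x4) is
#' clear. Secondary/supplementary records do not add ids beyond their
#' read_id. SAM input is converted with [Rsamtools::asBam()] first.
#'
#' @param path SAM or BAM file.
#' @return Character vector of unique mapped read ids.
#' @export
load_mapped_read_ids <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(path,
    param = Rsamtools::ScanBamParam(what = c("qname", "flag")))[[1]]
  mapped <- bitwAnd(res$flag, 4L) == 0L
  unique(res$qname[mapped])
}
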