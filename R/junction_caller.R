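# Alignment of candidate reads to the fusion library and event calling
# under the four evidence criteria.

#' Align candidate reads to the fusion junction library
#'
#' End-to-end ungapped alignment (either read orientation) with at most
#' `max_mismatches` mismatches. Hits anchored by fewer than `min_overhang`
#' bp on either arm are discarded; per read only the best-mismatch-count
#' hits are kept, and a read whose best hits tie across more than one
#' distinct gene pair is flagged ambiguous and contributes no evidence.
#'
#' @param seqs character vector of candidate read sequences.
#' @param library a [build_fusion_library()] result.
#' @param thresholds an [evidence_thresholds()].
#' @return Data frame of junction hits (`read` index into `seqs`,
#'   `junction_id`, `offset`, `mismatches`, `strand`, `left_overlap`,
#'   `right_overlap`, `oriented_seq`), with attribute `n_ambiguous`.
#' @export
align_reads_to_junctions <- function(seqs, library,
                                     thresholds = evidence_thresholds()) {
  empty <- data.frame(read = integer(0), junction_id = character(0),
                      offset = numeric(0), mismatches = integer(0),
                      strand = character(0), left_overlap = numeric(0),
                      right_overlap = numeric(0),
                      oriented_seq = character(0), stringsAsFactors = FALSE)
  attr(empty, "n_ambiguous") <- 0L
  if (length(seqs) == 0 || nrow(library) == 0) return(empty)

  hits <- .tc_match_hits(seqs, library$fused, thresholds$min_overhang,
                         thresholds$max_mismatches, TRUE)
  if (nrow(hits) == 0) return(empty)

  mid <- nchar(library$left_arm)[hits$target]
  len <- nchar(seqs)[hits$read]
  left <- pmin(pmax(mid - hits$offset, 0), len)
  right <- len - left
  ok <- left >= thresholds$min_overhang & right >= thresholds$min_overhang
  hits <- hits[ok, , drop = FALSE]
  left <- left[ok]
  right <- right[ok]
  if (nrow(hits) == 0) return(empty)

  # best-mismatch hits per read
  best <- stats::ave(hits$mismatches, hits$read, FUN = min)
  sel <- hits$mismatches == best
  hits <- hits[sel, , drop = FALSE]
  left <- left[sel]
  right <- right[sel]

  # ambiguity: best hits spanning >1 distinct gene pair (including pairs a
  # deduplicated fused sequence could represent)
  pair <- paste(library$donor_gene, library$acceptor_gene,
                sep = "|")[hits$target]
  multi_seq <- library$n_gene_pairs[hits$target] > 1
  npair <- stats::ave(as.integer(factor(paste(hits$read, pair))), hits$read,
                      FUN = function(z) length(unique(z)))
  ambiguous_read <- unique(hits$read[npair > 1 | multi_seq])
  keep <- !(hits$read %in% ambiguous_read)
  hits <- hits[keep, , drop = FALSE]
  left <- left[keep]
  right <- right[keep]

  oriented <- ifelse(hits$strand == "+", seqs[hits$read],
                     revcomp(seqs[hits$read]))
  out <- data.frame(read = hits$read,
                    junction_id = library$junction_id[hits$target],
                    offset = hits$offset, mismatches = hits$mismatches,
                    strand = hits$strand, left_overlap = left,
                    right_overlap = right, oriented_seq = oriented,
                    stringsAsFactors = FALSE)
  attr(out, "n_ambiguous") <- length(ambiguous_read)
  out
}

# placements of reads on one chimeric transcript, classified by side
.side_of <- function(offset, len, jo, min_overhang) {
  end <- offset + len
  ifelse(end <= jo, "donor",
         ifelse(offset >= jo, "acceptor",
                ifelse(offset <= jo - min_overhang & end >= jo + min_overhang,
                       "span", "near")))
}

# count pairs bridging the junction of one chimeric transcript: a forward
# placement of one mate and a reverse placement of the other, in FR order,
# fragment <= max_insert, the two mates on opposite sides of the junction
# (a qualifying junction-spanning read may stand in for one side).
.count_bridges <- function(pairs, chim_seq, jo, thresholds) {
  if (nrow(pairs) == 0) return(0L)
  n <- nrow(pairs)
  seqs <- c(pairs$seq1, pairs$seq2)
  hits <- .tc_match_hits(seqs, chim_seq, thresholds$min_overhang,
                         thresholds$max_mismatches, TRUE)
  if (nrow(hits) == 0) return(0L)
  hits$pair <- (hits$read - 1L) %% n + 1L
  hits$mate <- (hits$read - 1L) %/% n + 1L
  hits$len <- nchar(seqs)[hits$read]
  hits$side <- .side_of(hits$offset, hits$len, jo, thresholds$min_overhang)
  hits <- hits[hits$side != "near", , drop = FALSE]
  if (nrow(hits) == 0) return(0L)

  n_bridge <- 0L
  for (p in unique(hits$pair)) {
    h <- hits[hits$pair == p, , drop = FALSE]
    h1 <- h[h$mate == 1, , drop = FALSE]
    h2 <- h[h$mate == 2, , drop = FALSE]
    if (nrow(h1) == 0 || nrow(h2) == 0) next
    found <- FALSE
    for (i in seq_len(nrow(h1))) {
      for (j in seq_len(nrow(h2))) {
        a <- h1[i, ]
        b <- h2[j, ]
        if (a$strand == b$strand) next
        fwd <- if (a$strand == "+") a else b
        rev_ <- if (a$strand == "+") b else a
        if (fwd$offset > rev_$offset) next
        frag <- rev_$offset + rev_$len - fwd$offset
        if (frag > thresholds$max_insert) next
        sides <- c(a$side, b$side)
        opposite <- setequal(sides, c("donor", "acceptor")) ||
          ("span" %in% sides && any(sides %in% c("donor", "acceptor")))
        if (!opposite) next
        found <- TRUE
        break
      }
      if (found) break
    }
    if (found) n_bridge <- n_bridge + 1L
  }
  n_bridge
}

#' Collect per-junction evidence and apply criteria (i)-(iii)
#'
#' Non-redundant support counts distinct spanning read sequences (in
#' junction orientation, collapsing PCR duplicates and opposite-orientation
#' copies). Bridging pairs are counted on the chimeric transcript implied by
#' the junction (spliced donor prefix + spliced acceptor suffix); a
#' junction-spanning read's own mate may serve as its bridge.
#'
#' @param hits result of [align_reads_to_junctions()].
#' @param pairs all QC-retained pairs (used for bridge search).
#' @param library the fusion library.
#' @param genes,genome gene models and genome (to assemble the chimeric
#'   transcript for bridge counting).
#' @param thresholds an [evidence_thresholds()].
#' @return Data frame, one row per junction with spanning support:
#'   junction_id, n_nonredundant, has_perfect, bridge_pairs, n_spanning_hits
#'   and logical `pass_i`..`pass_iii`.
#' @export
collect_evidence <- function(hits, pairs, library, genes, genome,
                             thresholds = evidence_thresholds()) {
  if (nrow(hits) == 0)
    return(data.frame(junction_id = character(0), n_nonredundant = integer(0),
                      has_perfect = logical(0), bridge_pairs = integer(0),
                      n_spanning_hits = integer(0), pass_i = logical(0),
                      pass_ii = logical(0), pass_iii = logical(0),
                      stringsAsFactors = FALSE))
  sp <- split(hits, hits$junction_id)
  ev <- data.frame(
    junction_id = names(sp),
    n_nonredundant = vapply(sp, function(h)
      length(unique(h$oriented_seq)), integer(1)),
    has_perfect = vapply(sp, function(h) any(h$mismatches == 0), logical(1)),
    n_spanning_hits = vapply(sp, nrow, integer(1)),
    stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  ev$pass_i <- ev$n_nonredundant >= thresholds$min_nonredundant_reads &
    (!thresholds$require_perfect | ev$has_perfect)
  ev$pass_ii <- TRUE   # enforced per-hit at alignment time

  ev$bridge_pairs <- 0L
  for (r in which(ev$pass_i)) {
    jrow <- library[library$junction_id == ev$junction_id[r], , drop = FALSE]
    dtx <- gene_by_id(genes, jrow$donor_gene)$transcripts[[
      jrow$donor_transcript]]
    atx <- gene_by_id(genes, jrow$acceptor_gene)$transcripts[[
      jrow$acceptor_transcript]]
    ch <- assemble_chimeric_transcript(dtx, jrow$donor_exon, atx,
                                       jrow$acceptor_exon, genome)
    ev$bridge_pairs[r] <- .count_bridges(pairs, ch$sequence,
                                         ch$junction_offset, thresholds)
  }
  ev$pass_iii <- ev$bridge_pairs >= thresholds$min_bridge_pairs
  ev[, c("junction_id", "n_nonredundant", "has_perfect", "bridge_pairs",
         "n_spanning_hits", "pass_i", "pass_ii", "pass_iii")]
}

#' Remove readthrough (conjoined-gene) candidates — criterion (iv)
#'
#' A candidate is removed iff its donor and acceptor genes are on the same
#' chromosome and strand AND their spans overlap or no annotated gene lies
#' strictly between them within `neighbor_max_gap`.
#'
#' @param candidates data frame with donor_gene/acceptor_gene columns.
#' @param genes list of `gene_model` objects.
#' @param thresholds an [evidence_thresholds()].
#' @return The retained rows, with attribute `removed` holding the rest
#'   (plus a `removal_reason` column).
#' @export
readthrough_filter <- function(candidates, genes,
                               thresholds = evidence_thresholds()) {
  if (nrow(candidates) == 0) {
    attr(candidates, "removed") <- candidates
    return(candidates)
  }
  gtab <- data.frame(
    gene_id = vapply(genes, function(g) g$gene_id, character(1)),
    chrom = vapply(genes, function(g) g$chrom, character(1)),
    strand = vapply(genes, function(g) g$strand, character(1)),
    start = vapply(genes, function(g) g$start, numeric(1)),
    end = vapply(genes, function(g) g$end, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(gtab) <- gtab$gene_id

  is_rt <- logical(nrow(candidates))
  reason <- character(nrow(candidates))
  for (r in seq_len(nrow(candidates))) {
    d <- gtab[candidates$donor_gene[r], ]
    a <- gtab[candidates$acceptor_gene[r], ]
    if (d$chrom != a$chrom || d$strand != a$strand) next
    overlap <- d$start < a$end && a$start < d$end
    if (overlap) {
      is_rt[r] <- TRUE
      reason[r] <- "same_strand_overlapping"
      next
    }
    up <- if (d$start <= a$start) d else a
    dn <- if (d$start <= a$start) a else d
    gap <- dn$start - up$end
    if (gap > thresholds$neighbor_max_gap) next
    between <- gtab$chrom == d$chrom & gtab$start >= up$end &
      gtab$end <= dn$start &
      !(gtab$gene_id %in% c(d$gene_id, a$gene_id))
    if (!any(between)) {
      is_rt[r] <- TRUE
      reason[r] <- "same_strand_neighbouring"
    }
  }
  removed <- candidates[is_rt, , drop = FALSE]
  if (nrow(removed) > 0) removed$removal_reason <- reason[is_rt]
  out <- candidates[!is_rt, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Call trans-splicing events from reads
#'
#' Full composition of the detection stages: read QC, cis filter, fusion
#' library construction, junction alignment, evidence collection under
#' criteria (i)-(iii), and the readthrough filter (iv).
#'
#' @param genome a `genome_assembly`.
#' @param genes list of `gene_model` objects.
#' @param pairs raw read pairs (see [load_reads_fastq()]).
#' @param thresholds an [evidence_thresholds()].
#' @param qc a [qc_params()].
#' @param arm_length fusion-arm length; default
#'   `max(read_length - min_overhang, 80)`.
#' @param isoform_mode passed to [build_fusion_library()].
#' @param k seed length of the cis matcher.
#' @param mapped_read_ids optional character vector of read ids already
#'   explained by an external aligner (see [load_mapped_read_ids()]); when
#'   given it replaces the internal cis matcher.
#' @return An object of class `trans_events`: list with `events` (one row
#'   per called junction), `evidence` (all junctions with spanning support),
#'   `funnel` (counts entering/leaving every filter), `library_size`, and
#'   the effective thresholds.
#' @export
call_events <- function(genome, genes, pairs,
                        thresholds = evidence_thresholds(),
                        qc = qc_params(), arm_length = NULL,
                        isoform_mode = "representative", k = 20L,
                        mapped_read_ids = NULL) {
  funnel <- c(pairs_input = nrow(pairs))

  qcres <- filter_reads(pairs, qc)
  retained <- qcres$pairs
  funnel["pairs_qc_retained"] <- nrow(retained)

  if (is.null(mapped_read_ids)) {
    index <- build_cis_index(genome, genes, k)
    part <- partition_reads(retained, index, thresholds$max_mismatches)
    candidates <- part$candidates
  } else {
    cis <- retained$read_id %in% mapped_read_ids
    candidates <- retained[!cis, , drop = FALSE]
    candidates$mate1_cis <- FALSE
    candidates$mate2_cis <- FALSE
  }
  funnel["pairs_candidate"] <- nrow(candidates)

  if (is.null(arm_length)) {
    rl <- if (nrow(pairs) > 0) max(nchar(pairs$seq1), nchar(pairs$seq2)) else 100L
    arm_length <- max(rl - thresholds$min_overhang, 80L)
  }
  library <- build_fusion_library(genes, genome, arm_length = arm_length,
                                  isoform_mode = isoform_mode,
                                  min_overhang = thresholds$min_overhang)
  funnel["library_junctions"] <- nrow(library)

  # junction-spanning candidates: only non-cis-explained mates can span
  cand_seqs <- c(candidates$seq1[!candidates$mate1_cis],
                 candidates$seq2[!candidates$mate2_cis])
  hits <- align_reads_to_junctions(cand_seqs, library, thresholds)
  funnel["spanning_hits"] <- nrow(hits)
  funnel["ambiguous_reads"] <- attr(hits, "n_ambiguous")

  ev <- collect_evidence(hits, retained, library, genes, genome, thresholds)
  funnel["junctions_with_support"] <- nrow(ev)
  ok <- ev$pass_i & ev$pass_ii & ev$pass_iii
  called <- merge(ev[ok, , drop = FALSE], as.data.frame(library),
                  by = "junction_id")
  funnel["junctions_pass_i_iii"] <- nrow(called)

  called <- readthrough_filter(called, genes, thresholds)
  removed <- attr(called, "removed")
  funnel["events_called"] <- nrow(called)

  cols <- c("junction_id", "donor_gene", "donor_transcript", "donor_exon",
            "acceptor_gene", "acceptor_transcript", "acceptor_exon",
            "donor_site", "acceptor_site", "n_nonredundant", "has_perfect",
            "bridge_pairs")
  structure(list(events = called[, cols, drop = FALSE],
                 evidence = ev, removed_readthrough = removed,
                 funnel = funnel, library_size = nrow(library),
                 thresholds = thresholds),
            class = "trans_events")
}

#' @export
print.trans_events <- function(x, ...) {
  cat("trans_events:", nrow(x$events), "called event(s)\n")
  f <- x$funnel
  for (nm in names(f)) cat(sprintf("  %-24s %d\n", nm, f[[nm]]))
  invisible(x)
}

#' @export
summary.trans_events <- function(object, ...) {
  print(object)
  if (nrow(object$events) > 0)
    print(object$events[, c("junction_id", "donor_gene", "donor_exon",
                            "acceptor_gene", "acceptor_exon",
                            "n_nonredundant", "bridge_pairs")])
  invisible(object)
}
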