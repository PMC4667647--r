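# Synthetic-data generator: toy genomes with multi-exon GT..AG genes,
# planted trans-splicing truths of all four configuration types, readthrough
# decoys, and paired-end reads. Everything downstream is testable against
# the returned truth table without any external data.

#' Simulation configuration
#'
#' Defaults describe the regime the detection pipeline is designed for:
#' paired-end 100 bp reads, ~300 bp inserts, 50x per-transcript coverage,
#' a 0.2\% base substitution rate, one planted event of each organizational
#' type (SmDA, SmAD, DfStr, DfChr) and two same-strand readthrough decoys.
#'
#' @param seed integer seed; every generator output is deterministic in it.
#' @param n_chroms,n_scaffolds number of named chromosomes and of unplaced
#'   scaffolds (scaffolds host the DfChr events so the putative-distance
#'   convention is exercised).
#' @param chrom_length,scaffold_length sequence lengths (bp).
#' @param genes_per_chrom,genes_per_scaffold gene capacity per sequence.
#' @param exons_per_gene,exon_length,intron_length inclusive ranges
#'   (length-2 integer vectors) sampled per gene/exon/intron.
#' @param gc_fraction background GC content.
#' @param n_trans_events named counts of planted events per type, names in
#'   SmDA/SmAD/DfStr/DfChr.
#' @param n_readthrough_decoys number of same-strand adjacent-gene decoys
#'   expressed as fused transcripts (rejectable only by the readthrough
#'   filter).
#' @param read_length,insert_mean,insert_sd paired-end read geometry (bp).
#' @param min_segment_length bp; planted junction exon indices are chosen so
#'   that both the donor and the acceptor segment of a chimeric transcript
#'   reach this spliced length where the gene structure allows it. Keeping
#'   each segment longer than the largest plausible fragment
#'   (insert_mean + 3 insert_sd) guarantees that fragments can span the
#'   junction at interior positions; on shorter templates read pairs pin to
#'   the transcript ends and junction coverage becomes geometrically
#'   impossible.
#' @param base_error_rate per-base substitution probability.
#' @param coverage_per_transcript fold coverage of each cis transcript.
#' @param trans_expression_fraction fraction of a locus's coverage given to
#'   its chimeric transcript.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L, n_scaffolds = 2L,
                              chrom_length = 60000L, scaffold_length = 25000L,
                              genes_per_chrom = 6L, genes_per_scaffold = 3L,
                              exons_per_gene = c(4L, 7L),
                              exon_length = c(90L, 240L),
                              intron_length = c(60L, 400L),
                              gc_fraction = 0.45,
                              n_trans_events = c(SmDA = 1L, SmAD = 1L,
                                                 DfStr = 1L, DfChr = 1L),
                              n_readthrough_decoys = 2L,
                              read_length = 100L,
                              insert_mean = 300, insert_sd = 30,
                              min_segment_length = 320L,
                              base_error_rate = 0.002,
                              coverage_per_transcript = 50,
                              trans_expression_fraction = 0.5) {
  types <- c("SmDA", "SmAD", "DfStr", "DfChr")
  ev <- stats::setNames(rep(0L, 4), types)
  ev[names(n_trans_events)] <- as.integer(n_trans_events)
  stopifnot(
    all(ev >= 0), n_readthrough_decoys >= 0,
    read_length >= 40,            # must satisfy the 20 bp two-arm rule
    intron_length[1] >= 4,        # room for GT..AG
    exons_per_gene[1] >= 2,
    trans_expression_fraction >= 0, trans_expression_fraction <= 1
  )
  structure(list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    n_scaffolds = as.integer(n_scaffolds),
    chrom_length = as.integer(chrom_length),
    scaffold_length = as.integer(scaffold_length),
    genes_per_chrom = as.integer(genes_per_chrom),
    genes_per_scaffold = as.integer(genes_per_scaffold),
    exons_per_gene = as.integer(exons_per_gene),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    gc_fraction = gc_fraction, n_trans_events = ev,
    n_readthrough_decoys = as.integer(n_readthrough_decoys),
    read_length = as.integer(read_length),
    insert_mean = insert_mean, insert_sd = insert_sd,
    min_segment_length = as.integer(min_segment_length),
    base_error_rate = base_error_rate,
    coverage_per_transcript = coverage_per_transcript,
    trans_expression_fraction = trans_expression_fraction
  ), class = "simulation_config")
}

# One multi-exon gene on its transcription strand. The spliced transcript is
# a complete CDS: ATG start, internal-stop-free codons, terminal stop; exon
# boundaries split it arbitrarily, so CDS phase at any spliced coordinate is
# simply the coordinate mod 3. Introns start GT and end AG.
.sim_gene_local <- function(config) {
  n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
  ex_len <- sample(config$exon_length[1]:config$exon_length[2], n_ex,
                   replace = TRUE)
  total <- sum(ex_len)
  ex_len[n_ex] <- ex_len[n_ex] + (3L - total %% 3L) %% 3L
  total <- sum(ex_len)
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, stops)
  n_codon <- total %/% 3L
  spliced <- paste0("ATG",
                    paste(sample(codons, n_codon - 2L, replace = TRUE),
                          collapse = ""),
                    sample(stops, 1))
  in_len <- if (n_ex > 1)
    sample(config$intron_length[1]:config$intron_length[2], n_ex - 1L,
           replace = TRUE) else integer(0)
  introns <- vapply(in_len, function(L)
    paste0("GT", random_dna(L - 4L, config$gc_fraction), "AG"), character(1))
  # local (transcript-strand) coordinates of exons
  parts <- character(0)
  exon_local <- matrix(0L, n_ex, 2)
  pos <- 0L
  cum <- cumsum(ex_len)
  for (k in seq_len(n_ex)) {
    s <- if (k == 1) 1L else cum[k - 1] + 1L
    parts <- c(parts, substr(spliced, s, cum[k]))
    exon_local[k, ] <- c(pos, pos + ex_len[k])
    pos <- pos + ex_len[k]
    if (k < n_ex) {
      parts <- c(parts, introns[k])
      pos <- pos + nchar(introns[k])
    }
  }
  list(locus = paste(parts, collapse = ""), exon_local = exon_local,
       spliced = spliced)
}

# Assign planted-event and decoy gene slots to sequences. Each sequence is a
# vector of consecutive gene slots; SmDA/SmAD events occupy three slots
# (donor, spacer, acceptor) so an annotated gene always lies between the
# event genes and the readthrough filter cannot reject them; decoys occupy
# two adjacent same-strand slots.
.sim_plan <- function(config) {
  seq_names <- c(if (config$n_chroms > 0) paste0("chr", seq_len(config$n_chroms)),
                 if (config$n_scaffolds > 0)
                   paste0("scaffold_", seq_len(config$n_scaffolds)))
  capacity <- c(rep(config$genes_per_chrom, config$n_chroms),
                rep(config$genes_per_scaffold, config$n_scaffolds))
  names(capacity) <- seq_names
  used <- stats::setNames(rep(0L, length(capacity)), seq_names)

  take <- function(n_slots, exclude = character(0), prefer = seq_names) {
    for (s in setdiff(c(prefer, seq_names), exclude)) {
      if (capacity[s] - used[s] >= n_slots) {
        idx <- used[s] + seq_len(n_slots)
        used[s] <<- used[s] + n_slots
        return(list(seq = s, slots = idx))
      }
    }
    stop("simulation unrealizable: not enough gene slots for the ",
         "requested events; increase genes_per_chrom/n_chroms")
  }

  plan <- list()  # per planted unit: seq(s), slot indices, strands, roles
  ev <- config$n_trans_events
  for (i in seq_len(ev[["SmDA"]])) {
    st <- sample(c("+", "-"), 1)
    a <- take(3)
    # donor upstream of acceptor along transcription direction
    d_slot <- if (st == "+") a$slots[1] else a$slots[3]
    a_slot <- if (st == "+") a$slots[3] else a$slots[1]
    plan[[length(plan) + 1]] <- list(
      type = "SmDA", decoy = FALSE,
      genes = data.frame(seq = a$seq, slot = a$slots,
                         strand = c(st, sample(c("+", "-"), 1), st)),
      donor_slot = d_slot, acceptor_slot = a_slot, donor_seq = a$seq,
      acceptor_seq = a$seq)
  }
  for (i in seq_len(ev[["SmAD"]])) {
    st <- sample(c("+", "-"), 1)
    a <- take(3)
    d_slot <- if (st == "+") a$slots[3] else a$slots[1]  # acceptor upstream
    a_slot <- if (st == "+") a$slots[1] else a$slots[3]
    plan[[length(plan) + 1]] <- list(
      type = "SmAD", decoy = FALSE,
      genes = data.frame(seq = a$seq, slot = a$slots,
                         strand = c(st, sample(c("+", "-"), 1), st)),
      donor_slot = d_slot, acceptor_slot = a_slot, donor_seq = a$seq,
      acceptor_seq = a$seq)
  }
  for (i in seq_len(ev[["DfStr"]])) {
    st <- sample(c("+", "-"), 1)
    a <- take(2)
    plan[[length(plan) + 1]] <- list(
      type = "DfStr", decoy = FALSE,
      genes = data.frame(seq = a$seq, slot = a$slots,
                         strand = c(st, if (st == "+") "-" else "+")),
      donor_slot = a$slots[1], acceptor_slot = a$slots[2],
      donor_seq = a$seq, acceptor_seq = a$seq)
  }
  for (i in seq_len(ev[["DfChr"]])) {
    if (length(seq_names) < 2)
      stop("simulation unrealizable: DfChr events need at least two ",
           "chromosomes/scaffolds")
    # prefer unplaced scaffolds so the putative-distance rule is exercised
    scafs <- grep("^scaffold", seq_names, value = TRUE)
    a <- take(1, prefer = scafs)
    b <- take(1, exclude = a$seq, prefer = scafs)
    plan[[length(plan) + 1]] <- list(
      type = "DfChr", decoy = FALSE,
      genes = rbind(data.frame(seq = a$seq, slot = a$slots, strand = "+"),
                    data.frame(seq = b$seq, slot = b$slots, strand = "+")),
      donor_slot = a$slots[1], acceptor_slot = b$slots[1],
      donor_seq = a$seq, acceptor_seq = b$seq)
  }
  for (i in seq_len(config$n_readthrough_decoys)) {
    st <- sample(c("+", "-"), 1)
    a <- take(2)
    d_slot <- if (st == "+") a$slots[1] else a$slots[2]
    a_slot <- if (st == "+") a$slots[2] else a$slots[1]
    plan[[length(plan) + 1]] <- list(
      type = "SmDA", decoy = TRUE,
      genes = data.frame(seq = a$seq, slot = a$slots, strand = c(st, st)),
      donor_slot = d_slot, acceptor_slot = a_slot,
      donor_seq = a$seq, acceptor_seq = a$seq)
  }
  list(plan = plan, seq_names = seq_names, capacity = capacity)
}

#' Generate a toy genome, gene models and planted trans-splicing truths
#'
#' Every intron begins GT and ends AG on the transcript strand; every
#' spliced transcript is a complete CDS (ATG .. stop, no internal stop).
#' Planted events are placed so that their configuration realizes the
#' requested type and — for same-chromosome same-strand types — so that an
#' annotated spacer gene lies between donor and acceptor. Readthrough decoys
#' are pairs of adjacent same-strand genes fused with the same junction
#' grammar as real events. Output is deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A list with `genome` (a `genome_assembly`), `genes` (list of
#'   `gene_model`) and `truth` (data frame with columns donor_gene,
#'   donor_exon, acceptor_gene, acceptor_exon, type, is_decoy).
#' @export
generate_genome_and_genes <- function(config) {
  set.seed(config$seed)
  layout <- .sim_plan(config)
  seq_names <- layout$seq_names
  capacity <- layout$capacity

  # strand constraints from the plan; unconstrained slots get random strands
  strands <- lapply(capacity, function(n) rep(NA_character_, n))
  for (p in layout$plan)
    for (r in seq_len(nrow(p$genes)))
      strands[[p$genes$seq[r]]][p$genes$slot[r]] <- p$genes$strand[r]
  for (s in seq_names) {
    miss <- is.na(strands[[s]])
    strands[[s]][miss] <- sample(c("+", "-"), sum(miss), replace = TRUE)
  }

  genes <- list()
  sequences <- character(0)
  gene_counter <- 0L
  slot_gene <- list()  # seq -> slot index -> gene_id
  for (s in seq_names) {
    target_len <- if (grepl("^chr", s)) config$chrom_length else
      config$scaffold_length
    pos <- 0L
    chunks <- character(0)
    slot_gene[[s]] <- character(capacity[[s]])
    for (k in seq_len(capacity[[s]])) {
      gap <- sample(600:1500, 1)
      chunks <- c(chunks, random_dna(gap, config$gc_fraction))
      pos <- pos + gap
      gl <- .sim_gene_local(config)
      L <- nchar(gl$locus)
      gene_counter <- gene_counter + 1L
      gid <- sprintf("g%03d", gene_counter)
      tid <- paste0(gid, ".t1")
      strand <- strands[[s]][k]
      if (strand == "+") {
        ex <- gl$exon_local + pos
        chunks <- c(chunks, gl$locus)
      } else {
        # exon k local [a,b) -> genomic [pos + L - b, pos + L - a),
        # transcription order preserved
        ex <- cbind(pos + L - gl$exon_local[, 2],
                    pos + L - gl$exon_local[, 1])
        chunks <- c(chunks, revcomp(gl$locus))
      }
      pos <- pos + L
      tx <- transcript_model(tid, gid, s, strand, ex, cds = ex)
      genes[[gid]] <- gene_model(gid, list(tx))
      slot_gene[[s]][k] <- gid
      if (pos > target_len - 600L)
        stop("simulation unrealizable: sequence ", s,
             " too short for its genes; increase chrom_length")
    }
    chunks <- c(chunks, random_dna(target_len - pos, config$gc_fraction))
    sequences[[s]] <- paste(chunks, collapse = "")
  }

  truth <- data.frame(donor_gene = character(0), donor_exon = integer(0),
                      acceptor_gene = character(0), acceptor_exon = integer(0),
                      type = character(0), is_decoy = logical(0),
                      stringsAsFactors = FALSE)
  for (p in layout$plan) {
    dg <- slot_gene[[p$donor_seq]][p$donor_slot]
    ag <- slot_gene[[p$acceptor_seq]][p$acceptor_slot]
    dlens <- exon_lengths(representative_tx(genes[[dg]]))
    alens <- exon_lengths(representative_tx(genes[[ag]]))
    nd <- length(dlens)
    na_ <- length(alens)
    # internal boundaries only, with both chimeric segments at least
    # min_segment_length where the exon structure allows it (see
    # simulation_config); otherwise the closest achievable index
    d_ok <- which(cumsum(dlens)[seq_len(nd - 1L)] >= config$min_segment_length)
    if (length(d_ok) == 0) d_ok <- nd - 1L
    suffix <- rev(cumsum(rev(alens)))
    a_ok <- intersect(2:na_, which(suffix >= config$min_segment_length))
    if (length(a_ok) == 0) a_ok <- 2L
    truth <- rbind(truth, data.frame(
      donor_gene = dg,
      donor_exon = d_ok[sample.int(length(d_ok), 1)],
      acceptor_gene = ag,
      acceptor_exon = a_ok[sample.int(length(a_ok), 1)],
      type = p$type, is_decoy = p$decoy, stringsAsFactors = FALSE))
  }
  list(genome = genome_assembly(sequences), genes = unname(genes),
       truth = truth)
}

# Chimeric transcript for a truth row: donor exons 1..i + acceptor exons
# j..end of the representative transcripts.
.truth_chimera <- function(row, genes, genome) {
  dtx <- representative_tx(gene_by_id(genes, row$donor_gene))
  atx <- representative_tx(gene_by_id(genes, row$acceptor_gene))
  assemble_chimeric_transcript(dtx, row$donor_exon, atx, row$acceptor_exon,
                               genome)
}

#' Simulate paired-end reads from cis and planted chimeric transcripts
#'
#' Fragments are drawn from every gene's representative transcript at
#' `coverage_per_transcript` and, for each truth row (decoys included), from
#' the chimeric transcript at `coverage * trans_expression_fraction`.
#' Fragment length is Normal(insert_mean, insert_sd) truncated to
#' [read_length, transcript length]; mates are the forward/reverse ends of
#' the fragment (R1/R2 labels swapped at random). Substitution errors occur
#' at `base_error_rate`; base qualities encode that rate, and 10\% of reads
#' get a 1-5 bp Q2 low-quality tail to exercise trimming. The random stream
#' is seeded from `config$seed + 1000003` so genome generation and read
#' simulation are independently reproducible.
#'
#' @param config a [simulation_config()].
#' @param genome,genes,truth outputs of [generate_genome_and_genes()].
#' @param out_dir optional directory; if given, writes `reads_1.fastq`,
#'   `reads_2.fastq` and `truth.tsv` there.
#' @return A list with `pairs` (data frame, see [load_reads_fastq()]) and
#'   `truth` (truth rows actually expressed; rows whose chimeric transcript
#'   is shorter than the read length are dropped with a warning).
#' @export
simulate_read_pairs <- function(config, genome, genes, truth,
                                out_dir = NULL) {
  set.seed((config$seed + 1000003L) %% 2147483647L)
  rl <- config$read_length

  templates <- list()
  for (g in genes) {
    tx <- representative_tx(g)
    templates[[length(templates) + 1]] <- list(
      seq = spliced_sequence(tx, genome),
      cov = config$coverage_per_transcript,
      origin = tx$transcript_id)
  }
  keep <- rep(TRUE, nrow(truth))
  if (config$trans_expression_fraction > 0 && nrow(truth) > 0) {
    for (r in seq_len(nrow(truth))) {
      ch <- .truth_chimera(truth[r, ], genes, genome)
      if (nchar(ch$sequence) < rl) {
        warning("chimeric transcript for ", truth$donor_gene[r], "::",
                truth$acceptor_gene[r], " shorter than read length; skipped")
        keep[r] <- FALSE
        next
      }
      templates[[length(templates) + 1]] <- list(
        seq = ch$sequence,
        cov = config$coverage_per_transcript *
          config$trans_expression_fraction,
        origin = paste0("chimera_", truth$donor_gene[r], "_",
                        truth$acceptor_gene[r]))
    }
  }

  ids <- seqs1 <- seqs2 <- character(0)
  for (tpl in templates) {
    L <- nchar(tpl$seq)
    if (L < rl) next
    n_frag <- max(0L, round(tpl$cov * L / (2 * rl)))
    if (n_frag == 0) next
    flen <- pmin(pmax(round(rnorm(n_frag, config$insert_mean,
                                  config$insert_sd)), rl), L)
    start <- floor(runif(n_frag, 0, L - flen + 1))
    m1 <- substring(tpl$seq, start + 1, start + rl)
    m2 <- revcomp(substring(tpl$seq, start + flen - rl + 1, start + flen))
    swap <- runif(n_frag) < 0.5
    r1 <- ifelse(swap, m2, m1)
    r2 <- ifelse(swap, m1, m2)
    ids <- c(ids, sprintf("%s_f%05d", tpl$origin, seq_len(n_frag)))
    seqs1 <- c(seqs1, r1)
    seqs2 <- c(seqs2, r2)
  }

  add_errors <- function(seqs) {
    if (config$base_error_rate <= 0) return(seqs)
    n_err <- rbinom(length(seqs), nchar(seqs), config$base_error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(nchar(seqs[i]), n_err[i])
      for (p in pos) {
        cur <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      }
    }
    seqs
  }
  seqs1 <- add_errors(seqs1)
  seqs2 <- add_errors(seqs2)

  # per-base Q reflecting the simulated error rate; 10% of reads get a
  # 1-5 bp Q2 tail (with randomized bases) at the 5' or 3' end
  q_base <- round(-10 * log10(max(config$base_error_rate, 1e-4)))
  q_char <- phred_to_char(q_base)
  add_q2_tails <- function(seqs) {
    quals <- strrep(q_char, nchar(seqs))
    tailed <- which(runif(length(seqs)) < 0.10)
    for (i in tailed) {
      L <- nchar(seqs[i])
      tl <- sample(1:5, 1)
      if (runif(1) < 0.5) {
        substr(quals[i], 1, tl) <- strrep("#", tl)
        substr(seqs[i], 1, tl) <- random_dna(tl, 0.5)
      } else {
        substr(quals[i], L - tl + 1, L) <- strrep("#", tl)
        substr(seqs[i], L - tl + 1, L) <- random_dna(tl, 0.5)
      }
    }
    list(seqs = seqs, quals = quals)
  }
  t1 <- add_q2_tails(seqs1)
  t2 <- add_q2_tails(seqs2)

  pairs <- data.frame(read_id = ids, seq1 = t1$seqs, qual1 = t1$quals,
                      seq2 = t2$seqs, qual2 = t2$quals,
                      stringsAsFactors = FALSE)
  truth_out <- truth[keep, , drop = FALSE]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fastq_pair(pairs, file.path(out_dir, "reads_1.fastq"),
                     file.path(out_dir, "reads_2.fastq"))
    write_truth_tsv(truth_out, file.path(out_dir, "truth.tsv"))
  }
  list(pairs = pairs, truth = truth_out)
}

#' Write / read the planted-truth table
#' @param truth truth data frame.
#' @param path TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
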