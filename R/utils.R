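# Internal helpers shared across modules.

# Reverse complement for plain character vectors.
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Round half away from zero (matches the "77.93 / 67.3 / 1.58"-style report
# rounding rather than base R's round-half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Random DNA of length n with a given GC fraction, as one string.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# Phred+33 conversions.
phred_to_char <- function(q) {
  vapply(q, function(qq) intToUtf8(min(qq, 93) + 33), character(1))
}
char_to_phred <- function(s) {
  if (nchar(s) == 0) return(integer(0))
  utf8ToInt(s) - 33L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Spliced transcript sequence (mature mRNA, 5'->3') for a transcript model.
spliced_sequence <- function(tx, genome) {
  chrom_seq <- genome$sequences[[tx$chrom]]
  parts <- substring(chrom_seq, tx$exons[, 1] + 1L, tx$exons[, 2])
  if (tx$strand == "-") parts <- revcomp(parts)
  paste(parts, collapse = "")
}

exon_lengths <- function(tx) tx$exons[, 2] - tx$exons[, 1]

# Genomic coordinate (0-based) of the splice-donor side of exon `i`
# (position just past the exon's last transcribed base) and of the
# splice-acceptor side of exon `j` (position of its first transcribed base).
donor_site_coord <- function(tx, i) {
  unname(if (tx$strand == "+") tx$exons[i, 2] else tx$exons[i, 1])
}
acceptor_site_coord <- function(tx, j) {
  unname(if (tx$strand == "+") tx$exons[j, 1] else tx$exons[j, 2])
}

gene_by_id <- function(genes, id) {
  for (g in genes) if (g$gene_id == id) return(g)
  stop("unknown gene id: ", id)
}

representative_tx <- function(gene) {
  gene$transcripts[[gene$representative_transcript_id]]
}
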