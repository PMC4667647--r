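# Shared fixtures and independent oracles.

# ---- independent brute-force oracles ------------------------------------

.rc_chars <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
bf_revcomp <- function(x) {
  paste(rev(.rc_chars[strsplit(x, "")[[1]]]), collapse = "")
}

# all end-to-end ungapped placements of `read` (either orientation) on any
# target with <= max_mm mismatches, by full scan
bf_match_hits <- function(read, targets, max_mm) {
  out <- data.frame(target = integer(0), offset = numeric(0),
                    mismatches = integer(0), strand = character(0))
  for (orient in c("+", "-")) {
    r <- if (orient == "+") read else bf_revcomp(read)
    rc <- strsplit(r, "")[[1]]
    L <- length(rc)
    for (t in seq_along(targets)) {
      tc <- strsplit(targets[t], "")[[1]]
      if (length(tc) < L) next
      for (o in 0:(length(tc) - L)) {
        mm <- sum(rc != tc[(o + 1):(o + L)])
        if (mm <= max_mm)
          out <- rbind(out, data.frame(target = t, offset = o,
                                       mismatches = mm, strand = orient))
      }
    }
  }
  out
}

bf_match_any <- function(read, targets, max_mm) {
  nrow(bf_match_hits(read, targets, max_mm)) > 0
}

# exhaustive affine-gap Smith-Waterman (gap of length L costs open + L*ext,
# matching the convention used by the package aligner)
bf_local_align_score <- function(q, s, mat, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc)
  m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (horizontal)
  F_ <- matrix(-Inf, n + 1, m + 1) # gap in subject (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F_[i, j] <- max(H[i - 1, j] - (open + ext), F_[i - 1, j] - ext)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[qc[i - 1], sc[j - 1]],
                     E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- small hand-built annotation ----------------------------------------

# two-chromosome toy genome with two genes used across IO and caller tests
toy_genome_genes <- function() {
  set.seed(99)
  chr1 <- random_dna_str(600)
  chr2 <- random_dna_str(400)
  # force GT..AG introns for geneA (chr1 +, exons [10,110) [200,300))
  substr(chr1, 111, 112) <- "GT"
  substr(chr1, 199, 200) <- "AG"
  # geneB (chr2 -, exons in transcription order [250,350) then [50,150))
  # intron genomic [150,250); on - strand donor GT at genomic end side
  substr(chr2, 249, 250) <- bf_revcomp("GT")  # "AC"
  substr(chr2, 151, 152) <- bf_revcomp("AG")  # "CT"
  genome <- genome_assembly(c(chr1 = chr1, chr2 = chr2))
  txA <- transcript_model("geneA.t1", "geneA", "chr1", "+",
                          rbind(c(10, 110), c(200, 300)),
                          cds = rbind(c(10, 110), c(200, 300)))
  txB <- transcript_model("geneB.t1", "geneB", "chr2", "-",
                          rbind(c(250, 350), c(50, 150)))
  list(genome = genome,
       genes = list(gene_model("geneA", list(txA)),
                    gene_model("geneB", list(txB))))
}

# ---- cached default simulation (shared by several test files) -----------

.sim_cache <- new.env(parent = emptyenv())

default_sim <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    cfg <- simulation_config(seed = seed)
    sim <- generate_genome_and_genes(cfg)
    reads <- simulate_read_pairs(cfg, sim$genome, sim$genes, sim$truth)
    .sim_cache[[key]] <- list(config = cfg, genome = sim$genome,
                              genes = sim$genes, truth = reads$truth,
                              pairs = reads$pairs)
  }
  .sim_cache[[key]]
}

default_called <- function(seed = 1) {
  key <- paste0("c", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- default_sim(seed)
    .sim_cache[[key]] <- call_events(sim$genome, sim$genes, sim$pairs)
  }
  .sim_cache[[key]]
}

default_annotated <- function(seed = 1) {
  key <- paste0("a", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- default_sim(seed)
    .sim_cache[[key]] <- annotate_events(default_called(seed), sim$genes,
                                         sim$genome)
  }
  .sim_cache[[key]]
}

event_key <- function(df) {
  paste(df$donor_gene, df$donor_exon, df$acceptor_gene, df$acceptor_exon)
}
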