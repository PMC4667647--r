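# Small two-gene universe with controlled exon sizes for library arithmetic.
two_gene_world <- function(exon_len = 60, arm_length = 60) {
  set.seed(31)
  e <- exon_len
  mk_locus <- function() {
    ex1 <- random_dna_str(e)
    intron <- paste0("GT", random_dna_str(40), "AG")
    ex2 <- random_dna_str(e)
    paste0(ex1, intron, ex2)
  }
  l1 <- mk_locus()
  l2 <- mk_locus()
  chr1 <- paste0(random_dna_str(50), l1, random_dna_str(80))
  chr2 <- paste0(random_dna_str(50), l2, random_dna_str(80))
  genome <- genome_assembly(c(chr1 = chr1, chr2 = chr2))
  exons <- function(off) rbind(c(off, off + e), c(off + e + 44, off + 2 * e + 44))
  g1 <- gene_model("g1", list(transcript_model("g1.t1", "g1", "chr1", "+",
                                               exons(50))))
  g2 <- gene_model("g2", list(transcript_model("g2.t1", "g2", "chr2", "+",
                                               exons(50))))
  list(genome = genome, genes = list(g1, g2), arm_length = arm_length)
}

test_that("library enumerates ordered gene pairs x donor x acceptor boundaries", {
  w <- two_gene_world()
  lib <- build_fusion_library(w$genes, w$genome, arm_length = 60)
  # 2 ordered gene pairs x 2 donor boundaries x 2 acceptor boundaries
  expect_equal(nrow(lib), 8)
  expect_true(all(lib$donor_gene != lib$acceptor_gene))
  # single-gene annotation: no junction crosses one gene
  expect_equal(nrow(build_fusion_library(w$genes[1], w$genome,
                                         arm_length = 60)), 0)
})

test_that("arms are spliced, clipped at transcript ends, and short arms are dropped", {
  w <- two_gene_world()
  lib <- build_fusion_library(w$genes, w$genome, arm_length = 80)
  S1 <- transchimera:::spliced_sequence(w$genes[[1]]$transcripts[[1]],
                                        w$genome)
  # donor boundary at exon 2 of g1: arm = last 80 nt of the full spliced
  # transcript (crosses the cis junction)
  row <- lib[lib$donor_gene == "g1" & lib$donor_exon == 2 &
               lib$acceptor_gene == "g2" & lib$acceptor_exon == 1, ]
  expect_equal(row$left_arm, substr(S1, nchar(S1) - 79, nchar(S1)))
  # donor boundary at exon 1 (60 bp transcript prefix): clipped to 60
  row1 <- lib[lib$donor_gene == "g1" & lib$donor_exon == 1 &
                lib$acceptor_gene == "g2" & lib$acceptor_exon == 1, ]
  expect_equal(nchar(row1$left_arm), 60)

  # a 12 bp leading exon with no upstream sequence gives an arm under the
  # 20 bp floor: that boundary is dropped
  set.seed(32)
  tiny_chr <- paste0(random_dna_str(10), random_dna_str(12), "GT",
                     random_dna_str(30), "AG", random_dna_str(60),
                     random_dna_str(20))
  g3 <- gene_model("g3", list(transcript_model(
    "g3.t1", "g3", "chr3", "+", rbind(c(10, 22), c(56, 116)))))
  genome3 <- genome_assembly(c(w$genome$sequences, chr3 = tiny_chr))
  lib3 <- build_fusion_library(list(w$genes[[1]], g3), genome3,
                               arm_length = 80)
  expect_false(any(lib3$donor_gene == "g3" & lib3$donor_exon == 1))
  expect_true(any(lib3$donor_gene == "g3" & lib3$donor_exon == 2))
})

test_that("junction hit overlap arithmetic and the ambiguity rule behave", {
  w <- two_gene_world()
  lib <- build_fusion_library(w$genes, w$genome, arm_length = 60)
  row <- lib[lib$donor_gene == "g1" & lib$donor_exon == 1 &
               lib$acceptor_gene == "g2" & lib$acceptor_exon == 1, ]
  fused <- row$fused  # 60 + 60
  th <- evidence_thresholds()
  # offset 35: left 25, right 25 -> kept
  r_mid <- substr(fused, 36, 85)
  hits <- align_reads_to_junctions(r_mid, lib, th)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$left_overlap, 25)
  expect_equal(hits$right_overlap, 25)
  expect_equal(hits$junction_id, row$junction_id)
  # offset 10: left 50, right 0 -> discarded
  r_left <- substr(fused, 11, 60)
  expect_equal(nrow(align_reads_to_junctions(r_left, lib, th)), 0)
  # reverse-complemented spanning read is found on the minus strand
  hits_rc <- align_reads_to_junctions(bf_revcomp(r_mid), lib, th)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$oriented_seq, r_mid)

  # a read matching junctions of two distinct gene pairs with equal
  # mismatches is ambiguous and contributes no evidence
  ex2 <- w$genes[[2]]$transcripts[[1]]$exons
  g3 <- gene_model("g3dup", list(transcript_model("g3dup.t1", "g3dup",
                                                  "chr2dup", "+", ex2)))
  genome_dup <- genome_assembly(c(w$genome$sequences,
                                  chr2dup = w$genome$sequences[["chr2"]]))
  lib_dup <- build_fusion_library(list(w$genes[[1]], w$genes[[2]], g3),
                                  genome_dup, arm_length = 60)
  hits_amb <- align_reads_to_junctions(r_mid, lib_dup, th)
  expect_equal(nrow(hits_amb), 0)
  expect_gte(attr(hits_amb, "n_ambiguous"), 1)
})

test_that("evidence criteria (i)-(iii) gate junction support", {
  w <- two_gene_world()
  lib <- build_fusion_library(w$genes, w$genome, arm_length = 60)
  row <- lib[lib$donor_gene == "g1" & lib$donor_exon == 1 &
               lib$acceptor_gene == "g2" & lib$acceptor_exon == 1, ]
  fused <- row$fused
  th <- evidence_thresholds()
  ch <- assemble_chimeric_transcript(w$genes[[1]]$transcripts[[1]], 1,
                                     w$genes[[2]]$transcripts[[1]], 1,
                                     w$genome)
  # bridge pair: mate1 fully in donor part (fwd), mate2 fully in acceptor
  # part (reverse)
  donor_part <- substr(ch$sequence, 1, ch$junction_offset)
  acceptor_part <- substr(ch$sequence, ch$junction_offset + 1,
                          nchar(ch$sequence))
  bridge <- data.frame(read_id = "b1",
                       seq1 = substr(donor_part, 1, 40),
                       qual1 = strrep("I", 40),
                       seq2 = bf_revcomp(substr(acceptor_part, 21, 60)),
                       qual2 = strrep("I", 40), stringsAsFactors = FALSE)
  span1 <- substr(fused, 36, 85)
  span2 <- substr(fused, 31, 80)
  span2_mm <- span2
  substr(span2_mm, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                      substr(span2_mm, 10, 10))[1]
  span1_mm <- span1
  substr(span1_mm, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                      substr(span1_mm, 40, 40))[1]

  ev_of <- function(span_seqs, pairs) {
    hits <- align_reads_to_junctions(span_seqs, lib, th)
    collect_evidence(hits, pairs, lib, w$genes, w$genome, th)
  }
  no_pairs <- bridge[0, ]

  # 1 spanning read: fails (i)
  ev <- ev_of(span1, bridge)
  expect_false(ev$pass_i[ev$junction_id == row$junction_id])
  # 2 copies of the same sequence: non-redundant count 1, fails (i)
  ev <- ev_of(c(span1, span1), bridge)
  expect_equal(ev$n_nonredundant[ev$junction_id == row$junction_id], 1L)
  expect_false(all(ev$pass_i))
  # 2 distinct reads, both imperfect: fails (i) on the perfect-match rule
  ev <- ev_of(c(span1_mm, span2_mm), bridge)
  expect_false(ev$pass_i[ev$junction_id == row$junction_id])
  # 2 distinct reads, one perfect, with a bridging pair: passes (i)-(iii)
  ev <- ev_of(c(span1, span2_mm), bridge)
  idx <- ev$junction_id == row$junction_id
  expect_true(ev$pass_i[idx] && ev$pass_iii[idx])
  expect_gte(ev$bridge_pairs[idx], 1)
  # same without any bridging pair: fails (iii)
  ev <- ev_of(c(span1, span2_mm), no_pairs)
  expect_false(ev$pass_iii[ev$junction_id == row$junction_id])
})

test_that("readthrough filter removes same-strand neighbours but spares spaced and opposite-strand pairs", {
  mk_gene <- function(id, chrom, strand, start, end) {
    gene_model(id, list(transcript_model(paste0(id, ".t1"), id, chrom,
                                         strand, rbind(c(start, end)))))
  }
  genes <- list(
    mk_gene("a", "chr1", "+", 100, 200),
    mk_gene("b", "chr1", "+", 500, 700),       # adjacent to a, same strand
    mk_gene("c", "chr1", "+", 1000, 1200),     # third gene between a and d
    mk_gene("d", "chr1", "+", 1500, 1700),
    mk_gene("e", "chr1", "-", 550, 800),       # overlaps b, opposite strand
    mk_gene("f", "chr2", "+", 100, 200))
  cands <- data.frame(
    donor_gene = c("a", "a", "b", "a"),
    acceptor_gene = c("b", "d", "e", "f"),
    stringsAsFactors = FALSE)
  out <- readthrough_filter(cands, genes)
  kept <- paste(out$donor_gene, out$acceptor_gene)
  expect_false("a b" %in% kept)        # same-strand neighbours: removed
  expect_true("a d" %in% kept)         # intervening gene: retained
  expect_true("b e" %in% kept)         # opposite strand overlap: retained
  expect_true("a f" %in% kept)         # different chromosome: retained
  removed <- attr(out, "removed")
  expect_equal(removed$removal_reason, "same_strand_neighbouring")

  # same-strand overlapping genes are removed too
  genes2 <- list(mk_gene("x", "chr1", "+", 100, 400),
                 mk_gene("y", "chr1", "+", 300, 600))
  out2 <- readthrough_filter(data.frame(donor_gene = "x",
                                        acceptor_gene = "y",
                                        stringsAsFactors = FALSE), genes2)
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "removed")$removal_reason,
               "same_strand_overlapping")
})

test_that("called junction sequences are absent from every cis sequence", {
  sim <- default_sim()
  res <- default_called()
  lib_rows <- merge(res$events["junction_id"],
                    as.data.frame(build_fusion_library(
                      sim$genes, sim$genome, arm_length = 80)),
                    by = "junction_id")
  idx <- build_cis_index(sim$genome, sim$genes)
  for (r in seq_len(nrow(lib_rows))) {
    core <- substr(lib_rows$fused[r], nchar(lib_rows$left_arm[r]) - 19,
                   nchar(lib_rows$left_arm[r]) + 20)
    hitf <- vapply(idx$seqs, function(s) grepl(core, s, fixed = TRUE),
                   logical(1))
    hitr <- vapply(idx$seqs, function(s)
      grepl(bf_revcomp(core), s, fixed = TRUE), logical(1))
    expect_false(any(hitf | hitr))
  }
})
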