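mk_span_gene <- function(id, chrom, strand, start, end) {
  gene_model(id, list(transcript_model(paste0(id, ".t1"), id, chrom, strand,
                                       rbind(c(start, end)))))
}

test_that("event types follow chromosome, strand and transcription-direction order", {
  d <- mk_span_gene("d", "chr1", "+", 100, 200)
  a <- mk_span_gene("a", "chr1", "+", 5000, 6000)
  expect_equal(classify_event(d, a), "SmDA")
  expect_equal(classify_event(a, d), "SmAD")
  # on the minus strand the genomically rightmost gene is upstream
  dm <- mk_span_gene("dm", "chr1", "-", 5000, 6000)
  am <- mk_span_gene("am", "chr1", "-", 100, 200)
  expect_equal(classify_event(dm, am), "SmDA")
  expect_equal(classify_event(am, dm), "SmAD")
  expect_equal(classify_event(d, mk_span_gene("s", "chr1", "-", 5000, 6000)),
               "DfStr")
  expect_equal(classify_event(d, mk_span_gene("x", "scaf9", "+", 0, 100)),
               "DfChr")
})

test_that("distances: span gap, overlap zero, scaffold putative rule, placed-chrom NA", {
  genome <- genome_assembly(c(
    chr1 = strrep("A", 10000),
    scaffold_1 = strrep("A", 1000), scaffold_2 = strrep("A", 1000)))
  d <- mk_span_gene("d", "chr1", "+", 100, 200)
  a <- mk_span_gene("a", "chr1", "+", 5000, 6000)
  expect_equal(donor_acceptor_distance(d, a, genome), 4800)
  ov <- mk_span_gene("o", "chr1", "+", 150, 400)
  expect_equal(donor_acceptor_distance(d, ov, genome), 0)
  # putative DfChr distance: donor [900,950) on a 1000 bp scaffold (+),
  # acceptor [300,400) on its own scaffold (+): (1000-950) + 300 = 350
  ds <- mk_span_gene("ds", "scaffold_1", "+", 900, 950)
  as_ <- mk_span_gene("as", "scaffold_2", "+", 300, 400)
  expect_equal(donor_acceptor_distance(ds, as_, genome), 350)
  # minus-strand genes count distance to the edge they transcribe toward
  dsm <- mk_span_gene("dsm", "scaffold_1", "-", 900, 950)
  expect_equal(donor_acceptor_distance(dsm, as_, genome), 900 + 300)
  # a placed chromosome on either side leaves the distance undefined
  expect_true(is.na(donor_acceptor_distance(d, as_, genome)))
})

test_that("chimeric transcript assembly concatenates the right spliced pieces", {
  sim <- default_sim()
  ids <- vapply(sim$genes, function(g) g$gene_id, character(1))
  tr <- sim$truth[!sim$truth$is_decoy, ]
  for (r in seq_len(nrow(tr))) {
    dtx <- sim$genes[[which(ids == tr$donor_gene[r])]]$transcripts[[1]]
    atx <- sim$genes[[which(ids == tr$acceptor_gene[r])]]$transcripts[[1]]
    ch <- assemble_chimeric_transcript(dtx, tr$donor_exon[r], atx,
                                       tr$acceptor_exon[r], sim$genome)
    dl <- transchimera:::exon_lengths(dtx)
    al <- transchimera:::exon_lengths(atx)
    expect_equal(ch$junction_offset, sum(dl[seq_len(tr$donor_exon[r])]))
    expect_equal(nchar(ch$sequence),
                 sum(dl[seq_len(tr$donor_exon[r])]) +
                   sum(al[tr$acceptor_exon[r]:length(al)]))
    # prefix and suffix equal the spliced transcript pieces byte-for-byte
    dS <- transchimera:::spliced_sequence(dtx, sim$genome)
    expect_equal(substr(ch$sequence, 1, ch$junction_offset),
                 substr(dS, 1, ch$junction_offset))
  }
  # degenerate indices: full donor + full acceptor, out of range errors
  dtx <- sim$genes[[1]]$transcripts[[1]]
  atx <- sim$genes[[5]]$transcripts[[1]]
  full <- assemble_chimeric_transcript(dtx, nrow(dtx$exons), atx, 1,
                                       sim$genome)
  expect_equal(nchar(full$sequence),
               sum(transchimera:::exon_lengths(dtx)) +
                 sum(transchimera:::exon_lengths(atx)))
  expect_error(assemble_chimeric_transcript(dtx, nrow(dtx$exons) + 1, atx, 1,
                                            sim$genome), "out of range")
})

test_that("ORF scanning honours the ten-aa two-side rule and junction-straddling codons", {
  # transcript: ATG at 0, junction at 66, stop at codon 45 -> donor 22 full
  # codons, acceptor 22 (codon 23 straddles the junction at 66)
  set.seed(41)
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  body <- paste(sample(codons, 44, replace = TRUE), collapse = "")
  tx <- paste0("ATG", body, "TAA")   # 45 peptide codons, then the stop
  # junction on a codon boundary: codons 1..22 donor, 23..45 acceptor
  p <- predict_chimeric_protein(tx, junction_offset = 66)
  expect_equal(p$start, 0)
  expect_equal(p$donor_aa, 22)
  expect_equal(p$acceptor_aa, 23)
  expect_equal(nchar(p$peptide), 45)

  # junction inside codon 23: the straddling codon counts to neither side
  p2 <- predict_chimeric_protein(tx, junction_offset = 67)
  expect_equal(p2$donor_aa, 22)
  expect_equal(p2$acceptor_aa, 22)
  p3 <- predict_chimeric_protein(tx, junction_offset = 69)
  expect_equal(p3$donor_aa, 23)
  expect_equal(p3$acceptor_aa, 22)

  # ORF ending before the junction gives no protein ("CGT" repeats carry
  # neither an ATG nor a stop, so no competing ORF appears downstream)
  early_stop <- paste0("ATG", strrep("CGT", 15), "TAA", strrep("CGT", 40))
  expect_null(predict_chimeric_protein(early_stop, junction_offset = 100))

  # ATG only downstream of the junction: translation must start in the donor
  with_atg_late <- paste0(strrep("CGT", 40), "ATG",
                          paste(sample(codons, 30, replace = TRUE),
                                collapse = ""), "TAA")
  expect_null(predict_chimeric_protein(with_atg_late, junction_offset = 60))
})

test_that("frame flags equal engineered truth over all 12 CDS-phase combinations", {
  set.seed(43)
  # one exon per transcript keeps spliced coordinates equal to genomic
  # offsets; CDS start shifts of 0/1/2 encode the phases directly
  L <- 300
  seqs <- c(chrD = random_dna_str(L + 20), chrA = random_dna_str(L + 20))
  genome <- genome_assembly(seqs)
  jo <- 120L                       # junction offset in the chimeric product
  a_start <- 12L                   # ORF start inside the donor segment
  for (d_shift in 0:2) for (a_shift in 0:2) {
    dtx <- transcript_model("d.t1", "d", "chrD", "+", rbind(c(0, L)),
                            cds = rbind(c(a_start + d_shift, a_start +
                                            d_shift + 99)))
    atx <- transcript_model("a.t1", "a", "chrA", "+", rbind(c(0, L)),
                            cds = rbind(c(a_shift, a_shift + 99)))
    # acceptor segment starts at its exon 1, so the junction maps to
    # acceptor spliced coordinate 0; the chimeric ORF phase there is
    # (a_start - jo) mod 3
    fs <- frame_status(list(start = a_start), dtx, atx, donor_exon = 1,
                       acceptor_exon = 1, junction_offset = jo)
    expect_equal(fs$in_frame_with_donor, d_shift %% 3 == 0,
                 info = paste(d_shift, a_shift))
    expect_equal(fs$in_frame_with_acceptor,
                 (a_start - jo - a_shift) %% 3 == 0,
                 info = paste(d_shift, a_shift))
  }
  # CDS-less genes yield NA flags (three combinations)
  no_cds <- transcript_model("n.t1", "n", "chrD", "+", rbind(c(0, L)))
  with_cds <- transcript_model("w.t1", "w", "chrA", "+", rbind(c(0, L)),
                               cds = rbind(c(0, 99)))
  fs <- frame_status(list(start = 0), no_cds, with_cds, 1, 1, jo)
  expect_true(is.na(fs$in_frame_with_donor))
  expect_false(is.na(fs$in_frame_with_acceptor))
  fs <- frame_status(list(start = 0), with_cds, no_cds, 1, 1, jo)
  expect_false(is.na(fs$in_frame_with_donor))
  expect_true(is.na(fs$in_frame_with_acceptor))
  fs <- frame_status(list(start = 0), no_cds, no_cds, 1, 1, jo)
  expect_true(is.na(fs$in_frame_with_donor) &&
                is.na(fs$in_frame_with_acceptor))
})

test_that("compatible engineered phases reproduce the donor/acceptor peptide concatenation", {
  sim <- default_sim()
  ann <- default_annotated()
  ids <- vapply(sim$genes, function(g) g$gene_id, character(1))
  compatible <- which(ann$coding & ann$in_frame_with_donor &
                        ann$in_frame_with_acceptor)
  expect_gte(length(compatible), 1)
  for (r in compatible) {
    dtx <- sim$genes[[which(ids == ann$donor_gene[r])]]$transcripts[[1]]
    atx <- sim$genes[[which(ids == ann$acceptor_gene[r])]]$transcripts[[1]]
    dS <- transchimera:::spliced_sequence(dtx, sim$genome)
    aS <- transchimera:::spliced_sequence(atx, sim$genome)
    # donor CDS prefix peptide, cut at the junction
    seg <- event_peptide_segments(ann[r, ])
    donor_pep <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(dS, ann$orf_start[r] + 1,
             ann$orf_start[r] + 3 * ann$donor_aa[r]))))
    expect_equal(seg$donor_peptide, donor_pep)
    # acceptor segment peptide comes from the acceptor suffix in its own
    # CDS frame
    al <- transchimera:::exon_lengths(atx)
    askip <- if (ann$acceptor_exon[r] > 1)
      sum(al[seq_len(ann$acceptor_exon[r] - 1)]) else 0L
    straddle <- (ann$junction_offset[r] - ann$orf_start[r]) %% 3
    off <- askip + (3 - straddle) %% 3
    acc_pep <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(aS, off + 1, off + 3 * ann$acceptor_aa[r]))))
    expect_equal(seg$acceptor_peptide, acc_pep)
  }
})

test_that("cis-sharing classes follow the gene exon structures", {
  sim <- default_sim()
  ann <- default_annotated()
  # simulated junctions sit at internal boundaries of multi-exon genes
  expect_true(all(ann$cis_sharing == "both_arms"))
  # two single-exon genes share nothing
  g1 <- mk_span_gene("s1", "chr1", "+", 100, 400)
  g2 <- mk_span_gene("s2", "chr2", "+", 100, 400)
  expect_equal(cis_sharing_status(g1, g2, 400, 100), "neither")
  # donor boundary at the donor's last exon end is not a cis donor site
  toy <- toy_genome_genes()
  gA <- toy$genes[[1]]  # exons [10,110) [200,300) on +
  expect_equal(cis_sharing_status(gA, gA, 300, 200), "one_arm")
  expect_equal(cis_sharing_status(gA, gA, 110, 200), "both_arms")
})
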