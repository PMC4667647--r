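test_that("self-alignment gives full identity and coverage; bad input errors", {
  p <- strrep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", 4)
  a <- local_align_protein(p, p)
  expect_equal(a$identity_pct, 100)
  expect_equal(a$coverage_pct, 100)
  expect_lt(a$evalue, 1e-20)
  expect_error(local_align_protein("", p), "empty")
  expect_error(local_align_protein("MK7L", p), "non-amino-acid")
  expect_error(local_align_protein(p, p, search_space = 0), "positive")
})

test_that("aligner scores equal an exhaustive affine-gap DP oracle on short pairs", {
  mat <- transchimera:::get_blosum62()
  set.seed(55)
  for (trial in 1:20) {
    q <- random_aa(sample(8:30, 1))
    s <- if (trial %% 3 == 0) {
      # related pair: mutate/delete a few residues of q
      x <- strsplit(q, "")[[1]]
      drop <- sample(length(x), sample(0:2, 1))
      if (length(drop)) x <- x[-drop]
      paste(x, collapse = "")
    } else random_aa(sample(8:30, 1))
    if (nchar(s) < 1) s <- "A"
    got <- local_align_protein(q, s)$score
    want <- bf_local_align_score(q, s, mat)
    expect_equal(got, want, info = paste("trial", trial, q, s))
  }
})

test_that("aligner score is symmetric and ungapped scores sum substitution entries", {
  set.seed(56)
  mat <- transchimera:::get_blosum62()
  a <- random_aa(25)
  b <- random_aa(25)
  expect_equal(local_align_protein(a, b)$score,
               local_align_protein(b, a)$score)
  # identical sequences: raw score = sum of diagonal substitution scores
  expect_equal(local_align_protein(a, a)$score,
               sum(mat[cbind(strsplit(a, "")[[1]], strsplit(a, "")[[1]])]))
})

test_that("conserved-event screen demands both segments and distinct species", {
  set.seed(57)
  donor <- random_aa(120)
  acceptor <- random_aa(130)
  ev <- function(id, d, a) data.frame(event_id = id, donor_peptide = d,
                                      acceptor_peptide = a,
                                      stringsAsFactors = FALSE)
  shuffled <- paste(sample(strsplit(acceptor, "")[[1]]), collapse = "")
  both <- list(spA = ev("x", donor, acceptor), spB = ev("y", donor, acceptor))
  res <- conserved_event_screen(both)
  expect_equal(nrow(res), 2)   # found in both query directions
  partial <- list(spA = ev("x", donor, acceptor),
                  spB = ev("y", donor, shuffled))
  expect_equal(nrow(conserved_event_screen(partial)), 0)
  expect_equal(nrow(conserved_event_screen(both["spA"])), 0)
  # self-conservation control: the same species set under two labels
  dup <- list(s1 = ev("x", donor, acceptor), s2 = ev("x", donor, acceptor))
  expect_equal(nrow(conserved_event_screen(dup)), 2)
})

test_that("canonical-resemblance screen finds an intact breakup-gene copy at 90/50", {
  set.seed(58)
  canonical <- random_aa(200)
  # a chimera assembled from a two-part split of the canonical gene
  chimera <- paste0(substr(canonical, 1, 100), substr(canonical, 101, 200))
  other <- random_aa(180)
  trans_proteins <- data.frame(species = "spA", id = "ev1",
                               peptide = chimera, stringsAsFactors = FALSE)
  proteomes <- list(spB = c(broken_src = canonical, unrelated = other),
                    spA = c(self_copy = canonical))
  res <- canonical_resemblance_screen(trans_proteins, proteomes)
  expect_equal(res$matches$canonical_id, "broken_src")  # same species excluded
  expect_equal(res$count_matrix["spA", "spB"], 1L)

  # only half the trans protein matches (at 100% identity): the 90%
  # query-coverage rule rejects it
  res_half <- canonical_resemblance_screen(
    trans_proteins,
    list(spB = c(half_src = substr(canonical, 1, 100))))
  expect_equal(nrow(res_half$matches), 0)

  # identity degraded below 50% breaks the match
  degraded <- strsplit(chimera, "")[[1]]
  idx <- sample(length(degraded), round(0.55 * length(degraded)))
  degraded[idx] <- vapply(degraded[idx], function(ch)
    sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ch), 1),
    character(1))
  res_deg <- canonical_resemblance_screen(
    data.frame(species = "spA", id = "d", peptide = paste(degraded,
                                                          collapse = ""),
               stringsAsFactors = FALSE),
    list(spB = c(broken_src = canonical)))
  expect_equal(nrow(res_deg$matches), 0)
})

test_that("paralog screen flags duplicated segments and spares random ones", {
  set.seed(59)
  seg <- random_aa(120)
  ev <- data.frame(coding = TRUE, peptide = paste0(seg, seg),
                   donor_aa = 120L, acceptor_aa = 120L,
                   stringsAsFactors = FALSE)
  res <- paralog_screen(ev)
  expect_true(res$flags[1])
  # random unrelated segments of >= 100 aa essentially never pass 1e-5
  n_rand <- 100
  evr <- data.frame(coding = TRUE,
                    peptide = vapply(seq_len(n_rand), function(i)
                      paste0(random_aa(110), random_aa(110)), character(1)),
                    donor_aa = 110L, acceptor_aa = 110L,
                    stringsAsFactors = FALSE)
  resr <- paralog_screen(evr)
  expect_equal(sum(resr$flags), 0)
  # non-coding events are skipped
  evn <- data.frame(coding = FALSE, peptide = NA_character_,
                    donor_aa = NA_integer_, acceptor_aa = NA_integer_,
                    stringsAsFactors = FALSE)
  expect_true(is.na(paralog_screen(evn)$flags[1]))
})

test_that("screens are threshold-monotone", {
  set.seed(60)
  base <- random_aa(150)
  noisy <- strsplit(base, "")[[1]]
  idx <- sample(150, 60)
  noisy[idx] <- vapply(noisy[idx], function(ch)
    sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ch), 1),
    character(1))
  noisy <- paste(noisy, collapse = "")
  ev <- function(id, d, a) data.frame(event_id = id, donor_peptide = d,
                                      acceptor_peptide = a,
                                      stringsAsFactors = FALSE)
  sets <- list(spA = ev("x", base, base), spB = ev("y", noisy, noisy))
  strict <- homology_thresholds("conserved_event")
  relaxed <- homology_thresholds("conserved_event", evalue_max = 1e-2,
                                 coverage_min_pct = 30,
                                 identity_min_pct = 20)
  n_strict <- nrow(conserved_event_screen(sets, strict))
  n_relaxed <- nrow(conserved_event_screen(sets, relaxed))
  expect_gte(n_relaxed, n_strict)
})

test_that("BLAST tabular reader validates shape and recomputes coverage", {
  path <- tempfile()
  writeLines("q1\ts1\t100.0\t50\t0\t0\t1\t50\t1\t50\t1e-30\t100", path)
  tab <- read_blast_tab(path, query_lengths = c(q1 = 50))
  expect_equal(tab$query_coverage_pct, 100)
  expect_equal(tab$evalue, 1e-30)

  writeLines("q1\ts1\t100.0\t50\t0\t0\t50\t1\t1\t50\t1e-30\t100", path)
  expect_error(read_blast_tab(path), "ascend")
  writeLines("q1\ts1\t100.0", path)
  expect_error(read_blast_tab(path), "12 columns")
  writeLines(character(0), path)
  expect_equal(nrow(read_blast_tab(path)), 0)
})

test_that("domtblout reader and the BTB-upstream-of-FLYWCH rule", {
  path <- tempfile()
  row <- function(gene, domain, fullE, domE, envs, enve) paste(
    gene, "-", 500, domain, "-", 110, fullE, 200.1, 0.1, 1, 1,
    "1e-9", domE, 190.0, 0.1, 5, 100, 8, 105, envs, enve, 0.98,
    "description here", sep = " ")
  writeLines(c("# comment line",
               row("modA", "BTB", "1e-8", "1e-7", 10, 120),
               row("modA", "FLYWCH", "1e-9", "1e-8", 300, 360),
               row("revB", "FLYWCH", "1e-9", "1e-8", 10, 70),
               row("revB", "BTB", "1e-9", "1e-8", 200, 310),
               row("btbOnly", "BTB", "1e-9", "1e-8", 10, 120),
               row("weakC", "BTB", "1e-3", "1e-8", 10, 120),
               row("weakC", "FLYWCH", "1e-9", "1e-8", 300, 360)), path)
  hits <- read_domtblout(path)
  expect_equal(nrow(hits), 7)
  expect_equal(hits$env_start[1], 10L)
  expect_equal(hits$full_evalue[1], 1e-8)
  expect_equal(hits$dom_evalue[1], 1e-7)

  mod <- identify_modlike_genes(hits)
  expect_equal(mod, "modA")   # revB has FLYWCH first; weakC fails full E

  writeLines("# only comments", path)
  expect_equal(nrow(read_domtblout(path)), 0)
  writeLines(row("x", "BTB", "1e-8", "1e-7", 250, 120), path)
  expect_error(read_domtblout(path), "envelope")
})
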