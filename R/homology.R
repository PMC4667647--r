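# Protein homology screens: a local aligner with BLAST-like statistics, the
# three screens (conserved events across species, resemblance to canonical
# proteins, donor-acceptor paralogy), and readers for external BLAST
# tabular / HMMER domtblout results plus the BTB-upstream-of-FLYWCH rule.

#' Homology screen thresholds
#'
#' Modes: `conserved_event` and `paralog` use E <= 1e-5, coverage >= 60%,
#' identity >= 30%; `canonical_resemblance` uses E <= 1e-5, coverage >= 90%,
#' identity >= 50%.
#'
#' @param mode screen mode.
#' @param evalue_max,coverage_min_pct,identity_min_pct override defaults.
#' @return A list of class `homology_thresholds`.
#' @export
homology_thresholds <- function(mode = c("conserved_event",
                                         "canonical_resemblance", "paralog"),
                                evalue_max = 1e-5,
                                coverage_min_pct = NULL,
                                identity_min_pct = NULL) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
                     conserved_event = c(60, 30),
                     canonical_resemblance = c(90, 50),
                     paralog = c(60, 30))
  structure(list(mode = mode, evalue_max = evalue_max,
                 coverage_min_pct = coverage_min_pct %||% defaults[1],
                 identity_min_pct = identity_min_pct %||% defaults[2]),
            class = "homology_thresholds")
}

#' Optimal local protein alignment with BLAST-like statistics
#'
#' Smith-Waterman under BLOSUM62 with affine gaps (open 11, extend 1, the
#' BLASTP defaults). The bit score is S' = (lambda * S - ln K) / ln 2 with
#' gapped Karlin-Altschul constants lambda = 0.267, K = 0.041, and
#' E = m * n * 2^-S' with m the query length and n the subject (or supplied
#' search-space) length; parity with BLASTP is therefore approximate.
#' Identity uses alignment columns including gaps as denominator (BLAST
#' pident convention); coverage is query-side.
#'
#' @param query_aa,subject_aa amino-acid strings.
#' @param gap_open,gap_extend affine gap penalties.
#' @param search_space total subject length n for the E-value (defaults to
#'   `nchar(subject_aa)`).
#' @param lambda,K Karlin-Altschul constants.
#' @return A list of class `protein_alignment`: score, bits, evalue,
#'   identity_pct, coverage_pct, alignment_length, n_match, query/subject
#'   aligned spans.
#' @export
local_align_protein <- function(query_aa, subject_aa, gap_open = 11,
                                gap_extend = 1, search_space = NULL,
                                lambda = 0.267, K = 0.041) {
  if (nchar(query_aa) == 0 || nchar(subject_aa) == 0)
    stop("empty amino-acid sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYBZX*]", toupper(query_aa)) ||
      grepl("[^ACDEFGHIKLMNPQRSTVWYBZX*]", toupper(subject_aa)))
    stop("non-amino-acid character in input")
  mat <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(query_aa)),
    Biostrings::AAString(toupper(subject_aa)),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  S <- Biostrings::score(pa)
  qp <- Biostrings::pattern(pa)
  sp <- Biostrings::subject(pa)
  aln_len <- nchar(as.character(qp))   # alignment columns including gaps
  n_match <- Biostrings::nmatch(pa)
  m <- nchar(query_aa)
  n <- search_space %||% nchar(subject_aa)
  if (n <= 0) stop("search space must be positive")
  bits <- (lambda * S - log(K)) / log(2)
  q_range <- c(S4Vectors::start(qp), S4Vectors::end(qp))
  s_range <- c(S4Vectors::start(sp), S4Vectors::end(sp))
  structure(list(
    score = S, bits = bits,
    evalue = m * n * 2^(-bits),
    identity_pct = 100 * n_match / aln_len,
    coverage_pct = 100 * (q_range[2] - q_range[1] + 1) / m,
    alignment_length = aln_len, n_match = n_match,
    query_start = q_range[1], query_end = q_range[2],
    subject_start = s_range[1], subject_end = s_range[2]
  ), class = "protein_alignment")
}

# cached BLOSUM62 lookup
get_blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf(
    "protein_alignment: score %.0f (%.1f bits), E=%.3g, identity %.1f%%, query coverage %.1f%%\n",
    x$score, x$bits, x$evalue, x$identity_pct, x$coverage_pct))
  invisible(x)
}

.alignment_passes <- function(aln, thresholds) {
  aln$evalue <= thresholds$evalue_max &&
    aln$coverage_pct >= thresholds$coverage_min_pct &&
    aln$identity_pct >= thresholds$identity_min_pct
}

#' Conserved-event screen across species
#'
#' Event X of species A matches event Y of species B != A iff the donor
#' segments align AND the acceptor segments align, each at the
#' conserved-event thresholds (queries are X's segments); partial matching
#' by either segment alone is excluded.
#'
#' @param events_by_species named list (species -> data frame with columns
#'   `event_id`, `donor_peptide`, `acceptor_peptide`).
#' @param thresholds a [homology_thresholds()] (`conserved_event` mode).
#' @return Data frame of ordered matches: species_a, event_a, species_b,
#'   event_b.
#' @export
conserved_event_screen <- function(events_by_species,
                                   thresholds =
                                     homology_thresholds("conserved_event")) {
  out <- list()
  sp <- names(events_by_species)
  for (a in sp) for (b in setdiff(sp, a)) {
    ea <- events_by_species[[a]]
    eb <- events_by_species[[b]]
    for (i in seq_len(nrow(ea))) for (j in seq_len(nrow(eb))) {
      d <- local_align_protein(ea$donor_peptide[i], eb$donor_peptide[j])
      if (!.alignment_passes(d, thresholds)) next
      ac <- local_align_protein(ea$acceptor_peptide[i],
                                eb$acceptor_peptide[j])
      if (!.alignment_passes(ac, thresholds)) next
      out[[length(out) + 1]] <- data.frame(
        species_a = a, event_a = ea$event_id[i],
        species_b = b, event_b = eb$event_id[j], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(species_a = character(0), event_a = character(0),
                      species_b = character(0), event_b = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Screen trans-spliced proteins for resemblance to canonical proteins
#'
#' For each trans-spliced protein, lists canonical proteins from other
#' species whose alignment passes the canonical-resemblance thresholds
#' (E <= 1e-5, coverage >= 90%, identity >= 50%); also returns the
#' species-by-species count matrix (number of trans proteins with at least
#' one match per canonical species).
#'
#' @param trans_proteins data frame with columns `species`, `id`, `peptide`.
#' @param canonical_proteomes_by_species named list (species -> named
#'   character vector of canonical protein sequences).
#' @param thresholds a [homology_thresholds()] (`canonical_resemblance`).
#' @return List with `matches` (data frame) and `count_matrix` (trans
#'   species x canonical species).
#' @export
canonical_resemblance_screen <- function(trans_proteins,
                                         canonical_proteomes_by_species,
                                         thresholds =
                                           homology_thresholds("canonical_resemblance")) {
  canon_sp <- names(canonical_proteomes_by_species)
  trans_sp <- unique(trans_proteins$species)
  matches <- list()
  for (i in seq_len(nrow(trans_proteins))) {
    for (s in setdiff(canon_sp, trans_proteins$species[i])) {
      prots <- canonical_proteomes_by_species[[s]]
      for (pid in names(prots)) {
        aln <- local_align_protein(trans_proteins$peptide[i], prots[[pid]])
        if (.alignment_passes(aln, thresholds))
          matches[[length(matches) + 1]] <- data.frame(
            trans_species = trans_proteins$species[i],
            trans_id = trans_proteins$id[i],
            canonical_species = s, canonical_id = pid,
            identity_pct = aln$identity_pct,
            coverage_pct = aln$coverage_pct, evalue = aln$evalue,
            stringsAsFactors = FALSE)
      }
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(trans_species = character(0), trans_id = character(0),
               canonical_species = character(0), canonical_id = character(0),
               identity_pct = numeric(0), coverage_pct = numeric(0),
               evalue = numeric(0), stringsAsFactors = FALSE)
  cm <- matrix(0L, length(trans_sp), length(canon_sp),
               dimnames = list(trans_sp, canon_sp))
  if (nrow(matches) > 0) {
    agg <- unique(matches[, c("trans_species", "trans_id",
                              "canonical_species")])
    tab <- table(agg$trans_species, agg$canonical_species)
    cm[rownames(tab), colnames(tab)] <- tab
  }
  list(matches = matches, count_matrix = cm)
}

#' Flag events whose donor and acceptor segments are homologous (paralogy)
#'
#' An event is flagged when its donor peptide segment aligns to its acceptor
#' peptide segment at the paralog thresholds; non-coding events are skipped.
#'
#' @param events `annotated_events` data frame (or any frame with `coding`,
#'   `peptide`, `donor_aa`, `acceptor_aa`).
#' @param thresholds a [homology_thresholds()] (`paralog` mode).
#' @return List with `flags` (logical, NA for skipped events) and
#'   `fraction_flagged` among coding events.
#' @export
paralog_screen <- function(events,
                           thresholds = homology_thresholds("paralog")) {
  flags <- rep(NA, nrow(events))
  for (r in seq_len(nrow(events))) {
    seg <- event_peptide_segments(events[r, ])
    if (is.null(seg) || nchar(seg$donor_peptide) == 0 ||
        nchar(seg$acceptor_peptide) == 0) next
    aln <- local_align_protein(seg$donor_peptide, seg$acceptor_peptide)
    flags[r] <- .alignment_passes(aln, thresholds)
  }
  n_coding <- sum(!is.na(flags))
  list(flags = flags,
       fraction_flagged = if (n_coding > 0) sum(flags, na.rm = TRUE) /
         n_coding else NA_real_)
}

#' Read BLAST tabular (outfmt 6) protein alignments
#'
#' Standard 12 columns (qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore). Query coverage is recomputed from the
#' aligned query span when query lengths are supplied.
#'
#' @param path tabular file.
#' @param query_lengths optional named vector of query lengths.
#' @return Data frame of alignments, with `query_coverage_pct` where
#'   computable.
#' @export
read_blast_tab <- function(path, query_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(lines) == 0) {
    out <- as.data.frame(stats::setNames(
      replicate(12, character(0), simplify = FALSE), cols),
      stringsAsFactors = FALSE)
    out$query_coverage_pct <- numeric(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12))
    stop("BLAST tabular line ", which(nc != 12)[1], ": expected 12 columns, got ",
         nc[nc != 12][1])
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- cols
  for (numcol in c("pident", "length", "mismatch", "gapopen", "qstart",
                   "qend", "sstart", "send", "evalue", "bitscore"))
    out[[numcol]] <- as.numeric(out[[numcol]])
  bad <- which(out$qstart > out$qend)
  if (length(bad) > 0)
    stop("BLAST tabular line ", bad[1],
         ": qstart > qend (protein query coordinates must ascend)")
  out$query_coverage_pct <- NA_real_
  if (!is.null(query_lengths)) {
    ql <- query_lengths[out$qseqid]
    out$query_coverage_pct <- 100 * (out$qend - out$qstart + 1) / ql
  }
  out
}

#' Read HMMER3 domtblout domain hits
#'
#' One hit per domain row; comment lines are skipped. Keeps the target
#' (gene/protein) id, query (domain model) name, envelope coordinates and
#' the full-sequence and per-domain (independent) E-values.
#'
#' @param path domtblout file.
#' @return Data frame with columns gene_id, domain, env_start, env_end,
#'   full_evalue, dom_evalue.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  out <- data.frame(gene_id = character(0), domain = character(0),
                    env_start = integer(0), env_end = integer(0),
                    full_evalue = numeric(0), dom_evalue = numeric(0),
                    stringsAsFactors = FALSE)
  for (ln in keep) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 22)
      stop("domtblout line ", ln, ": expected >= 22 fields, got ", length(f))
    env_start <- suppressWarnings(as.integer(f[20]))
    env_end <- suppressWarnings(as.integer(f[21]))
    full_e <- suppressWarnings(as.numeric(f[7]))
    dom_e <- suppressWarnings(as.numeric(f[13]))
    if (anyNA(c(env_start, env_end, full_e, dom_e)))
      stop("domtblout line ", ln, ": malformed numeric field")
    if (env_start >= env_end)
      stop("domtblout line ", ln, ": envelope start must precede end")
    out <- rbind(out, data.frame(
      gene_id = f[1], domain = f[4], env_start = env_start,
      env_end = env_end, full_evalue = full_e, dom_evalue = dom_e,
      stringsAsFactors = FALSE))
  }
  out
}

#' Identify mod(mdg4)-like genes from BTB/FLYWCH domain hits
#'
#' A gene qualifies when it carries at least one BTB hit and one FLYWCH hit,
#' each with full-sequence AND per-domain E-value at or below `evalue_max`,
#' and its 5'-most BTB envelope starts upstream of its 5'-most FLYWCH
#' envelope.
#'
#' @param domain_hits data frame from [read_domtblout()].
#' @param evalue_max inclusion threshold for both E-values.
#' @param btb,flywch domain (query model) names.
#' @return Character vector of qualifying gene ids.
#' @export
identify_modlike_genes <- function(domain_hits, evalue_max = 1e-5,
                                   btb = "BTB", flywch = "FLYWCH") {
  ok <- domain_hits$full_evalue <= evalue_max &
    domain_hits$dom_evalue <= evalue_max
  hits <- domain_hits[ok, , drop = FALSE]
  out <- character(0)
  for (g in unique(hits$gene_id)) {
    h <- hits[hits$gene_id == g, , drop = FALSE]
    b <- h[h$domain == btb, , drop = FALSE]
    f <- h[h$domain == flywch, , drop = FALSE]
    if (nrow(b) == 0 || nrow(f) == 0) next
    if (min(b$env_start) < min(f$env_start)) out <- c(out, g)
  }
  out
}
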