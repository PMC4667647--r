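# Global-profile statistics of called events: box-plot summaries, exon-count
# distributions, splice-site base-frequency matrices, frame-bias test and
# report proportions.

#' Box-plot statistics (Tukey conventions)
#'
#' Quartiles by linear interpolation (quantile type 7); whiskers extend to
#' the most extreme observations within 1.5 IQR of the quartiles; anything
#' beyond is an outlier.
#'
#' @param values numeric vector (n >= 1).
#' @return List of class `box_stats`: q1, median, q3, whisker_low,
#'   whisker_high, outliers, n.
#' @export
box_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("box_stats: empty input")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - 1.5 * iqr
  hi_lim <- q[3] + 1.5 * iqr
  inside <- values >= lo_lim & values <= hi_lim
  structure(list(q1 = q[1], median = q[2], q3 = q[3],
                 whisker_low = min(values[inside]),
                 whisker_high = max(values[inside]),
                 outliers = sort(values[!inside]), n = length(values)),
            class = "box_stats")
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf("box_stats (n=%d): q1=%.4g median=%.4g q3=%.4g whiskers=[%.4g, %.4g], %d outlier(s)\n",
              x$n, x$q1, x$median, x$q3, x$whisker_low, x$whisker_high,
              length(x$outliers)))
  invisible(x)
}

#' Exon-count distributions of trans-spliced segments
#'
#' For each annotated event, counts of donor-retained, donor-discarded,
#' acceptor-retained and acceptor-discarded exons, plus the exon counts of
#' all annotated cis transcripts for comparison. Retained + discarded equals
#' the transcript's exon count for every event.
#'
#' @param events `annotated_events` data frame.
#' @param genes list of `gene_model` objects.
#' @return List of five integer vectors: donor_retained, donor_discarded,
#'   acceptor_retained, acceptor_discarded, cis.
#' @export
exon_count_histogram <- function(events, genes) {
  donor_total <- integer(nrow(events))
  acceptor_total <- integer(nrow(events))
  for (r in seq_len(nrow(events))) {
    donor_total[r] <- nrow(gene_by_id(genes, events$donor_gene[r])$
      transcripts[[events$donor_transcript[r]]]$exons)
    acceptor_total[r] <- nrow(gene_by_id(genes, events$acceptor_gene[r])$
      transcripts[[events$acceptor_transcript[r]]]$exons)
  }
  cis <- unlist(lapply(genes, function(g)
    vapply(g$transcripts, function(tx) nrow(tx$exons), integer(1))))
  list(donor_retained = events$donor_exon,
       donor_discarded = donor_total - events$donor_exon,
       acceptor_retained = acceptor_total - events$acceptor_exon + 1L,
       acceptor_discarded = events$acceptor_exon - 1L,
       cis = unname(cis))
}

#' Base-frequency matrices around the junction splice sites
#'
#' For each event, extracts the genomic sequence around the donor boundary
#' (`exonic_w` bases inside the exon, `intronic_w` beyond it, strand-aware)
#' and around the acceptor boundary, and aggregates positional A/C/G/T/N
#' frequencies. Events whose window runs off the contig are skipped with a
#' warning.
#'
#' @param events `annotated_events` data frame (needs donor/acceptor genes,
#'   transcripts and sites).
#' @param genes,genome gene models and genome.
#' @param exonic_w,intronic_w window widths in bp.
#' @return List of class `base_frequency_matrix` with `donor` and `acceptor`
#'   matrices (rows A/C/G/T/N, columns 5'->3' positions labelled E-5..E-1,
#'   I+1..I+10 for the donor and I-10..I-1, E+1..E+5 for the acceptor) and
#'   `n_events` used per site.
#' @export
junction_base_matrix <- function(events, genes, genome, exonic_w = 5L,
                                 intronic_w = 10L) {
  bases <- c("A", "C", "G", "T", "N")
  w <- exonic_w + intronic_w
  donor_counts <- matrix(0, 5, w, dimnames = list(bases, NULL))
  acceptor_counts <- matrix(0, 5, w, dimnames = list(bases, NULL))
  n_d <- 0L
  n_a <- 0L
  for (r in seq_len(nrow(events))) {
    dg <- gene_by_id(genes, events$donor_gene[r])
    ag <- gene_by_id(genes, events$acceptor_gene[r])
    dchr <- genome$sequences[[dg$chrom]]
    achr <- genome$sequences[[ag$chrom]]
    b <- events$donor_site[r]
    dwin <- if (dg$strand == "+") {
      if (b - exonic_w < 0 || b + intronic_w > nchar(dchr)) NULL
      else substr(dchr, b - exonic_w + 1, b + intronic_w)
    } else {
      if (b - intronic_w < 0 || b + exonic_w > nchar(dchr)) NULL
      else revcomp(substr(dchr, b - intronic_w + 1, b + exonic_w))
    }
    a <- events$acceptor_site[r]
    awin <- if (ag$strand == "+") {
      if (a - intronic_w < 0 || a + exonic_w > nchar(achr)) NULL
      else substr(achr, a - intronic_w + 1, a + exonic_w)
    } else {
      if (a - exonic_w < 0 || a + intronic_w > nchar(achr)) NULL
      else revcomp(substr(achr, a - exonic_w + 1, a + intronic_w))
    }
    if (is.null(dwin) || is.null(awin)) {
      warning("window off contig end for event ", r, "; skipped")
    }
    if (!is.null(dwin)) {
      ch <- strsplit(dwin, "")[[1]]
      for (p in seq_len(w)) donor_counts[ch[p], p] <-
          donor_counts[ch[p], p] + 1
      n_d <- n_d + 1L
    }
    if (!is.null(awin)) {
      ch <- strsplit(awin, "")[[1]]
      for (p in seq_len(w)) acceptor_counts[ch[p], p] <-
          acceptor_counts[ch[p], p] + 1
      n_a <- n_a + 1L
    }
  }
  colnames(donor_counts) <- c(paste0("E", -exonic_w:-1),
                              paste0("I+", 1:intronic_w))
  colnames(acceptor_counts) <- c(paste0("I", -intronic_w:-1),
                                 paste0("E+", 1:exonic_w))
  list_out <- list(
    donor = if (n_d > 0) donor_counts / n_d else donor_counts,
    acceptor = if (n_a > 0) acceptor_counts / n_a else acceptor_counts,
    n_donor = n_d, n_acceptor = n_a)
  class(list_out) <- "base_frequency_matrix"
  list_out
}

#' Chi-square test of reading-frame bias
#'
#' One-degree-of-freedom goodness-of-fit of the observed in-frame count
#' against a binomial null (default p = 1/3, a random frame offset between
#' two CDSs).
#'
#' @param n_inframe,n_total counts.
#' @param null_p null in-frame probability.
#' @return List with `chi2`, `p_value`, `df`.
#' @export
frame_bias_test <- function(n_inframe, n_total, null_p = 1 / 3) {
  if (n_total == 0) stop("frame_bias_test: n_total is zero")
  stopifnot(n_inframe >= 0, n_inframe <= n_total)
  ht <- suppressWarnings(
    chisq.test(c(n_inframe, n_total - n_inframe),
               p = c(null_p, 1 - null_p)))
  list(chi2 = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Report percentage with half-away-from-zero rounding
#'
#' @param numerator,denominator counts; zero denominator is an error.
#' @param digits decimals kept (2 for gene fractions, 1 for ratio-style
#'   values).
#' @return `100 * numerator / denominator`, rounded half away from zero.
#' @export
proportion_pct <- function(numerator, denominator, digits = 2) {
  if (any(denominator == 0)) stop("proportion_pct: zero denominator")
  round_half_up(100 * numerator / denominator, digits)
}

#' Named report proportions from a list of count pairs
#'
#' @param counts named list; each element is `c(numerator, denominator)` or
#'   a list with those two values.
#' @param digits decimals kept per proportion (recycled).
#' @return Named numeric vector of percentages.
#' @export
proportion_summaries <- function(counts, digits = 2) {
  digits <- rep_len(digits, length(counts))
  out <- numeric(length(counts))
  for (i in seq_along(counts)) {
    x <- unlist(counts[[i]])
    out[i] <- proportion_pct(x[1], x[2], digits[i])
  }
  stats::setNames(out, names(counts))
}

#' Global profile report of annotated events
#'
#' Event counts by type; distance box stats per type against canonical
#' intron lengths; length box stats of canonical transcripts, trans-spliced
#' products and donor/acceptor segments; exon-count histograms; cis-sharing
#' counts; coding and in-frame fractions with the frame-bias chi-square; and
#' the junction base-frequency matrices.
#'
#' @param events `annotated_events` data frame.
#' @param genes,genome gene models and genome.
#' @return List of class `profile_report`.
#' @export
profile_report <- function(events, genes, genome) {
  type_counts <- table(factor(events$type,
                              levels = c("SmDA", "SmAD", "DfStr", "DfChr")))
  intron_lengths <- unlist(lapply(genes, function(g)
    lapply(g$transcripts, function(tx) {
      if (nrow(tx$exons) < 2) return(numeric(0))
      gstart <- sort(tx$exons[, 1])
      gend <- sort(tx$exons[, 2])
      gstart[-1] - gend[-length(gend)]
    })))
  dist_stats <- lapply(split(events$distance_bp, events$type),
                       function(v) if (any(!is.na(v))) box_stats(v) else NULL)
  cis_lengths <- unlist(lapply(genes, function(g)
    vapply(g$transcripts, function(tx) sum(exon_lengths(tx)), numeric(1))))
  seg_len <- list(
    canonical = box_stats(cis_lengths),
    trans_product = if (nrow(events)) box_stats(nchar(events$chimeric_transcript)) else NULL,
    donor_segment = if (nrow(events)) box_stats(events$junction_offset) else NULL,
    acceptor_segment = if (nrow(events))
      box_stats(nchar(events$chimeric_transcript) - events$junction_offset)
      else NULL)
  coding_n <- sum(events$coding)
  inframe_n <- sum(events$in_frame_with_donor & events$in_frame_with_acceptor,
                   na.rm = TRUE)
  frame_defined_n <- sum(!is.na(events$in_frame_with_donor) &
                           !is.na(events$in_frame_with_acceptor))
  fractions <- c(
    coding_pct = if (nrow(events)) proportion_pct(coding_n, nrow(events), 2)
      else NA_real_,
    inframe_pct = if (frame_defined_n > 0)
      proportion_pct(inframe_n, frame_defined_n, 1) else NA_real_)
  chi <- if (frame_defined_n > 0)
    frame_bias_test(inframe_n, frame_defined_n) else NULL
  structure(list(
    n_events = nrow(events),
    type_counts = type_counts,
    distance_stats = dist_stats,
    intron_length_stats = if (length(intron_lengths)) box_stats(intron_lengths) else NULL,
    length_stats = seg_len,
    exon_histograms = if (nrow(events)) exon_count_histogram(events, genes) else NULL,
    cis_sharing_counts = table(factor(events$cis_sharing,
                                      levels = c("both_arms", "one_arm",
                                                 "neither"))),
    coding_n = coding_n, inframe_n = inframe_n,
    frame_defined_n = frame_defined_n,
    fractions = fractions, frame_bias = chi,
    base_matrix = if (nrow(events))
      junction_base_matrix(events, genes, genome) else NULL
  ), class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  cat("profile_report:", x$n_events, "event(s)\n")
  cat("  types:", paste(names(x$type_counts), as.integer(x$type_counts),
                        sep = "=", collapse = " "), "\n")
  cat("  cis sharing:", paste(names(x$cis_sharing_counts),
                              as.integer(x$cis_sharing_counts),
                              sep = "=", collapse = " "), "\n")
  if (!is.na(x$fractions["coding_pct"]))
    cat(sprintf("  coding: %d (%.2f%%)\n", x$coding_n,
                x$fractions["coding_pct"]))
  if (!is.null(x$frame_bias))
    cat(sprintf("  in-frame both sides: %d/%d (chi2=%.3g, p=%.3g)\n",
                x$inframe_n, x$frame_defined_n, x$frame_bias$chi2,
                x$frame_bias$p_value))
  invisible(x)
}

#' Serialize a profile report
#'
#' Writes a flat TSV of the scalar metrics plus a JSON rendering of the full
#' report and position-weight-matrix text for the base matrices.
#'
#' @param report a `profile_report`.
#' @param path_tsv,path_json output files (either may be NULL to skip).
#' @export
write_profile_report <- function(report, path_tsv = NULL, path_json = NULL) {
  flat <- data.frame(
    metric = c("n_events",
               paste0("type_", names(report$type_counts)),
               paste0("cis_sharing_", names(report$cis_sharing_counts)),
               "coding_n", "coding_pct", "inframe_n", "frame_defined_n",
               "inframe_pct", "frame_chi2", "frame_p"),
    value = c(report$n_events, as.integer(report$type_counts),
              as.integer(report$cis_sharing_counts),
              report$coding_n, report$fractions[["coding_pct"]],
              report$inframe_n, report$frame_defined_n,
              report$fractions[["inframe_pct"]],
              if (is.null(report$frame_bias)) NA else report$frame_bias$chi2,
              if (is.null(report$frame_bias)) NA else
                report$frame_bias$p_value),
    stringsAsFactors = FALSE)
  if (!is.null(path_tsv))
    write.table(flat, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json)) {
    ser <- report
    class(ser) <- NULL
    ser$type_counts <- as.list(report$type_counts)
    ser$cis_sharing_counts <- as.list(report$cis_sharing_counts)
    unbox_stats <- function(b) if (is.null(b)) NULL else unclass(b)
    ser$distance_stats <- lapply(ser$distance_stats, unbox_stats)
    ser$length_stats <- lapply(ser$length_stats, unbox_stats)
    ser$intron_length_stats <- unbox_stats(ser$intron_length_stats)
    if (!is.null(ser$base_matrix)) {
      ser$base_matrix <- list(
        donor = as.data.frame(ser$base_matrix$donor),
        acceptor = as.data.frame(ser$base_matrix$acceptor),
        n_donor = ser$base_matrix$n_donor,
        n_acceptor = ser$base_matrix$n_acceptor)
    }
    jsonlite::write_json(ser, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(flat)
}

#' Write a base-frequency matrix as position-weight-matrix text
#'
#' Tab-separated, one row per base, consumable by logo-rendering tools.
#' @param mat a `base_frequency_matrix`.
#' @param path output file.
#' @export
write_pwm_text <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (site in c("donor", "acceptor")) {
    writeLines(paste0("# ", site, " site"), con)
    m <- mat[[site]]
    writeLines(paste(c("base", colnames(m)), collapse = "\t"), con)
    for (b in rownames(m))
      writeLines(paste(c(b, format(m[b, ], digits = 6)), collapse = "\t"),
                 con)
  }
  invisible(path)
}
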