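# Three-step read quality filter: (1) retain a read only when at least 60%
# of its bases have Q >= 20 (evaluated on the untrimmed read), (2) trim
# contiguous low-quality runs from both ends, (3) discard trimmed reads with
# more than one N. A minimum post-trim length keeps the downstream 20 bp
# two-arm rule satisfiable.

#' Quality-filter parameters
#'
#' @param min_quality Phred threshold defining a high-quality base.
#' @param min_fraction_hq minimum fraction of high-quality bases (inclusive:
#'   a 10 bp read with exactly 6 such bases passes at 0.60).
#' @param max_n maximum number of N bases tolerated after trimming.
#' @param min_length_after_trim reads shorter than this after end-trimming
#'   are rejected.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_quality = 20L, min_fraction_hq = 0.60,
                      max_n = 1L, min_length_after_trim = 20L) {
  stopifnot(min_fraction_hq > 0, min_fraction_hq <= 1, max_n >= 0)
  structure(list(min_quality = as.integer(min_quality),
                 min_fraction_hq = min_fraction_hq,
                 max_n = as.integer(max_n),
                 min_length_after_trim = as.integer(min_length_after_trim)),
            class = "qc_params")
}

#' Trim low-quality ends from a single read
#'
#' Contiguous runs of bases with Q < `min_quality` are removed from each end;
#' trimming stops at the first high-quality base from each side.
#'
#' @param read list with `sequence` (string) and `qualities` (integer Phred
#'   vector of the same length).
#' @param params a [qc_params()].
#' @return The trimmed read, or NULL if it falls below
#'   `min_length_after_trim` (rejection is a return state, not an error).
#' @export
quality_trim_read <- function(read, params = qc_params()) {
  q <- read$qualities
  stopifnot(length(q) == nchar(read$sequence))
  hq <- which(q >= params$min_quality)
  if (length(hq) == 0) return(NULL)
  a <- hq[1]
  b <- hq[length(hq)]
  if (b - a + 1L < params$min_length_after_trim) return(NULL)
  read$sequence <- substr(read$sequence, a, b)
  read$qualities <- q[a:b]
  read
}

#' Quality-filter paired reads
#'
#' Applies, per read: the high-quality-fraction rule, end trimming, and the
#' N-count rule. A pair is retained only when both mates survive (downstream
#' bridging needs both); set `keep_singletons = TRUE` to also return pairs
#' where exactly one mate survives (the failing mate is emptied).
#'
#' @param pairs data frame of pairs (see [load_reads_fastq()]).
#' @param params a [qc_params()].
#' @param keep_singletons retain pairs with a single surviving mate.
#' @return A list with `pairs` (retained, sequences/qualities trimmed) and
#'   `report` (data frame of per-read and per-pair counts; the per-read
#'   rejection reasons plus passes sum to the input read count).
#' @export
filter_reads <- function(pairs, params = qc_params(),
                         keep_singletons = FALSE) {
  qc1 <- .tc_qc(pairs$seq1, pairs$qual1, params$min_quality,
                params$min_fraction_hq, params$max_n,
                params$min_length_after_trim)
  qc2 <- .tc_qc(pairs$seq2, pairs$qual2, params$min_quality,
                params$min_fraction_hq, params$max_n,
                params$min_length_after_trim)
  pass1 <- qc1[, 1] == 0L
  pass2 <- qc2[, 1] == 0L
  keep <- if (keep_singletons) pass1 | pass2 else pass1 & pass2

  trim <- function(seqs, quals, qc, pass) {
    s <- substr(seqs, qc[, 2], qc[, 3])
    q <- substr(quals, qc[, 2], qc[, 3])
    s[!pass] <- ""
    q[!pass] <- ""
    list(s = s, q = q)
  }
  t1 <- trim(pairs$seq1, pairs$qual1, qc1, pass1)
  t2 <- trim(pairs$seq2, pairs$qual2, qc2, pass2)
  out <- data.frame(read_id = pairs$read_id[keep],
                    seq1 = t1$s[keep], qual1 = t1$q[keep],
                    seq2 = t2$s[keep], qual2 = t2$q[keep],
                    stringsAsFactors = FALSE)

  status <- c(qc1[, 1], qc2[, 1])
  report <- data.frame(
    metric = c("reads_input", "reads_pass", "reads_low_quality_fraction",
               "reads_too_short_after_trim", "reads_too_many_n",
               "pairs_input", "pairs_retained", "pairs_dropped_mate_failed"),
    count = c(length(status), sum(status == 0L), sum(status == 1L),
              sum(status == 2L), sum(status == 3L),
              nrow(pairs), nrow(out), nrow(pairs) - nrow(out)),
    stringsAsFactors = FALSE)
  list(pairs = out, report = report)
}

#' Write a QC report as TSV
#' @param report report data frame from [filter_reads()].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
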