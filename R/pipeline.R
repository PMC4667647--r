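# Pipeline orchestration: a configuration (R list or YAML file) drives the
# full run and every artifact lands in the output directory. Also the event
# table serializers shared by the CLI.

#' Write annotated events as TSV
#' @param events `annotated_events` (or called-events) data frame.
#' @param path output file.
#' @export
write_events_tsv <- function(events, path) {
  ev <- as.data.frame(events)
  ev$chimeric_transcript <- NULL   # sequences go to FASTA, not the table
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write events as BEDPE (two boundary anchors)
#' @param events annotated events with genomic boundary sites.
#' @param genes gene models (for chromosome and strand).
#' @param path output file.
#' @export
write_events_bedpe <- function(events, genes, path) {
  lines <- character(0)
  for (r in seq_len(nrow(events))) {
    dg <- gene_by_id(genes, events$donor_gene[r])
    ag <- gene_by_id(genes, events$acceptor_gene[r])
    ds <- events$donor_site[r]
    as_ <- events$acceptor_site[r]
    lines <- c(lines, paste(
      dg$chrom, max(0, ds - 1), ds, ag$chrom, as_, as_ + 1,
      events$junction_id[r], 0, dg$strand, ag$strand, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write chimeric transcripts / proteins of annotated events as FASTA
#' @param events `annotated_events` data frame.
#' @param path output file.
#' @export
write_chimeric_transcripts_fasta <- function(events, path) {
  if (nrow(events) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  set <- Biostrings::DNAStringSet(events$chimeric_transcript)
  names(set) <- paste0(events$junction_id, "|", events$donor_gene, "|",
                       events$acceptor_gene)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' @rdname write_chimeric_transcripts_fasta
#' @export
write_chimeric_proteins_fasta <- function(events, path) {
  coding <- events[events$coding, , drop = FALSE]
  if (nrow(coding) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  set <- Biostrings::AAStringSet(coding$peptide)
  names(set) <- paste0(coding$junction_id, "|", coding$donor_gene, "|",
                       coding$acceptor_gene, "|donor_aa=", coding$donor_aa,
                       "|acceptor_aa=", coding$acceptor_aa)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Pipeline configuration
#'
#' Either a YAML file path or a named list. Recognized keys: `genome`,
#' `gff3`, `fastq_r1`, `fastq_r2`, optional `sam`, `out_dir`, `seed`,
#' `arm_length`, `isoform_mode`, `min_side_aa`, plus nested `qc` and
#' `thresholds` lists overriding [qc_params()] / [evidence_thresholds()]
#' fields, and nested `simulate` overriding [simulation_config()] fields.
#'
#' @param config list or YAML path.
#' @return Normalized configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config$isoform_mode <- config$isoform_mode %||% "representative"
  config$min_side_aa <- config$min_side_aa %||% 10L
  qc <- do.call(qc_params, config$qc %||% list())
  th <- do.call(evidence_thresholds, config$thresholds %||% list())
  config$qc <- qc
  config$thresholds <- th
  class(config) <- "pipeline_config"
  config
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
}

#' Run the full detection pipeline
#'
#' Loads the inputs, calls events, annotates them, computes the global
#' profile and the within-species paralogy screen, and writes every artifact
#' (qc_report.tsv, candidate_reads.fastq, junction_library.fasta,
#' events.tsv, events.bedpe, chimeric_transcripts.fasta,
#' chimeric_proteins.fasta, profile_report.tsv/.json,
#' homology/paralog_screen.tsv, run.log) into `out_dir`. Outputs are
#' deterministic for fixed inputs and seed.
#'
#' @param config a [pipeline_config()] (or list/YAML path coercible to one).
#' @return Invisibly, a list with the annotated events, profile report and
#'   output directory.
#' @export
run_full_pipeline <- function(config) {
  config <- pipeline_config(config)
  for (key in c("genome", "gff3", "fastq_r1", "fastq_r2")) {
    if (is.null(config[[key]]))
      stop("pipeline config missing required path: ", key)
    if (!file.exists(config[[key]]))
      stop("pipeline config: file not found for ", key, ": ", config[[key]])
  }
  out <- config$out_dir %||% stop("pipeline config missing out_dir")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "homology"), showWarnings = FALSE)
  log_con <- file(file.path(out, "run.log"), "w")
  on.exit(close(log_con))
  set.seed(config$seed)

  .log_line(log_con, "parameters: seed=", config$seed,
            " isoform_mode=", config$isoform_mode,
            " qc={", paste(names(config$qc), unlist(config$qc), sep = "=",
                           collapse = ", "), "}",
            " thresholds={", paste(names(config$thresholds),
                                   unlist(config$thresholds), sep = "=",
                                   collapse = ", "), "}")

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      .log_line(log_con, "STAGE FAILED: ", name, ": ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    .log_line(log_con, sprintf("stage %-12s done in %.2fs", name,
                               as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs"))))
    res
  }

  genome <- stage("load", {
    g <- load_genome_fasta(config$genome)
    g
  })
  genes <- stage("annotation", load_annotation_gff3(config$gff3, genome))
  pairs <- stage("reads", load_reads_fastq(config$fastq_r1, config$fastq_r2))
  mapped <- if (!is.null(config$sam))
    stage("sam_flags", load_mapped_read_ids(config$sam)) else NULL

  qcres <- stage("qc", filter_reads(pairs, config$qc))
  write_qc_report(qcres$report, file.path(out, "qc_report.tsv"))
  .log_line(log_con, "qc: ", nrow(pairs), " pairs in, ",
            nrow(qcres$pairs), " retained")

  called <- stage("detect", call_events(
    genome, genes, pairs, thresholds = config$thresholds, qc = config$qc,
    arm_length = config$arm_length, isoform_mode = config$isoform_mode,
    mapped_read_ids = mapped))
  for (nm in names(called$funnel))
    .log_line(log_con, "funnel: ", nm, "=", called$funnel[[nm]])

  # candidate reads for inspection
  index <- build_cis_index(genome, genes)
  part <- partition_reads(qcres$pairs, index,
                          config$thresholds$max_mismatches)
  cand <- part$candidates
  cand_lines <- character(0)
  for (m in 1:2) {
    sel <- !cand[[paste0("mate", m, "_cis")]]
    if (!any(sel)) next
    cand_lines <- c(cand_lines, as.vector(rbind(
      paste0("@", cand$read_id[sel], "/", m),
      cand[[paste0("seq", m)]][sel], "+",
      cand[[paste0("qual", m)]][sel])))
  }
  writeLines(cand_lines, file.path(out, "candidate_reads.fastq"))

  lib <- build_fusion_library(
    genes, genome,
    arm_length = config$arm_length %||%
      max(max(nchar(pairs$seq1)) - config$thresholds$min_overhang, 80L),
    isoform_mode = config$isoform_mode,
    min_overhang = config$thresholds$min_overhang)
  export_fusion_library_fasta(lib, file.path(out, "junction_library.fasta"))

  ann <- stage("annotate", annotate_events(called, genes, genome,
                                           config$min_side_aa))
  write_events_tsv(ann, file.path(out, "events.tsv"))
  write_events_bedpe(ann, genes, file.path(out, "events.bedpe"))
  write_chimeric_transcripts_fasta(ann, file.path(out,
                                                  "chimeric_transcripts.fasta"))
  write_chimeric_proteins_fasta(ann, file.path(out,
                                               "chimeric_proteins.fasta"))

  prof <- stage("profile", profile_report(ann, genes, genome))
  write_profile_report(prof, file.path(out, "profile_report.tsv"),
                       file.path(out, "profile_report.json"))
  if (!is.null(prof$base_matrix))
    write_pwm_text(prof$base_matrix, file.path(out, "junction_pwm.txt"))

  par <- stage("homology", paralog_screen(ann))
  par_df <- data.frame(junction_id = ann$junction_id,
                       donor_gene = ann$donor_gene,
                       acceptor_gene = ann$acceptor_gene,
                       donor_acceptor_homologous = par$flags,
                       stringsAsFactors = FALSE)
  write.table(par_df, file.path(out, "homology", "paralog_screen.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  .log_line(log_con, "done: ", nrow(ann), " event(s) called")
  invisible(list(events = ann, profile = prof, out_dir = out))
}

#' Run the simulation subcommand: write a synthetic dataset to disk
#'
#' Generates the genome, annotation, reads and truth table of a
#' [simulation_config()] and writes genome.fasta, genes.gff3,
#' reads_1.fastq, reads_2.fastq and truth.tsv into `out_dir`.
#'
#' @param config a `simulation_config`, or a list of overrides for one.
#' @param out_dir output directory.
#' @return Invisibly, the in-memory simulation (genome, genes, truth, pairs).
#' @export
run_simulation <- function(config = simulation_config(), out_dir) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_genome_and_genes(config)
  reads <- simulate_read_pairs(config, sim$genome, sim$genes, sim$truth,
                               out_dir = out_dir)
  write_genome_fasta(sim$genome, file.path(out_dir, "genome.fasta"))
  write_annotation_gff3(sim$genes, file.path(out_dir, "genes.gff3"))
  invisible(list(genome = sim$genome, genes = sim$genes,
                 truth = reads$truth, pairs = reads$pairs))
}
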