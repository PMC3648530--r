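# File-driven pipeline: simulate -> trim -> ingest -> score/outliers -> QC ->
# SNPs, configured by a single JSON file. Stages communicate only via files
# so every intermediate is inspectable, and the whole run is reproducible
# from the global seed.

#' Read and validate a pipeline configuration
#'
#' The config is a JSON object with a global `seed`, an `outdir`, a `stages`
#' array (any of "simulate", "trim", "ingest", "outliers", "qc", "snps"), and
#' optional per-stage parameter blocks (`sim`, `trim`, `ingest`, `outliers`,
#' `snps`) plus `inputs` paths for stages run on external files.
#'
#' @param path path to the JSON config file.
#' @return a validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a config given directly as a list.
#' @export
as_pipeline_config <- function(cfg) {
  stopifnot(is.list(cfg))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$outdir <- cfg$outdir %||% stop("config needs `outdir`", call. = FALSE)
  all_stages <- c("simulate", "trim", "ingest", "outliers", "qc", "snps")
  cfg$stages <- cfg$stages %||% all_stages
  bad <- setdiff(cfg$stages, all_stages)
  if (length(bad))
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  cfg$inputs <- as.list(cfg$inputs %||% list())
  structure(cfg, class = "pipeline_config")
}

cfg_input <- function(cfg, key, produced, stage) {
  p <- cfg$inputs[[key]] %||% produced[[key]]
  if (is.null(p) || !file.exists(p))
    stop(sprintf("stage '%s' needs input '%s' but no existing file is configured or produced",
                 stage, key), call. = FALSE)
  p
}

#' Run the divergence-scanning pipeline
#'
#' Executes the enabled stages in dependency order. Inputs for each stage are
#' taken from the files produced by earlier stages or from `inputs` in the
#' config. Before any work, the availability of every enabled stage's inputs
#' is checked. A manifest of all outputs (with md5 checksums) and the
#' parameters used is written to `manifest.json` in the output directory;
#' rerunning with an identical config reproduces identical checksums.
#'
#' @param config a `pipeline_config`, or a path to a JSON config file.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else as_pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$outdir, name)
  produced <- list()
  sp <- do.call(sim_params, c(list(seed = cfg$seed), as.list(cfg$sim)))
  tspec <- do.call(trim_spec, as.list(cfg$trim))
  opars <- do.call(outlier_params, as.list(cfg$outliers))
  spars <- do.call(snp_filter_params, as.list(cfg$snps))
  cutoffs <- as.numeric(cfg$ingest$cutoffs %||% c(1e-50, 1e-25, Inf))

  # pre-flight: every enabled stage must be able to find its inputs, either
  # from an earlier enabled stage or from cfg$inputs
  will_produce <- if ("simulate" %in% cfg$stages)
    c("contigs", "blast", "reads", "pileup", "truth") else character()
  needs <- list(trim = "reads", ingest = c("blast", "contigs"),
                outliers = "blast", qc = c("blast", "contigs"),
                snps = "pileup")
  for (st in intersect(cfg$stages, names(needs))) {
    for (key in needs[[st]]) {
      if (key %in% will_produce) next
      p <- cfg$inputs[[key]]
      if (is.null(p) || !file.exists(p))
        stop(sprintf("pre-flight: stage '%s' enabled but input '%s' is missing",
                     st, key), call. = FALSE)
    }
  }

  if ("simulate" %in% cfg$stages) {
    sim <- simulate_contigs(sp)
    Biostrings::writeXStringSet(sim$contigs, out("contigs.fasta"))
    fwrite(sim$truth, out("truth_contigs.tsv"), sep = "\t")
    hits <- simulate_alignment_table(sp, sim$truth)
    fwrite(hits, out("alignments.tsv"), sep = "\t", col.names = FALSE)
    reads <- simulate_reads(sp)
    write_fastq(reads$reads, out("reads.fastq"))
    fwrite(reads$truth, out("truth_reads.tsv"), sep = "\t")
    pu <- simulate_pileup(sp, sim$contigs)
    writeLines(pu$pileup, out("pileup.txt"))
    fwrite(pu$truth, out("truth_pileup.tsv"), sep = "\t")
    produced <- list(contigs = out("contigs.fasta"),
                     blast = out("alignments.tsv"),
                     reads = out("reads.fastq"), pileup = out("pileup.txt"),
                     truth = out("truth_contigs.tsv"))
  }

  if ("trim" %in% cfg$stages) {
    trim_fastq(cfg_input(cfg, "reads", produced, "trim"), tspec,
               out_fastq = out("reads.trimmed.fastq"),
               log_tsv = out("trim_log.tsv"))
  }

  top <- NULL
  if (any(c("ingest", "outliers", "qc") %in% cfg$stages)) {
    hits <- parse_blast_tab(cfg_input(cfg, "blast", produced, "ingest"))
    top <- evalue_stepdown(hits, cutoffs)
  }
  if ("ingest" %in% cfg$stages) {
    fwrite(top, out("top_hits.tsv"), sep = "\t")
    fwrite(per_chromosome_summary(top), out("chromosome_summary.tsv"),
           sep = "\t")
    fwrite(classify_unique_chromosome(
      parse_blast_tab(cfg_input(cfg, "blast", produced, "ingest"))),
      out("unique_chromosome.tsv"), sep = "\t")
  }

  report <- NULL
  if ("outliers" %in% cfg$stages) {
    scores <- data.table(contig_id = top$qseqid,
                         score = composite_score(top$pident, top$length))
    fwrite(scores, out("composite_scores.tsv"), sep = "\t")
    report <- call_outliers(scores, opars)
    jsonlite::write_json(
      list(lower_bound = report$lower_bound,
           upper_bound = report$upper_bound, n_total = report$n_total,
           conserved = report$conserved, diverged = report$diverged),
      out("outlier_report.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("qc" %in% cfg$stages) {
    meta <- load_contigs(cfg_input(cfg, "contigs", produced, "qc"))
    qc_tab <- merge(meta, top[, .(contig_id = qseqid, pident,
                                  alignment_length = length)],
                    by = "contig_id")
    fwrite(pairwise_correlations(
      qc_tab[, .(size = length, gc, pident, alignment_length)]),
      out("qc_correlations.tsv"), sep = "\t")
    if (!is.null(report)) {
      ov <- size_outlier_overlap(meta, report)
      jsonlite::write_json(
        list(n_overlap = ov$n_overlap, overlap = ov$overlap),
        out("qc_size_overlap.json"), auto_unbox = TRUE)
    }
  }

  if ("snps" %in% cfg$stages) {
    pu <- parse_pileup(cfg_input(cfg, "pileup", produced, "snps"))
    calls <- call_snps(pu, spars)
    fwrite(calls, out("snp_calls.tsv"), sep = "\t")
    write_snp_vcf(calls, out("snp_calls.vcf"))
  }

  files <- setdiff(list.files(cfg$outdir, full.names = TRUE),
                   out("manifest.json"))
  manifest <- list(
    seed = cfg$seed, stages = cfg$stages,
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         bytes = file.size(files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
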