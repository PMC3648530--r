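# Ingestion of BLAST tabular (outfmt 6) alignment files: parsing, E-value
# step-down top-hit selection, tie-breaking, and per-chromosome summaries.

blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Parse a BLAST tabular (outfmt 6) file
#'
#' Reads the standard 12-column tab-separated BLAST output and validates every
#' row. Row order is preserved.
#'
#' @param path path to the TSV file (no header).
#' @return a `data.table` with columns qseqid, sseqid, pident, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' @export
parse_blast_tab <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such file: '%s'", path), call. = FALSE)
  empty <- data.table(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric())
  if (file.size(path) == 0L) return(empty)
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(
    character = 1:2), fill = TRUE)
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) != 12L)
    stop(sprintf("'%s': expected 12 tab-separated columns, found %d",
                 path, ncol(dt)), call. = FALSE)
  setnames(dt, blast_cols)
  num_cols <- blast_cols[3:12]
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(dt[[cc]]))
    bad <- which(is.na(v) & !is.na(dt[[cc]]))
    if (length(bad) || anyNA(v))
      stop(sprintf("'%s' line %d: non-numeric value in column '%s'",
                   path, c(bad, which(is.na(v)))[1], cc), call. = FALSE)
    set(dt, j = cc, value = v)
  }
  validate_hits(dt, path)
  int_cols <- c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send")
  for (cc in int_cols) set(dt, j = cc, value = as.integer(dt[[cc]]))
  dt[]
}

validate_hits <- function(dt, origin = "hits") {
  bad_line <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("'%s' line %d: %s", origin, i[1], what), call. = FALSE)
  }
  bad_line(dt$pident <= 0 | dt$pident > 100, "pident outside (0, 100]")
  bad_line(dt$length < 1, "alignment length < 1")
  bad_line(dt$qstart > dt$qend, "qstart > qend")
  bad_line(dt$evalue < 0, "negative evalue")
  bad_line(dt$bitscore <= 0, "non-positive bitscore")
  invisible(dt)
}

# Deterministic total order used for all top-hit selection: minimum evalue,
# ties by maximum bitscore, then maximum alignment length, then
# lexicographically smallest (sseqid, sstart).
order_hits <- function(dt) {
  with(dt, order(evalue, -bitscore, -length, sseqid, sstart))
}

#' Select the top hit among the hits of one query
#'
#' Minimum E-value; ties broken by maximum bitscore, then maximum alignment
#' length, then lexicographically smallest (sseqid, sstart) for determinism.
#' Permuting the input rows never changes the result.
#'
#' @param hits a `data.table`/data.frame of alignment hits for a single query.
#' @return the selected one-row `data.table`, or `NULL` for an empty input.
#' @export
select_top_hit <- function(hits) {
  hits <- as.data.table(hits)
  if (nrow(hits) == 0L) return(NULL)
  hits[order_hits(hits)][1L]
}

#' E-value step-down top-hit selection
#'
#' Reproduces the disk-saving staged workflow: at stage k only hits with
#' E-value at or below `cutoffs[k]` are considered; queries with at least one
#' such hit are resolved there by [select_top_hit()]; the remainder fall
#' through to the next, more permissive stage. The final stage (`NA` or `Inf`)
#' applies no cutoff. The result is provably identical to a single-pass
#' unrestricted top-hit selection.
#'
#' @param hits a hit table as returned by [parse_blast_tab()].
#' @param cutoffs strictly increasing (relaxing) E-value cutoffs; the last may
#'   be `NA`/`Inf` for "none". Default `c(1e-50, 1e-25, Inf)`.
#' @return a `data.table` of one top hit per query with a `stage` column
#'   recording the stage at which each query was resolved.
#' @export
evalue_stepdown <- function(hits, cutoffs = c(1e-50, 1e-25, Inf)) {
  hits <- as.data.table(hits)
  cutoffs[is.na(cutoffs)] <- Inf
  if (length(cutoffs) < 1L || any(diff(cutoffs) <= 0))
    stop("`cutoffs` must be strictly relaxing (increasing)", call. = FALSE)
  if (nrow(hits) == 0L) return(hits[, stage := integer()][])
  unresolved <- unique(hits$qseqid)
  out <- vector("list", length(cutoffs))
  for (k in seq_along(cutoffs)) {
    pool <- hits[qseqid %chin% unresolved & evalue <= cutoffs[k]]
    if (nrow(pool)) {
      top <- pool[pool[, .I[order_hits(.SD)[1L]], by = qseqid]$V1]
      top[, stage := k]
      out[[k]] <- top
      unresolved <- setdiff(unresolved, top$qseqid)
    }
    if (!length(unresolved)) break
  }
  rbindlist(out)[order(qseqid)][]
}

#' Classify whether a contig aligns to a single chromosome
#'
#' A contig is "unique" when every retained hit for it names the same subject
#' chromosome.
#'
#' @param hits hit table with at least `qseqid` and `sseqid`.
#' @return a `data.table` with columns `qseqid`, `unique_chromosome` (logical)
#'   and `sseqid` (the chromosome when unique, otherwise NA).
#' @export
classify_unique_chromosome <- function(hits) {
  hits <- as.data.table(hits)
  if (nrow(hits) == 0L)
    return(data.table(qseqid = character(), unique_chromosome = logical(),
                      sseqid = character()))
  hits[, .(unique_chromosome = uniqueN(sseqid) == 1L,
           sseqid = if (uniqueN(sseqid) == 1L) sseqid[1L] else NA_character_),
       by = qseqid]
}

#' Per-chromosome summary of top hits
#'
#' @param top_hits one retained hit per query (e.g. from [evalue_stepdown()]).
#' @return a `data.table` with one row per subject chromosome: number of
#'   contigs, median and mean percent identity, and median alignment length.
#' @export
per_chromosome_summary <- function(top_hits) {
  top_hits <- as.data.table(top_hits)
  if (nrow(top_hits) == 0L)
    stop("`top_hits` is empty", call. = FALSE)
  out <- top_hits[, .(n_contigs = .N,
                      median_pident = median(pident),
                      mean_pident = mean(pident),
                      median_length = median(as.numeric(length))),
                  by = sseqid]
  setorder(out, sseqid)[]
}

#' Load contig metadata from a FASTA file
#'
#' @param path FASTA file of contigs.
#' @return a `data.table` with `contig_id`, `length` (bp) and `gc` (G+C
#'   fraction over non-N bases; NA for all-N contigs).
#' @export
load_contigs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate contig identifier '%s' in '%s'",
                 ids[duplicated(ids)][1], path), call. = FALSE)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- ifelse(acgt > 0, rowSums(freq[, c("G", "C"), drop = FALSE]) / acgt,
               NA_real_)
  data.table(contig_id = ids, length = Biostrings::width(seqs), gc = gc)
}
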