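# Read trimming: running-sum quality trimming, terminal ambiguity trimming,
# and Smith-Waterman adapter removal.

#' Construct a quality read
#'
#' A sequencing read with per-base Phred scores, the substrate of the trimmer.
#'
#' @param read_id identifier.
#' @param bases character string over A, C, G, T, N.
#' @param quals integer vector of Phred scores in \[0, 60\], one per base.
#' @return an object of class `quality_read`.
#' @export
#' @examples
#' quality_read("r1", "ACGT", c(30, 30, 30, 30))
quality_read <- function(read_id, bases, quals) {
  stopifnot(is.character(bases), length(bases) == 1L)
  quals <- as.integer(quals)
  if (nchar(bases) != length(quals))
    stop("`bases` and `quals` must have the same length", call. = FALSE)
  if (length(quals) && (anyNA(quals) || any(quals < 0L) || any(quals > 60L)))
    stop("Phred scores must lie in [0, 60]", call. = FALSE)
  if (nchar(bases) && grepl("[^ACGTN]", bases))
    stop("`bases` may only contain A, C, G, T, N", call. = FALSE)
  structure(list(read_id = as.character(read_id), bases = bases, quals = quals),
            class = "quality_read")
}

#' Trimming parameters
#'
#' @param limit error-probability limit for quality trimming; a base
#'   contributes `limit - P_error` to the running sum. Default 0.05.
#' @param max_end_n maximum number of ambiguous nucleotides tolerated at each
#'   read end before the read is flagged; terminal N runs are always removed.
#'   Default 3.
#' @param adapters character vector of adapter sequences (A/C/G/T).
#' @param sw_match,sw_mismatch,sw_gap Smith-Waterman scores for the adapter
#'   search (defaults +1 / -2 / -3, linear gaps).
#' @param sw_min_score minimum local-alignment score for an adapter match to
#'   be removed. Default 10 (an exact 10-mer).
#' @return an object of class `trim_spec`.
#' @export
trim_spec <- function(limit = 0.05, max_end_n = 3L, adapters = character(),
                      sw_match = 1, sw_mismatch = -2, sw_gap = -3,
                      sw_min_score = 10) {
  if (!is.numeric(limit) || length(limit) != 1L || limit <= 0 || limit >= 1)
    stop("`limit` must lie strictly in (0, 1)", call. = FALSE)
  assert_count(max_end_n, "max_end_n")
  if (!is.numeric(sw_min_score) || sw_min_score <= 0)
    stop("`sw_min_score` must be > 0", call. = FALSE)
  adapters <- toupper(as.character(adapters))
  if (length(adapters) && any(grepl("[^ACGT]", adapters)))
    stop("adapters may only contain A, C, G, T", call. = FALSE)
  structure(list(limit = limit, max_end_n = as.integer(max_end_n),
                 adapters = adapters, sw_match = sw_match,
                 sw_mismatch = sw_mismatch, sw_gap = sw_gap,
                 sw_min_score = sw_min_score),
            class = "trim_spec")
}

#' Convert a Phred score to an error probability
#'
#' `P_error = 10^(-Q/10)`, so Q = 0 maps to certainty of error (P = 1),
#' Q = 10 to 0.1, Q = 20 to 0.01.
#'
#' @param q numeric vector of Phred scores, all >= 0.
#' @return numeric vector of error probabilities in (0, 1\].
#' @export
#' @examples
#' phred_to_perror(c(0, 10, 20))
phred_to_perror <- function(q) {
  if (!is.numeric(q) || (length(q) && any(is.na(q) | q < 0)))
    stop("Phred scores must be numeric and >= 0", call. = FALSE)
  10^(-q / 10)
}

new_trim_result <- function(read_id, start0, end0, discarded, stages) {
  structure(list(read_id = read_id,
                 kept_start = as.integer(start0), kept_end = as.integer(end0),
                 discarded = isTRUE(discarded),
                 stages = as.character(stages)),
            class = "trim_result")
}

#' Running-sum quality trimming of a single read
#'
#' For each base, the score `limit - P_error(Q)` is accumulated in a running
#' sum that is reset to zero whenever it drops below zero. The retained region
#' runs from the first positive position of the segment containing the
#' running-sum maximum through the (leftmost) maximum itself; this is exactly
#' the maximum-sum contiguous substring of the per-base scores. A read whose
#' running sum never rises above zero is discarded.
#'
#' @param read a [quality_read()].
#' @param spec a [trim_spec()].
#' @return a `trim_result` with the kept interval as a 0-based half-open
#'   interval into the original read, a `discarded` flag, and the stages that
#'   altered the read.
#' @export
quality_trim <- function(read, spec = trim_spec()) {
  stopifnot(inherits(read, "quality_read"), inherits(spec, "trim_spec"))
  n <- length(read$quals)
  if (n == 0L)
    return(new_trim_result(read$read_id, 0L, 0L, FALSE, character()))
  s <- spec$limit - phred_to_perror(read$quals)
  rs <- 0; best <- 0; best_start <- 1L; best_end <- 0L; seg_start <- 1L
  for (i in seq_len(n)) {
    rs <- rs + s[i]
    if (rs < 0) {
      rs <- 0
      seg_start <- i + 1L
    } else if (rs > best) {       # strictly greater: leftmost maximum wins
      best <- rs
      best_start <- seg_start
      best_end <- i
    }
  }
  if (best_end == 0L)             # running sum never exceeded zero
    return(new_trim_result(read$read_id, 0L, 0L, TRUE, "quality"))
  altered <- best_start > 1L || best_end < n
  new_trim_result(read$read_id, best_start - 1L, best_end, FALSE,
                  if (altered) "quality" else character())
}

#' Trim terminal ambiguous bases
#'
#' Removes runs of N from both ends of the read. `max_end_n` governs
#' tolerance: a terminal run longer than `max_end_n`, or more than `max_end_n`
#' internal Ns, flags the read in the stage log (internal Ns are not excised,
#' preserving coordinates). No terminal N ever remains.
#'
#' @inheritParams quality_trim
#' @return a `trim_result` relative to the read as given.
#' @export
ambiguity_trim <- function(read, spec = trim_spec()) {
  stopifnot(inherits(read, "quality_read"), inherits(spec, "trim_spec"))
  n <- nchar(read$bases)
  if (n == 0L)
    return(new_trim_result(read$read_id, 0L, 0L, FALSE, character()))
  ch <- strsplit(read$bases, "", fixed = TRUE)[[1]]
  is_n <- ch == "N"
  lead <- if (is_n[1]) which.min(is_n) - 1L else 0L
  if (all(is_n)) lead <- n
  trail <- if (lead < n && is_n[n]) which.min(rev(is_n)) - 1L else 0L
  if (lead >= n)
    return(new_trim_result(read$read_id, 0L, 0L, TRUE, "ambiguity"))
  start0 <- lead
  end0 <- n - trail
  internal_n <- sum(is_n[(start0 + 1L):end0])
  stages <- character()
  if (lead > 0L || trail > 0L) stages <- "ambiguity"
  if (lead > spec$max_end_n || trail > spec$max_end_n ||
      internal_n > spec$max_end_n)
    stages <- union(stages, "ambiguity_flag")
  new_trim_result(read$read_id, start0, end0, FALSE, stages)
}

# Local Smith-Waterman search of one read against the adapter set via
# Biostrings; returns the leftmost read position (1-based) at which a match
# scoring >= sw_min_score begins, or NA if none.
adapter_match_start <- function(bases, spec) {
  if (!length(spec$adapters) || nchar(bases) == 0L) return(NA_integer_)
  mat <- sw_substitution_matrix(spec)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(spec$adapters),
    subject = Biostrings::DNAString(bases),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = -spec$sw_gap)
  sc <- Biostrings::score(aln)
  hit <- which(sc >= spec$sw_min_score)
  if (!length(hit)) return(NA_integer_)
  min(IRanges::start(Biostrings::subject(aln)[hit]))
}

sw_substitution_matrix <- function(spec) {
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(spec$sw_mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- spec$sw_match
  mat["N", ] <- spec$sw_mismatch
  mat[, "N"] <- spec$sw_mismatch
  mat
}

#' Remove adapter sequence from a read
#'
#' Each adapter is locally aligned (Smith-Waterman; match/mismatch/gap scores
#' from the spec) against the read. Any match scoring at least `sw_min_score`
#' is removed together with all bases 3' of it; the search repeats on the
#' shortened read until no match remains.
#'
#' @inheritParams quality_trim
#' @return a `trim_result` relative to the read as given.
#' @export
adapter_trim <- function(read, spec = trim_spec()) {
  stopifnot(inherits(read, "quality_read"), inherits(spec, "trim_spec"))
  n <- nchar(read$bases)
  end0 <- n
  repeat {
    cur <- substr(read$bases, 1L, end0)
    pos <- adapter_match_start(cur, spec)
    if (is.na(pos)) break
    end0 <- pos - 1L
    if (end0 == 0L) break
  }
  if (end0 == 0L && n > 0L)
    return(new_trim_result(read$read_id, 0L, 0L, TRUE, "adapter"))
  new_trim_result(read$read_id, 0L, end0, FALSE,
                  if (end0 < n) "adapter" else character())
}

subset_read <- function(read, start0, end0) {
  quality_read(read$read_id,
               if (end0 > start0) substr(read$bases, start0 + 1L, end0) else "",
               read$quals[seq_len(end0 - start0) + start0])
}

#' Full trimming of a single read
#'
#' Applies quality trimming, terminal ambiguity trimming, and adapter removal
#' in that order and composes the stage intervals into one kept interval on
#' the original read.
#'
#' @inheritParams quality_trim
#' @return a `trim_result` with coordinates into the original read.
#' @export
trim_read <- function(read, spec = trim_spec()) {
  q <- quality_trim(read, spec)
  if (q$discarded) return(q)
  offset <- q$kept_start
  stages <- q$stages
  r1 <- subset_read(read, q$kept_start, q$kept_end)
  a <- ambiguity_trim(r1, spec)
  stages <- union(stages, a$stages)
  if (a$discarded)
    return(new_trim_result(read$read_id, 0L, 0L, TRUE, stages))
  offset <- offset + a$kept_start
  r2 <- subset_read(r1, a$kept_start, a$kept_end)
  d <- adapter_trim(r2, spec)
  stages <- union(stages, d$stages)
  if (d$discarded)
    return(new_trim_result(read$read_id, 0L, 0L, TRUE, stages))
  new_trim_result(read$read_id, offset + d$kept_start, offset + d$kept_end,
                  FALSE, stages)
}

read_fastq_records <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.table(read_id = character(), bases = character(),
                      quals = character()))
  }
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4",
                 path, length(lines)), call. = FALSE)
  ids <- lines[seq(1L, length(lines), by = 4L)]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ record at line %d of '%s': header '%s'",
                 (bad[1] - 1L) * 4L + 1L, path, ids[bad[1]]), call. = FALSE)
  bases <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  if (any(nchar(bases) != nchar(quals))) {
    bad <- which(nchar(bases) != nchar(quals))[1]
    stop(sprintf("malformed FASTQ record '%s': sequence and quality lengths differ",
                 ids[bad]), call. = FALSE)
  }
  data.table(read_id = sub("^@", "", sub("\\s.*$", "", ids)),
             bases = toupper(bases), quals = quals)
}

qual_string_to_phred <- function(q) as.integer(utf8ToInt(q)) - 33L
phred_to_qual_string <- function(q) intToUtf8(as.integer(q) + 33L)

#' Trim a FASTQ file
#'
#' Runs the full trimming pipeline over every read of a FASTQ file
#' (Phred+33). Discarded reads are omitted from the output FASTQ but logged.
#'
#' @param in_fastq path to the input FASTQ.
#' @param spec a [trim_spec()].
#' @param out_fastq optional path for the trimmed FASTQ.
#' @param log_tsv optional path for the per-read TSV trim log.
#' @return (invisibly) a `data.table` log with columns `read_id`,
#'   `kept_start`, `kept_end` (0-based half-open), `discarded`, `stages`.
#' @export
trim_fastq <- function(in_fastq, spec = trim_spec(), out_fastq = NULL,
                       log_tsv = NULL) {
  rec <- read_fastq_records(in_fastq)
  n <- nrow(rec)
  log <- data.table(read_id = rec$read_id,
                    kept_start = integer(n), kept_end = integer(n),
                    discarded = logical(n), stages = character(n))
  out_seq <- character(n); out_qual <- character(n)
  if (n) {
    phreds <- lapply(rec$quals, qual_string_to_phred)
    # Stage 1+2 per read; adapter matching is batched below for speed.
    starts <- integer(n); ends <- integer(n); disc <- logical(n)
    stages <- vector("list", n)
    for (i in seq_len(n)) {
      rd <- quality_read(rec$read_id[i], rec$bases[i],
                         pmin(phreds[[i]], 60L))
      q <- quality_trim(rd, spec)
      if (q$discarded) {
        disc[i] <- TRUE; stages[[i]] <- q$stages; next
      }
      r1 <- subset_read(rd, q$kept_start, q$kept_end)
      a <- ambiguity_trim(r1, spec)
      stages[[i]] <- union(q$stages, a$stages)
      if (a$discarded) { disc[i] <- TRUE; next }
      starts[i] <- q$kept_start + a$kept_start
      ends[i] <- q$kept_start + a$kept_end
    }
    if (length(spec$adapters)) {
      live <- which(!disc)
      if (length(live)) {
        cut <- batch_adapter_cut(substr(rec$bases[live], starts[live] + 1L,
                                        ends[live]), spec)
        newly_disc <- cut$end0 == 0L
        stages[live] <- Map(function(s, hit) if (hit) union(s, "adapter") else s,
                            stages[live], cut$hit)
        ends[live] <- starts[live] + cut$end0
        disc[live][newly_disc] <- TRUE
        starts[live][newly_disc] <- 0L
        ends[live][newly_disc] <- 0L
      }
    }
    log$kept_start <- ifelse(disc, 0L, starts)
    log$kept_end <- ifelse(disc, 0L, ends)
    log$discarded <- disc
    log$stages <- vapply(stages, function(s)
      paste(s, collapse = ","), character(1))
    keep <- !disc & ends > starts
    out_seq <- substr(rec$bases, starts + 1L, ends)[keep]
    out_qual <- substr(rec$quals, starts + 1L, ends)[keep]
    kept_ids <- rec$read_id[keep]
  } else {
    keep <- logical(0); kept_ids <- character(0)
  }
  if (!is.null(out_fastq)) {
    con <- file(out_fastq, "wb")
    on.exit(close(con), add = TRUE)
    if (any(keep))
      writeLines(as.vector(rbind(paste0("@", kept_ids), out_seq,
                                 "+", out_qual)), con)
  }
  if (!is.null(log_tsv)) fwrite(log, log_tsv, sep = "\t")
  invisible(log)
}

# Vectorized adapter removal over many (already quality/ambiguity trimmed)
# read sequences: repeatedly aligns every adapter against all still-matching
# reads and cuts at the leftmost qualifying match.
batch_adapter_cut <- function(seqs, spec) {
  end0 <- nchar(seqs)
  hit_any <- logical(length(seqs))
  active <- which(end0 > 0L)
  mat <- sw_substitution_matrix(spec)
  while (length(active)) {
    cur <- substr(seqs[active], 1L, end0[active])
    cutpos <- rep(NA_integer_, length(active))
    for (ad in spec$adapters) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(cur),
        subject = Biostrings::DNAString(ad),
        type = "local", substitutionMatrix = mat,
        gapOpening = 0, gapExtension = -spec$sw_gap)
      sc <- Biostrings::score(aln)
      st <- IRanges::start(Biostrings::pattern(aln))
      ok <- sc >= spec$sw_min_score
      cutpos[ok] <- pmin(cutpos[ok], st[ok], na.rm = TRUE)
    }
    found <- !is.na(cutpos)
    if (!any(found)) break
    idx <- active[found]
    end0[idx] <- cutpos[found] - 1L
    hit_any[idx] <- TRUE
    active <- idx[end0[idx] > 0L]
  }
  list(end0 = end0, hit = hit_any)
}
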