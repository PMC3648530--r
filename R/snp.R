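# Neighborhood Quality Standard (NQS) biallelic SNP filtering over
# samtools-style text pileups, plus density summaries with sex-chromosome
# exclusion.

#' NQS SNP-filter parameters
#'
#' Defaults are the published parameter set: analysis window 11 bp, minimum
#' central and window-average quality 20, at most 2 gaps+mismatches per read
#' window, qualified coverage between 10X and 60X, minimum variant frequency
#' 35%, biallelic columns only.
#'
#' @param window odd analysis window size in bp (>= 3).
#' @param min_central_qual minimum Phred quality of the candidate base.
#' @param min_avg_qual minimum mean Phred quality over the read's window.
#' @param max_gap_mismatch maximum gaps + mismatches (excluding the candidate
#'   position itself) within the read's window.
#' @param min_coverage,max_coverage qualified-read depth gates.
#' @param min_variant_freq minimum alternate-allele fraction among qualified
#'   reads.
#' @param biallelic_only require exactly two alleles among qualified reads.
#' @return an object of class `snp_filter_params`.
#' @export
snp_filter_params <- function(window = 11L, min_central_qual = 20,
                              min_avg_qual = 20, max_gap_mismatch = 2L,
                              min_coverage = 10L, max_coverage = 60L,
                              min_variant_freq = 0.35,
                              biallelic_only = TRUE) {
  assert_count(window, "window", min = 3L)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  assert_count(max_gap_mismatch, "max_gap_mismatch")
  assert_count(min_coverage, "min_coverage", min = 1L)
  assert_count(max_coverage, "max_coverage", min = 1L)
  if (min_coverage > max_coverage)
    stop("min_coverage must be <= max_coverage", call. = FALSE)
  stop_if_not_scalar_prob(min_variant_freq, "min_variant_freq")
  if (min_variant_freq <= 0)
    stop("`min_variant_freq` must be > 0", call. = FALSE)
  structure(list(window = as.integer(window),
                 min_central_qual = min_central_qual,
                 min_avg_qual = min_avg_qual,
                 max_gap_mismatch = as.integer(max_gap_mismatch),
                 min_coverage = as.integer(min_coverage),
                 max_coverage = as.integer(max_coverage),
                 min_variant_freq = min_variant_freq,
                 biallelic_only = isTRUE(biallelic_only)),
            class = "snp_filter_params")
}

#' Parse a samtools-style 6-column text pileup into threaded observations
#'
#' Reads the text pileup (contig, 1-based position, reference base, depth,
#' base string, quality string) and threads read identities through
#' consecutive columns using the `^`/`$` read start/end markers, assuming the
#' samtools convention for coordinate-sorted input: continuing reads appear
#' before newly started reads in each column. Insertions/deletions attached
#' with `+n`/`-n` are skipped (indel calling is out of scope); `*` is kept as
#' a gap observation.
#'
#' @param path path to the pileup file, or a character vector of pileup lines
#'   via `text =`.
#' @param text optional character vector of pileup lines (overrides `path`).
#' @return a `data.table` of per-read per-column observations: `contig_id`,
#'   `pos`, `ref`, `depth`, `uid` (threaded read id), `base`, `qual`,
#'   `is_gap`.
#' @export
parse_pileup <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  if (!length(lines))
    return(data.table(contig_id = character(), pos = integer(),
                      ref = character(), depth = integer(), uid = integer(),
                      base = character(), qual = integer(),
                      is_gap = logical()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    stop(sprintf("malformed pileup line %d: expected 6 columns, found %d",
                 which(nf != 6L)[1], nf[nf != 6L][1]), call. = FALSE)
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  contig <- m[, 1]; pos <- as.integer(m[, 2]); ref <- m[, 3]
  depth <- as.integer(m[, 4]); bstr <- m[, 5]; qstr <- m[, 6]
  if (anyNA(pos) || anyNA(depth))
    stop("malformed pileup: non-numeric position or depth", call. = FALSE)
  out <- vector("list", length(lines))
  active <- integer(0)            # uids of reads continuing from previous col
  next_uid <- 1L
  last_contig <- ""
  last_pos <- -1L
  for (i in seq_along(lines)) {
    if (contig[i] != last_contig) {
      active <- integer(0)
      last_pos <- -1L
    } else if (pos[i] < last_pos) {
      stop(sprintf("pileup not sorted at line %d (%s:%d)", i, contig[i],
                   pos[i]), call. = FALSE)
    } else if (pos[i] > last_pos + 1L) {
      active <- integer(0)        # coverage gap: reads cannot span it
    }
    last_contig <- contig[i]
    last_pos <- pos[i]
    ch <- strsplit(bstr[i], "", fixed = TRUE)[[1]]
    quals <- qual_string_to_phred(qstr[i])
    bases <- character(depth[i]); gaps <- logical(depth[i])
    uids <- integer(depth[i]); ends <- logical(depth[i])
    slot <- 0L; k <- 1L; n_new <- 0L
    while (k <= length(ch)) {
      c0 <- ch[k]
      if (c0 == "^") {            # read start: mapq char + base follow
        slot <- slot + 1L
        uids[slot] <- next_uid
        next_uid <- next_uid + 1L
        n_new <- n_new + 1L
        k <- k + 2L
        c0 <- ch[k]
      } else if (c0 == "+" || c0 == "-") {   # indel attached to previous obs
        nd <- regmatches(substr(bstr[i], k + 1L, nchar(bstr[i])),
                         regexpr("^[0-9]+", substr(bstr[i], k + 1L,
                                                   nchar(bstr[i]))))
        ilen <- as.integer(nd)
        k <- k + 1L + nchar(nd) + ilen
        next
      } else {
        slot <- slot + 1L
        if (slot - n_new > length(active))
          stop(sprintf("pileup line %d: more continuing reads than active",
                       i), call. = FALSE)
        uids[slot] <- if (slot <= length(active)) active[slot] else {
          # started without ^ marker (shouldn't happen); assign fresh uid
          next_uid <- next_uid + 1L
          next_uid - 1L
        }
      }
      if (c0 == "$") stop(sprintf("pileup line %d: dangling '$'", i),
                          call. = FALSE)
      up <- toupper(c0)
      bases[slot] <- if (up %in% c(".", ",")) toupper(ref[i]) else up
      gaps[slot] <- up == "*"
      if (k < length(ch) && ch[k + 1L] == "$") {
        ends[slot] <- TRUE
        k <- k + 1L
      }
      k <- k + 1L
    }
    if (slot != depth[i])
      stop(sprintf("pileup line %d: %d observations but depth %d", i, slot,
                   depth[i]), call. = FALSE)
    if (length(quals) != depth[i])
      stop(sprintf("pileup line %d: quality string length mismatch", i),
           call. = FALSE)
    out[[i]] <- data.table(contig_id = contig[i], pos = pos[i],
                           ref = toupper(ref[i]), depth = depth[i],
                           uid = uids, base = bases, qual = quals,
                           is_gap = gaps, masked = ref[i] == "N" ||
                             ref[i] %in% letters)
    active <- uids[!ends]
  }
  rbindlist(out)[]
}

#' Call biallelic SNPs with the Neighborhood Quality Standard filter
#'
#' A read's observation at a column qualifies only if the central base
#' quality is at least `min_central_qual`, the mean quality over the read's
#' bases within the centered window (clipped at read ends) is at least
#' `min_avg_qual`, and the read carries at most `max_gap_mismatch`
#' mismatches plus gaps within that window (the candidate position itself is
#' not counted). A column yields a call only if the qualified depth lies
#' within the coverage gates, exactly two alleles are seen among qualified
#' reads (reference plus one alternate), and the alternate fraction is at
#' least `min_variant_freq`. Columns whose reference base is masked (N or
#' lowercase) are skipped.
#'
#' @param pileup observation table from [parse_pileup()].
#' @param params a [snp_filter_params()].
#' @return a `data.table` of calls: `contig_id`, `pos`, `ref`, `alt`,
#'   `depth` (qualified), `alt_fraction`.
#' @export
call_snps <- function(pileup, params = snp_filter_params()) {
  stopifnot(inherits(params, "snp_filter_params"))
  pileup <- as.data.table(pileup)
  empty <- data.table(contig_id = character(), pos = integer(),
                      ref = character(), alt = character(), depth = integer(),
                      alt_fraction = numeric())
  if (nrow(pileup) == 0L) return(empty)
  unsorted <- pileup[, .(bad = is.unsorted(pos)), by = contig_id]
  if (any(unsorted$bad))
    stop("pileup must be sorted by contig and position", call. = FALSE)
  half <- params$window %/% 2L
  obs <- copy(pileup)
  if (!"masked" %in% names(obs)) obs[, masked := FALSE]
  obs[, mm := (!is_gap & base != ref) | is_gap]
  obs[, qn := as.numeric(qual)]
  # per (contig, read) window statistics via cumulative sums over the read's
  # consecutive columns
  setorder(obs, contig_id, uid, pos)
  obs[, idx := seq_len(.N), by = .(contig_id, uid)]
  obs[, `:=`(cq = cumsum(qn), cm = cumsum(mm)), by = .(contig_id, uid)]
  obs[, nread := .N, by = .(contig_id, uid)]
  obs[, `:=`(lo = pmax(1L, idx - half), hi = pmin(nread, idx + half))]
  grp <- obs[, {
    cq0 <- c(0, cq); cm0 <- c(0, cm)
    .(pos = pos, wq = (cq0[hi + 1L] - cq0[lo]) / (hi - lo + 1L),
      wm = cm0[hi + 1L] - cm0[lo] - mm,      # exclude the candidate base
      central = qual, base = base, is_gap = is_gap, ref = ref,
      masked = masked)
  }, by = .(contig_id, uid)]
  grp[, pass := central >= params$min_central_qual &
        wq >= params$min_avg_qual & wm <= params$max_gap_mismatch & !is_gap]
  qual_obs <- grp[pass == TRUE & masked == FALSE]
  if (nrow(qual_obs) == 0L) return(empty)
  calls <- qual_obs[, {
    d <- .N
    alleles <- unique(base)
    alt_alleles <- setdiff(alleles, ref[1])
    ok <- d >= params$min_coverage & d <= params$max_coverage
    if (params$biallelic_only)
      ok <- ok && length(alleles) == 2L && ref[1] %in% alleles
    if (ok && length(alt_alleles) == 1L) {
      af <- sum(base == alt_alleles) / d
      if (af >= params$min_variant_freq)
        .(ref = ref[1], alt = alt_alleles, depth = d, alt_fraction = af)
      else NULL
    } else NULL
  }, by = .(contig_id, pos)]
  if (nrow(calls) == 0L) return(empty)
  setorder(calls, contig_id, pos)[]
}

#' SNP density per kilobase with sex-chromosome exclusion
#'
#' `density = total calls / total mapped non-excluded bp * 1000`, computed
#' over contigs with a chromosome assignment; calls on contigs mapped to
#' excluded chromosomes (by default Z and W, optionally carrying a GGA/TGU
#' prefix) are left out of the headline figure and reported separately.
#'
#' @param calls SNP call table from [call_snps()] (needs `contig_id`).
#' @param contig_lengths data.frame with `contig_id`, `length`.
#' @param chrom_map data.frame with `contig_id`, `sseqid`; may be partial.
#' @param excluded chromosome names to exclude (default Z and W).
#' @return list with `density_per_kb` (headline autosomal figure),
#'   `per_chromosome` table, and counts of excluded and unmapped calls.
#' @export
snp_density <- function(calls, contig_lengths, chrom_map,
                        excluded = c("Z", "W")) {
  calls <- as.data.table(calls)
  contig_lengths <- as.data.table(contig_lengths)
  chrom_map <- as.data.table(chrom_map)
  if (nrow(calls) &&
      !all(calls$contig_id %chin% contig_lengths$contig_id))
    stop("call on a contig with no recorded length", call. = FALSE)
  strip <- function(x) sub("^(GGA|TGU)", "", x)
  map <- merge(contig_lengths, chrom_map, by = "contig_id", all.x = TRUE)
  map[, excluded_chrom := !is.na(sseqid) & strip(sseqid) %in% excluded]
  counts <- calls[, .(n_snps = .N), by = contig_id]
  map <- merge(map, counts, by = "contig_id", all.x = TRUE)
  map[is.na(n_snps), n_snps := 0L]
  mapped <- map[!is.na(sseqid) & excluded_chrom == FALSE]
  dens <- if (nrow(mapped) && sum(mapped$length) > 0)
    sum(mapped$n_snps) / sum(as.numeric(mapped$length)) * 1000 else 0
  per_chrom <- map[!is.na(sseqid),
                   .(n_snps = sum(n_snps), total_bp = sum(as.numeric(length)),
                     density_per_kb = sum(n_snps) /
                       sum(as.numeric(length)) * 1000),
                   by = sseqid][order(sseqid)]
  list(density_per_kb = dens,
       per_chromosome = per_chrom,
       n_excluded_calls = map[excluded_chrom == TRUE, sum(n_snps)],
       n_unmapped_calls = map[is.na(sseqid), sum(n_snps)])
}

#' Write SNP calls as a minimal VCF
#'
#' Fixed header, unphased heterozygous genotypes, no INFO beyond depth and
#' allele frequency.
#'
#' @param calls call table from [call_snps()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_snp_vcf <- function(calls, path) {
  calls <- as.data.table(calls)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=divergescan",
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Qualified read depth">',
           '##INFO=<ID=AF,Number=1,Type=Float,Description="Alternate allele fraction">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample")
  body <- if (nrow(calls)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f\tGT\t0/1",
    calls$contig_id, calls$pos, calls$ref, calls$alt, calls$depth,
    calls$alt_fraction) else character()
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}
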