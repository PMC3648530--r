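# Independent brute-force oracles. These deliberately re-derive every rule
# from first principles (loops, exhaustive enumeration) and never call the
# implementation paths they check.

# Maximum-sum contiguous substring by exhaustive O(n^2) enumeration over all
# (i, j); returns the best sum (0 if every substring is negative).
bf_max_subsum <- function(s) {
  best <- 0
  n <- length(s)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in i:n) {
      acc <- acc + s[j]
      if (acc > best) best <- acc
    }
  }
  best
}

# Smith-Waterman local alignment score by direct dynamic programming with
# linear gap penalties; returns the maximal cell score and the 1-based start
# column (read position) of the best-scoring local alignment.
bf_sw <- function(read, adapter, match = 1, mismatch = -2, gap = -3) {
  a <- strsplit(adapter, "")[[1]]
  b <- strsplit(read, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  back_j <- matrix(0L, n + 1, m + 1)   # read start backtracked per cell
  for (j in seq_len(m) + 1L) back_j[1, j] <- j   # alignment starting fresh
  back_j[1, 1] <- 1L
  best <- 0; best_start <- NA_integer_; best_j <- Inf
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      sub <- H[i - 1, j - 1] +
        if (a[i - 1] == b[j - 1] && a[i - 1] != "N") match else mismatch
      del <- H[i - 1, j] + gap
      ins <- H[i, j - 1] + gap
      sc <- max(0, sub, del, ins)
      H[i, j] <- sc
      back_j[i, j] <- if (sc == 0) j else if (sc == sub) back_j[i - 1, j - 1]
        else if (sc == del) back_j[i - 1, j] else back_j[i, j - 1]
      if (sc > best || (sc == best && back_j[i, j] < best_j)) {
        if (sc > 0) { best <- sc; best_j <- back_j[i, j] }
      }
    }
  }
  list(score = best,
       start = if (best > 0) as.integer(best_j) else NA_integer_)
}

# Literal single-pass top-hit selection: scan every hit of a query, keeping
# the better one under (evalue asc, bitscore desc, length desc, sseqid asc,
# sstart asc).
bf_top_hit <- function(hits) {
  best <- NULL
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (is.null(best)) { best <- h; next }
    better <- FALSE
    if (h$evalue < best$evalue) better <- TRUE
    else if (h$evalue == best$evalue) {
      if (h$bitscore > best$bitscore) better <- TRUE
      else if (h$bitscore == best$bitscore) {
        if (h$length > best$length) better <- TRUE
        else if (h$length == best$length) {
          if (h$sseqid < best$sseqid) better <- TRUE
          else if (h$sseqid == best$sseqid && h$sstart < best$sstart)
            better <- TRUE
        }
      }
    }
    if (better) best <- h
  }
  best
}

# Literal application of every NQS rule, read by read, column by column.
bf_snp_calls <- function(obs, params) {
  obs <- as.data.frame(obs)
  half <- params$window %/% 2
  out <- list()
  for (cid in unique(obs$contig_id)) {
    co <- obs[obs$contig_id == cid, ]
    for (p in sort(unique(co$pos))) {
      col <- co[co$pos == p, ]
      if (isTRUE(col$masked[1])) next
      ref <- col$ref[1]
      passing <- character(0)
      for (r in seq_len(nrow(col))) {
        rd <- co[co$uid == col$uid[r], ]
        if (col$is_gap[r]) next
        if (col$qual[r] < params$min_central_qual) next
        win <- rd[rd$pos >= p - half & rd$pos <= p + half, ]
        if (mean(win$qual) < params$min_avg_qual) next
        mm <- sum((win$base != win$ref | win$is_gap) & win$pos != p)
        if (mm > params$max_gap_mismatch) next
        passing <- c(passing, col$base[r])
      }
      d <- length(passing)
      if (d < params$min_coverage || d > params$max_coverage) next
      alleles <- unique(passing)
      if (params$biallelic_only && !(length(alleles) == 2 && ref %in% alleles))
        next
      alt <- setdiff(alleles, ref)
      if (length(alt) != 1) next
      af <- sum(passing == alt) / d
      if (af < params$min_variant_freq) next
      out[[length(out) + 1]] <- data.frame(
        contig_id = cid, pos = p, ref = ref, alt = alt, depth = d,
        alt_fraction = af)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(contig_id = character(), pos = integer(), ref = character(),
               alt = character(), depth = integer(), alt_fraction = numeric())
}

# Spearman via explicit average ranks followed by a plain Pearson formula.
bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Random quality read for property tests.
random_read <- function(len, id = "r") {
  quality_read(id,
               paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""),
               sample(0:45, len, replace = TRUE))
}

# Random BLAST-like hit table with heavy tie structure to exercise
# tie-breaking.
random_hit_table <- function(n_queries, max_hits = 6) {
  rows <- list()
  for (q in seq_len(n_queries)) {
    k <- sample.int(max_hits, 1)
    len <- sample(c(50L, 200L, 800L), k, replace = TRUE)
    ev <- sample(c(0, 1e-60, 1e-30, 1e-5), k, replace = TRUE)
    rows[[q]] <- data.frame(
      qseqid = sprintf("q%04d", q),
      sseqid = sample(c("chr1", "chr2", "chrZ"), k, replace = TRUE),
      pident = round(runif(k, 60, 100), 2),
      length = len,
      mismatch = 0L, gapopen = 0L,
      qstart = 1L, qend = len,
      sstart = sample.int(1e6, k), send = sample.int(1e6, k),
      evalue = ev,
      bitscore = sample(c(100, 400, 500), k, replace = TRUE))
  }
  do.call(rbind, rows)
}

# A handcrafted clean pileup column set: `n_ref` reference reads and `n_alt`
# alternate reads of given quality spanning 2*half+1 columns around `pos`.
make_clean_pileup <- function(n_ref, n_alt, q = 30, contig = "c1",
                              pos = 10L, half = 5L, ref = "A", alt = "G") {
  reads <- list()
  uid <- 0L
  span <- (pos - half):(pos + half)
  for (i in seq_len(n_ref + n_alt)) {
    uid <- uid + 1L
    b <- rep(ref, length(span))
    if (i > n_ref) b[span == pos] <- alt
    reads[[uid]] <- data.frame(contig_id = contig, pos = span, ref = ref,
                               depth = n_ref + n_alt, uid = uid, base = b,
                               qual = q, is_gap = FALSE, masked = FALSE)
  }
  out <- do.call(rbind, reads)
  out[order(out$pos, out$uid), ]
}
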