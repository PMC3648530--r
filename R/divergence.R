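# The composite divergence statistic (percent identity normalized by
# alignment length), percentile outlier calling, normality testing, and the
# quality-control recalculations that probe outlier robustness.

#' Composite divergence score
#'
#' Percent identity normalized for alignment length:
#' `score = (pident/100) / length`. Small values indicate extended
#' conservation (high identity over a long alignment); large values indicate
#' putative divergence, with the distribution maximum 1/19 = 0.052631579
#' attained by a 19-bp alignment at 100% identity.
#'
#' @param pident percent identity in (0, 100\]. Vectorized.
#' @param length alignment length in bp, >= 1. Vectorized.
#' @return numeric score(s) in (0, 1\].
#' @export
#' @examples
#' composite_score(100, 19)   # 0.052631579, the maximal observable value
#' composite_score(74, 759)   # a typical genome-wide median alignment
composite_score <- function(pident, length) {
  if (!is.numeric(pident) || !is.numeric(length))
    stop("`pident` and `length` must be numeric", call. = FALSE)
  if (any(is.na(pident)) || any(pident <= 0 | pident > 100))
    stop("`pident` must lie in (0, 100]", call. = FALSE)
  if (any(is.na(length)) || any(length < 1))
    stop("`length` must be >= 1", call. = FALSE)
  (pident / 100) / length
}

#' Percentile outlier-calling parameters
#'
#' @param upper_percentile upper (divergence) percentile, default 99.98.
#' @param lower_percentile lower (conservation) percentile, default 0.02.
#' @param min_n minimum number of scores required; below this, percentile
#'   tails are meaningless and [call_outliers()] errors. Default 100.
#' @return an object of class `outlier_params`.
#' @export
outlier_params <- function(upper_percentile = 99.98, lower_percentile = 0.02,
                           min_n = 100L) {
  if (!(lower_percentile > 0 && lower_percentile < upper_percentile &&
        upper_percentile < 100))
    stop("need 0 < lower_percentile < upper_percentile < 100", call. = FALSE)
  assert_count(min_n, "min_n", min = 2L)
  structure(list(upper_percentile = upper_percentile,
                 lower_percentile = lower_percentile,
                 min_n = as.integer(min_n)),
            class = "outlier_params")
}

#' Call conserved and diverged outlier contigs by nearest-rank percentiles
#'
#' Interval bounds are placed at the nearest-rank percentiles (value at index
#' `ceiling(p/100 * n)` of the ascending ordered scores). A contig is an
#' outlier when its score is *equal to or more extreme* than a bound: scores
#' at or below the lower bound are conserved outliers, scores at or above the
#' upper bound are diverged outliers. The tie rule matters because diverged
#' contigs frequently share identical scores (short perfect alignments).
#'
#' @param scores either a numeric vector named by contig, or a data.frame
#'   with columns `contig_id` and `score`.
#' @param params an [outlier_params()].
#' @return an object of class `outlier_report`: list with `lower_bound`,
#'   `upper_bound`, `conserved` and `diverged` contig-id character vectors,
#'   `n_total`, and the params used.
#' @export
call_outliers <- function(scores, params = outlier_params()) {
  stopifnot(inherits(params, "outlier_params"))
  if (is.data.frame(scores)) {
    ids <- as.character(scores$contig_id)
    x <- as.numeric(scores$score)
  } else {
    x <- as.numeric(scores)
    ids <- names(scores) %||% as.character(seq_along(x))
  }
  n <- length(x)
  if (n < params$min_n)
    stop(sprintf("need at least %d scores to place %g/%g percentile bounds (got %d)",
                 params$min_n, params$lower_percentile,
                 params$upper_percentile, n), call. = FALSE)
  if (anyNA(x)) stop("scores contain NA", call. = FALSE)
  sx <- sort(x)
  lower <- sx[nearest_rank_index(params$lower_percentile, n)]
  upper <- sx[nearest_rank_index(params$upper_percentile, n)]
  if (lower == upper)
    stop("degenerate score distribution: percentile bounds coincide",
         call. = FALSE)
  structure(list(lower_bound = lower, upper_bound = upper,
                 conserved = ids[x <= lower], diverged = ids[x >= upper],
                 n_total = n, params = params),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report: n = %d, bounds [%.6g, %.6g]\n",
              x$n_total, x$lower_bound, x$upper_bound))
  cat(sprintf("  conserved outliers: %d\n", length(x$conserved)))
  cat(sprintf("  diverged outliers:  %d\n", length(x$diverged)))
  invisible(x)
}

# Kolmogorov-Smirnov D against a normal with mean/sd estimated from the
# sample (the statistic of the Lilliefors test).
lilliefors_D <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  i <- seq_len(n)
  max(i / n - p, p - (i - 1) / n)
}

#' Monte-Carlo null distribution of the Lilliefors statistic
#'
#' The null distribution of the Lilliefors D depends only on the sample size,
#' so it can be computed once and reused across many tests of equally sized
#' samples.
#'
#' @param n sample size.
#' @param nrep number of Monte-Carlo replicates (default 10000).
#' @param seed RNG seed.
#' @return sorted numeric vector of `nrep` null D statistics.
#' @export
lilliefors_null <- function(n, nrep = 10000L, seed = 1L) {
  assert_count(n, "n", min = 4L)
  assert_count(nrep, "nrep", min = 100L)
  with_seed(seed, {
    sort(vapply(seq_len(nrep), function(i) lilliefors_D(rnorm(n)),
                numeric(1)))
  })
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' KS distance between the sample and a normal distribution whose mean and
#' standard deviation are estimated from the sample, with the p-value taken
#' from a seeded Monte-Carlo null (required because the parameters are
#' estimated; the classical KS null would be anti-conservative).
#'
#' @param x numeric sample, n >= 10, non-zero variance.
#' @param nrep Monte-Carlo replicates when `null` is not supplied.
#' @param seed RNG seed for the Monte-Carlo null.
#' @param null optional precomputed null from [lilliefors_null()] for
#'   `length(x)`.
#' @return list with `statistic` (D), `p_value`, and `n`.
#' @export
lilliefors_normality <- function(x, nrep = 10000L, seed = 1L, null = NULL) {
  x <- as.numeric(x)
  if (length(x) < 10L) stop("need n >= 10", call. = FALSE)
  if (anyNA(x)) stop("sample contains NA", call. = FALSE)
  if (sd(x) == 0) stop("zero-variance sample", call. = FALSE)
  D <- lilliefors_D(x)
  if (is.null(null)) null <- lilliefors_null(length(x), nrep, seed)
  p <- (1 + sum(null >= D)) / (length(null) + 1)
  list(statistic = D, p_value = p, n = length(x))
}

#' Recompute the composite score of a conserved outlier over multiple hits
#'
#' For large conserved contigs the top hit alone may under-use the alignment
#' evidence; pooling all non-overlapping syntenic hits recalculates the score
#' via summation: pooled identical bases divided by the square of the total
#' alignment length,
#' `(sum(pident/100 * length)) / (sum(length))^2`.
#' With a single hit this reduces exactly to [composite_score()]; appending
#' additional aligned length at comparable identity moves the score further
#' left (more extreme conservation).
#'
#' @param hits data.frame with columns `pident`, `length`, and (for the
#'   overlap check) `qstart`, `qend`. At least one row.
#' @return the pooled score (single numeric).
#' @export
recompute_conserved_multi <- function(hits) {
  hits <- as.data.table(hits)
  if (nrow(hits) == 0L) stop("need at least one hit", call. = FALSE)
  if (any(hits$pident <= 0 | hits$pident > 100) || any(hits$length < 1))
    stop("invalid pident/length", call. = FALSE)
  if (all(c("qstart", "qend") %in% names(hits)) && nrow(hits) > 1L) {
    iv <- hits[order(qstart)]
    if (any(iv$qstart[-1] <= iv$qend[-nrow(iv)]))
      stop("hits overlap on the query; pooling requires non-overlapping hits",
           call. = FALSE)
  }
  sum(hits$pident / 100 * hits$length) / sum(hits$length)^2
}

#' Refute diverged outliers with alternate alignment evidence
#'
#' A diverged outlier is removed from the report iff an alternate hit for it
#' is longer than the original top hit, more significant (lower E-value), and
#' its recomputed composite score falls strictly inside the report's interval
#' bounds -- i.e. better evidence firmly places the contig back inside the
#' bulk of the distribution. Removals are logged with their evidence.
#'
#' @param report an [call_outliers()] report.
#' @param alternate_hits hit table of alternate alignments keyed by `qseqid`.
#' @param original_hits the top hits originally used, keyed by `qseqid` (for
#'   the longer/more-significant comparison).
#' @return the filtered `outlier_report`, with a `refuted` data.table listing
#'   each removed contig and its evidence.
#' @export
refute_outliers <- function(report, alternate_hits, original_hits) {
  stopifnot(inherits(report, "outlier_report"))
  alternate_hits <- as.data.table(alternate_hits)
  original_hits <- as.data.table(original_hits)
  refuted <- data.table(contig_id = character(), alt_length = integer(),
                        alt_pident = numeric(), alt_evalue = numeric(),
                        new_score = numeric())
  if (nrow(alternate_hits)) {
    for (cid in report$diverged) {
      alts <- alternate_hits[qseqid == cid]
      orig <- original_hits[qseqid == cid]
      if (nrow(alts) == 0L || nrow(orig) == 0L) next
      orig <- orig[order_hits(orig)][1L]
      alts <- alts[length > orig$length & evalue < orig$evalue]
      if (nrow(alts) == 0L) next
      alts[, new_score := composite_score(pident, length)]
      ok <- alts[new_score > report$lower_bound &
                 new_score < report$upper_bound]
      if (nrow(ok)) {
        best <- ok[order_hits(ok)][1L]
        refuted <- rbind(refuted, data.table(
          contig_id = cid, alt_length = best$length,
          alt_pident = best$pident, alt_evalue = best$evalue,
          new_score = best$new_score))
      }
    }
  }
  report$diverged <- setdiff(report$diverged, refuted$contig_id)
  report$refuted <- refuted
  report
}
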