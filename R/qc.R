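# Quality-control battery: pairwise correlations among contig properties,
# contig-size percentile overlap with divergence outliers, and the chi-square
# SNP-enrichment test between outlier classes.

#' Pairwise correlations among contig properties
#'
#' Pearson r and Spearman rho (average-rank ties) for all unordered pairs of
#' the supplied columns; by default contig size, GC fraction, percent
#' identity, and alignment length.
#'
#' @param tab data.frame with the variables to correlate.
#' @param vars columns to use (default: all numeric columns).
#' @return a `data.table` with `var1`, `var2`, `pearson_r`, `spearman_rho`,
#'   `n`. Constant columns yield NA coefficients.
#' @export
pairwise_correlations <- function(tab, vars = NULL) {
  tab <- as.data.table(tab)
  if (is.null(vars))
    vars <- names(tab)[vapply(tab, is.numeric, logical(1))]
  if (length(vars) < 2L)
    stop("need at least two numeric variables", call. = FALSE)
  cc <- tab[stats::complete.cases(tab[, ..vars])]
  if (nrow(cc) < 3L) stop("need at least 3 complete rows", call. = FALSE)
  pairs <- utils::combn(vars, 2L)
  out <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    x <- cc[[pairs[1, j]]]; y <- cc[[pairs[2, j]]]
    const <- sd(x) == 0 || sd(y) == 0
    out[[j]] <- data.table(
      var1 = pairs[1, j], var2 = pairs[2, j],
      pearson_r = if (const) NA_real_ else cor(x, y),
      spearman_rho = if (const) NA_real_ else cor(x, y, method = "spearman"),
      n = length(x))
  }
  rbindlist(out)[]
}

#' Overlap between contig-size outliers and divergence outliers
#'
#' Applies the identical nearest-rank percentile rule to the full ordered
#' distribution of contig sizes, then intersects the size outliers (both
#' tails) with the divergence outliers (conserved plus diverged).
#'
#' @param contig_sizes numeric vector of contig sizes named by contig_id, or
#'   a data.frame with `contig_id` and `length`.
#' @param report a divergence [call_outliers()] report over the same contig
#'   universe.
#' @param params an [outlier_params()] (defaults to the report's own).
#' @return list with `size_outliers`, `divergence_outliers`, `overlap`
#'   (character vectors) and `n_overlap`.
#' @export
size_outlier_overlap <- function(contig_sizes, report, params = NULL) {
  stopifnot(inherits(report, "outlier_report"))
  if (is.data.frame(contig_sizes)) {
    sizes <- as.numeric(contig_sizes$length)
    names(sizes) <- as.character(contig_sizes$contig_id)
  } else sizes <- contig_sizes
  params <- params %||% report$params
  div_out <- union(report$conserved, report$diverged)
  if (!all(div_out %in% names(sizes)))
    stop("contig universes differ: divergence outliers missing from sizes",
         call. = FALSE)
  size_report <- call_outliers(sizes, params)
  size_out <- union(size_report$conserved, size_report$diverged)
  ov <- intersect(size_out, div_out)
  list(size_outliers = size_out, divergence_outliers = div_out,
       overlap = ov, n_overlap = length(ov))
}

#' Chi-square test of SNP enrichment between outlier classes
#'
#' Treats every base pair of each outlier class as a Bernoulli trial (SNP or
#' not) and tests homogeneity of the two proportions with a Pearson
#' chi-square on the 2x2 table \{conserved, diverged\} x \{SNP bp, non-SNP
#' bp\}, 1 df, no continuity correction.
#'
#' @param conserved,diverged numeric `c(snp_count, total_bp)` for each class.
#' @return list with the 2x2 `table`, `chi2`, `df`, `p_value`, per-class
#'   densities, and `expected_warning` when any expected cell is below 1.
#' @export
snp_enrichment_chisq <- function(conserved, diverged) {
  check <- function(x, nm) {
    if (length(x) != 2L || any(x < 0) || x[2] <= 0 || x[1] > x[2])
      stop(sprintf("`%s` must be c(snp_count, total_bp) with 0 <= snps <= bp > 0",
                   nm), call. = FALSE)
  }
  check(conserved, "conserved"); check(diverged, "diverged")
  tab <- rbind(conserved = c(snp = conserved[1],
                             non_snp = conserved[2] - conserved[1]),
               diverged = c(snp = diverged[1],
                            non_snp = diverged[2] - diverged[1]))
  N <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / N
  chi2 <- sum((tab - expected)^2 / expected)
  list(table = tab, chi2 = chi2, df = 1L,
       p_value = pchisq(chi2, df = 1L, lower.tail = FALSE),
       density_conserved = conserved[1] / conserved[2],
       density_diverged = diverged[1] / diverged[2],
       expected_warning = any(expected < 1))
}
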