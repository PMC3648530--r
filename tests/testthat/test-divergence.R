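test_that("composite_score matches its closed form and monotonicity", {
  expect_identical(round(composite_score(100, 19), 9), 0.052631579)
  expect_equal(composite_score(100, 1), 1.0)
  expect_equal(composite_score(74, 759), 0.74 / 759)
  expect_error(composite_score(100, 0), "length")
  expect_error(composite_score(0, 10), "pident")
  expect_error(composite_score(101, 10), "pident")
  # strictly decreasing in length, strictly increasing in pident
  lens <- seq(19, 5000, by = 37)
  expect_true(all(diff(composite_score(85, lens)) < 0))
  pids <- seq(1, 100, by = 0.5)
  expect_true(all(diff(composite_score(pids, 500)) > 0))
})

test_that("call_outliers places nearest-rank bounds with inclusive ties", {
  # enumerated order-statistics example: 10 distinct values, 90/10
  x <- setNames((1:10) / 10, paste0("c", 1:10))
  rep10 <- call_outliers(x, outlier_params(90, 10, min_n = 10))
  expect_equal(rep10$lower_bound, 0.1)
  expect_equal(rep10$upper_bound, 0.9)
  expect_equal(rep10$conserved, "c1")
  expect_equal(sort(rep10$diverged), c("c10", "c9"))
  # boundary ties are all included ("equal to or more extreme")
  y <- setNames(c(rep(1, 95), rep(9, 5)) / 10, paste0("t", 1:100))
  repy <- call_outliers(y, outlier_params(97, 3, min_n = 100))
  expect_equal(sort(repy$diverged), sort(paste0("t", 96:100)))
  # degenerate distribution errors
  expect_error(call_outliers(setNames(rep(0.5, 100), paste0("d", 1:100)),
                             outlier_params(min_n = 100)),
               "degenerate")
  # too few scores errors
  expect_error(call_outliers(x, outlier_params()), "at least")
  # permutation invariance
  set.seed(5)
  z <- setNames(runif(500), paste0("p", 1:500))
  r1 <- call_outliers(z, outlier_params(99, 1))
  zs <- sample(z)
  r2 <- call_outliers(zs, outlier_params(99, 1))
  expect_equal(sort(r1$conserved), sort(r2$conserved))
  expect_equal(sort(r1$diverged), sort(r2$diverged))
  expect_equal(r1$lower_bound, r2$lower_bound)
})

test_that("planted conserved/diverged contigs are recovered at defaults", {
  p <- sim_params(seed = 23, n_contigs = 5000)
  sc <- simulate_contigs(p)
  hits <- simulate_alignment_table(p, sc$truth)
  top <- evalue_stepdown(hits)
  scores <- data.frame(contig_id = top$qseqid,
                       score = composite_score(top$pident, top$length))
  rep <- call_outliers(scores, outlier_params())
  truth <- sc$truth
  planted_con <- truth$contig_id[truth$planted_class == "conserved"]
  planted_div <- truth$contig_id[truth$planted_class == "diverged"]
  sens_con <- mean(planted_con %in% rep$conserved)
  sens_div <- mean(planted_div %in% rep$diverged)
  expect_gte(sens_con, 0.95)
  expect_gte(sens_div, 0.95)
  bg <- truth$contig_id[truth$planted_class == "background"]
  fp <- sum(bg %in% c(rep$conserved, rep$diverged))
  expect_gte(1 - fp / length(bg), 0.999)
})

test_that("lilliefors statistic is affine invariant and detects skew", {
  set.seed(77)
  x <- rnorm(200, 5, 3)
  d1 <- lilliefors_normality(x, nrep = 500, seed = 1)$statistic
  d2 <- lilliefors_normality(3 * x + 10, nrep = 500, seed = 1)$statistic
  expect_equal(d1, d2, tolerance = 1e-12)
  # strongly right-skewed sample rejected hard
  e <- lilliefors_normality(rexp(1000), nrep = 2000, seed = 2)
  expect_lt(e$p_value, 0.001)
  expect_error(lilliefors_normality(rep(1, 50)), "variance")
  expect_error(lilliefors_normality(rnorm(5)), "n >= 10")
})

test_that("multi-hit summation pooling behaves as specified", {
  # single hit reduces exactly to composite_score
  one <- data.frame(pident = 95, length = 10000L, qstart = 1L, qend = 10000L)
  expect_equal(recompute_conserved_multi(one), composite_score(95, 10000))
  expect_equal(recompute_conserved_multi(one), 9.5e-05)
  # equal-identity second hit exacerbates conservation (score decreases)
  two <- rbind(one, data.frame(pident = 95, length = 5000L,
                               qstart = 12000L, qend = 16999L))
  expect_lt(recompute_conserved_multi(two), recompute_conserved_multi(one))
  # direct arithmetic: (200) / (200^2)
  pair <- data.frame(pident = c(100, 100), length = c(100L, 100L),
                     qstart = c(1L, 200L), qend = c(100L, 299L))
  expect_equal(recompute_conserved_multi(pair), 0.005)
  # overlapping query intervals are rejected
  bad <- data.frame(pident = c(95, 95), length = c(100L, 100L),
                    qstart = c(1L, 50L), qend = c(100L, 149L))
  expect_error(recompute_conserved_multi(bad), "overlap")
  # pooling monotonicity: appending a hit with identity fraction <= pooled
  # fraction strictly decreases the pooled score
  set.seed(31)
  for (i in 1:30) {
    k <- sample(1:4, 1)
    lens <- sample(500:5000, k)
    pids <- runif(k, 80, 99)
    qs <- cumsum(lens + 100) - lens
    h <- data.frame(pident = pids, length = lens, qstart = qs,
                    qend = qs + lens - 1)
    pooled <- recompute_conserved_multi(h)
    pooled_ident <- sum(pids / 100 * lens) / sum(lens)
    extra_pid <- runif(1, 50, pooled_ident * 100)
    h2 <- rbind(h, data.frame(pident = extra_pid,
                              length = 1000L,
                              qstart = max(h$qend) + 10,
                              qend = max(h$qend) + 1009))
    expect_lt(recompute_conserved_multi(h2), pooled)
  }
})

test_that("refute_outliers removes only firmly relocated diverged outliers", {
  set.seed(12)
  scores <- setNames(c(runif(498, 1e-4, 5e-3), 1 / 19, 1 / 20),
                     paste0("c", 1:500))
  rep0 <- call_outliers(scores, outlier_params(99.8, 0.2))
  expect_true(all(c("c499", "c500") %in% rep0$diverged))
  orig <- data.frame(qseqid = c("c499", "c500"), sseqid = "chr1",
                     pident = 100, length = c(19L, 20L), mismatch = 0L,
                     gapopen = 0L, qstart = 1L, qend = c(19L, 20L),
                     sstart = 1L, send = c(19L, 20L), evalue = 3.6,
                     bitscore = c(38, 40))
  # no alternate evidence: unchanged
  r_none <- refute_outliers(rep0, orig[0, ], orig)
  expect_equal(sort(r_none$diverged), sort(rep0$diverged))
  # longer, more significant alternate inside bounds removes c499
  alt <- data.frame(qseqid = "c499", sseqid = "chr1", pident = 90,
                    length = 1000L, mismatch = 100L, gapopen = 0L,
                    qstart = 1L, qend = 1000L, sstart = 1L, send = 1000L,
                    evalue = 1e-150, bitscore = 900)
  r1 <- refute_outliers(rep0, alt, orig)
  expect_false("c499" %in% r1$diverged)
  expect_true("c500" %in% r1$diverged)
  expect_equal(r1$refuted$contig_id, "c499")
  # alternate shorter than the original never removes
  alt_short <- transform(alt, length = 10L, qend = 10L, send = 10L)
  r2 <- refute_outliers(rep0, alt_short, orig)
  expect_true("c499" %in% r2$diverged)
})
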