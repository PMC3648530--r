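test_that("coverage gates and the derived clean-column call work", {
  params <- snp_filter_params()
  # depth 8, all passing: below min coverage, no call
  expect_equal(nrow(call_snps(make_clean_pileup(4, 4), params)), 0)
  # depth 70: above max coverage, no call
  expect_equal(nrow(call_snps(make_clean_pileup(35, 35), params)), 0)
  # depth 20, 10 ref + 10 alt, Q30, clean windows: one call at 0.5
  calls <- call_snps(make_clean_pileup(10, 10), params)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos, 10L)
  expect_equal(calls$ref, "A")
  expect_equal(calls$alt, "G")
  expect_equal(calls$depth, 20L)
  expect_equal(calls$alt_fraction, 0.5)
})

test_that("per-read NQS window rules gate observations", {
  params <- snp_filter_params()
  # low central quality on alt reads removes them from the qualified depth
  pu <- make_clean_pileup(10, 10)
  pu$qual[pu$pos == 10 & pu$base == "G"] <- 19
  expect_equal(nrow(call_snps(pu, params)), 0)
  # low window-average quality disqualifies
  pu2 <- make_clean_pileup(10, 10)
  pu2$qual[pu2$uid > 10] <- 15
  pu2$qual[pu2$pos == 10] <- 30          # central fine, window mean 15-ish
  expect_equal(nrow(call_snps(pu2, params)), 0)
  # >2 mismatches in an alt read's window disqualify it (candidate excluded)
  pu3 <- make_clean_pileup(10, 10)
  for (u in 11:20)
    pu3$base[pu3$uid == u & pu3$pos %in% c(6, 7, 8)] <- "T"
  expect_equal(nrow(call_snps(pu3, params)), 0)
  # exactly 2 extra mismatches still pass; the two mismatch columns are
  # themselves clean biallelic columns, so three calls result
  pu4 <- make_clean_pileup(10, 10)
  for (u in 11:20)
    pu4$base[pu4$uid == u & pu4$pos %in% c(6, 7)] <- "G"
  calls4 <- call_snps(pu4, params)
  expect_equal(nrow(calls4), 3)
  expect_true(10L %in% calls4$pos)
  # tri-allelic columns are never called
  pu5 <- make_clean_pileup(10, 10)
  pu5$base[pu5$uid %in% 16:20 & pu5$pos == 10] <- "C"
  expect_equal(nrow(call_snps(pu5, params)), 0)
  # masked reference columns are skipped
  pu6 <- make_clean_pileup(10, 10)
  pu6$masked <- TRUE
  expect_equal(nrow(call_snps(pu6, params)), 0)
  # variant frequency below threshold is not called
  pu7 <- make_clean_pileup(14, 6)        # alt fraction 0.30 < 0.35
  expect_equal(nrow(call_snps(pu7, params)), 0)
})

test_that("call_snps matches a literal brute-force on random small pileups", {
  set.seed(88)
  params <- snp_filter_params(min_coverage = 5L, max_coverage = 40L)
  for (trial in 1:8) {
    # random threaded observations over <= 50 columns
    L <- sample(20:50, 1)
    n_reads <- sample(8:25, 1)
    rl <- sample(8:15, 1)
    obs <- list()
    for (u in seq_len(n_reads)) {
      s <- sample.int(max(1L, L - rl + 1L), 1)
      pos <- s:(s + rl - 1)
      ref <- "A"
      base <- sample(c("A", "A", "A", "A", "G", "T"), rl, replace = TRUE)
      obs[[u]] <- data.frame(contig_id = "c1", pos = pos, ref = ref,
                             depth = 0L, uid = u, base = base,
                             qual = sample(10:40, rl, replace = TRUE),
                             is_gap = runif(rl) < 0.03, masked = FALSE)
    }
    obs <- do.call(rbind, obs)
    obs <- obs[order(obs$pos, obs$uid), ]
    got <- call_snps(obs, params)
    want <- bf_snp_calls(obs, params)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      got_df <- as.data.frame(got)
      rownames(got_df) <- rownames(want) <- NULL
      expect_equal(got_df[order(got_df$pos), ],
                   want[order(want$pos), ], tolerance = 1e-12)
    }
  }
})

test_that("tightening any threshold never increases the number of calls", {
  # monotonicity holds per threshold while the upper coverage gate is not
  # binding (tightening a per-read gate can otherwise pull an over-covered
  # column back under max_coverage); a loose max_coverage isolates the rule
  set.seed(99)
  p <- sim_params(seed = 99, n_contigs = 6, n_pileup_contigs = 3,
                  variant_fraction = 0.01, max_pileup_len = 1500L)
  sc <- simulate_contigs(p)
  pu <- simulate_pileup(p, sc$contigs)
  obs <- parse_pileup(text = pu$pileup)
  loose_max <- 10000L
  base <- snp_filter_params(max_coverage = loose_max)
  n0 <- nrow(call_snps(obs, base))
  tighter <- list(
    snp_filter_params(max_coverage = loose_max, min_central_qual = 30),
    snp_filter_params(max_coverage = loose_max, min_avg_qual = 30),
    snp_filter_params(max_coverage = loose_max, max_gap_mismatch = 0L),
    snp_filter_params(max_coverage = loose_max, min_coverage = 20L),
    snp_filter_params(max_coverage = loose_max, min_variant_freq = 0.45))
  for (tp in tighter)
    expect_lte(nrow(call_snps(obs, tp)), n0)
  # tightening max_coverage itself also never adds calls
  expect_lte(nrow(call_snps(obs, snp_filter_params(max_coverage = 60L))),
             n0)
  expect_lte(nrow(call_snps(obs, snp_filter_params(max_coverage = 40L))),
             nrow(call_snps(obs, snp_filter_params(max_coverage = 60L))))
})

test_that("planted clean variants are recovered from simulated pileups", {
  p <- sim_params(seed = 55, n_contigs = 12, n_pileup_contigs = 6,
                  variant_fraction = 0.008)
  sc <- simulate_contigs(p)
  pu <- simulate_pileup(p, sc$contigs)
  obs <- parse_pileup(text = pu$pileup)
  calls <- call_snps(obs, snp_filter_params())
  rec <- pu$truth[pu$truth$recoverable == TRUE, ]
  expect_gt(nrow(rec), 20)
  hit <- merge(rec, calls, by = c("contig_id", "pos"))
  expect_gte(nrow(hit) / nrow(rec), 0.95)
  # the planted alternate allele is the called one
  expect_true(all(hit$alt.x == hit$alt.y))
})

test_that("parse_pileup threads reads and rejects malformed input", {
  lines <- c("c1\t1\tA\t1\t^~.\tI",
             "c1\t2\tA\t2\t.^~G\tIC",
             "c1\t3\tA\t2\t.$G$\tID")
  obs <- parse_pileup(text = lines)
  expect_equal(nrow(obs), 5)
  expect_equal(obs$uid[obs$pos == 3], c(1L, 2L))
  expect_equal(obs$base[obs$uid == 2], c("G", "G"))
  expect_equal(obs$qual, c(40L, 40L, 34L, 40L, 35L))
  expect_error(parse_pileup(text = "c1\t1\tA\t2"), "6 columns")
  expect_error(parse_pileup(text = c("c1\t5\tA\t1\t^~.\tI",
                                     "c1\t4\tA\t1\t^~.\tI")),
               "sorted")
  expect_error(parse_pileup(text = "c1\t1\tA\t2\t^~.\tII"), "observations")
})

test_that("snp_density excludes sex chromosomes and partitions correctly", {
  calls <- data.frame(contig_id = c(rep("a", 1000), rep("z", 50)),
                      pos = 1, ref = "A", alt = "G", depth = 20,
                      alt_fraction = 0.5)
  lens <- data.frame(contig_id = c("a", "z", "u"),
                     length = c(1e6, 5e4, 1e4))
  map <- data.frame(contig_id = c("a", "z"), sseqid = c("GGA1", "GGAZ"))
  d <- snp_density(calls, lens, map)
  expect_equal(d$density_per_kb, 1.0)
  expect_equal(d$n_excluded_calls, 50)
  expect_equal(d$n_unmapped_calls, 0)
  # zero calls give zero density
  d0 <- snp_density(calls[0, ], lens, map)
  expect_equal(d0$density_per_kb, 0)
  # calls on unknown contigs are a consistency error
  expect_error(snp_density(transform(calls, contig_id = "ghost"), lens, map),
               "length")
})
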