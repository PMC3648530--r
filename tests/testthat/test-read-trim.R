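test_that("phred_to_perror follows the Phred relation and rejects negatives", {
  expect_equal(phred_to_perror(0), 1.0)
  expect_equal(phred_to_perror(10), 0.1)
  expect_equal(phred_to_perror(20), 0.01)
  expect_error(phred_to_perror(-1), "Phred")
})

test_that("quality_trim keeps the maximum-sum segment", {
  spec <- trim_spec(limit = 0.05)
  # all high quality: kept whole
  r <- quality_read("hi", strrep("A", 100), rep(40L, 100))
  res <- quality_trim(r, spec)
  expect_equal(c(res$kept_start, res$kept_end), c(0L, 100L))
  expect_false(res$discarded)
  # all Q2: P_error ~ 0.631 > limit, running sum never positive
  r2 <- quality_read("lo", strrep("A", 20), rep(2L, 20))
  expect_true(quality_trim(r2, spec)$discarded)
  # worked mixed case: the three Q40 bases survive
  r3 <- quality_read("mix", "AACCCA", c(2L, 2L, 40L, 40L, 40L, 2L))
  res3 <- quality_trim(r3, spec)
  expect_equal(c(res3$kept_start, res3$kept_end), c(2L, 5L))
  # empty read: empty result, not an error
  r0 <- quality_read("e", "", integer())
  expect_false(quality_trim(r0, spec)$discarded)
})

test_that("quality_trim segment score equals the exhaustive max-subsum oracle", {
  spec <- trim_spec(limit = 0.05)
  set.seed(101)
  for (i in 1:200) {
    len <- sample(1:80, 1)
    r <- random_read(len, sprintf("r%03d", i))
    s <- spec$limit - phred_to_perror(r$quals)
    res <- quality_trim(r, spec)
    got <- if (res$discarded) 0 else
      sum(s[(res$kept_start + 1):res$kept_end])
    expect_equal(got, bf_max_subsum(s), tolerance = 1e-12)
    expect_gte(got, 0)
  }
})

test_that("raising the limit never lowers the kept segment score", {
  set.seed(202)
  for (i in 1:50) {
    r <- random_read(sample(5:60, 1))
    score_at <- function(limit) {
      spec <- trim_spec(limit = limit)
      s <- limit - phred_to_perror(r$quals)
      res <- quality_trim(r, spec)
      if (res$discarded) 0 else sum(s[(res$kept_start + 1):res$kept_end])
    }
    expect_gte(score_at(0.2), score_at(0.05))
  }
})

test_that("ambiguity_trim removes terminal N runs and flags violations", {
  spec <- trim_spec(max_end_n = 3)
  qr <- function(b) quality_read("x", b, rep(30L, nchar(b)))
  a <- ambiguity_trim(qr("NNACGTNN"), spec)
  expect_equal(c(a$kept_start, a$kept_end), c(2L, 6L))
  expect_false("ambiguity_flag" %in% a$stages)
  b <- ambiguity_trim(qr("ACGT"), spec)
  expect_equal(c(b$kept_start, b$kept_end), c(0L, 4L))
  expect_length(b$stages, 0)
  # run of 4 exceeds the cap: still removed entirely, but flagged
  cc <- ambiguity_trim(qr("NNNNACGT"), spec)
  expect_equal(substr("NNNNACGT", cc$kept_start + 1, cc$kept_end), "ACGT")
  expect_true("ambiguity_flag" %in% cc$stages)
  # all-N read is discarded
  expect_true(ambiguity_trim(qr("NNNN"), spec)$discarded)
  # internal Ns beyond the cap flag but are not excised
  d <- ambiguity_trim(qr("ACNNNNCA"), spec)
  expect_equal(c(d$kept_start, d$kept_end), c(0L, 8L))
  expect_true("ambiguity_flag" %in% d$stages)
})

test_that("adapter_trim removes matches at or above threshold with 3' bases", {
  insert <- "GATTACAGATTACAGT"
  adapter <- "ACGTACGTAC"
  spec <- trim_spec(adapters = adapter, sw_min_score = nchar(adapter))
  qr <- function(b) quality_read("x", b, rep(30L, nchar(b)))
  # exact adapter + trailing bases: insert kept
  r <- qr(paste0(insert, adapter, "TTTT"))
  res <- adapter_trim(r, spec)
  expect_equal(substr(r$bases, res$kept_start + 1, res$kept_end), insert)
  # no adapter: unchanged
  res2 <- adapter_trim(qr(insert), spec)
  expect_equal(c(res2$kept_start, res2$kept_end), c(0L, nchar(insert)))
  expect_length(res2$stages, 0)
  # one internal mismatch at threshold len - 3: removed
  mm <- adapter
  substr(mm, 5, 5) <- "T"   # A -> T mismatch
  spec3 <- trim_spec(adapters = adapter,
                     sw_min_score = nchar(adapter) * 1 - 3)
  res3 <- adapter_trim(qr(paste0(insert, mm)), spec3)
  expect_equal(substr(r$bases, res3$kept_start + 1, res3$kept_end), insert)
  expect_true("adapter" %in% res3$stages)
})

test_that("adapter_trim agrees with a dynamic-programming SW oracle", {
  set.seed(303)
  adapter <- "ACGTTGCACA"
  spec <- trim_spec(adapters = adapter, sw_min_score = 8)
  for (i in 1:60) {
    r <- random_read(sample(20:60, 1))
    oracle <- bf_sw(r$bases, adapter)
    res <- adapter_trim(r, spec)
    if (oracle$score >= spec$sw_min_score) {
      expect_lte(res$kept_end, oracle$start - 1L)
    } else {
      expect_equal(res$kept_end, nchar(r$bases))
    }
  }
})

test_that("trim_fastq preserves order, logs discards, removes planted adapters", {
  tmp <- withr::local_tempdir()
  # empty file
  empty <- file.path(tmp, "empty.fastq"); file.create(empty)
  log0 <- trim_fastq(empty, trim_spec(),
                     out_fastq = file.path(tmp, "e.out.fastq"))
  expect_equal(nrow(log0), 0)
  expect_length(readLines(file.path(tmp, "e.out.fastq")), 0)
  # 3-read fixture with one all-Q2 read
  f3 <- file.path(tmp, "three.fastq")
  writeLines(c("@a", "ACGTACGTAC", "+", strrep("I", 10),
               "@b", "ACGTACGTAC", "+", strrep("#", 10),
               "@c", "ACGTACGTAC", "+", strrep("I", 10)), f3)
  out3 <- file.path(tmp, "three.out.fastq")
  log3 <- trim_fastq(f3, trim_spec(), out_fastq = out3)
  expect_equal(nrow(log3), 3)
  expect_equal(log3$read_id, c("a", "b", "c"))
  expect_equal(log3$discarded, c(FALSE, TRUE, FALSE))
  expect_equal(length(readLines(out3)), 8)
  # malformed record errors with the record named
  bad <- file.path(tmp, "bad.fastq")
  writeLines(c("@a", "ACGT", "+", "II"), bad)
  expect_error(trim_fastq(bad, trim_spec()), "malformed FASTQ")
  # planted adapters: >= 99% of planted adapter bases removed
  p <- sim_params(seed = 31, read_count = 2000)
  rd <- simulate_reads(p)
  fq <- file.path(tmp, "sim.fastq")
  write_fastq(rd$reads, fq)
  spec <- trim_spec(adapters = p$adapter_sequences,
                    sw_min_score = nchar(p$adapter_sequences))
  log <- trim_fastq(fq, spec)
  m <- merge(log, rd$truth, by = "read_id")
  pl <- m[!is.na(m$adapter_start), ]
  expect_gt(nrow(pl), 100)
  kept_adapter_bases <- pmax(0, pmin(pl$kept_end, pl$adapter_end) -
                                pmax(pl$kept_start + 1, pl$adapter_start) + 1)
  frac_removed <- 1 - sum(kept_adapter_bases) /
    sum(pl$adapter_end - pl$adapter_start + 1)
  expect_gte(frac_removed, 0.99)
})

test_that("the full trim pipeline is idempotent on simulated reads", {
  p <- sim_params(seed = 17, read_count = 300)
  rd <- simulate_reads(p)
  spec <- trim_spec(adapters = p$adapter_sequences,
                    sw_min_score = nchar(p$adapter_sequences))
  tmp <- withr::local_tempdir()
  f1 <- file.path(tmp, "a.fastq"); f2 <- file.path(tmp, "b.fastq")
  f3 <- file.path(tmp, "c.fastq")
  write_fastq(rd$reads, f1)
  trim_fastq(f1, spec, out_fastq = f2)
  trim_fastq(f2, spec, out_fastq = f3)
  expect_identical(readLines(f3), readLines(f2))
})
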