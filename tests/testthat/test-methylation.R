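test_that("CpG call round-trip and validation", {
  calls <- cpg_calls(c("chr1", "chr1", "chr2"), c(100, 250, 7),
                     c("+", "-", "+"), c(3, 0, 10), c(7, 5, 0))
  expect_equal(calls$cov, c(10, 5, 10))
  f <- tempfile(fileext = ".tsv")
  write_cpg_calls(calls, f)
  expect_equal(as.data.frame(read_cpg_calls(f)), as.data.frame(calls))

  # empty file -> empty set
  f0 <- tempfile(); writeLines(character(0), f0)
  expect_equal(nrow(read_cpg_calls(f0)), 0L)

  # malformed strand reported with its line number
  fbad <- tempfile()
  writeLines(c("chr1\t10\t+\t1\t2", "chr1\t20\t*\t1\t2"), fbad)
  expect_error(read_cpg_calls(fbad), "line 2")

  # duplicate positions per (chrom, strand) rejected
  expect_error(cpg_calls(c("chr1", "chr1"), c(5, 5), c("+", "+"),
                         c(1, 1), c(1, 1)), "unique")
})

test_that("methylation level pools coverage-weighted ratios", {
  calls <- cpg_calls(rep("chr1", 3), c(100, 200, 5000), rep("+", 3),
                     c(4, 1, 9), c(4, 1, 1))
  iv <- GRanges("chr1", IRanges(1, 1000))
  ml <- meth_level(calls, iv)
  expect_equal(ml$level, 5 / 10)  # (4+1)/(8+2)
  expect_equal(ml$n_cpgs, 2)

  # all fully methylated -> 1; empty interval -> NA, not 0
  full <- cpg_calls("chr1", 50, "+", 7, 0)
  expect_equal(meth_level(full, iv)$level, 1)
  expect_true(is.na(meth_level(calls, GRanges("chr1", IRanges(3000, 4000)))$level))

  # per-CpG mean variant differs when coverage is unequal
  ml2 <- meth_level(calls, iv, per_cpg_mean = TRUE)
  expect_equal(ml2$level, mean(c(4 / 8, 1 / 2)))

  # raising min_cov never gains CpGs
  n1 <- meth_level(calls, iv, min_cov = 1)$n_cpgs
  n5 <- meth_level(calls, iv, min_cov = 5)$n_cpgs
  expect_lte(n5, n1)
})

test_that("pooling identity holds on disjoint interval unions", {
  set.seed(8)
  calls <- simulate_cpg_calls("chr1", seq(10, 9990, by = 25), 0.4, 10)
  parts <- GRanges("chr1", IRanges(c(1, 3001, 7001), c(3000, 7000, 10000)))
  whole <- GRanges("chr1", IRanges(1, 10000))
  mp <- meth_level(calls, parts)
  mw <- meth_level(calls, whole)
  expect_equal(sum(mp$meth) / sum(mp$total), mw$level)
  expect_equal(sum(mp$n_cpgs), mw$n_cpgs)
})

test_that("planted methylation levels are recovered within binomial error", {
  set.seed(12)
  for (lvl in c(0.2, 0.5, 0.8)) {
    calls <- simulate_cpg_calls("chr1", seq(50, 200 * 50, by = 50), lvl, 10)
    est <- meth_level(calls, GRanges("chr1", IRanges(1, 2e5)))$level
    expect_equal(est, lvl, tolerance = 0.03)
  }
})

test_that("promoter CGI stratification uses half-open 1-bp overlap", {
  layout <- genome_layout("chr1", 1e5)
  tss <- GRanges("chr1", IRanges(c(20000, 60000), width = 1),
                 strand = "+")
  seqlengths(tss) <- layout_seqlengths_for_test(layout)
  names(tss) <- c("gA", "gB")
  # promoter of gA: 0-based [14999, 24999). A CGI ending exactly at its
  # start (abutting under the half-open convention) must not count.
  cgi <- GRanges("chr1", IRanges(14001, 14999))
  calls <- simulate_cpg_calls("chr1", seq(100, 99900, by = 100), 0.5, 10)
  res <- promoter_meth_by_cgi(calls, tss, cgi)
  expect_equal(nrow(res$with_cgi), 0)
  expect_equal(nrow(res$without_cgi), 2)
  # CGI fully inside the promoter counts
  cgi2 <- GRanges("chr1", IRanges(19001, 19200))
  res2 <- promoter_meth_by_cgi(calls, tss, cgi2)
  expect_equal(nrow(res2$with_cgi), 1)
})

test_that("promoter CGI groups separate planted levels", {
  layout <- genome_layout("chr1", 2.2e6)
  n <- 50
  tss_all <- GRanges("chr1", IRanges(seq(15000, by = 21000,
                                         length.out = 2 * n), width = 1),
                     strand = "+")
  seqlengths(tss_all) <- layout_seqlengths_for_test(layout)
  cgi <- GRanges("chr1", IRanges(start(tss_all)[seq_len(n)] - 300,
                                 width = 600))
  set.seed(3)
  pos <- sort(unique(unlist(lapply(start(tss_all), function(s)
    seq(s - 4000, s + 4000, by = 200)))))
  prom_with <- GRanges("chr1", IRanges(start(tss_all)[seq_len(n)] - 5000,
                                       width = 10000))
  lvl <- ifelse(overlapsAny(GRanges("chr1", IRanges(pos, width = 1)),
                            prom_with), 0.2, 0.8)
  calls <- simulate_cpg_calls("chr1", pos, lvl, 10)
  res <- promoter_meth_by_cgi(calls, tss_all, cgi)
  tt <- two_group_t(res$with_cgi$level, res$without_cgi$level)
  expect_lt(tt$p, 0.001)
  expect_lt(mean(res$with_cgi$level), mean(res$without_cgi$level))
})

test_that("region methylation profiles recover planted body/flank contrast", {
  layout <- genome_layout("chr1", 1e6)
  body <- GRanges("chr1", IRanges(400001, 600000))
  seqlengths(body) <- layout_seqlengths_for_test(layout)
  set.seed(9)
  pos <- seq(25, 1e6, by = 50)
  lvl <- ifelse(pos > 400000 & pos <= 600000, 0.8, 0.5)
  calls <- simulate_cpg_calls("chr1", pos, lvl, 10)
  prof <- region_meth_profile(calls, body)
  b <- mean(prof$mean[prof$axis == "body"], na.rm = TRUE)
  f <- mean(prof$mean[prof$axis == "flank"], na.rm = TRUE)
  expect_equal(b - f, 0.3, tolerance = 0.05)
  # uniform level gives a flat profile
  calls2 <- simulate_cpg_calls("chr1", pos, 0.5, 10)
  prof2 <- region_meth_profile(calls2, body)
  expect_equal(mean(prof2$mean), 0.5, tolerance = 0.02)
  expect_lt(max(abs(prof2$mean - 0.5)), 0.15)
})
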