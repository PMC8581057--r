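# Direct construction of diff tables lets the boundary semantics be
# pinned exactly without simulation noise.
mk_diff <- function(ids, fc, padj = rep(1e-6, length(ids))) {
  data.frame(feature_id = ids, mean_a = 1, mean_b = 1, fc = fc,
             p = padj, padj = padj, stringsAsFactors = FALSE)
}

mk_samples <- function(groups) {
  sample_table(paste0(groups, "_r1"), groups, rep(1L, length(groups)),
               rep(1e6, length(groups)))
}

mk_fpkm <- function(ids, groups, value = 50) {
  m <- matrix(value, length(ids), length(groups),
              dimnames = list(ids, paste0(groups, "_r1")))
  m
}

test_that("EGA gene taxonomy applies thresholds with legend boundary rules", {
  grps <- c("IVO2c", "IVO4c", "SCNT4c")
  ids <- paste0("g", 1:6)
  fpkm <- mk_fpkm(ids, grps)
  fpkm["g2", "IVO4c_r1"] <- 4.9  # fails the FPKM floor
  samples <- mk_samples(grps)
  prim <- mk_diff(ids, fc = c(4, 4, 4, 4, 2.9, 4),
                  padj = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.2))
  sec <- mk_diff(ids, fc = c(6, 6, 2, 2.0001, 1, 1))
  cl <- classify_ega_genes(fpkm, samples, prim, sec)
  expect_equal(cl$label,
               c("OFF",    # fc_primary 4, fpkm 50, padj .01, sec 6
                 "NONE",   # expression floor fails
                 "FULLY_ON",  # sec exactly 2 is inclusive
                 "PARTIALLY_ON",  # sec just above 2
                 "NONE",   # primary fc at 2.9 fails > 3
                 "NONE"))  # padj fails
  # partition: exactly one label per feature
  expect_true(all(table(cl$feature_id) == 1))
})

test_that("PFF gene taxonomy uses its reversed boundary semantics", {
  grps <- c("PFF", "IVO4c", "SCNT4c")
  ids <- paste0("g", 1:4)
  fpkm <- mk_fpkm(ids, grps)
  samples <- mk_samples(grps)
  prim <- mk_diff(ids, fc = rep(10, 4), padj = rep(1e-4, 4))
  sec <- mk_diff(ids, fc = c(1.5, 5, 2, 4.999))
  cl <- classify_pff_genes(fpkm, samples, prim, sec)
  expect_equal(cl$label, c("ON",          # FC < 2
                           "FULLY_OFF",   # FC exactly 5 inclusive
                           "PARTIALLY_OFF",  # FC exactly 2 inclusive
                           "PARTIALLY_OFF"))
})

test_that("restoration flags follow the strict fold-change rules", {
  cl <- rbind(
    data.frame(feature_id = c("e1", "e2"), kind = "gene", axis = "EGA",
               label = "OFF", fc_primary = 10, fc_secondary = 10,
               p = 1e-5, padj = 1e-4),
    data.frame(feature_id = c("p1", "p2"), kind = "gene", axis = "PFF",
               label = "ON", fc_primary = 10, fc_secondary = 1,
               p = 1e-5, padj = 1e-4))
  grps <- c("SCNT4c", "SCNT4c_KG")
  samples <- mk_samples(grps)
  # expression chosen so (treated + .5)/(SCNT4c + .5) hits exact values
  expr <- matrix(c(9.5, 24.5,    # e1: fc 2.5 -> restored
                   9.5, 19.5,    # e2: fc 2.0 exactly -> NOT (strict >)
                   19.5, 9.5,    # p1: fc 0.5 exactly -> NOT silenced
                   19.5, 4.5),   # p2: fc 0.25 -> silenced
                 nrow = 4, byrow = TRUE,
                 dimnames = list(c("e1", "e2", "p1", "p2"),
                                 samples$sample))
  res <- assess_restoration(cl, expr, samples, "SCNT4c_KG")
  expect_equal(res$flags$restored, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$fraction, 0.5)
  expect_error(assess_restoration(cl, expr, samples, "SCNT4c_TDG"),
               "absent")
})

test_that("repeat tiers nest and respect the VST floor", {
  grps <- c("IVO2c", "IVO4c")
  samples <- mk_samples(grps)
  # de-logged VST means: choose VST values giving known fold changes
  v <- function(x) log2(x + 1)
  vst <- matrix(c(v(40), v(60.25),   # fc (60.25+.5)/(40.5) = 1.5  tier >1
                  v(10), v(62.5),    # fc 6 -> tier >5
                  v(40), v(121),     # fc 121.5/40.5 = 3 -> tier >2
                  v(1), v(28)),      # fc 19 but vst_ref 4.86 < 5 floor
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("r", 1:4), samples$sample))
  fams <- c("SSRS1", "MLT1E2", "L1_SS", "weird")
  cls <- classify_repeats(vst, samples, fams)
  expect_equal(cls$repeats$ega_on, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(cls$repeats$tier[1:3], c("FC>1", "FC>5", "FC>2"))
  expect_equal(cls$repeats$class, c("satellite", "LTR", "LINE", "unknown"))
  # nesting of cumulative tier sets
  fc <- cls$repeats$fc
  expect_true(all(which(fc > 5) %in% which(fc > 2)))
  expect_true(all(which(fc > 2) %in% which(fc > 1)))
  # composition counts only EGA-ON repeats
  expect_equal(sum(cls$composition), 3)
})

test_that("window screening merges bookended windows and relabels regions", {
  sim <- small_sim()
  cfg <- sim$config
  windows <- make_windows(sim$layout, cfg$window_size, cfg$window_step)
  wc <- count_reads_matrix(sim$reads, windows, sim$samples$sample)
  rsamp <- sim$samples
  rsamp$lib_size <- vapply(rsamp$sample, function(s)
    as.numeric(sum(sim$reads$sample == s)), numeric(1))
  res <- classify_regions(wc, windows, rsamp, sim$reads, axis = "EGA")
  expect_gt(length(res$regions), 0)
  # no region shorter than one window
  expect_true(all(width(res$regions) >= cfg$window_size))
  # merged regions are disjoint and non-bookended
  expect_true(length(reduce(res$regions)) == length(res$regions))

  # idempotence: re-screening the merged regions (as their own windows)
  # returns the same spans with the same labels
  rc <- count_reads_matrix(sim$reads, res$regions, rsamp$sample)
  res2 <- classify_regions(rc, res$regions, rsamp, sim$reads, axis = "EGA")
  expect_equal(as.character(seqnames(res2$regions)),
               as.character(seqnames(res$regions)))
  expect_equal(start(res2$regions), start(res$regions))
  expect_equal(end(res2$regions), end(res$regions))
  expect_equal(mcols(res2$regions)$label, mcols(res$regions)$label)

  # planted blocks are recovered within one window step per side
  ega_blocks <- sim$truth_regions[
    mcols(sim$truth_regions)$label %in% c("EGA_FULLY_ON", "EGA_OFF")]
  ov <- findOverlaps(ega_blocks, res$regions)
  expect_equal(length(ov), length(ega_blocks))
  for (h in seq_len(length(ov))) {
    b <- ega_blocks[queryHits(ov)[h]]
    r <- res$regions[subjectHits(ov)[h]]
    expect_lte(abs(start(r) - start(b)), cfg$window_step)
    expect_lte(abs(end(r) - end(b)), cfg$window_step)
  }
})

test_that("gene classification recovers planted truth on synthetic data", {
  sim <- small_sim()
  samples <- sim$samples
  fpkm_g <- fpkm_matrix(sim$gene_counts, width(sim$genes),
                        samples$lib_size)
  d1 <- diff_gene_table(sim$gene_counts, samples, "IVO4c", "IVO2c")
  d2 <- diff_gene_table(sim$gene_counts, samples, "IVO4c", "SCNT4c")
  cl <- classify_ega_genes(fpkm_g, samples, d1, d2)
  planted <- mcols(sim$genes)$label
  sens <- mean(cl$label[planted == "EGA_OFF"] == "OFF")
  prec <- mean(planted[cl$label == "OFF"] == "EGA_OFF")
  expect_gte(sens, 0.9)
  expect_gte(prec, 0.9)
})
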