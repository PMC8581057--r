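test_that("configuration validation rejects impossible designs", {
  expect_error(simulation_config(frac_ega_on = 1.2), "fractions")
  expect_error(simulation_config(replicates_per_group = 0), "replicate")
  expect_error(simulation_config(dispersion = -1), "dispersion")
  expect_error(simulation_config(chrom_length = 10000), "window")
  # chromosome too short to host the requested features
  cfg <- simulation_config(n_chroms = 1, chrom_length = 60000,
                           n_genes = 500)
  expect_error(suppressWarnings(simulate_experiment(cfg)), "too short")
})

test_that("the same seed reproduces the experiment bit-for-bit", {
  cfg <- simulation_config(seed = 5, n_genes = 60, n_repeats = 40,
                           chrom_length = 2e6, n_region_blocks = 1,
                           reads_per_sample = 5000)
  s1 <- suppressWarnings(simulate_experiment(cfg))
  s2 <- suppressWarnings(simulate_experiment(cfg))
  expect_identical(s1$gene_counts, s2$gene_counts)
  expect_identical(s1$repeat_counts, s2$repeat_counts)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$chip$SCNT4c$chip$counts, s2$chip$SCNT4c$chip$counts)
  expect_identical(as.data.frame(s1$meth$PFF), as.data.frame(s2$meth$PFF))
  expect_identical(s1$truth, s2$truth)
})

test_that("planted label counts follow exact floor rounding", {
  cfg <- simulation_config(seed = 2, n_genes = 1000, frac_ega_on = 0.3,
                           frac_ega_off_given_on = 0.4,
                           frac_pff_off = 0.25,
                           frac_pff_on_given_off = 0.1,
                           n_region_blocks = 0, reads_per_sample = 1000,
                           n_repeats = 100)
  sim <- suppressWarnings(simulate_experiment(cfg))
  g <- sim$truth[sim$truth$feature_kind == "gene", ]
  expect_equal(sum(g$planted_label %in% c("EGA_FULLY_ON", "EGA_OFF")), 300)
  expect_equal(sum(g$planted_label == "EGA_OFF"), 120)
  expect_equal(sum(g$planted_label %in% c("PFF_FULLY_OFF", "PFF_ON")), 250)
  expect_equal(sum(g$planted_label == "PFF_ON"), 25)
  # restoration bookkeeping: floor(restore_frac * class size)
  expect_equal(sum(g$planted_restored[g$planted_label == "EGA_OFF"]),
               floor(0.6 * 120))

  # zero fraction forces zero labels
  cfg0 <- simulation_config(seed = 2, n_genes = 100, frac_ega_on = 0,
                            n_region_blocks = 0, reads_per_sample = 1000,
                            n_repeats = 50)
  sim0 <- suppressWarnings(simulate_experiment(cfg0))
  g0 <- sim0$truth[sim0$truth$feature_kind == "gene", ]
  expect_equal(sum(startsWith(g0$planted_label, "EGA")), 0)
})

test_that("empirical group means recover the planted expectations", {
  cfg <- simulation_config(seed = 7, n_genes = 150, n_repeats = 40,
                           replicates_per_group = 60, dispersion = 0.01,
                           n_region_blocks = 0, reads_per_sample = 1000)
  sim <- suppressWarnings(simulate_experiment(cfg))
  lab <- mcols(sim$genes)$label
  res <- mcols(sim$genes)$restored
  mu <- vapply(seq_along(sim$genes), function(i) {
    m <- switch(lab[i], EGA_FULLY_ON = , EGA_OFF = cfg$activation_fc, 1)
    cfg$baseline_mean * m
  }, numeric(1))
  ivo4 <- sim$samples$sample[sim$samples$group == "IVO4c"]
  emp <- rowMeans(sim$gene_counts[, ivo4])
  se <- sqrt((mu + cfg$dispersion * mu^2) / length(ivo4))
  expect_gte(mean(abs(emp - mu) <= 3 * se), 0.95)
})

test_that("fixture files round-trip and satisfy BED invariants", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)
  back <- read_fixture(dir)
  expect_identical(back$gene_counts, sim$gene_counts)
  expect_identical(back$repeat_counts, sim$repeat_counts)
  expect_equal(back$layout, sim$layout)
  expect_identical(as.data.frame(back$reads), as.data.frame(sim$reads))
  expect_equal(start(back$genes), start(sim$genes))
  expect_equal(as.character(strand(back$genes)),
               as.character(strand(sim$genes)))
  expect_identical(back$truth, sim$truth)
  expect_equal(back$chip$PFF$chip$counts, sim$chip$PFF$chip$counts)
  expect_equal(back$chip$PFF$chip$lib_size, sim$chip$PFF$chip$lib_size)
  expect_identical(as.data.frame(back$meth$SCNT4c),
                   as.data.frame(sim$meth$SCNT4c))
  expect_equal(mcols(back$truth_regions)$label,
               mcols(sim$truth_regions)$label)

  # BED invariants: 0 <= start < end <= chrom length
  for (f in c("genes.bed", "repeats.bed", "truth_regions.bed")) {
    bed <- read.table(file.path(dir, f), sep = "\t")
    expect_true(all(bed[[2]] >= 0))
    expect_true(all(bed[[2]] < bed[[3]]))
    expect_true(all(bed[[3]] <= sim$layout[bed[[1]]]))
  }

  # CpG file row sums equal the simulated coverage
  cpg <- read.table(file.path(dir, "cpg_PFF.tsv"), sep = "\t")
  expect_equal(cpg[[4]] + cpg[[5]], sim$meth$PFF$cov)
})

test_that("planted ChIP enrichment lands on resistant features", {
  sim <- small_sim()
  resist <- sim$truth_regions[
    mcols(sim$truth_regions)$label %in% c("EGA_OFF", "PFF_ON")]
  ok <- sim$truth_regions[
    mcols(sim$truth_regions)$label %in% c("EGA_FULLY_ON", "PFF_FULLY_OFF")]
  tr <- sim$chip$SCNT4c
  hi <- intensity(tr$chip, tr$input, resist)
  lo <- intensity(tr$chip, tr$input, ok)
  expect_gt(min(hi), max(lo))
})
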