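# Shared small fixtures built in code.

tiny_layout <- function() genome_layout(c("chr1", "chr2"), c(1e5, 6e4))

layout_seqlengths_for_test <- function(layout)
  setNames(as.integer(layout), names(layout))

# A small but fully structured simulated experiment, reused by several
# test files (built once per test run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 11, n_chroms = 2, chrom_length = 3e6,
                               n_genes = 200, n_repeats = 150,
                               replicates_per_group = 3,
                               n_region_blocks = 1,
                               reads_per_sample = 40000)
      cache <<- suppressWarnings(simulate_experiment(cfg))
    }
    cache
  }
})

# Count matrix with two groups of NB replicates for differential tests.
two_group_counts <- function(n_genes, mu_a, mu_b, reps = 3, phi = 0.1,
                             seed = 1) {
  set.seed(seed)
  ca <- matrix(rnbinom(n_genes * reps, mu = mu_a, size = 1 / phi), n_genes)
  cb <- matrix(rnbinom(n_genes * reps, mu = mu_b, size = 1 / phi), n_genes)
  counts <- cbind(ca, cb)
  rownames(counts) <- sprintf("g%04d", seq_len(n_genes))
  colnames(counts) <- c(paste0("A_rep", seq_len(reps)),
                        paste0("B_rep", seq_len(reps)))
  samples <- sample_table(colnames(counts),
                          rep(c("A", "B"), each = reps),
                          rep(seq_len(reps), 2),
                          pmax(colSums(counts), 1))
  list(counts = counts, samples = samples)
}
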