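# Shared study configuration for the analysis scripts. Sourced by every
# numbered driver so the whole workflow runs off one seeded design:
# six sample groups (PFF, IVO2c, IVO4c, SCNT4c and the two treated
# clone groups), three replicates, a two-chromosome 8-Mb toy genome
# with planted EGA/PFF structure at the study's fold-change scales.

library(rrscan)
suppressPackageStartupMessages(library(GenomicRanges))

study_config <- simulation_config(
  seed = 104729L,
  n_chroms = 2, chrom_length = 4e6,
  n_genes = 800, n_repeats = 400,
  replicates_per_group = 3,
  frac_ega_on = 0.2, frac_ega_off_given_on = 0.4,
  frac_pff_off = 0.25, frac_pff_on_given_off = 0.1,
  activation_fc = 10, chip_enrich_fc = 4,
  restore_frac = 0.6,
  n_region_blocks = 2,
  reads_per_sample = 100000
)

study_thresholds <- threshold_config()

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

study_sim <- function() suppressWarnings(simulate_experiment(study_config))
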