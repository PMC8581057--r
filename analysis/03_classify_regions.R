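#!/usr/bin/env Rscript
# Region-level taxonomy: 50-kb sliding windows (20-kb step) screened by
# fold change, RPM floor and pooled Fisher test, merged into maximal
# regions and relabelled from the merged spans; compared to the planted
# blocks.

source("analysis/00_config.R")

sim <- study_sim()
windows <- make_windows(sim$layout, study_config$window_size,
                        study_config$window_step)
cat("built", length(windows), "windows over",
    format(sum(sim$layout), big.mark = ","), "bp\n")

wc <- count_reads_matrix(sim$reads, windows, sim$samples$sample)
rsamp <- sim$samples
rsamp$lib_size <- rep(study_config$reads_per_sample, nrow(rsamp))

for (axis in c("EGA", "PFF")) {
  res <- classify_regions(wc, windows, rsamp, sim$reads,
                          study_thresholds, axis = axis)
  cat("\n", axis, "axis: ", length(res$regions), " merged regions, ",
      "lengths ", paste(range(width(res$regions)) / 1000, collapse = "-"),
      " kb\n", sep = "")
  print(table(mcols(res$regions)$label))
  df <- regions_as_frame(res$regions, axis)
  write.table(df, file.path(results_dir,
                            paste0(tolower(axis), "_regions.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cat("\nPlanted blocks for comparison:\n")
print(data.frame(id = names(sim$truth_regions),
                 label = mcols(sim$truth_regions)$label,
                 kb = width(sim$truth_regions) / 1000))
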