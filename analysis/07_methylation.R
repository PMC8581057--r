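#!/usr/bin/env Rscript
# CpG methylation over the planted blocks and CGI-stratified promoters:
# resistant features are hypermethylated in PFF and SCNT4c and
# demethylated after transient TDG expression (SCNT4c_TDG); CGI
# promoters stay lowly methylated throughout.

source("analysis/00_config.R")

sim <- study_sim()
blocks <- sim$truth_regions
resist <- blocks[mcols(blocks)$label %in% c("EGA_OFF", "PFF_ON")]
faithful <- blocks[mcols(blocks)$label %in% c("EGA_FULLY_ON",
                                              "PFF_FULLY_OFF")]

cat("region methylation levels (pooled CpG ratio):\n")
rows <- list()
for (smp in names(sim$meth)) {
  mr <- meth_level(sim$meth[[smp]], resist)
  mf <- meth_level(sim$meth[[smp]], faithful)
  cat(sprintf("  %-11s resistant %.3f   faithful %.3f\n", smp,
              mean(mr$level), mean(mf$level)))
  rows[[smp]] <- data.frame(sample = smp,
                            resistant = mean(mr$level),
                            faithful = mean(mf$level))
}
write.table(do.call(rbind, rows),
            file.path(results_dir, "meth_region_levels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("\npromoter methylation by CGI status:\n")
tss <- gene_tss(sim$genes)
for (smp in c("SCNT4c", "SCNT4c_TDG")) {
  pm <- promoter_meth_by_cgi(sim$meth[[smp]], tss, sim$cgi)
  tt <- two_group_t(na.omit(pm$with_cgi$level),
                    na.omit(pm$without_cgi$level))
  cat(sprintf("  %-11s with CGI %.3f   without CGI %.3f   (t test %s)\n",
              smp, mean(pm$with_cgi$level, na.rm = TRUE),
              mean(pm$without_cgi$level, na.rm = TRUE),
              signif_stars(tt$p)))
}

# scaled-body profile over resistant blocks in SCNT4c vs SCNT4c_TDG
for (smp in c("SCNT4c", "SCNT4c_TDG")) {
  prof <- region_meth_profile(sim$meth[[smp]], resist)
  out <- data.frame(bin = seq_along(prof$mean), part = prof$axis,
                    level = prof$mean)
  write.table(out, file.path(results_dir,
                             paste0("meth_region_profile_", smp, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s body %.3f flank %.3f\n", smp,
              mean(prof$mean[prof$axis == "body"], na.rm = TRUE),
              mean(prof$mean[prof$axis == "flank"], na.rm = TRUE)))
}
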