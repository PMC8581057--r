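#!/usr/bin/env Rscript
# Treatment-restoration scoring: which EGA-OFF features are reactivated
# (FC > 2, treated vs SCNT4c) and which PFF-ON features are silenced
# (FC < 0.5) in the KDM4A+GSK126 (SCNT4c_KG) and TDG-overexpression
# (SCNT4c_TDG) groups.

source("analysis/00_config.R")

sim <- study_sim()
smp <- sim$samples
fpkm_g <- fpkm_matrix(sim$gene_counts, width(sim$genes), smp$lib_size)
norm_g <- normalized_counts(sim$gene_counts)

ega <- classify_ega_genes(
  fpkm_g, smp,
  diff_gene_table(sim$gene_counts, smp, "IVO4c", "IVO2c"),
  diff_gene_table(sim$gene_counts, smp, "IVO4c", "SCNT4c"),
  study_thresholds)
pff <- classify_pff_genes(
  fpkm_g, smp,
  diff_gene_table(sim$gene_counts, smp, "PFF", "IVO4c"),
  diff_gene_table(sim$gene_counts, smp, "PFF", "SCNT4c"),
  study_thresholds)

fractions <- list()
for (treated in c("SCNT4c_KG", "SCNT4c_TDG")) {
  re <- assess_restoration(ega, norm_g, smp, treated, study_thresholds)
  rp <- assess_restoration(pff, norm_g, smp, treated, study_thresholds)
  cat(sprintf("%s: %.1f%% of %d EGA-OFF genes reactivated, %.1f%% of %d PFF-ON genes silenced\n",
              treated, 100 * re$fraction, nrow(re$flags),
              100 * rp$fraction, nrow(rp$flags)))
  fractions[[paste0("ega_off_", treated)]] <- re$fraction
  fractions[[paste0("pff_on_", treated)]] <- rp$fraction
  flags <- rbind(cbind(re$flags, treated = treated),
                 cbind(rp$flags, treated = treated))
  write.table(flags,
              file.path(results_dir, paste0("restoration_", treated,
                                            ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat(sprintf("\nplanted restore fraction was %.2f\n",
            study_config$restore_frac))
write_class_summary(file.path(results_dir, "restoration_summary.json"),
                    class_counts = list(ega_off = nrow(ega[ega$label == "OFF", ]),
                                        pff_on = nrow(pff[pff$label == "ON", ])),
                    restored_fractions = fractions)
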