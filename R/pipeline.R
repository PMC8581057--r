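#' Run the full identification pipeline on a simulated experiment
#'
#' Simulate (or reuse) a planted-truth experiment, then: classify genes
#' on both axes, build sliding windows and classify merged regions on
#' both axes, score restoration in both treated groups, tier the
#' repeats, compute input-normalised ChIP meta-profiles over the
#' classified EGA regions and the classified-gene TSSs, and aggregate
#' CpG methylation over regions and CGI-stratified promoters. All
#' tables are written as TSV plus a JSON summary; given the same
#' configuration (and hence seed) the output files are byte-identical
#' across runs.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir output directory.
#' @param sim optional pre-built `rr_sim` (must match `cfg`).
#' @param thr a [threshold_config()].
#' @return invisibly, a list with the in-memory results (`sim`,
#'   `ega_genes`, `pff_genes`, `ega_regions`, `pff_regions`,
#'   `restoration`, `repeats`, `chip_profiles`, `methylation`).
#' @export
run_pipeline <- function(cfg = simulation_config(), out_dir,
                         sim = NULL, thr = threshold_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  if (is.null(sim)) sim <- simulate_experiment(cfg)
  samples <- sim$samples

  # --- genes ---------------------------------------------------------
  fpkm_g <- fpkm_matrix(sim$gene_counts, width(sim$genes),
                        samples$lib_size)
  norm_g <- normalized_counts(sim$gene_counts)
  diff_ega <- diff_gene_table(sim$gene_counts, samples, "IVO4c", "IVO2c",
                              eps = thr$pseudocount)
  diff_ega2 <- diff_gene_table(sim$gene_counts, samples, "IVO4c", "SCNT4c",
                               eps = thr$pseudocount)
  diff_pff <- diff_gene_table(sim$gene_counts, samples, "PFF", "IVO4c",
                              eps = thr$pseudocount)
  diff_pff2 <- diff_gene_table(sim$gene_counts, samples, "PFF", "SCNT4c",
                               eps = thr$pseudocount)
  ega_genes <- classify_ega_genes(fpkm_g, samples, diff_ega, diff_ega2, thr)
  pff_genes <- classify_pff_genes(fpkm_g, samples, diff_pff, diff_pff2, thr)
  data.table::fwrite(ega_genes, fp("ega_genes.tsv"), sep = "\t")
  data.table::fwrite(pff_genes, fp("pff_genes.tsv"), sep = "\t")

  # --- windows / regions --------------------------------------------
  windows <- make_windows(sim$layout, cfg$window_size, cfg$window_step)
  win_counts <- count_reads_matrix(sim$reads, windows, samples$sample)
  region_samples <- samples
  region_samples$lib_size <- vapply(samples$sample, function(s)
    as.numeric(sum(sim$reads$sample == s)), numeric(1))
  ega_reg <- classify_regions(win_counts, windows, region_samples,
                              sim$reads, thr, axis = "EGA")
  pff_reg <- classify_regions(win_counts, windows, region_samples,
                              sim$reads, thr, axis = "PFF")
  data.table::fwrite(regions_as_frame(ega_reg$regions, "EGA"),
                     fp("ega_regions.tsv"), sep = "\t")
  data.table::fwrite(regions_as_frame(pff_reg$regions, "PFF"),
                     fp("pff_regions.tsv"), sep = "\t")

  # --- restoration ---------------------------------------------------
  restoration <- list()
  for (treated in c("SCNT4c_KG", "SCNT4c_TDG")) {
    restoration[[treated]] <- list(
      ega_genes = assess_restoration(ega_genes, norm_g, samples, treated,
                                     thr),
      pff_genes = assess_restoration(pff_genes, norm_g, samples, treated,
                                     thr),
      ega_regions = assess_restoration(regions_as_frame(ega_reg$regions,
                                                        "EGA"),
                                       ega_reg$rpm, region_samples,
                                       treated, thr),
      pff_regions = assess_restoration(regions_as_frame(pff_reg$regions,
                                                        "PFF"),
                                       pff_reg$rpm, region_samples,
                                       treated, thr))
  }

  # --- repeats -------------------------------------------------------
  vst_r <- vst_transform(sim$repeat_counts)
  rep_cls <- classify_repeats(vst_r, samples, mcols(sim$repeats)$family,
                              thr)
  data.table::fwrite(rep_cls$repeats, fp("repeats_classified.tsv"),
                     sep = "\t")

  # --- ChIP meta-profiles over classified EGA regions ----------------
  chip_profiles <- list()
  if (length(ega_reg$regions)) {
    for (smp in names(sim$chip)) {
      prof <- region_metaprofile(sim$chip[[smp]]$chip,
                                 sim$chip[[smp]]$input, ega_reg$regions)
      chip_profiles[[smp]] <- prof
      data.table::fwrite(data.table::data.table(
        bin = seq_along(prof$mean), part = prof$axis, mean = prof$mean),
        fp(paste0("chip_profile_", smp, ".tsv")), sep = "\t")
    }
  }

  # --- methylation ---------------------------------------------------
  methylation <- list()
  if (length(ega_reg$regions)) {
    for (smp in names(sim$meth)) {
      ml <- meth_level(sim$meth[[smp]], ega_reg$regions)
      methylation[[paste0("regions_", smp)]] <- ml
      data.table::fwrite(ml, fp(paste0("meth_regions_", smp, ".tsv")),
                         sep = "\t")
    }
  }
  prom <- promoter_meth_by_cgi(sim$meth$SCNT4c, gene_tss(sim$genes),
                               sim$cgi, half_width = cfg$tss_flank)
  methylation$promoters_scnt4c <- prom
  data.table::fwrite(prom$with_cgi, fp("meth_promoters_cgi.tsv"),
                     sep = "\t")
  data.table::fwrite(prom$without_cgi, fp("meth_promoters_nocgi.tsv"),
                     sep = "\t")

  # --- summary -------------------------------------------------------
  write_class_summary(
    fp("summary.json"),
    class_counts = list(
      ega_off_genes = sum(ega_genes$label == "OFF"),
      pff_on_genes = sum(pff_genes$label == "ON"),
      ega_regions = length(ega_reg$regions),
      pff_regions = length(pff_reg$regions),
      ega_on_repeats = sum(rep_cls$repeats$ega_on)),
    restored_fractions = list(
      ega_genes_kg = restoration$SCNT4c_KG$ega_genes$fraction,
      pff_genes_kg = restoration$SCNT4c_KG$pff_genes$fraction,
      ega_regions_kg = restoration$SCNT4c_KG$ega_regions$fraction,
      pff_regions_kg = restoration$SCNT4c_KG$pff_regions$fraction))

  invisible(list(sim = sim, ega_genes = ega_genes, pff_genes = pff_genes,
                 ega_regions = ega_reg, pff_regions = pff_reg,
                 restoration = restoration, repeats = rep_cls,
                 chip_profiles = chip_profiles,
                 methylation = methylation))
}
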