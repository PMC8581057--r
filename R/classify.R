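#' Classification thresholds
#'
#' The fold-change / expression-floor / significance thresholds of the
#' EGA and PFF taxonomies, with the figure-legend boundary semantics
#' preserved exactly (see [classify_ega_genes()] etc.).
#'
#' @param gene_on_fc primary FC screen for genes (default 3).
#' @param gene_expr_min_fpkm FPKM floor in the reference group (default 5).
#' @param gene_p adjusted-p screen for genes (default 0.05).
#' @param region_fc primary FC screen for windows/regions (default 5).
#' @param region_min_rpm RPM floor in the reference group (default 10; the
#'   analysis narrative's value -- an alternative floor of 5 appears in
#'   some workflows and can be set here).
#' @param region_p Fisher-p screen for windows (default 0.01, unadjusted;
#'   set `region_adjust = TRUE` for BH).
#' @param region_adjust BH-adjust window p-values before screening
#'   (default `FALSE`).
#' @param sub_full_max_fc secondary-FC boundary between full and partial
#'   reprogramming (default 2).
#' @param sub_partial_max_fc secondary-FC boundary between partial and
#'   failed reprogramming (default 5).
#' @param restore_fc treated-vs-SCNT4c FC defining restoration (default 2;
#'   silencing uses `1 / restore_fc`).
#' @param repeat_fc_tiers ascending FC tier cut-offs for repeats
#'   (default `c(1, 2, 5)`).
#' @param repeat_min_vst VST floor in IVO4c for repeats (default 5).
#' @param pseudocount pseudocount for all fold changes (default 0.5).
#' @return list of class `threshold_config`.
#' @export
threshold_config <- function(gene_on_fc = 3, gene_expr_min_fpkm = 5,
                             gene_p = 0.05, region_fc = 5,
                             region_min_rpm = 10, region_p = 0.01,
                             region_adjust = FALSE,
                             sub_full_max_fc = 2, sub_partial_max_fc = 5,
                             restore_fc = 2, repeat_fc_tiers = c(1, 2, 5),
                             repeat_min_vst = 5, pseudocount = 0.5) {
  thr <- list(gene_on_fc = gene_on_fc, gene_expr_min_fpkm = gene_expr_min_fpkm,
              gene_p = gene_p, region_fc = region_fc,
              region_min_rpm = region_min_rpm, region_p = region_p,
              region_adjust = isTRUE(region_adjust),
              sub_full_max_fc = sub_full_max_fc,
              sub_partial_max_fc = sub_partial_max_fc,
              restore_fc = restore_fc, repeat_fc_tiers = sort(repeat_fc_tiers),
              repeat_min_vst = repeat_min_vst, pseudocount = pseudocount)
  nums <- unlist(thr[setdiff(names(thr), "region_adjust")])
  if (any(nums <= 0)) stop("thresholds must be positive")
  if (!(thr$sub_full_max_fc < thr$sub_partial_max_fc))
    stop("sub_full_max_fc must be < sub_partial_max_fc")
  structure(thr, class = "threshold_config")
}

# Subgroup labels from the secondary fold change.
# EGA axis (IVO4c vs SCNT4c): FC <= 2 FULLY_ON; 2 < FC <= 5 PARTIALLY_ON;
#   FC > 5 OFF.
# PFF axis (PFF vs SCNT4c): FC >= 5 FULLY_OFF; 2 <= FC < 5 PARTIALLY_OFF;
#   FC < 2 ON.
subgroup_label <- function(fc_secondary, axis, thr) {
  lo <- thr$sub_full_max_fc; hi <- thr$sub_partial_max_fc
  if (axis == "EGA") {
    ifelse(fc_secondary <= lo, "FULLY_ON",
           ifelse(fc_secondary <= hi, "PARTIALLY_ON", "OFF"))
  } else {
    ifelse(fc_secondary >= hi, "FULLY_OFF",
           ifelse(fc_secondary >= lo, "PARTIALLY_OFF", "ON"))
  }
}

classified_frame <- function(feature_id, kind, axis, label, fc_primary,
                             fc_secondary, p, padj = NA_real_) {
  data.frame(feature_id = feature_id, kind = kind, axis = axis,
             label = label, fc_primary = fc_primary,
             fc_secondary = fc_secondary, p = p, padj = padj,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify genes on the EGA axis
#'
#' A gene enters the EGA class iff its count-level FC(IVO4c/IVO2c)
#' exceeds `gene_on_fc`, its mean FPKM in IVO4c exceeds
#' `gene_expr_min_fpkm`, and the adjusted p of the IVO4c-vs-IVO2c count
#' test is below `gene_p`. EGA genes are then subdivided by the
#' count-level FC(IVO4c/SCNT4c): `FULLY_ON` (FC <= 2), `PARTIALLY_ON`
#' (2 < FC <= 5), `OFF` (FC > 5). All other genes get label `NONE`.
#' Fold changes come from the size-factor-normalized count contrasts
#' (robust to library composition); FPKM supplies the expression floor
#' only.
#'
#' @param expr_fpkm genes x samples FPKM matrix (columns named by sample).
#' @param samples a [sample_table()] covering IVO2c, IVO4c, SCNT4c.
#' @param diff_primary [diff_gene_table()] for IVO4c vs IVO2c.
#' @param diff_secondary [diff_gene_table()] for IVO4c vs SCNT4c (its
#'   fold change supplies the subgrouping; its p-values are not used).
#' @param thr a [threshold_config()].
#' @return classified-feature `data.frame` (one row per gene, axis
#'   `"EGA"`).
#' @export
classify_ega_genes <- function(expr_fpkm, samples, diff_primary,
                               diff_secondary,
                               thr = threshold_config()) {
  ids <- rownames(expr_fpkm)
  gm <- group_means(expr_fpkm, samples, "IVO4c")
  i1 <- match(ids, diff_primary$feature_id)
  i2 <- match(ids, diff_secondary$feature_id)
  fc_primary <- diff_primary$fc[i1]
  fc_secondary <- diff_secondary$fc[i2]
  padj <- diff_primary$padj[i1]
  in_class <- fc_primary > thr$gene_on_fc &
    gm[, "IVO4c"] > thr$gene_expr_min_fpkm & padj < thr$gene_p
  label <- ifelse(in_class, subgroup_label(fc_secondary, "EGA", thr), "NONE")
  classified_frame(ids, "gene", "EGA", label,
                   fc_primary, fc_secondary, diff_primary$p[i1], padj)
}

#' Classify genes on the PFF axis
#'
#' PFF class iff count-level FC(PFF/IVO4c) > `gene_on_fc`, mean FPKM in
#' PFF > `gene_expr_min_fpkm`, and adjusted p (PFF vs IVO4c) <
#' `gene_p`; subdivided by count-level FC(PFF/SCNT4c): `FULLY_OFF`
#' (FC >= 5), `PARTIALLY_OFF` (2 <= FC < 5), `ON` (FC < 2).
#'
#' @inheritParams classify_ega_genes
#' @param diff_primary [diff_gene_table()] for PFF vs IVO4c.
#' @param diff_secondary [diff_gene_table()] for PFF vs SCNT4c.
#' @return classified-feature `data.frame` (axis `"PFF"`).
#' @export
classify_pff_genes <- function(expr_fpkm, samples, diff_primary,
                               diff_secondary,
                               thr = threshold_config()) {
  ids <- rownames(expr_fpkm)
  gm <- group_means(expr_fpkm, samples, "PFF")
  i1 <- match(ids, diff_primary$feature_id)
  i2 <- match(ids, diff_secondary$feature_id)
  fc_primary <- diff_primary$fc[i1]
  fc_secondary <- diff_secondary$fc[i2]
  padj <- diff_primary$padj[i1]
  in_class <- fc_primary > thr$gene_on_fc &
    gm[, "PFF"] > thr$gene_expr_min_fpkm & padj < thr$gene_p
  label <- ifelse(in_class, subgroup_label(fc_secondary, "PFF", thr), "NONE")
  classified_frame(ids, "gene", "PFF", label,
                   fc_primary, fc_secondary, diff_primary$p[i1], padj)
}

# Pooled group counts and Fisher p per interval for a window contrast.
window_stats <- function(counts, samples, group_a, group_b, thr) {
  ids_a <- samples_in_group(samples, group_a)
  ids_b <- samples_in_group(samples, group_b)
  lib_a <- sum(samples$lib_size[match(ids_a, samples$sample)])
  lib_b <- sum(samples$lib_size[match(ids_b, samples$sample)])
  pooled_a <- rowSums(counts[, ids_a, drop = FALSE])
  pooled_b <- rowSums(counts[, ids_b, drop = FALSE])
  rpm_a <- rowMeans(rpm_matrix(counts[, ids_a, drop = FALSE],
                               samples$lib_size[match(ids_a, samples$sample)]))
  rpm_b <- rowMeans(rpm_matrix(counts[, ids_b, drop = FALSE],
                               samples$lib_size[match(ids_b, samples$sample)]))
  p <- fisher_window_test(pooled_a, lib_a - pooled_a, pooled_b, lib_b - pooled_b)
  list(rpm_a = rpm_a, rpm_b = rpm_b,
       fc = fold_change(rpm_a, rpm_b, thr$pseudocount), p = p)
}

#' Classify merged genomic regions on one axis
#'
#' Four steps: (i) screen sliding windows by FC, RPM floor and Fisher p on
#' the primary contrast; (ii) merge overlapping or bookended passing
#' windows into maximal regions; (iii) recompute counts, mean RPM, fold
#' changes and Fisher p over each merged span from the read positions
#' (pooled within group); (iv) label each region from its recomputed
#' secondary-contrast FC with the same interval rules as genes.
#'
#' @param window_counts windows x samples count matrix (rownames =
#'   `names(windows)`).
#' @param windows `GRanges` from [make_windows()] (sorted internally if
#'   needed).
#' @param samples a [sample_table()]; library sizes are the per-sample
#'   totals used for RPM.
#' @param reads `data.table` of read 5' positions (`sample`, `chrom`,
#'   `pos`) used to recompute counts over merged spans.
#' @param thr a [threshold_config()].
#' @param axis `"EGA"` (IVO4c vs IVO2c, then IVO4c vs SCNT4c) or `"PFF"`
#'   (PFF vs IVO4c, then PFF vs SCNT4c).
#' @return list with `regions` (a `GRanges` with region_id, label,
#'   fc_primary, fc_secondary, p, rpm_ref in `mcols`) and `rpm` (regions x
#'   samples RPM matrix for downstream restoration scoring).
#' @export
classify_regions <- function(window_counts, windows, samples, reads,
                             thr = threshold_config(),
                             axis = c("EGA", "PFF")) {
  axis <- match.arg(axis)
  ord <- order(as.factor(seqnames(windows)), start(windows))
  windows <- windows[ord]
  window_counts <- window_counts[ord, , drop = FALSE]
  grp <- switch(axis,
                EGA = c(a = "IVO4c", b = "IVO2c", sec = "SCNT4c"),
                PFF = c(a = "PFF", b = "IVO4c", sec = "SCNT4c"))
  ws <- window_stats(window_counts, samples, grp[["a"]], grp[["b"]], thr)
  p_screen <- if (thr$region_adjust) bh_adjust(ws$p) else ws$p
  pass <- ws$fc > thr$region_fc & ws$rpm_a > thr$region_min_rpm &
    p_screen < thr$region_p
  if (!any(pass)) {
    return(list(regions = GRanges(), rpm = matrix(numeric(0), 0,
                                                  nrow(samples))))
  }
  regions <- reduce(windows[pass])  # merges overlapping and bookended
  names(regions) <- paste0(axis, "_region_",
                           seqnames(regions), ":", start(regions) - 1, "-",
                           end(regions))
  rc <- count_reads_matrix(reads, regions, samples$sample)
  rs_primary <- window_stats(rc, samples, grp[["a"]], grp[["b"]], thr)
  rs_secondary <- window_stats(rc, samples, grp[["a"]], grp[["sec"]], thr)
  mcols(regions) <- DataFrame(
    region_id = names(regions),
    label = subgroup_label(rs_secondary$fc, axis, thr),
    fc_primary = rs_primary$fc,
    fc_secondary = rs_secondary$fc,
    p = rs_primary$p,
    rpm_ref = rs_primary$rpm_a)
  rpm_all <- rpm_matrix(rc, samples$lib_size[match(colnames(rc),
                                                   samples$sample)])
  list(regions = regions, rpm = rpm_all)
}

#' Convert classified regions to a classified-feature data frame
#'
#' @param regions the `regions` element of [classify_regions()].
#' @param axis `"EGA"` or `"PFF"`.
#' @return classified-feature `data.frame` with chrom/start/end columns
#'   (0-based half-open starts, BED-style).
#' @export
regions_as_frame <- function(regions, axis) {
  if (length(regions) == 0L)
    return(cbind(classified_frame(character(0), character(0), character(0),
                                  character(0), numeric(0), numeric(0),
                                  numeric(0)),
                 chrom = character(0), start = numeric(0), end = numeric(0)))
  out <- classified_frame(mcols(regions)$region_id, "region", axis,
                          mcols(regions)$label, mcols(regions)$fc_primary,
                          mcols(regions)$fc_secondary, mcols(regions)$p)
  out$chrom <- as.character(seqnames(regions))
  out$start <- start(regions) - 1
  out$end <- end(regions)
  out
}

#' Score treatment restoration of resistant features
#'
#' An EGA-OFF feature counts as reactivated in a treated group iff
#' FC(treated/SCNT4c) > `restore_fc`; a PFF-ON feature counts as silenced
#' iff FC(treated/SCNT4c) < `1 / restore_fc` (strict inequalities, so FC
#' exactly 0.5 is not silenced at the default).
#'
#' @param classified classified-feature `data.frame` (genes or regions).
#'   Only rows with label `OFF` (EGA axis) or `ON` (PFF axis) are scored.
#' @param expr features x samples normalized-expression matrix (FPKM for
#'   genes, RPM for regions); rownames must cover
#'   `classified$feature_id`.
#' @param samples a [sample_table()] containing SCNT4c and the treated
#'   group.
#' @param treated treated group label (e.g. `"SCNT4c_KG"`).
#' @param thr a [threshold_config()].
#' @return list with `flags` (`data.frame`: feature_id, axis, fc_treated,
#'   restored) and `fraction` (restored fraction among scored features,
#'   `NaN` when none).
#' @export
assess_restoration <- function(classified, expr, samples, treated,
                               thr = threshold_config()) {
  if (!treated %in% samples$group) stop("treated group '", treated,
                                        "' absent from samples")
  resistant <- classified[(classified$axis == "EGA" & classified$label == "OFF") |
                          (classified$axis == "PFF" & classified$label == "ON"), ]
  gm <- group_means(expr, samples, c("SCNT4c", treated))
  gm <- gm[match(resistant$feature_id, rownames(expr)), , drop = FALSE]
  fc_treated <- fold_change(gm[, treated], gm[, "SCNT4c"], thr$pseudocount)
  restored <- ifelse(resistant$axis == "EGA",
                     fc_treated > thr$restore_fc,
                     fc_treated < 1 / thr$restore_fc)
  flags <- data.frame(feature_id = resistant$feature_id,
                      axis = resistant$axis, fc_treated = fc_treated,
                      restored = restored, row.names = NULL,
                      stringsAsFactors = FALSE)
  list(flags = flags,
       fraction = if (nrow(flags)) mean(flags$restored) else NaN)
}

#' Classify repeat elements into EGA expression tiers
#'
#' A repeat is EGA-ON iff the fold change of de-logged VST group means
#' (`2^mean - 1`) for IVO4c over IVO2c exceeds the lowest tier cut-off
#' and its mean VST in IVO4c exceeds `repeat_min_vst`. Its tier is the
#' highest cut-off exceeded, so the tier sets nest:
#' `{FC>5}` within `{FC>2}` within `{FC>1}`.
#'
#' @param vst repeats x samples VST matrix from [vst_transform()].
#' @param samples a [sample_table()].
#' @param families character vector of repeat family names (row order);
#'   missing/NA families are reported as class `"unknown"`.
#' @param thr a [threshold_config()].
#' @return list with `repeats` (`data.frame`: feature_id, family, class,
#'   fc, vst_ref, ega_on, tier) and `composition` (table of repeat classes
#'   among EGA-ON repeats).
#' @export
classify_repeats <- function(vst, samples, families,
                             thr = threshold_config()) {
  gm <- group_means(vst, samples, c("IVO2c", "IVO4c"))
  delog <- function(x) pmax(2^x - 1, 0)
  fc <- fold_change(delog(gm[, "IVO4c"]), delog(gm[, "IVO2c"]),
                    thr$pseudocount)
  tiers <- thr$repeat_fc_tiers
  ega_on <- fc > tiers[1L] & gm[, "IVO4c"] > thr$repeat_min_vst
  tier_idx <- rowSums(outer(fc, tiers, ">"))
  tier <- ifelse(ega_on, paste0("FC>", tiers[pmax(tier_idx, 1L)]),
                 NA_character_)
  cls <- repeat_class(families)
  out <- data.frame(feature_id = rownames(vst),
                    family = families, class = cls,
                    fc = fc, vst_ref = gm[, "IVO4c"],
                    ega_on = ega_on, tier = tier,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(repeats = out, composition = table(class = cls[ega_on]))
}

# Repeat family -> class lookup for the family vocabulary used by the
# simulator and common RepeatMasker naming; anything unrecognised is
# "unknown".
repeat_class <- function(families) {
  map <- c(SSRS1 = "satellite", SAT = "satellite",
           `ERV1-2-I_SS` = "LTR", `ERV1-2B-LTR_SS` = "LTR",
           MLT1E2 = "LTR", LTR14B_SS = "LTR", ERVL = "LTR",
           L1_SS = "LINE", L1 = "LINE", L2 = "LINE",
           PRE1 = "SINE", PRE0_SS = "SINE", MIR = "SINE",
           Charlie = "DNA", hAT = "DNA", Mariner = "DNA")
  out <- unname(map[as.character(families)])
  out[is.na(out)] <- "unknown"
  out
}

#' Write a class-count / restoration summary as JSON
#'
#' @param path output path.
#' @param class_counts named list or vector of class counts.
#' @param restored_fractions named list of restored fractions (optional).
#' @return the path, invisibly.
#' @export
write_class_summary <- function(path, class_counts,
                                restored_fractions = NULL) {
  obj <- list(class_counts = as.list(class_counts))
  if (!is.null(restored_fractions))
    obj$restored_fractions <- as.list(restored_fractions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
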