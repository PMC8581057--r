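#' Simulation configuration
#'
#' Parameters of the planted-truth multi-omic simulator. Defaults encode
#' the statistical structure the analysis assumes: negative-binomial
#' counts with bulk-RNA-seq overdispersion, a 10-fold planted activation
#' at EGA, 4-fold repressive-mark enrichment and hypermethylation on
#' resistant features, and six sample groups (PFF, IVO2c, IVO4c, SCNT4c,
#' SCNT4c_KG, SCNT4c_TDG).
#'
#' @param seed RNG seed; fixes all outputs bit-for-bit.
#' @param n_chroms,chrom_length genome layout (equal-length chromosomes).
#' @param n_genes,n_repeats feature numbers.
#' @param replicates_per_group replicates per sample group (default 2).
#' @param baseline_mean expected count of an expressed feature (default
#'   100).
#' @param dispersion NB dispersion phi, `var = mu + phi mu^2` (default
#'   0.1).
#' @param frac_ega_on fraction of genes activated at IVO4c.
#' @param frac_ega_off_given_on fraction of EGA genes that fail in SCNT4c.
#' @param frac_pff_off fraction of genes expressed in PFF and silenced at
#'   EGA.
#' @param frac_pff_on_given_off fraction of PFF-OFF genes that stay on in
#'   SCNT4c.
#' @param activation_fc planted fold change for activation/silencing
#'   (default 10).
#' @param chip_enrich_fc planted ChIP enrichment on resistant features
#'   (default 4).
#' @param meth_high,meth_low,meth_background planted CpG methylation
#'   proportions (defaults 0.8 / 0.2 / 0.5).
#' @param restore_frac fraction of resistant features restored in treated
#'   groups (default 0.6).
#' @param n_region_blocks planted region blocks per type, recycled to the
#'   four types (EGA fully-on, EGA-OFF, PFF fully-off, PFF-ON); default 2
#'   each.
#' @param region_block_min,region_block_max block length range in bp;
#'   blocks are planted aligned to the window step grid.
#' @param region_gap minimum gap between blocks in bp (default 300 kb, so
#'   100-kb meta-profile flanks of neighbouring blocks do not collide).
#' @param reads_per_sample read 5' positions simulated per sample for the
#'   sliding-window axis (default 2e5).
#' @param gene_length gene length in bp (default 2000).
#' @param window_size,window_step sliding-window geometry the blocks are
#'   aligned to (defaults 50 kb / 20 kb).
#' @param chip_bin,chip_base_rate ChIP track binning (bp) and baseline
#'   Poisson rate per bin (defaults 200 bp, 20 reads).
#' @param cpg_spacing,cgi_cpg_spacing CpG grid spacing outside/inside CpG
#'   islands (defaults 150 / 20 bp).
#' @param cpg_coverage mean per-CpG bisulfite coverage (Poisson; default
#'   10).
#' @param frac_cgi_promoters fraction of gene promoters given a CpG
#'   island (default 0.5).
#' @param tss_flank promoter half-width used for planted promoter signal
#'   (default 5 kb).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 5e6,
                              n_genes = 1000L, n_repeats = 600L,
                              replicates_per_group = 2L,
                              baseline_mean = 100, dispersion = 0.1,
                              frac_ega_on = 0.2,
                              frac_ega_off_given_on = 0.4,
                              frac_pff_off = 0.25,
                              frac_pff_on_given_off = 0.1,
                              activation_fc = 10, chip_enrich_fc = 4,
                              meth_high = 0.8, meth_low = 0.2,
                              meth_background = 0.5, restore_frac = 0.6,
                              n_region_blocks = 2L,
                              region_block_min = 100000,
                              region_block_max = 200000,
                              region_gap = 300000,
                              reads_per_sample = 200000L,
                              gene_length = 2000L, window_size = 50000L,
                              window_step = 20000L, chip_bin = 200L,
                              chip_base_rate = 20, cpg_spacing = 150L,
                              cgi_cpg_spacing = 20L, cpg_coverage = 10,
                              frac_cgi_promoters = 0.5, tss_flank = 5000L) {
  cfg <- as.list(environment())
  fracs <- c(cfg$frac_ega_on, cfg$frac_ega_off_given_on, cfg$frac_pff_off,
             cfg$frac_pff_on_given_off, cfg$restore_frac,
             cfg$frac_cgi_promoters, cfg$meth_high, cfg$meth_low,
             cfg$meth_background)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$replicates_per_group < 1L) stop("need at least one replicate")
  if (cfg$baseline_mean <= 0 || cfg$dispersion <= 0)
    stop("baseline mean and dispersion must be > 0")
  if (cfg$chrom_length < cfg$window_size)
    stop("chromosomes must be at least one window long")
  if (cfg$frac_ega_on + cfg$frac_pff_off > 1)
    stop("frac_ega_on + frac_pff_off must not exceed 1")
  cfg$n_region_blocks <- rep_len(as.integer(cfg$n_region_blocks), 4L)
  structure(cfg, class = "simulation_config")
}

sim_groups <- c("PFF", "IVO2c", "IVO4c", "SCNT4c", "SCNT4c_KG",
                "SCNT4c_TDG")

block_types <- c("EGA_FULLY_ON", "EGA_OFF", "PFF_FULLY_OFF", "PFF_ON")

sim_layout <- function(cfg) {
  genome_layout(paste0("chr", seq_len(cfg$n_chroms)),
                rep(cfg$chrom_length, cfg$n_chroms))
}

# Evenly spaced feature intervals, offset from chromosome ends so that
# TSS +/- tss_flank windows stay on-chromosome, optionally avoiding
# forbidden intervals (planted region blocks are gene-poor, mirroring the
# heterochromatic character of reprogramming-resistant regions).
place_features <- function(cfg, n, feat_len, offset = 0,
                           forbidden = GRanges()) {
  layout <- sim_layout(cfg)
  # per-chromosome intervals where a feature start may fall
  allowed <- lapply(names(layout), function(ch) {
    ok <- IRanges(cfg$tss_flank + 1 + offset,
                  layout[[ch]] - cfg$tss_flank - feat_len)
    if (length(forbidden)) {
      bad <- ranges(forbidden[seqnames(forbidden) == ch])
      if (length(bad)) {
        # grow so that the whole feature and its promoter stay outside
        bad <- IRanges(start(bad) - cfg$tss_flank - feat_len,
                       end(bad) + cfg$tss_flank)
        ok <- setdiff(ok, bad)
      }
    }
    ok[width(ok) > feat_len]
  })
  lens <- vapply(allowed, function(r) sum(as.numeric(width(r))), numeric(1))
  if (sum(lens) < n * (feat_len + 1))
    stop("chromosome too short to host requested features")
  per <- diff(round(cumsum(c(0, lens)) / sum(lens) * n))
  gr <- GRanges()
  for (k in seq_along(layout)) {
    if (per[k] == 0L) next
    spacing <- floor(lens[k] / per[k])
    if (spacing < feat_len + 1)
      stop("chromosome too short to host requested features")
    offs <- (seq_len(per[k]) - 1) * spacing  # offsets in allowed space
    cum <- cumsum(c(0, as.numeric(width(allowed[[k]]))))
    seg <- findInterval(offs, cum, rightmost.closed = FALSE)
    starts <- start(allowed[[k]])[seg] + (offs - cum[seg])
    gr <- suppressWarnings(
      c(gr, GRanges(names(layout)[k], IRanges(starts, width = feat_len))))
  }
  seqlevels(gr) <- names(layout)
  seqlengths(gr) <- layout_seqlengths(layout)
  gr
}

# floor(fraction * n) labelled features chosen by a seeded shuffle.
assign_labels <- function(n, cfg) {
  n_ega <- floor(cfg$frac_ega_on * n)
  n_ega_off <- floor(cfg$frac_ega_off_given_on * n_ega)
  n_pff <- floor(cfg$frac_pff_off * n)
  n_pff_on <- floor(cfg$frac_pff_on_given_off * n_pff)
  perm <- sample.int(n)
  label <- rep("NONE", n)
  ega <- perm[seq_len(n_ega)]
  label[ega[seq_len(n_ega_off)]] <- "EGA_OFF"
  label[setdiff(ega, ega[seq_len(n_ega_off)])] <- "EGA_FULLY_ON"
  pff <- perm[n_ega + seq_len(n_pff)]
  label[pff[seq_len(n_pff_on)]] <- "PFF_ON"
  label[setdiff(pff, pff[seq_len(n_pff_on)])] <- "PFF_FULLY_OFF"
  label
}

restore_flags <- function(label, cfg) {
  restored <- rep(FALSE, length(label))
  for (lb in c("EGA_OFF", "PFF_ON")) {
    idx <- which(label == lb)
    n_res <- floor(cfg$restore_frac * length(idx))
    restored[idx[seq_len(n_res)]] <- TRUE
  }
  restored
}

# Planted group means for one gene-like feature.
label_means <- function(label, restored, cfg) {
  base <- cfg$baseline_mean; hi <- cfg$activation_fc * base
  mu <- setNames(rep(base, length(sim_groups)), sim_groups)
  if (label == "EGA_FULLY_ON") {
    mu[c("IVO4c", "SCNT4c", "SCNT4c_KG", "SCNT4c_TDG")] <- hi
  } else if (label == "EGA_OFF") {
    mu["IVO4c"] <- hi
    if (restored) mu[c("SCNT4c_KG", "SCNT4c_TDG")] <- hi
  } else if (label == "PFF_FULLY_OFF") {
    mu["PFF"] <- hi
  } else if (label == "PFF_ON") {
    mu["PFF"] <- hi
    mu["SCNT4c"] <- hi
    if (!restored) mu[c("SCNT4c_KG", "SCNT4c_TDG")] <- hi
  }
  mu
}

nb_count_matrix <- function(mu_matrix, cfg) {
  reps <- cfg$replicates_per_group
  size <- 1 / cfg$dispersion
  cols <- as.vector(t(outer(sim_groups, seq_len(reps),
                            function(g, r) paste0(g, "_rep", r))))
  mu_cols <- mu_matrix[, rep(sim_groups, each = reps), drop = FALSE]
  counts <- matrix(rnbinom(length(mu_cols), mu = as.vector(mu_cols),
                           size = size),
                   nrow = nrow(mu_matrix),
                   dimnames = list(rownames(mu_matrix), cols))
  storage.mode(counts) <- "integer"
  counts
}

sim_sample_table <- function(cfg, lib_sizes) {
  reps <- cfg$replicates_per_group
  ids <- as.vector(t(outer(sim_groups, seq_len(reps),
                           function(g, r) paste0(g, "_rep", r))))
  sample_table(ids, rep(sim_groups, each = reps),
               rep(seq_len(reps), times = length(sim_groups)),
               lib_sizes[ids])
}

# Grid-aligned planted region blocks, spread sequentially over the
# chromosomes with at least region_gap between blocks.
place_blocks <- function(cfg) {
  layout <- sim_layout(cfg)
  step <- cfg$window_step
  n_per_type <- cfg$n_region_blocks
  types <- rep(block_types, n_per_type)
  if (length(types) == 0L)
    return(GRanges(seqlengths = layout_seqlengths(layout)))
  types <- sample(types)  # interleave types along the genome
  len_choices <- seq(ceiling(cfg$region_block_min / step) * step,
                     floor(cfg$region_block_max / step) * step, by = step)
  lens <- sample(len_choices, length(types), replace = TRUE)
  gap <- ceiling(cfg$region_gap / step) * step
  chrom_i <- 1L; cursor <- gap
  chs <- character(length(types)); starts0 <- numeric(length(types))
  for (i in seq_along(types)) {
    while (cursor + lens[i] + gap > layout[[chrom_i]]) {
      chrom_i <- chrom_i + 1L
      if (chrom_i > length(layout))
        stop("chromosomes too short to host requested region blocks")
      cursor <- gap
    }
    chs[i] <- names(layout)[chrom_i]
    starts0[i] <- cursor
    cursor <- cursor + lens[i] + gap
  }
  gr <- GRanges(chs, IRanges(starts0 + 1, width = lens))
  seqlevels(gr) <- names(layout)
  seqlengths(gr) <- layout_seqlengths(layout)
  mcols(gr)$label <- types
  mcols(gr)$restored <- restore_flags(types, cfg)
  names(gr) <- paste0("block_", seq_along(gr), "_", types)
  gr
}

# Per-sample read 5' positions from a piecewise-constant density over
# baseline genome and planted blocks.
simulate_region_reads <- function(cfg, blocks, samples) {
  layout <- sim_layout(cfg)
  # disjoint segments: block pieces + the gaps between them
  segs <- GRanges(seqlengths = layout_seqlengths(layout))
  for (ch in names(layout)) {
    bl <- blocks[seqnames(blocks) == ch]
    bounds <- sort(unique(c(0, start(bl) - 1, end(bl), layout[[ch]])))
    s0 <- head(bounds, -1L); e0 <- tail(bounds, -1L)
    keep <- e0 > s0
    segs <- suppressWarnings(
      c(segs, GRanges(ch, IRanges(s0[keep] + 1, e0[keep]))))
  }
  hit <- findOverlaps(segs, blocks, type = "within")
  seg_label <- rep("NONE", length(segs))
  seg_restored <- rep(FALSE, length(segs))
  seg_label[queryHits(hit)] <- mcols(blocks)$label[subjectHits(hit)]
  seg_restored[queryHits(hit)] <- mcols(blocks)$restored[subjectHits(hit)]
  fc <- cfg$activation_fc
  seg_weight <- function(group) {
    w <- rep(1, length(segs))
    up <- switch(group,
      PFF = seg_label %in% c("PFF_FULLY_OFF", "PFF_ON"),
      IVO2c = rep(FALSE, length(segs)),
      IVO4c = seg_label %in% c("EGA_FULLY_ON", "EGA_OFF"),
      SCNT4c = seg_label %in% c("EGA_FULLY_ON", "PFF_ON"),
      SCNT4c_KG = seg_label == "EGA_FULLY_ON" |
        (seg_label == "EGA_OFF" & seg_restored) |
        (seg_label == "PFF_ON" & !seg_restored),
      SCNT4c_TDG = seg_label == "EGA_FULLY_ON" |
        (seg_label == "EGA_OFF" & seg_restored) |
        (seg_label == "PFF_ON" & !seg_restored))
    w[up] <- fc
    w
  }
  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    w <- seg_weight(samples$group[i]) * width(segs)
    nseg <- as.vector(stats::rmultinom(1L, cfg$reads_per_sample,
                                       w / sum(w)))
    pos <- unlist(lapply(which(nseg > 0), function(s)
      start(segs)[s] + floor(runif(nseg[s]) * width(segs)[s])))
    out[[i]] <- data.table::data.table(
      sample = samples$sample[i],
      chrom = rep(as.character(seqnames(segs)), nseg),
      pos = as.integer(pos))
  }
  data.table::rbindlist(out)
}

#' Simulate one binned ChIP or input coverage track
#'
#' Poisson counts per fixed-width bin around a baseline rate, with bins
#' whose midpoints fall in `enriched` intervals scaled by `enrich_fc`.
#'
#' @param layout a [genome_layout()].
#' @param bin_width bin width in bp.
#' @param base_rate baseline Poisson mean per bin.
#' @param enriched `GRanges` of enriched intervals (empty for a flat
#'   input track).
#' @param enrich_fc rate multiplier inside `enriched` (default 1).
#' @param role,mark passed to [signal_track()].
#' @return a [signal_track()].
#' @export
simulate_chip_track <- function(layout, bin_width, base_rate,
                                enriched = GRanges(), enrich_fc = 1,
                                role = "chip", mark = NA_character_) {
  counts <- list()
  for (ch in names(layout)) {
    nb <- ceiling(layout[[ch]] / bin_width)
    rate <- rep(base_rate, nb)
    if (length(enriched)) {
      mids <- GRanges(ch, IRanges((seq_len(nb) - 1) * bin_width +
                                    floor(bin_width / 2) + 1, width = 1L))
      rate[overlapsAny(mids, enriched)] <- base_rate * enrich_fc
    }
    counts[[ch]] <- rpois(nb, rate)
  }
  signal_track(layout, bin_width, counts, role = role, mark = mark)
}

#' Simulate per-CpG bisulfite calls at given sites and levels
#'
#' Coverage is Poisson(`coverage`); the methylated count is
#' Binomial(coverage, level). Sites drawing zero coverage are kept with
#' zero counts.
#'
#' @param chrom,pos site coordinates (1-based).
#' @param level per-site methylation proportion (recycled).
#' @param coverage mean coverage (default 10).
#' @return a [cpg_calls()] table (all plus-strand).
#' @export
simulate_cpg_calls <- function(chrom, pos, level, coverage = 10) {
  n <- length(pos)
  level <- rep_len(level, n)
  cov <- rpois(n, coverage)
  m <- rbinom(n, cov, level)
  cpg_calls(chrom, pos, rep("+", n), m, cov - m)
}

# CpG site grid: background spacing everywhere, dense spacing inside CGIs.
cpg_site_grid <- function(cfg, cgi) {
  layout <- sim_layout(cfg)
  sites <- lapply(names(layout), function(ch) {
    bg <- seq(1L, layout[[ch]], by = cfg$cpg_spacing)
    dense <- integer(0)
    cg <- cgi[seqnames(cgi) == ch]
    if (length(cg))
      dense <- unlist(lapply(seq_along(cg), function(i)
        seq(start(cg)[i], end(cg)[i], by = cfg$cgi_cpg_spacing)))
    data.table::data.table(chrom = ch,
                           pos = sort(unique(c(bg, as.integer(dense)))))
  })
  data.table::rbindlist(sites)
}

# Planted methylation level per CpG site for one sample.
planted_meth_levels <- function(cfg, sites, genes, cgi, blocks, group) {
  gpos <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
  lvl <- rep(cfg$meth_background, nrow(sites))
  tss <- gene_tss(genes)
  prom <- suppressWarnings(resize(tss, width = 2 * cfg$tss_flank,
                                  fix = "center"))
  prom <- trim_to_layout(prom)
  resistant_gene <- mcols(genes)$label %in% c("EGA_OFF", "PFF_ON")
  has_cgi <- mcols(genes)$has_cgi
  # somatic promoter methylation outside CGIs
  lvl[overlapsAny(gpos, prom[!has_cgi])] <- cfg$meth_high
  # resistant blocks and resistant non-CGI promoters are hypermethylated
  resistant_blocks <- blocks[mcols(blocks)$label %in% c("EGA_OFF", "PFF_ON")]
  lvl[overlapsAny(gpos, resistant_blocks)] <- cfg$meth_high
  lvl[overlapsAny(gpos, prom[resistant_gene & !has_cgi])] <- cfg$meth_high
  if (group == "SCNT4c_TDG") {
    # transient TDG expression demethylates the resistant features
    lvl[overlapsAny(gpos, resistant_blocks)] <- cfg$meth_low
    lvl[overlapsAny(gpos, prom[resistant_gene])] <- cfg$meth_low
  }
  # CpG islands stay unmethylated except under the TDG override above
  if (group != "SCNT4c_TDG")
    lvl[overlapsAny(gpos, cgi)] <- cfg$meth_low
  else
    lvl[overlapsAny(gpos, cgi) &
          !overlapsAny(gpos, c(granges(resistant_blocks),
                               granges(prom[resistant_gene])))] <- cfg$meth_low
  lvl
}

#' Strand-aware TSS positions of gene intervals
#' @param genes `GRanges` with strand.
#' @return width-1 `GRanges` at each gene's 5' end.
#' @export
gene_tss <- function(genes) {
  suppressWarnings(resize(genes, width = 1L, fix = "start"))
}

#' Simulate a planted-truth multi-omic experiment
#'
#' Generates, under one seed: gene and repeat count matrices for the six
#' sample groups with negative-binomial noise and planted
#' EGA-ON/OFF and PFF-OFF/ON structure; read positions over a genome with
#' planted activated/persistent region blocks; matched ChIP/input tracks
#' with repressive-mark enrichment on resistant features; per-CpG
#' bisulfite calls with planted methylation levels; gene, repeat and CGI
#' annotations; and a truth table recording every planted label.
#'
#' @param cfg a [simulation_config()].
#' @return list of class `rr_sim` with elements `config`, `layout`,
#'   `samples`, `genes`, `gene_counts`, `repeats`, `repeat_counts`,
#'   `truth_regions`, `reads`, `chip`, `meth`, `cgi`, `truth`.
#' @export
simulate_experiment <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  layout <- sim_layout(cfg)

  # planted region blocks first: genes avoid them (resistant regions are
  # gene-poor heterochromatin)
  blocks <- place_blocks(cfg)

  # genes: placement, labels, counts
  genes <- place_features(cfg, cfg$n_genes, cfg$gene_length,
                          forbidden = blocks)
  strand(genes) <- sample(c("+", "-"), length(genes), replace = TRUE)
  names(genes) <- sprintf("gene%05d", seq_along(genes))
  g_label <- assign_labels(length(genes), cfg)
  g_restored <- restore_flags(g_label, cfg)
  has_cgi <- rep(FALSE, length(genes))
  has_cgi[sample.int(length(genes),
                     floor(cfg$frac_cgi_promoters * length(genes)))] <- TRUE
  mcols(genes) <- DataFrame(label = g_label, restored = g_restored,
                            has_cgi = has_cgi)
  mu_genes <- t(vapply(seq_along(genes), function(i)
    label_means(g_label[i], g_restored[i], cfg), numeric(6)))
  rownames(mu_genes) <- names(genes)
  gene_counts <- nb_count_matrix(mu_genes, cfg)
  samples <- sim_sample_table(cfg, colSums(gene_counts))

  # repeats: placement, families, tiers, counts
  repeats <- place_features(cfg, cfg$n_repeats, 500L, offset = 700L)
  names(repeats) <- sprintf("rep%05d", seq_along(repeats))
  fam_pool <- c("SSRS1", "ERV1-2-I_SS", "ERV1-2B-LTR_SS", "MLT1E2",
                "LTR14B_SS", "L1_SS", "PRE1", "Charlie")
  fams <- sample(fam_pool, length(repeats), replace = TRUE)
  n_rep_ega <- floor(cfg$frac_ega_on * length(repeats))
  tier_fc <- c(1.5, 3, cfg$activation_fc)
  tier_lab <- c("FC>1", "FC>2", "FC>5")
  r_label <- rep("NONE", length(repeats))
  r_fc <- rep(1, length(repeats))
  idx <- sample.int(length(repeats))[seq_len(n_rep_ega)]
  tier_of <- rep_len(seq_along(tier_fc), n_rep_ega)
  r_label[idx] <- tier_lab[tier_of]
  r_fc[idx] <- tier_fc[tier_of]
  r_restored <- restore_flags(ifelse(r_label == "NONE", "NONE", "EGA_OFF"),
                              cfg)
  base <- cfg$baseline_mean
  mu_rep <- matrix(base, length(repeats), 6,
                   dimnames = list(names(repeats), sim_groups))
  mu_rep[, "IVO4c"] <- base * r_fc
  mu_rep[r_restored, "SCNT4c_KG"] <- base * r_fc[r_restored]
  mu_rep[r_restored, "SCNT4c_TDG"] <- base * r_fc[r_restored]
  mcols(repeats) <- DataFrame(family = fams, label = r_label,
                              restored = r_restored)
  repeat_counts <- nb_count_matrix(mu_rep, cfg)

  # read positions over the block structure
  reads <- simulate_region_reads(cfg, blocks, samples)

  # ChIP: repressive mark enriched on resistant blocks and resistant-gene
  # promoters, in both PFF and SCNT4c; matched flat inputs
  tss <- gene_tss(genes)
  resistant_prom <- trim_to_layout(suppressWarnings(
    resize(tss[g_label %in% c("EGA_OFF", "PFF_ON")],
           width = 2 * cfg$tss_flank, fix = "center")))
  enriched <- reduce(c(granges(blocks[mcols(blocks)$label %in%
                                        c("EGA_OFF", "PFF_ON")]),
                       granges(resistant_prom)))
  chip <- list()
  for (smp in c("PFF", "SCNT4c")) {
    chip[[smp]] <- list(
      chip = simulate_chip_track(layout, cfg$chip_bin, cfg$chip_base_rate,
                                 enriched, cfg$chip_enrich_fc,
                                 role = "chip", mark = "H3K9me3"),
      input = simulate_chip_track(layout, cfg$chip_bin,
                                  cfg$chip_base_rate, role = "input"))
  }

  # methylation: CGIs at selected promoters, CpG grid, planted levels
  cgi_genes <- genes[has_cgi]
  cgi <- trim_to_layout(suppressWarnings(
    resize(gene_tss(cgi_genes), width = 1000L, fix = "center")))
  names(cgi) <- NULL
  sites <- cpg_site_grid(cfg, cgi)
  meth <- list()
  for (smp in c("PFF", "SCNT4c", "SCNT4c_TDG")) {
    lvl <- planted_meth_levels(cfg, sites, genes, cgi, blocks, smp)
    meth[[smp]] <- simulate_cpg_calls(sites$chrom, sites$pos, lvl,
                                      cfg$cpg_coverage)
  }

  truth_rows <- function(ids, kind, label, restored) {
    if (length(ids) == 0L)
      return(data.frame(feature_id = character(0),
                        feature_kind = character(0),
                        planted_label = character(0),
                        planted_restored = logical(0),
                        stringsAsFactors = FALSE))
    data.frame(feature_id = ids, feature_kind = kind,
               planted_label = label, planted_restored = restored,
               stringsAsFactors = FALSE)
  }
  truth <- rbind(
    truth_rows(names(genes), "gene", g_label, g_restored),
    truth_rows(names(blocks), "window-region", mcols(blocks)$label,
               mcols(blocks)$restored),
    truth_rows(names(repeats), "repeat", r_label, r_restored))

  structure(list(config = cfg, layout = layout, samples = samples,
                 genes = genes, gene_counts = gene_counts,
                 repeats = repeats, repeat_counts = repeat_counts,
                 truth_regions = blocks, reads = reads, chip = chip,
                 meth = meth, cgi = cgi, truth = truth),
            class = "rr_sim")
}

#' @export
print.rr_sim <- function(x, ...) {
  cat("rr_sim: ", length(x$genes), " genes, ", length(x$repeats),
      " repeats, ", length(x$truth_regions), " planted blocks, ",
      nrow(x$samples), " samples (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}
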