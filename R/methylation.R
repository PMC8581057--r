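#' CpG call set
#'
#' Per-CpG bisulfite calls: chromosome, 1-based position, strand,
#' methylated and unmethylated read counts.
#'
#' @param chrom,pos,strand,meth,unmeth per-CpG fields; positions must be
#'   unique per (chrom, strand) and counts non-negative.
#' @return `data.table` of class `cpg_calls` with a `cov` column.
#' @export
cpg_calls <- function(chrom, pos, strand, meth, unmeth) {
  dt <- data.table::data.table(chrom = as.character(chrom),
                               pos = as.integer(pos),
                               strand = as.character(strand),
                               meth = as.integer(meth),
                               unmeth = as.integer(unmeth))
  if (nrow(dt)) {
    if (any(dt$meth < 0 | dt$unmeth < 0)) stop("counts must be non-negative")
    if (anyDuplicated(dt[, c("chrom", "strand", "pos")]))
      stop("positions must be unique per (chrom, strand)")
  }
  dt[, "cov" := dt$meth + dt$unmeth]
  data.table::setattr(dt, "class", c("cpg_calls", class(dt)))
  dt[]
}

#' Read a CpG call file
#'
#' Tab-separated, no header: chrom, 1-based position, strand, methylated
#' count, unmethylated count (the common cytosine-report layout).
#'
#' @param path input path.
#' @return a [cpg_calls()] table.
#' @export
read_cpg_calls <- function(path) {
  if (file.size(path) == 0)
    return(cpg_calls(character(0), integer(0), character(0), integer(0),
                     integer(0)))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 3)),
                          fill = TRUE)
  if (ncol(dt) != 5L)
    stop("malformed CpG file (need 5 columns): ", path)
  bad <- which(is.na(dt[[2]]) | is.na(dt[[4]]) | is.na(dt[[5]]) |
                 !dt[[3]] %in% c("+", "-"))
  if (length(bad))
    stop("malformed CpG row at line ", bad[1L], " of ", path)
  cpg_calls(dt[[1]], dt[[2]], dt[[3]], dt[[4]], dt[[5]])
}

#' Write a CpG call file
#' @param calls a [cpg_calls()] table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cpg_calls <- function(calls, path) {
  data.table::fwrite(calls[, c("chrom", "pos", "strand", "meth", "unmeth")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

cpg_positions <- function(calls) {
  GRanges(calls$chrom, IRanges(calls$pos, width = 1L))
}

#' CpG methylation level over intervals
#'
#' Per interval, the coverage-weighted pooled ratio
#' `sum(methylated) / sum(methylated + unmethylated)` over contained CpGs
#' with coverage at least `min_cov`; intervals with no qualifying CpG get
#' `NA` (undefined, not zero). Setting `per_cpg_mean = TRUE` averages the
#' per-CpG ratios instead.
#'
#' @param calls a [cpg_calls()] table.
#' @param intervals `GRanges`.
#' @param min_cov minimum per-CpG coverage (default 1).
#' @param per_cpg_mean average per-CpG ratios instead of pooling
#'   (default `FALSE`).
#' @return `data.frame`: interval (name or coordinates), meth, total,
#'   level, n_cpgs.
#' @export
meth_level <- function(calls, intervals, min_cov = 1L,
                       per_cpg_mean = FALSE) {
  keep <- calls$cov >= min_cov
  sub <- calls[keep, ]
  hits <- findOverlaps(cpg_positions(sub), intervals)
  n <- length(intervals)
  meth <- total <- ncpg <- numeric(n)
  ratio_sum <- numeric(n)
  if (length(hits)) {
    j <- subjectHits(hits); q <- queryHits(hits)
    meth <- as.numeric(tapply(sub$meth[q], factor(j, levels = seq_len(n)),
                              sum, default = 0))
    total <- as.numeric(tapply(sub$cov[q], factor(j, levels = seq_len(n)),
                               sum, default = 0))
    ncpg <- as.numeric(tapply(q, factor(j, levels = seq_len(n)), length,
                              default = 0))
    ratio_sum <- as.numeric(tapply(sub$meth[q] / sub$cov[q],
                                   factor(j, levels = seq_len(n)), sum,
                                   default = 0))
  }
  level <- ifelse(total > 0,
                  if (per_cpg_mean) ratio_sum / pmax(ncpg, 1)
                  else meth / pmax(total, 1),
                  NA_real_)
  nm <- names(intervals)
  if (is.null(nm))
    nm <- paste0(seqnames(intervals), ":", start(intervals) - 1, "-",
                 end(intervals))
  data.frame(interval = nm, meth = meth, total = total, level = level,
             n_cpgs = ncpg, row.names = NULL, stringsAsFactors = FALSE)
}

#' Promoter methylation stratified by CpG-island overlap
#'
#' Promoters are `[TSS - half_width, TSS + half_width)` clipped to the
#' chromosome; a promoter is "with CGI" iff it overlaps any CGI interval
#' by at least 1 bp.
#'
#' @inheritParams meth_level
#' @param tss `GRanges` of width-1 TSS positions (names used as gene
#'   ids).
#' @param cgi `GRanges` of CpG islands.
#' @param half_width promoter half-width in bp (default 5 kb).
#' @return list with `with_cgi` and `without_cgi` [meth_level()]
#'   data frames.
#' @export
promoter_meth_by_cgi <- function(calls, tss, cgi, half_width = 5000,
                                 min_cov = 1L) {
  prom <- suppressWarnings(resize(tss, width = 2 * half_width, fix = "center"))
  prom <- trim_to_layout(prom)
  has_cgi <- overlapsAny(prom, cgi)
  list(with_cgi = meth_level(calls, prom[has_cgi], min_cov = min_cov),
       without_cgi = meth_level(calls, prom[!has_cgi], min_cov = min_cov))
}

# Clip GRanges to [1, seqlength]; requires seqlengths set.
trim_to_layout <- function(gr) {
  sl <- seqlengths(gr)
  if (any(is.na(sl[as.character(seqnames(gr))])))
    stop("seqlengths required to clip intervals")
  start(gr) <- pmax(start(gr), 1L)
  end(gr) <- pmin(end(gr), sl[as.character(seqnames(gr))])
  gr
}

#' Scaled-body methylation meta-profile over regions
#'
#' Same flank/body/flank binning as [region_metaprofile()]; each bin's
#' value is the pooled CpG ratio across all features. Bins with no
#' qualifying CpG in any feature are `NA` and excluded from summaries.
#'
#' @inheritParams meth_level
#' @param regions `GRanges` (minus-strand features orientation-flipped).
#' @param flank flank width in bp (default 100 kb).
#' @param body_bins,flank_bins binning (defaults 100 / 50).
#' @return list of class `meta_profile`: `mean` (pooled per-bin level),
#'   `matrix` (per-feature per-bin levels), `axis`.
#' @export
region_meth_profile <- function(calls, regions, flank = 100000,
                                body_bins = 100L, flank_bins = 50L,
                                min_cov = 1L) {
  if (length(regions) == 0L) stop("empty region set")
  sub <- calls[calls$cov >= min_cov, ]
  data.table::setorder(sub, chrom, pos)
  nb <- 2L * flank_bins + body_bins
  num <- den <- matrix(0, length(regions), nb)
  lvl <- matrix(NA_real_, length(regions), nb)
  ch <- as.character(seqnames(regions))
  str <- as.character(strand(regions))
  sl <- seqlengths(regions)
  # per-chromosome sorted positions with cumulative counts
  by_chrom <- split(sub, sub$chrom)
  cums <- lapply(by_chrom, function(cc)
    list(pos = cc$pos, m = c(0, cumsum(as.numeric(cc$meth))),
         c = c(0, cumsum(as.numeric(cc$cov)))))
  for (i in seq_along(regions)) {
    edges <- metaprofile_edges(sl[[ch[i]]], start(regions)[i] - 1,
                               end(regions)[i], str[i], flank, body_bins,
                               flank_bins)
    cc <- cums[[ch[i]]]
    if (is.null(cc)) next
    ok <- !is.na(edges[, 1])
    # CpGs in 0-based half-open bin (s, e]: positions pos > s & pos <= e
    iS <- findInterval(edges[ok, 1], cc$pos)
    iE <- findInterval(edges[ok, 2], cc$pos)
    num[i, ok] <- cc$m[iE + 1L] - cc$m[iS + 1L]
    den[i, ok] <- cc$c[iE + 1L] - cc$c[iS + 1L]
    lvl[i, ok] <- ifelse(den[i, ok] > 0, num[i, ok] / pmax(den[i, ok], 1),
                         NA_real_)
  }
  pooled_num <- colSums(num); pooled_den <- colSums(den)
  mean_lvl <- ifelse(pooled_den > 0, pooled_num / pmax(pooled_den, 1),
                     NA_real_)
  axis <- rep(c("flank", "body", "flank"),
              c(flank_bins, body_bins, flank_bins))
  structure(list(matrix = lvl, mean = mean_lvl, axis = axis),
            class = "meta_profile")
}
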