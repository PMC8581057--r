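#' Binned coverage track
#'
#' Per-chromosome coverage counts on a fixed binning plus the library
#' size, for one ChIP or input sample.
#'
#' @param layout a [genome_layout()].
#' @param bin_width bin width in bp (default 200).
#' @param counts named list (per chromosome) of non-negative per-bin
#'   counts; chromosome `i` needs `ceiling(length / bin_width)` bins.
#' @param lib_size total mapped reads; default is the sum of counts.
#' @param role `"chip"` or `"input"`.
#' @param mark histone-mark name (e.g. `"H3K9me3"`), `NA` for input.
#' @return list of class `signal_track` (stores per-chromosome cumulative
#'   sums for fast interval queries).
#' @export
signal_track <- function(layout, bin_width = 200L, counts,
                         lib_size = NULL, role = c("chip", "input"),
                         mark = NA_character_) {
  role <- match.arg(role)
  stopifnot(inherits(layout, "genome_layout"))
  if (!setequal(names(counts), names(layout)))
    stop("counts must cover exactly the layout chromosomes")
  counts <- counts[names(layout)]
  for (ch in names(layout)) {
    nb <- ceiling(layout[[ch]] / bin_width)
    if (length(counts[[ch]]) != nb)
      stop("chromosome ", ch, " needs ", nb, " bins")
    if (any(counts[[ch]] < 0)) stop("negative bin counts")
  }
  if (is.null(lib_size)) lib_size <- sum(vapply(counts, sum, numeric(1)))
  if (lib_size <= 0) stop("library size must be > 0")
  structure(list(layout = layout, bin_width = as.numeric(bin_width),
                 counts = counts,
                 cumsums = lapply(counts, function(x) c(0, cumsum(as.numeric(x)))),
                 lib_size = as.numeric(lib_size), role = role, mark = mark),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track (", x$role,
      if (!is.na(x$mark)) paste0(", ", x$mark) else "", "): ",
      length(x$counts), " chromosome(s), bin ", x$bin_width, " bp, ",
      format(x$lib_size, big.mark = ","), " reads\n", sep = "")
  invisible(x)
}

# Read mass of a track on 0-based half-open intervals [s0, e0) of one
# chromosome, prorating partially covered bins by overlap fraction so the
# result is invariant to rebinning on bin-aligned intervals. Vectorised
# over intervals.
track_interval_counts <- function(track, chrom, s0, e0) {
  cs <- track$cumsums[[chrom]]
  if (is.null(cs)) stop("unknown chromosome: ", chrom)
  bw <- track$bin_width
  nbin <- length(cs) - 1L
  s0 <- pmax(s0, 0); e0 <- pmin(e0, track$layout[[chrom]])
  sb <- s0 / bw; eb <- e0 / bw
  mass_at <- function(b) {  # cumulative mass up to bin coordinate b
    lo <- floor(b)
    frac <- b - lo
    lo <- pmin(lo, nbin)
    cs[lo + 1L] + ifelse(lo < nbin, track$counts[[chrom]][lo + 1L], 0) * frac
  }
  pmax(mass_at(eb) - mass_at(sb), 0)
}

# Density in RPM per kb over 0-based half-open intervals.
track_density <- function(track, chrom, s0, e0) {
  len_kb <- (e0 - s0) / 1000
  track_interval_counts(track, chrom, s0, e0) * 1e6 /
    (track$lib_size * len_kb)
}

#' Input-normalized ChIP intensity over intervals
#'
#' Read counts are normalized by input, total mapped reads and interval
#' length: with `d = RPM / kb` densities,
#' `intensity = log2((d_chip + eps) / (d_input + eps))`. The log-ratio is
#' symmetric and invariant to sequencing depth (scaling a track's counts
#' and library size together leaves it unchanged).
#'
#' @param chip,input matched [signal_track()]s on the same binning.
#' @param intervals `GRanges`.
#' @param eps density pseudocount in RPM/kb (default 0.1).
#' @return numeric vector of intensities (log2 units), one per interval.
#' @export
intensity <- function(chip, input, intervals, eps = 0.1) {
  if (chip$bin_width != input$bin_width)
    stop("chip and input must share the binning")
  if (any(width(intervals) <= 0)) stop("zero-length interval")
  ch <- as.character(seqnames(intervals))
  s0 <- start(intervals) - 1; e0 <- end(intervals)
  out <- numeric(length(intervals))
  for (cc in unique(ch)) {
    i <- ch == cc
    dc <- track_density(chip, cc, s0[i], e0[i])
    di <- track_density(input, cc, s0[i], e0[i])
    out[i] <- log2((dc + eps) / (di + eps))
  }
  out
}

# Bin edges (0-based) for one feature's flank/body/flank axis; returns a
# matrix [n_bins x 2] of (start, end), NA rows for bins clipped off the
# chromosome. Minus-strand features are flipped to 5'->3'.
metaprofile_edges <- function(chrom_len, s0, e0, strand, flank, body_bins,
                              flank_bins) {
  fb <- flank / flank_bins
  left <- cbind(s0 - flank + (0:(flank_bins - 1)) * fb,
                s0 - flank + (1:flank_bins) * fb)
  body <- cbind(s0 + (0:(body_bins - 1)) * (e0 - s0) / body_bins,
                s0 + (1:body_bins) * (e0 - s0) / body_bins)
  right <- cbind(e0 + (0:(flank_bins - 1)) * fb, e0 + (1:flank_bins) * fb)
  edges <- rbind(left, body, right)
  clipped <- edges[, 1] < 0 | edges[, 2] > chrom_len
  edges[clipped, ] <- NA_real_
  if (strand == "-") edges <- edges[rev(seq_len(nrow(edges))), , drop = FALSE]
  edges
}

#' Scaled-body meta-profile of ChIP intensity over regions
#'
#' Each region body is rescaled to `body_bins` equal sub-intervals; the
#' `flank` bp on each side are cut into `flank_bins` fixed-width bins.
#' Per-bin intensity is computed as in [intensity()] and averaged over
#' features. Flank bins falling off a chromosome end are clipped: they are
#' `NA` in the per-feature matrix and excluded from the mean.
#'
#' @inheritParams intensity
#' @param regions `GRanges` (strand respected: minus-strand features are
#'   orientation-flipped).
#' @param flank flank width in bp (default 100 kb).
#' @param body_bins scaled body bins (default 100).
#' @param flank_bins fixed-width bins per flank (default 50).
#' @return list of class `meta_profile`: `matrix` (features x bins),
#'   `mean` (per-bin mean over features), `axis` (`"flank"`, `"body"`,
#'   `"flank"` labels per bin).
#' @export
region_metaprofile <- function(chip, input, regions, flank = 100000,
                               body_bins = 100L, flank_bins = 50L,
                               eps = 0.1) {
  if (length(regions) == 0L) stop("empty region set")
  nb <- 2L * flank_bins + body_bins
  mat <- matrix(NA_real_, length(regions), nb)
  ch <- as.character(seqnames(regions))
  str <- as.character(strand(regions))
  for (i in seq_along(regions)) {
    edges <- metaprofile_edges(chip$layout[[ch[i]]], start(regions)[i] - 1,
                               end(regions)[i], str[i], flank, body_bins,
                               flank_bins)
    ok <- !is.na(edges[, 1])
    if (!any(ok)) next
    dc <- track_density(chip, ch[i], edges[ok, 1], edges[ok, 2])
    di <- track_density(input, ch[i], edges[ok, 1], edges[ok, 2])
    mat[i, ok] <- log2((dc + eps) / (di + eps))
  }
  axis <- rep(c("flank", "body", "flank"),
              c(flank_bins, body_bins, flank_bins))
  structure(list(matrix = mat, mean = colMeans(mat, na.rm = TRUE),
                 axis = axis),
            class = "meta_profile")
}

#' TSS-centered meta-profile of ChIP intensity
#'
#' Fixed-width bins over `[TSS - half_width, TSS + half_width)`;
#' minus-strand profiles are reversed so the bin axis runs 5' to 3'.
#'
#' @inheritParams intensity
#' @param tss `GRanges` of width-1 TSS positions with strand.
#' @param half_width half-window in bp (default 5 kb).
#' @param bins number of bins (default 100).
#' @return list of class `meta_profile` (as [region_metaprofile()], axis
#'   all `"tss"`).
#' @export
tss_metaprofile <- function(chip, input, tss, half_width = 5000,
                            bins = 100L, eps = 0.1) {
  if (length(tss) == 0L) stop("empty TSS set")
  bw <- 2 * half_width / bins
  mat <- matrix(NA_real_, length(tss), bins)
  ch <- as.character(seqnames(tss))
  str <- as.character(strand(tss))
  for (i in seq_along(tss)) {
    center <- start(tss)[i] - 1
    if (center - half_width < 0 ||
        center + half_width > chip$layout[[ch[i]]])
      stop("TSS window off chromosome: ", ch[i], ":", center)
    edges <- cbind(center - half_width + (0:(bins - 1)) * bw,
                   center - half_width + (1:bins) * bw)
    dc <- track_density(chip, ch[i], edges[, 1], edges[, 2])
    di <- track_density(input, ch[i], edges[, 1], edges[, 2])
    prof <- log2((dc + eps) / (di + eps))
    if (str[i] == "-") prof <- rev(prof)
    mat[i, ] <- prof
  }
  structure(list(matrix = mat, mean = colMeans(mat, na.rm = TRUE),
                 axis = rep("tss", bins)),
            class = "meta_profile")
}

#' Mean per-feature intensity of a meta-profile
#' @param profile a `meta_profile`.
#' @param part which bins to average: `"all"`, `"body"` or `"flank"`.
#' @return numeric vector, one mean per feature (NA bins excluded).
#' @export
profile_feature_means <- function(profile, part = c("all", "body", "flank")) {
  part <- match.arg(part)
  cols <- if (part == "all") seq_along(profile$axis)
          else which(profile$axis == part)
  rowMeans(profile$matrix[, cols, drop = FALSE], na.rm = TRUE)
}

#' Pairwise t comparisons of per-feature intensities between classes
#'
#' Pooled-variance two-tailed t tests ([two_group_t()]) for every pair of
#' feature classes, with significance stars at 0.05/0.01/0.001.
#'
#' @param groups named list of numeric vectors (per-feature mean
#'   intensities per class). Classes with fewer than 2 members are
#'   skipped with a warning.
#' @return `data.frame`: class_a, class_b, t, p, stars.
#' @export
compare_intensity <- function(groups) {
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) {
    warning("skipping classes with < 2 features: ",
            paste(names(groups)[sizes < 2L], collapse = ", "))
    groups <- groups[sizes >= 2L]
  }
  nm <- names(groups)
  if (length(nm) < 2L) stop("need >= 2 classes with >= 2 features")
  pairs <- utils::combn(nm, 2L)
  res <- apply(pairs, 2L, function(pr) {
    ht <- two_group_t(groups[[pr[1L]]], groups[[pr[2L]]])
    data.frame(class_a = pr[1L], class_b = pr[2L], t = ht$t, p = ht$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$stars <- signif_stars(out$p)
  out
}
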