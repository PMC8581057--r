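#' Sample metadata table
#'
#' @param sample sample ids (unique).
#' @param group group label per sample (e.g. `"IVO4c"`).
#' @param replicate replicate index within group.
#' @param lib_size total mapped reads per sample (> 0).
#' @return `data.frame` with columns sample, group, replicate, lib_size.
#' @export
sample_table <- function(sample, group, replicate, lib_size) {
  if (anyDuplicated(sample)) stop("sample ids must be unique")
  if (any(lib_size <= 0)) stop("every sample needs library size > 0")
  data.frame(sample = as.character(sample), group = as.character(group),
             replicate = as.integer(replicate),
             lib_size = as.numeric(lib_size),
             stringsAsFactors = FALSE)
}

samples_in_group <- function(samples, grp) {
  out <- samples$sample[samples$group == grp]
  if (length(out) == 0L) stop("no samples in group '", grp, "'")
  out
}

#' Reads per million mapped reads
#'
#' `count * 1e6 / library_size`.
#'
#' @param count read count(s) in the feature.
#' @param library_size total mapped reads (> 0).
#' @return RPM value(s).
#' @export
rpm <- function(count, library_size) {
  if (any(library_size <= 0)) stop("library_size must be > 0")
  count * 1e6 / library_size
}

#' Fragments per kilobase per million mapped reads
#'
#' `count * 1e9 / (feature_length * library_size)`.
#'
#' @param count read count(s).
#' @param feature_length feature length in bp (> 0).
#' @param library_size total mapped reads (> 0).
#' @return FPKM value(s).
#' @export
fpkm <- function(count, feature_length, library_size) {
  if (any(feature_length <= 0)) stop("feature_length must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  count * 1e9 / (feature_length * library_size)
}

#' RPM matrix from a count matrix
#' @param counts features x samples count matrix.
#' @param lib_sizes per-sample library sizes (column order).
#' @return numeric matrix of RPM values (unit attribute `"RPM"`).
#' @export
rpm_matrix <- function(counts, lib_sizes) {
  out <- sweep(counts, 2L, lib_sizes, function(c, n) rpm(c, n))
  attr(out, "unit") <- "RPM"
  out
}

#' FPKM matrix from a count matrix
#' @inheritParams rpm_matrix
#' @param lengths per-feature lengths in bp (row order).
#' @return numeric matrix of FPKM values (unit attribute `"FPKM"`).
#' @export
fpkm_matrix <- function(counts, lengths, lib_sizes) {
  out <- counts * 1e9 / outer(as.numeric(lengths), as.numeric(lib_sizes))
  dimnames(out) <- dimnames(counts)
  attr(out, "unit") <- "FPKM"
  out
}

#' Median-of-ratios size factors
#'
#' Reference is the per-feature geometric mean over samples, computed on
#' features with all-positive counts; each sample's size factor is the
#' median ratio of its counts to the reference. When no feature is
#' positive in every sample, falls back to library-size ratios
#' (`colSums / mean(colSums)`).
#'
#' @param counts features x samples count matrix.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    logc <- log(counts[pos, , drop = FALSE])
    ref <- rowMeans(logc)
    sf <- apply(logc, 2L, function(x) exp(median(x - ref)))
  } else {
    ls <- colSums(counts)
    if (all(ls == 0)) stop("all-zero count matrix")
    sf <- ls / mean(ls)
  }
  sf
}

#' Variance-stabilising transform of a count matrix
#'
#' Size factors by median-of-ratios, then the shifted-log transform
#' `log2(count / size_factor + 1)`, which is strictly increasing in the
#' count for a fixed size factor and approximately variance-flattening for
#' overdispersed counts. This is a generic variance-stabilising transform
#' validated by its monotonicity and depth-equalisation properties, not a
#' parametric dispersion-fit.
#'
#' @param counts features x samples non-negative count matrix.
#' @return numeric matrix of transformed values with attributes
#'   `size_factors` and `unit = "VST"`.
#' @export
vst_transform <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L) stop("need at least one sample")
  if (all(counts == 0)) stop("all-zero count matrix")
  sf <- size_factors(counts)
  out <- log2(sweep(counts, 2L, sf, "/") + 1)
  attr(out, "size_factors") <- sf
  attr(out, "unit") <- "VST"
  out
}

#' Size-factor-normalized counts
#'
#' Counts divided by their median-of-ratios [size_factors()]; the
#' composition-robust normalized unit used for fold changes and
#' restoration scoring.
#'
#' @param counts features x samples count matrix.
#' @return numeric matrix (unit attribute `"normcount"`).
#' @export
normalized_counts <- function(counts) {
  out <- sweep(as.matrix(counts), 2L, size_factors(counts), "/")
  attr(out, "unit") <- "normcount"
  out
}

#' Per-group means of an expression matrix
#'
#' @param mat features x samples matrix (columns named by sample id).
#' @param samples a [sample_table()].
#' @param groups groups to average (default: all present).
#' @return features x groups matrix of within-group means.
#' @export
group_means <- function(mat, samples, groups = unique(samples$group)) {
  out <- vapply(groups, function(g) {
    ids <- samples_in_group(samples, g)
    rowMeans(mat[, ids, drop = FALSE])
  }, numeric(nrow(mat)))
  matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), groups))
}
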