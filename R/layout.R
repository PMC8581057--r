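#' Genome layout
#'
#' An ordered set of chromosome names with lengths, the shared coordinate
#' frame for every interval in the pipeline. Represented as a named numeric
#' vector (name -> length in bp), insertion-ordered.
#'
#' @param chroms character vector of unique chromosome names.
#' @param lengths positive integer lengths in bp, one per chromosome.
#' @return named numeric vector of class `genome_layout`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths))
    stop("chroms and lengths must have equal length")
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (length(chroms) == 0L) stop("empty genome layout")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(setNames(lengths, chroms), class = "genome_layout")
}

#' Read a two-column chrom-sizes file
#'
#' @param path tab-separated file: chromosome name, length in bp.
#' @return a [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L) stop("chrom sizes file needs two columns: ", path)
  genome_layout(dt[[1L]], as.numeric(dt[[2L]]))
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp total\n")
  invisible(x)
}

# GRanges seqinfo carrying the layout's lengths, insertion order preserved.
layout_seqlengths <- function(layout) setNames(as.integer(layout), names(layout))

#' Sliding windows over a genome layout
#'
#' Per chromosome, windows start at 0, `step`, 2*`step`, ... (0-based
#' genomic offsets) and a window is emitted only when it fits entirely on
#' the chromosome (`start + size <= length`); partial terminal windows are
#' dropped so that no window, and hence no merged region, is shorter than
#' `size`.
#'
#' @param layout a [genome_layout()].
#' @param size window size in bp (default 50 kb).
#' @param step step between window starts in bp (default 20 kb);
#'   `0 < step <= size`.
#' @return `GRanges` of windows, sorted by chromosome then start, with
#'   seqlengths set from the layout.
#' @examples
#' make_windows(genome_layout("chr1", 1e5))  # [0,50k), [20k,70k), [40k,90k)
#' @export
make_windows <- function(layout, size = 50000L, step = 20000L) {
  stopifnot(inherits(layout, "genome_layout"))
  size <- as.numeric(size); step <- as.numeric(step)
  if (!(step > 0 && step <= size)) stop("require 0 < step <= size")
  per_chrom <- lapply(names(layout), function(ch) {
    len <- layout[[ch]]
    n <- floor((len - size) / step) + 1
    if (n < 1) return(NULL)
    starts0 <- (seq_len(n) - 1) * step
    GRanges(ch, IRanges(start = starts0 + 1, width = size))
  })
  gr <- suppressWarnings(
    do.call(c, c(per_chrom[!vapply(per_chrom, is.null, logical(1))],
                 list(GRanges()))))
  seqlevels(gr) <- names(layout)
  seqlengths(gr) <- layout_seqlengths(layout)
  if (length(gr))
    names(gr) <- paste0(seqnames(gr), ":", start(gr) - 1, "-", end(gr))
  gr
}

#' Count read 5' positions in intervals
#'
#' Each read is assigned by its 5' position to every interval containing
#' it, so overlapping sliding windows each count the read.
#'
#' @param reads a `data.frame`/`data.table` with columns `chrom` and `pos`
#'   (1-based bp of the 5' end); an optional `sample` column is ignored
#'   here (see [count_reads_matrix()]).
#' @param intervals `GRanges` of target intervals.
#' @return integer vector of counts, one per interval.
#' @export
count_in_intervals <- function(reads, intervals) {
  if (nrow(reads) == 0L) return(integer(length(intervals)))
  pos <- GRanges(reads$chrom, IRanges(reads$pos, width = 1L))
  unname(countOverlaps(intervals, pos))
}

#' Per-sample interval count matrix from pooled read positions
#'
#' @param reads `data.table` with columns `sample`, `chrom`, `pos`.
#' @param intervals `GRanges`.
#' @param sample_ids sample order for the columns (default: order of first
#'   appearance in `reads`).
#' @return integer matrix, intervals x samples, rownames from
#'   `names(intervals)`.
#' @export
count_reads_matrix <- function(reads, intervals, sample_ids = unique(reads$sample)) {
  m <- vapply(sample_ids, function(s)
    count_in_intervals(reads[reads$sample == s, ], intervals),
    integer(length(intervals)))
  m <- matrix(m, nrow = length(intervals),
              dimnames = list(names(intervals), sample_ids))
  m
}
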