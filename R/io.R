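# Plain-text readers and writers. All interval files use the standard
# 0-based half-open BED/bedGraph frame on disk and are converted to the
# 1-based GRanges frame in memory at this boundary.

#' Write intervals as BED
#'
#' BED6 when strand/names are available (`name` carries the feature id or
#' repeat family, score 0), BED3 otherwise. Extra `mcols` columns listed
#' in `extra` are appended (BED6+).
#'
#' @param gr `GRanges`.
#' @param path output path.
#' @param name character vector of names (default `names(gr)`).
#' @param extra names of `mcols(gr)` columns to append.
#' @param bed3 write only chrom/start/end.
#' @return the path, invisibly.
#' @export
write_bed <- function(gr, path, name = names(gr), extra = character(0),
                      bed3 = FALSE) {
  dt <- data.table::data.table(chrom = as.character(seqnames(gr)),
                               start = start(gr) - 1L, end = end(gr))
  if (!bed3) {
    dt$name <- if (is.null(name)) "." else name
    dt$score <- 0L
    dt$strand <- as.character(strand(gr))
    for (col in extra) dt[[col]] <- mcols(gr)[[col]]
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED6(+) file as GRanges
#'
#' @param path input path.
#' @param layout optional [genome_layout()] used to set seqlengths.
#' @param extra names for columns after the sixth.
#' @return `GRanges` (names from the BED name column when present).
#' @export
read_bed <- function(path, layout = NULL, extra = character(0)) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  gr <- GRanges(dt[[1]], IRanges(dt[[2]] + 1L, dt[[3]]))
  if (ncol(dt) >= 6L) {
    names(gr) <- dt[[4]]
    strand(gr) <- dt[[6]]
    for (k in seq_along(extra)) {
      if (ncol(dt) >= 6L + k) mcols(gr)[[extra[k]]] <- dt[[6L + k]]
    }
  }
  if (!is.null(layout)) {
    seqlevels(gr) <- names(layout)
    seqlengths(gr) <- layout_seqlengths(layout)
  }
  gr
}

#' Write a signal track as bedGraph
#'
#' One row per bin (0-based half-open), value = bin count.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$counts), function(ch) {
    n <- length(track$counts[[ch]])
    data.table::data.table(
      chrom = ch,
      start = (seq_len(n) - 1L) * as.integer(track$bin_width),
      end = pmin(seq_len(n) * as.integer(track$bin_width),
                 as.integer(track$layout[[ch]])),
      value = track$counts[[ch]])
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph of per-bin counts as a signal track
#'
#' @param path bedGraph path (fixed-width bins expected).
#' @param layout a [genome_layout()].
#' @param bin_width bin width in bp.
#' @param lib_size library size (default: sum of values).
#' @param role,mark passed to [signal_track()].
#' @return a [signal_track()].
#' @export
read_bedgraph <- function(path, layout, bin_width, lib_size = NULL,
                          role = "chip", mark = NA_character_) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  counts <- lapply(names(layout), function(ch) {
    nb <- ceiling(layout[[ch]] / bin_width)
    out <- numeric(nb)
    sub <- dt[dt[[1]] == ch, ]
    if (nrow(sub)) out[sub[[2]] / bin_width + 1L] <- sub[[4]]
    out
  })
  names(counts) <- names(layout)
  signal_track(layout, bin_width, counts, lib_size = lib_size, role = role,
               mark = mark)
}

#' Write a count matrix with sample metadata
#'
#' @param counts features x samples matrix.
#' @param path output TSV (first column `feature_id`).
#' @return the path, invisibly.
#' @export
write_counts <- function(counts, path) {
  dt <- data.table::data.table(feature_id = rownames(counts))
  for (cn in colnames(counts)) dt[[cn]] <- counts[, cn]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a count matrix TSV
#' @param path TSV with `feature_id` column then one column per sample.
#' @return integer matrix with feature rownames.
#' @export
read_counts <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a simulated experiment to a fixture directory
#'
#' Emits the plain-text file set consumed by the pipeline: chrom sizes,
#' sample table, gene/repeat count TSVs, BED annotations (genes, repeats,
#' planted truth regions; CGIs as BED3), read positions, bedGraph ChIP
#' tracks plus a track metadata sidecar, per-sample CpG call files and
#' the truth table. [read_fixture()] round-trips the set.
#'
#' @param sim an `rr_sim` from [simulate_experiment()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  fp <- function(...) file.path(out_dir, ...)
  data.table::fwrite(data.table::data.table(chrom = names(sim$layout),
                                            length = as.integer(sim$layout)),
                     fp("chrom.sizes"), sep = "\t", col.names = FALSE)
  data.table::fwrite(sim$samples, fp("samples.tsv"), sep = "\t")
  write_counts(sim$gene_counts, fp("gene_counts.tsv"))
  write_counts(sim$repeat_counts, fp("repeat_counts.tsv"))
  write_bed(sim$genes, fp("genes.bed"))
  write_bed(sim$repeats, fp("repeats.bed"),
            name = mcols(sim$repeats)$family)
  write_bed(sim$cgi, fp("cgi.bed"), bed3 = TRUE)
  write_bed(sim$truth_regions, fp("truth_regions.bed"),
            extra = c("label", "restored"))
  data.table::fwrite(sim$reads, fp("reads.tsv"), sep = "\t")
  meta <- list()
  for (smp in names(sim$chip)) {
    for (role in c("chip", "input")) {
      tr <- sim$chip[[smp]][[role]]
      fn <- paste0("chip_", smp, "_", role, ".bedGraph")
      write_bedgraph(tr, fp(fn))
      meta[[length(meta) + 1L]] <- data.table::data.table(
        file = fn, sample = smp, role = role, mark = tr$mark,
        bin_width = tr$bin_width, lib_size = tr$lib_size)
    }
  }
  data.table::fwrite(data.table::rbindlist(meta), fp("tracks.tsv"),
                     sep = "\t")
  for (smp in names(sim$meth))
    write_cpg_calls(sim$meth[[smp]], fp(paste0("cpg_", smp, ".tsv")))
  data.table::fwrite(sim$truth, fp("truth.tsv"), sep = "\t")
  invisible(out_dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with the same elements as an `rr_sim` except `config`.
#' @export
read_fixture <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  layout <- read_chrom_sizes(fp("chrom.sizes"))
  samples <- as.data.frame(data.table::fread(fp("samples.tsv")))
  tracks <- data.table::fread(fp("tracks.tsv"))
  chip <- list()
  for (i in seq_len(nrow(tracks))) {
    tr <- read_bedgraph(fp(tracks$file[i]), layout, tracks$bin_width[i],
                        lib_size = tracks$lib_size[i],
                        role = tracks$role[i], mark = tracks$mark[i])
    chip[[tracks$sample[i]]][[tracks$role[i]]] <- tr
  }
  meth <- list()
  for (f in list.files(dir, pattern = "^cpg_.*\\.tsv$")) {
    smp <- sub("^cpg_(.*)\\.tsv$", "\\1", f)
    meth[[smp]] <- read_cpg_calls(fp(f))
  }
  list(layout = layout, samples = samples,
       gene_counts = read_counts(fp("gene_counts.tsv")),
       repeat_counts = read_counts(fp("repeat_counts.tsv")),
       genes = read_bed(fp("genes.bed"), layout),
       repeats = read_bed(fp("repeats.bed"), layout),
       cgi = read_bed(fp("cgi.bed"), layout),
       truth_regions = read_bed(fp("truth_regions.bed"), layout,
                                extra = c("label", "restored")),
       reads = data.table::fread(fp("reads.tsv")),
       chip = chip, meth = meth,
       truth = as.data.frame(data.table::fread(fp("truth.tsv"))))
}
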