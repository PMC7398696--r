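#' Read and write BED interval files
#'
#' Intervals are carried internally as 0-based half-open data frames
#' (`chrom`, `start`, `end`, optional `label`); on disk they are standard
#' BED (also 0-based half-open), read and written through rtracklayer.  A
#' 4th BED column maps to `label` (exclusion class or gene id).
#'
#' @param path BED file path.
#' @param x Data frame with `chrom`, `start`, `end` and optionally
#'   `label`/`gene_id`.
#' @return `read_bed()`: a data frame; `write_bed()`: `path`, invisibly.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) out$label <- nm
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  label <- if (!is.null(x$label)) x$label else x$gene_id
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(start = x$start + 1L,
                                                end = x$end))
  if (!is.null(label)) S4Vectors::mcols(gr)$name <- label
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal coverage are collapsed to bedGraph intervals (0-based
#' half-open) and exported through rtracklayer.
#'
#' @param track A `coverage_track`.
#' @param path Output path (conventionally `.bedgraph`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  sl <- attr(track, "seqlengths")
  grl <- lapply(names(track), function(chr) {
    r <- rle(track[[chr]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    GenomicRanges::GRanges(chr, IRanges::IRanges(starts, ends),
                           score = r$values, seqlengths = sl)
  })
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read fragments from a BED file as a fragment set
#'
#' @param path BED file of fragment intervals.
#' @param seqlengths Optional named chromosome lengths for bounds checks.
#' @return A `fragment_set`.
#' @export
read_fragments <- function(path, seqlengths = NULL) {
  fragment_set(read_bed(path)[, c("chrom", "start", "end")], seqlengths)
}

#' @rdname read_fragments
#' @param frags A `fragment_set`.
#' @export
write_fragments <- function(frags, path) {
  write_bed(frags, path)
}
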