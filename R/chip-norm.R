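#' Mononucleosome fragment-size selection
#'
#' Keeps exactly the fragments whose length (`end - start`) lies within the
#' closed range `[min_len, max_len]` — by default 130-180 bp, the
#' mononucleosome-protected size window of an MNase digest.  Both bounds
#' are inclusive; order is preserved; filtering is idempotent.
#'
#' @param frags A `fragment_set` (or any data frame with `chrom`, `start`,
#'   `end`).
#' @param min_len,max_len Inclusive length bounds in bp (defaults 130 and
#'   180).
#' @return The filtered `fragment_set`.
#' @examples
#' f <- fragment_set(data.frame(chrom = "c", start = 0,
#'                              end = c(129, 130, 155, 180, 181)))
#' filter_fragments(f)$end
#' @export
filter_fragments <- function(frags, min_len = 130L, max_len = 180L) {
  stopifnot(is.data.frame(frags))
  if (min_len < 1 || min_len > max_len)
    stop("require 1 <= min_len <= max_len")
  len <- frags$end - frags$start
  out <- frags[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' Per-base fragment coverage over a genome
#'
#' Counts, at every base of every chromosome, the number of fragments
#' overlapping it under half-open semantics (base `i` is covered iff
#' `start <= i < end`).
#'
#' @param frags A `fragment_set`.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param provenance `"ip"` or `"input"`, recorded on the track.
#' @return A `coverage_track`: a named list of per-base numeric vectors
#'   (one per chromosome, position 1 of the vector = genomic position 0),
#'   with attributes `seqlengths`, `provenance`, and `norm_factor`
#'   (`NA` until normalized).
#' @examples
#' f <- fragment_set(data.frame(chrom = "c", start = 10, end = 13))
#' as.numeric(coverage_track(f, c(c = 20))$c)
#' @export
coverage_track <- function(frags, seqlengths, provenance = "ip") {
  stopifnot(is.data.frame(frags))
  if (!all(frags$chrom %in% names(seqlengths)))
    stop("fragment on unknown chromosome: ",
         paste(unique(setdiff(frags$chrom, names(seqlengths))),
               collapse = ", "))
  if (any(frags$end > seqlengths[frags$chrom]))
    stop("fragment extends past chromosome end")
  track <- lapply(names(seqlengths), function(chr) {
    sel <- frags$chrom == chr
    len <- as.integer(seqlengths[[chr]])
    if (!any(sel)) return(numeric(len))
    ir <- IRanges::IRanges(start = frags$start[sel] + 1L,
                           end = frags$end[sel])
    as.numeric(IRanges::coverage(ir, width = len))
  })
  names(track) <- names(seqlengths)
  structure(track, seqlengths = seqlengths, provenance = provenance,
            norm_factor = NA_real_, class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  sl <- attr(x, "seqlengths")
  cat(sprintf("Coverage track (%s): %d chromosome(s), %d bp\n",
              attr(x, "provenance"), length(sl), sum(sl)))
  nf <- attr(x, "norm_factor")
  if (!is.na(nf))
    cat(sprintf("  normalized; non-heterochromatic median factor = %.6g\n",
                nf))
  invisible(x)
}

# logical mask of positions NOT excluded, per chromosome
.nonexcluded_mask <- function(seqlengths, exclusions) {
  mask <- lapply(seqlengths, function(len) rep(TRUE, len))
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    .check_intervals(exclusions, seqlengths)
    for (i in seq_len(nrow(exclusions))) {
      chr <- exclusions$chrom[i]
      mask[[chr]][(exclusions$start[i] + 1L):exclusions$end[i]] <- FALSE
    }
  }
  mask
}

#' Normalize a coverage track to the non-heterochromatic genome-wide median
#'
#' Divides every per-base value by the median of per-base coverage over all
#' positions outside the exclusion regions (rDNA, subtelomeres, and any
#' heterochromatic chromosome excluded outright).  After normalization the
#' median over non-excluded positions is exactly 1.  IP and input tracks
#' are normalized independently so they can be plotted on the same scale.
#' Even position counts take the median as the mean of the two central
#' values (the `stats::median()` convention).
#'
#' @param track A `coverage_track`.
#' @param exclusions Exclusion data frame (`chrom`, `start`, `end`,
#'   optional `label`); `NULL` excludes nothing.
#' @return The normalized `coverage_track`; the divisor is recorded in
#'   attribute `norm_factor`.
#' @examples
#' f <- fragment_set(data.frame(chrom = "c", start = 0:4, end = 20))
#' tr <- coverage_track(f, c(c = 5))
#' as.numeric(normalize_to_nonhet_median(tr, NULL)$c)
#' @export
normalize_to_nonhet_median <- function(track, exclusions = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  sl <- attr(track, "seqlengths")
  mask <- .nonexcluded_mask(sl, exclusions)
  vals <- unlist(lapply(names(track), function(chr) track[[chr]][mask[[chr]]]),
                 use.names = FALSE)
  if (length(vals) == 0L)
    stop("all positions are excluded; nothing to take the median over")
  med <- stats::median(vals)
  if (med == 0)
    stop("non-excluded genome-wide median coverage is 0; the library is ",
         "too shallow (or the exclusions too broad) to normalize against")
  out <- lapply(track, function(v) v / med)
  attributes(out) <- attributes(track)
  attr(out, "norm_factor") <- med
  out
}

#' Per-gene length- and mean-normalized coverage
#'
#' Sums track coverage over each gene interval, divides by gene length to
#' get a density, then divides each density by the mean density over all
#' genes, so the normalized densities average exactly 1.
#'
#' @param track A `coverage_track` (raw or median-normalized).
#' @param genes Data frame with columns `gene_id` (optional; generated if
#'   absent), `chrom`, `start`, `end` (0-based half-open).
#' @return A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `coverage_sum`, `density`, `normalized_density`.
#' @export
gene_normalized_coverage <- function(track, genes) {
  stopifnot(inherits(track, "coverage_track"), is.data.frame(genes))
  if (nrow(genes) == 0L) stop("'genes' is empty")
  sl <- attr(track, "seqlengths")
  .check_intervals(genes, sl)
  if (any(genes$end - genes$start < 1))
    stop("zero-length gene interval")
  if (is.null(genes$gene_id))
    genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  sums <- vapply(seq_len(nrow(genes)), function(i) {
    sum(track[[genes$chrom[i]]][(genes$start[i] + 1L):genes$end[i]])
  }, 0)
  density <- sums / (genes$end - genes$start)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = genes$start, end = genes$end, coverage_sum = sums,
             density = density,
             normalized_density = density / mean(density))
}

#' Programmed-enrichment recovery from a normalized IP track
#'
#' Convenience summary used to verify that a locus given an elevated IP
#' enrichment in the generator is recovered after size selection and median
#' normalization: the mean normalized coverage over the locus divided by
#' the mean over the rest of the (non-excluded) genome.
#'
#' @param track A normalized IP `coverage_track`.
#' @param locus One-row data frame (`chrom`, `start`, `end`).
#' @param exclusions Exclusions applied during normalization (the locus is
#'   additionally removed from the background).
#' @return The enrichment ratio (single number).
#' @export
locus_enrichment <- function(track, locus, exclusions = NULL) {
  stopifnot(inherits(track, "coverage_track"), nrow(locus) == 1L)
  sl <- attr(track, "seqlengths")
  .check_intervals(locus, sl)
  mask <- .nonexcluded_mask(sl, exclusions)
  idx <- (locus$start + 1L):locus$end
  locus_mean <- mean(track[[locus$chrom]][idx])
  mask[[locus$chrom]][idx] <- FALSE
  bg <- unlist(lapply(names(track), function(chr) track[[chr]][mask[[chr]]]),
               use.names = FALSE)
  locus_mean / mean(bg)
}
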