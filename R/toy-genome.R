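#' Construct a toy genome with positioned nucleosomes
#'
#' A small artificial genome for exercising the MNase ChIP workflow:
#' chromosomes with fixed lengths, nucleosome dyad positions, a
#' per-nucleosome immunoprecipitation enrichment factor, and labelled
#' exclusion regions (rDNA, subtelomeres, a whole chromosome) that the
#' median normalization must ignore.
#'
#' @param seqlengths Named integer vector of chromosome lengths (bp).
#' @param nucleosomes Data frame with columns `chrom`, `dyad` (0-based
#'   position) and optionally `enrichment` (non-negative IP weight,
#'   default 1).  If `NULL`, nucleosomes are placed at a regular
#'   `spacing` along every chromosome with enrichment 1.
#' @param exclusions Data frame with columns `chrom`, `start`, `end`
#'   (0-based, half-open) and `label` in `c("rDNA", "subtelomere",
#'   "chromosome")`; may be `NULL`.
#' @param spacing Nucleosome repeat length used when `nucleosomes` is
#'   `NULL` (default 165 bp).
#' @return A list of class `toy_genome` with elements `seqlengths`,
#'   `nucleosomes`, `exclusions`.
#' @examples
#' g <- toy_genome(c(chrI = 20000L, chrII = 10000L))
#' nrow(g$nucleosomes)
#' @export
toy_genome <- function(seqlengths, nucleosomes = NULL, exclusions = NULL,
                       spacing = 165L) {
  if (is.null(names(seqlengths)) || any(names(seqlengths) == ""))
    stop("'seqlengths' must be a named vector of chromosome lengths")
  if (any(seqlengths < 1)) stop("chromosome lengths must be positive")
  seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  if (is.null(nucleosomes)) {
    nucleosomes <- do.call(rbind, lapply(names(seqlengths), function(chr) {
      dyads <- seq.int(spacing %/% 2L, seqlengths[[chr]] - 1L, by = spacing)
      data.frame(chrom = chr, dyad = dyads, enrichment = 1)
    }))
  }
  stopifnot(all(c("chrom", "dyad") %in% names(nucleosomes)))
  if (is.null(nucleosomes$enrichment)) nucleosomes$enrichment <- 1
  if (!all(nucleosomes$chrom %in% names(seqlengths)))
    stop("nucleosome on unknown chromosome")
  if (any(nucleosomes$dyad < 0 |
          nucleosomes$dyad >= seqlengths[nucleosomes$chrom]))
    stop("nucleosome dyad outside chromosome bounds")
  if (any(!is.finite(nucleosomes$enrichment)) ||
      any(nucleosomes$enrichment < 0))
    stop("'enrichment' factors must be finite and non-negative")
  if (!is.null(exclusions)) .check_intervals(exclusions, seqlengths,
                                             require_label = TRUE)
  structure(list(seqlengths = seqlengths, nucleosomes = nucleosomes,
                 exclusions = exclusions), class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("Toy genome: %d chromosome(s), %d bp total, %d nucleosomes\n",
              length(x$seqlengths), sum(x$seqlengths),
              nrow(x$nucleosomes)))
  if (!is.null(x$exclusions))
    cat(sprintf("  %d exclusion region(s): %s\n", nrow(x$exclusions),
                paste(unique(x$exclusions$label), collapse = ", ")))
  invisible(x)
}

.check_intervals <- function(iv, seqlengths, require_label = FALSE) {
  need <- c("chrom", "start", "end", if (require_label) "label")
  if (!all(need %in% names(iv)))
    stop("interval table must have columns ", paste(need, collapse = ", "))
  if (!all(iv$chrom %in% names(seqlengths)))
    stop("interval on unknown chromosome: ",
         paste(setdiff(iv$chrom, names(seqlengths)), collapse = ", "))
  if (any(iv$start < 0) || any(iv$end > seqlengths[iv$chrom]) ||
      any(iv$start >= iv$end))
    stop("invalid interval: require 0 <= start < end <= chromosome length")
  if (require_label &&
      !all(iv$label %in% c("rDNA", "subtelomere", "chromosome")))
    stop("exclusion labels must be 'rDNA', 'subtelomere', or 'chromosome'")
  invisible(iv)
}

#' Default subtelomeric exclusion intervals
#'
#' Subtelomere coordinates are not standardized; by default the terminal
#' `width` bp of each chromosome end are flagged (override with an explicit
#' exclusion table where real coordinates are known).
#'
#' @param seqlengths Named chromosome lengths.
#' @param width Bases flagged at each end (default 20000).
#' @return An exclusion data frame with `label = "subtelomere"`.
#' @export
subtelomere_exclusions <- function(seqlengths, width = 20000L) {
  do.call(rbind, lapply(names(seqlengths), function(chr) {
    len <- seqlengths[[chr]]
    w <- min(width, len)
    ends <- unique(rbind(data.frame(start = 0L, end = w),
                         data.frame(start = max(len - w, 0L), end = len)))
    data.frame(chrom = chr, start = ends$start, end = ends$end,
               label = "subtelomere")
  }))
}

#' Simulate MNase ChIP fragments over a toy genome
#'
#' Fragments are centred on nucleosome dyads with Gaussian-jittered
#' mononucleosomal lengths; for an IP library the dyads are sampled with
#' probability proportional to their enrichment factor, for an input
#' library uniformly.  A stated fraction of fragments are given short
#' subnucleosomal lengths (below 130 bp) so the downstream size gate has
#' something to remove.  Fragments are clipped to chromosome bounds;
#' coordinates are 0-based half-open.
#'
#' @param genome A [toy_genome()].
#' @param n_fragments Number of fragments (>= 1).
#' @param frag_mean,frag_sd Mononucleosome fragment-length model (bp).
#' @param subnuc_frac Fraction of subnucleosomal fragments.
#' @param subnuc_mean,subnuc_sd Subnucleosomal length model (bp; capped at
#'   129).
#' @param dyad_jitter_sd SD of the Gaussian jitter of fragment centres
#'   around the dyad (bp).
#' @param ip Sample dyads proportionally to enrichment (IP) or uniformly
#'   (input)?
#' @param seed Integer seed.
#' @return A `fragment_set` data frame with columns `chrom`, `start`,
#'   `end`.
#' @examples
#' g <- toy_genome(c(chrI = 20000L))
#' f <- simulate_fragments(g, 100, seed = 1)
#' range(f$end - f$start)
#' @export
simulate_fragments <- function(genome, n_fragments, frag_mean = 155,
                               frag_sd = 10, subnuc_frac = 0,
                               subnuc_mean = 90, subnuc_sd = 15,
                               dyad_jitter_sd = 10, ip = FALSE,
                               seed = NULL) {
  stopifnot(inherits(genome, "toy_genome"))
  if (nrow(genome$nucleosomes) == 0L) stop("genome has no nucleosomes")
  if (n_fragments < 1) stop("'n_fragments' must be >= 1")
  .check_scalar(subnuc_frac, "subnuc_frac", lower = 0, upper = 1)
  .with_seed(seed, {
    nuc <- genome$nucleosomes
    prob <- if (ip) nuc$enrichment else rep(1, nrow(nuc))
    idx <- sample.int(nrow(nuc), n_fragments, replace = TRUE, prob = prob)
    centre <- nuc$dyad[idx] +
      round(stats::rnorm(n_fragments, 0, dyad_jitter_sd))
    sub <- stats::runif(n_fragments) < subnuc_frac
    len <- integer(n_fragments)
    len[!sub] <- pmax(1L, round(stats::rnorm(sum(!sub), frag_mean,
                                             frag_sd)))
    len[sub] <- pmin(129L, pmax(1L, round(stats::rnorm(sum(sub),
                                                       subnuc_mean,
                                                       subnuc_sd))))
    chrom <- nuc$chrom[idx]
    chrlen <- genome$seqlengths[chrom]
    start <- pmax(0L, centre - len %/% 2L)
    end <- pmin(as.integer(chrlen), start + len)
    start <- pmin(start, end - 1L)  # keep length >= 1 after clipping
    start <- pmax(start, 0L)
    fragment_set(data.frame(chrom = chrom, start = start, end = end,
                            stringsAsFactors = FALSE),
                 seqlengths = genome$seqlengths)
  })
}

#' Fragment sets: genomic intervals in BED convention
#'
#' @param x Data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @param seqlengths Optional named chromosome lengths for bounds checks.
#' @return A `fragment_set` data frame.
#' @export
fragment_set <- function(x, seqlengths = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$start >= x$end))
    stop("fragments must satisfy start < end")
  if (any(x$start < 0)) stop("fragment start < 0")
  if (!is.null(seqlengths)) {
    if (!all(x$chrom %in% names(seqlengths)))
      stop("fragment on unknown chromosome")
    if (any(x$end > seqlengths[x$chrom]))
      stop("fragment extends past chromosome end")
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  rownames(x) <- NULL
  class(x) <- c("fragment_set", "data.frame")
  x
}
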