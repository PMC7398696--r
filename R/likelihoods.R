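#' Log-likelihoods of the two establishment models at one timepoint
#'
#' `loglik_gradual()` evaluates the gradual (tune-down) model: all cells draw
#' from the ON distribution with its mean multiplied by `scale_s` and its
#' dispersion unchanged.  `loglik_switch()` evaluates the switch
#' (all-or-nothing) model: a fraction `w_off` of cells is stably OFF (point
#' mass at zero by default) and the remainder draw from the unchanged ON
#' distribution.
#'
#' At the boundary the models coincide with the ON distribution itself:
#' `loglik_switch(x, on, 0) == loglik_gradual(x, on, 1)` exactly.
#'
#' @param counts Integer vector of per-cell counts at one timepoint, or a
#'   `cell_counts` data frame.
#' @param on An [on_distribution()].
#' @param scale_s Transcription scale in (0, 1] multiplying the ON mean.
#' @param w_off Fraction of stably OFF cells, in [0, 1].
#' @param off_residual_mean Mean residual transcripts in OFF cells; with the
#'   default 0 the OFF component is an exact point mass at zero.
#' @return The summed per-cell log-likelihood (a single number).
#' @examples
#' on <- on_distribution(2, 0)
#' loglik_gradual(c(0L, 1L), on, scale_s = 0.5)  # Poisson(1): -2
#' @export
loglik_gradual <- function(counts, on, scale_s) {
  counts <- .as_count_vector(counts)
  if (length(counts) == 0L) stop("'counts' is empty")
  stopifnot(inherits(on, "on_distribution"))
  .check_scalar(scale_s, "scale_s", lower = 0, upper = 1, lower_open = TRUE)
  sum(don(counts, on, mu = scale_s * on$mu, log = TRUE))
}

#' @rdname loglik_gradual
#' @export
loglik_switch <- function(counts, on, w_off, off_residual_mean = 0) {
  counts <- .as_count_vector(counts)
  if (length(counts) == 0L) stop("'counts' is empty")
  stopifnot(inherits(on, "on_distribution"))
  .check_scalar(w_off, "w_off", lower = 0, upper = 1)
  .check_scalar(off_residual_mean, "off_residual_mean", lower = 0)
  p_on <- don(counts, on)
  p_off <- if (off_residual_mean > 0) {
    stats::dpois(counts, off_residual_mean)
  } else as.numeric(counts == 0)
  sum(log(w_off * p_off + (1 - w_off) * p_on))
}
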