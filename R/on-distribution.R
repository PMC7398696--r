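#' ON-state transcript-count distribution
#'
#' The shared anchor of both establishment models: an overdispersed count
#' distribution describing transcripts per expressing cell.  Parameterized as
#' a negative binomial with mean `mu` and dispersion `alpha` such that
#' `Var(X) = mu + alpha * mu^2`; `alpha = 0` degenerates to Poisson.
#'
#' @param mu Mean transcripts per cell (non-negative).
#' @param alpha Dispersion (non-negative); `alpha = 0` gives a Poisson.
#' @return An object of class `on_distribution` with elements `mu` and
#'   `alpha`.
#' @examples
#' on <- on_distribution(6, 0.5)
#' mean(ron(1e4, on))
#' @export
on_distribution <- function(mu, alpha = 0) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.numeric(alpha),
            length(alpha) == 1L)
  if (!is.finite(mu) || mu < 0)
    stop("'mu' must be a finite non-negative number, got ", mu)
  if (!is.finite(alpha) || alpha < 0)
    stop("'alpha' must be a finite non-negative number, got ", alpha)
  structure(list(mu = mu, alpha = alpha), class = "on_distribution")
}

#' @export
print.on_distribution <- function(x, ...) {
  cat("ON transcript-count distribution\n")
  cat(sprintf("  mean (mu):          %.4g transcripts/cell\n", x$mu))
  cat(sprintf("  dispersion (alpha): %.4g  [variance = %.4g]\n",
              x$alpha, x$mu + x$alpha * x$mu^2))
  cat(if (x$alpha == 0) "  family: Poisson (alpha = 0)\n"
      else sprintf("  family: negative binomial (size = %.4g)\n", 1 / x$alpha))
  invisible(x)
}

#' Density and random generation for the ON distribution
#'
#' `don()` evaluates the probability mass function at a given mean scale;
#' `ron()` draws counts.  Both accept an explicit mean `mu` overriding the
#' distribution's own mean, which is how the gradual model's scaled means are
#' evaluated without constructing a new object.
#'
#' @param x Vector of non-negative integer counts.
#' @param n Number of draws.
#' @param on An [on_distribution()].
#' @param mu Optional mean override (defaults to `on$mu`).
#' @param log Return log-probabilities?
#' @return `don()`: numeric vector of (log-)probabilities; `ron()`: integer
#'   counts.
#' @export
don <- function(x, on, mu = on$mu, log = FALSE) {
  stopifnot(inherits(on, "on_distribution"))
  if (on$alpha == 0) {
    stats::dpois(x, lambda = mu, log = log)
  } else {
    stats::dnbinom(x, mu = mu, size = 1 / on$alpha, log = log)
  }
}

#' @rdname don
#' @export
ron <- function(n, on, mu = on$mu) {
  stopifnot(inherits(on, "on_distribution"))
  if (on$alpha == 0) {
    stats::rpois(n, lambda = mu)
  } else {
    stats::rnbinom(n, mu = mu, size = 1 / on$alpha)
  }
}

#' Fit the ON distribution to pre-induction counts
#'
#' Maximum-likelihood fit of `(mu, alpha)` to a sample of per-cell transcript
#' counts, typically the pre-induction timepoint where all cells express.
#' The mean is profiled out analytically (for fixed dispersion the NB mean
#' MLE is the sample mean), leaving a one-dimensional optimization over
#' `alpha`, floored at 0 (Poisson).
#'
#' @param counts Integer vector of per-cell counts, or a `cell_counts` data
#'   frame (its `count` column is used).
#' @param alpha_max Upper bound of the dispersion search (default 50).
#' @return An `on_distribution` with additional fields `logLik`, `n`, and
#'   `alpha_se` (observed-information standard error, `NA` at the Poisson
#'   boundary).
#' @examples
#' set.seed(1)
#' fit_on_distribution(rnbinom(500, mu = 6, size = 2))
#' @export
fit_on_distribution <- function(counts, alpha_max = 50) {
  counts <- .as_count_vector(counts)
  if (length(counts) == 0L) stop("'counts' is empty")
  if (all(counts == 0))
    stop("all pre-induction counts are zero: the ON state is undefined")
  if (length(counts) < 20L)
    warning("fewer than 20 cells; ON-distribution fit may be unstable")
  mu_hat <- mean(counts)
  nll <- function(alpha) {
    -sum(stats::dnbinom(counts, mu = mu_hat, size = 1 / alpha, log = TRUE))
  }
  ll_pois <- sum(stats::dpois(counts, lambda = mu_hat, log = TRUE))
  # sample variance <= mean: no overdispersion signal, take the Poisson edge
  if (stats::var(counts) <= mu_hat) {
    alpha_hat <- 0
    ll <- ll_pois
  } else {
    opt <- stats::optimize(nll, interval = c(1e-8, alpha_max))
    if (-opt$objective > ll_pois) {
      alpha_hat <- opt$minimum
      ll <- -opt$objective
    } else {
      alpha_hat <- 0
      ll <- ll_pois
    }
  }
  out <- on_distribution(mu_hat, alpha_hat)
  out$logLik <- ll
  out$n <- length(counts)
  out$alpha_se <- if (alpha_hat > 0) {
    h <- stats::optimHess(alpha_hat, nll)
    if (is.finite(h) && h > 0) sqrt(1 / h[1]) else NA_real_
  } else NA_real_
  out
}

# Accept either a bare count vector or the cell_counts table dialect.
.as_count_vector <- function(counts) {
  if (is.data.frame(counts)) {
    if (!"count" %in% names(counts))
      stop("data frame input must have a 'count' column")
    counts <- counts$count
  }
  if (!is.numeric(counts)) stop("'counts' must be numeric")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("'counts' must be non-negative integers with no missing values")
  as.integer(counts)
}
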