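#' Compare the gradual and switch establishment models on the same data
#'
#' Both models carry one free parameter per post-baseline timepoint on top
#' of the shared ON fit, so AIC comparison reduces to the log-likelihood
#' comparison; both are reported.  Optionally a parametric bootstrap is run:
#' `n_bootstrap` datasets are simulated under each fitted model (baseline
#' included, so the ON fit is re-estimated each time), both models are
#' refit, and the bootstrap distribution of the log-likelihood difference
#' yields a p-value for the observed difference under each null.
#'
#' The difference is `delta = logLik(gradual) - logLik(switch)`.  Under the
#' gradual null the p-value is the probability of a `delta` at least as
#' unfavourable to the gradual model as observed
#' (`P(delta* <= delta_obs)`), and symmetrically under the switch null.
#'
#' @param fit_gradual,fit_switch `establishment_fit` objects for the two
#'   models, fit to the same data.
#' @param n_bootstrap Number of parametric-bootstrap replicates per null
#'   (0 disables the bootstrap).
#' @param seed Integer seed for the bootstrap.
#' @param tie_tol Per-cell log-likelihood tolerance below which the
#'   comparison is declared a tie (default 1e-6 per cell).
#' @return An object of class `model_comparison`: `delta_loglik`, `aic`
#'   (named vector), `selected` (`"gradual"`, `"switch"`, or `"tie"`),
#'   `tie`, `p_gradual`, `p_switch`, `n_bootstrap`, and the bootstrap draws.
#' @examples
#' on <- on_distribution(6, 0.3)
#' tc <- rbind(simulate_counts_gradual(on, 1, 0, 300, seed = 1, timepoint = 0),
#'             simulate_counts_gradual(on, 0.4, 1, 300, seed = 2, timepoint = 2))
#' fg <- fit_establishment(count ~ timepoint_hr, tc, "gradual", ci = FALSE)
#' fs <- fit_establishment(count ~ timepoint_hr, tc, "switch", ci = FALSE)
#' compare_models(fg, fs)
#' @export
compare_models <- function(fit_gradual, fit_switch, n_bootstrap = 0,
                           seed = NULL, tie_tol = 1e-6) {
  stopifnot(inherits(fit_gradual, "establishment_fit"),
            inherits(fit_switch, "establishment_fit"))
  if (fit_gradual$model != "gradual" || fit_switch$model != "switch")
    stop("arguments must be a gradual fit and a switch fit, in that order")
  if (!identical(fit_gradual$timepoints$n_cells,
                 fit_switch$timepoints$n_cells) ||
      !identical(fit_gradual$timepoints$timepoint,
                 fit_switch$timepoints$timepoint))
    stop("the two fits do not cover the same data")
  if (n_bootstrap < 0 || n_bootstrap != floor(n_bootstrap))
    stop("'n_bootstrap' must be a non-negative integer")

  n_cells <- sum(fit_gradual$timepoints$n_cells)
  delta <- fit_gradual$logLik - fit_switch$logLik
  k <- nrow(fit_gradual$timepoints) + 2L  # equal for both models
  aic <- c(gradual = -2 * fit_gradual$logLik + 2 * k,
           switch = -2 * fit_switch$logLik + 2 * k)
  tie <- abs(delta) < tie_tol * n_cells
  selected <- if (tie) "tie" else if (delta > 0) "gradual" else "switch"

  boot <- list(gradual = numeric(0), switch = numeric(0))
  p_gradual <- p_switch <- NA_real_
  if (n_bootstrap > 0) {
    boot <- .with_seed(seed, list(
      gradual = .bootstrap_deltas(fit_gradual, n_bootstrap),
      switch = .bootstrap_deltas(fit_switch, n_bootstrap)
    ))
    p_gradual <- (1 + sum(boot$gradual <= delta)) / (n_bootstrap + 1)
    p_switch <- (1 + sum(boot$switch >= delta)) / (n_bootstrap + 1)
  }

  structure(list(delta_loglik = delta, aic = aic, selected = selected,
                 tie = tie, p_gradual = p_gradual, p_switch = p_switch,
                 n_bootstrap = n_bootstrap, bootstrap = boot,
                 n_cells = n_cells,
                 note = paste("equal parameter counts: AIC comparison",
                              "reduces to the log-likelihood comparison")),
            class = "model_comparison")
}

# Simulate a full time course (baseline + later timepoints) under `fit`,
# refit the ON state and both models, and return the logLik differences.
.bootstrap_deltas <- function(fit, n_bootstrap) {
  on <- fit$on
  vapply(seq_len(n_bootstrap), function(b) {
    pre <- ron(fit$n_pre, on)
    if (all(pre == 0)) pre[1] <- 1L  # degenerate redraw guard, measure zero
    on_b <- fit_on_distribution(pre)
    d <- 0
    for (j in seq_len(nrow(fit$timepoints))) {
      row <- fit$timepoints[j, ]
      x <- if (fit$model == "gradual") {
        ron(row$n_cells, on, mu = row$estimate * on$mu)
      } else {
        off <- stats::runif(row$n_cells) < row$estimate
        z <- integer(row$n_cells)
        z[!off] <- ron(sum(!off), on)
        if (fit$off_residual_mean > 0)
          z[off] <- stats::rpois(sum(off), fit$off_residual_mean)
        z
      }
      fg <- fit_timepoint(x, on_b, "gradual", ci = FALSE)
      fs <- fit_timepoint(x, on_b, "switch", ci = FALSE,
                          off_residual_mean = fit$off_residual_mean)
      d <- d + (fg$logLik - fs$logLik)
    }
    d
  }, 0)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Establishment model comparison (gradual vs switch)\n")
  cat(sprintf("  delta logLik (gradual - switch): %.4f over %d cells\n",
              x$delta_loglik, x$n_cells))
  cat(sprintf("  AIC: gradual %.2f, switch %.2f  (%s)\n",
              x$aic["gradual"], x$aic["switch"], x$note))
  cat(sprintf("  selected model: %s%s\n", x$selected,
              if (x$tie) " (tie: |delta| below tolerance)" else ""))
  if (x$n_bootstrap > 0) {
    cat(sprintf("  parametric bootstrap (%d replicates per null):\n",
                x$n_bootstrap))
    cat(sprintf("    P(delta as extreme | gradual true) = %.4f\n",
                x$p_gradual))
    cat(sprintf("    P(delta as extreme | switch true)  = %.4f\n",
                x$p_switch))
  }
  invisible(x)
}

#' Summary statistics of a per-cell count sample
#'
#' The population summaries the establishment argument rests on: the
#' fraction of zero-count cells, the mean over all cells, the mean over
#' expressing (nonzero) cells, and a two-sample shape statistic comparing
#' the nonzero counts with a reference sample.  Under the switch model the
#' nonzero-cell distribution retains the pre-induction shape; under the
#' gradual model it shifts down.
#'
#' The shape statistic is the two-sample Kolmogorov-Smirnov distance with
#' counts treated as continuous and ties handled by the pooled empirical
#' CDFs; its p-value is asymptotic by default or from a permutation test
#' when `n_perm > 0`.
#'
#' @param counts Integer vector or `cell_counts` data frame.
#' @param reference Optional reference sample (vector or `cell_counts`),
#'   e.g. the pre-induction counts; enables the shape comparison.
#' @param n_perm Permutation replicates for the shape test p-value
#'   (0 = asymptotic).
#' @return A list of class `count_summary`: `n`, `zero_fraction`,
#'   `mean_all`, `mean_nonzero`, `n_nonzero`, and (given a reference)
#'   `shape_distance` and `shape_p_value`.  `mean_nonzero` and the shape
#'   fields are `NA` with `no_nonzero = TRUE` when no cell expresses.
#' @examples
#' summary_stats(c(0L, 0L, 1L, 2L))
#' @export
summary_stats <- function(counts, reference = NULL, n_perm = 0) {
  counts <- .as_count_vector(counts)
  if (length(counts) == 0L) stop("'counts' is empty")
  nz <- counts[counts > 0]
  out <- list(n = length(counts),
              zero_fraction = mean(counts == 0),
              mean_all = mean(counts),
              mean_nonzero = if (length(nz)) mean(nz) else NA_real_,
              n_nonzero = length(nz),
              no_nonzero = length(nz) == 0L)
  if (!is.null(reference)) {
    reference <- .as_count_vector(reference)
    ref_nz <- reference[reference > 0]
    if (length(nz) == 0L || length(ref_nz) == 0L) {
      out$shape_distance <- NA_real_
      out$shape_p_value <- NA_real_
      out$no_nonzero <- TRUE
    } else {
      ks <- .ks_two_sample(nz, ref_nz, n_perm = n_perm)
      out$shape_distance <- ks$statistic
      out$shape_p_value <- ks$p_value
    }
  }
  class(out) <- "count_summary"
  out
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("n = %d cells: zero fraction %.3f, mean %.3f", x$n,
              x$zero_fraction, x$mean_all))
  if (!is.na(x$mean_nonzero))
    cat(sprintf(", mean of %d nonzero cells %.3f", x$n_nonzero,
                x$mean_nonzero))
  cat("\n")
  if (!is.null(x$shape_distance))
    cat(sprintf("nonzero-shape KS distance vs reference: %.4f (p = %.4g)\n",
                x$shape_distance, x$shape_p_value))
  if (isTRUE(x$no_nonzero))
    cat("note: nonzero-cell statistics unavailable (no expressing cells)\n")
  invisible(x)
}

# Two-sample KS distance on the pooled support (tie-safe), with asymptotic
# or permutation p-value.
.ks_two_sample <- function(x, y, n_perm = 0) {
  n <- length(x); m <- length(y)
  grid <- sort(unique(c(x, y)))
  d <- max(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
  if (n_perm > 0) {
    pooled <- c(x, y)
    stat_perm <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n + m, n)
      g <- sort(unique(pooled))
      max(abs(stats::ecdf(pooled[idx])(g) - stats::ecdf(pooled[-idx])(g)))
    }, 0)
    p <- (1 + sum(stat_perm >= d)) / (n_perm + 1)
  } else {
    en <- sqrt(n * m / (n + m))
    t <- (en + 0.12 + 0.11 / en) * d
    p <- max(0, min(1, 2 * sum((-1)^(1:100 - 1) * exp(-2 * t^2 * (1:100)^2))))
  }
  list(statistic = d, p_value = p)
}
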