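#' Fit one establishment model at a single timepoint
#'
#' One-dimensional maximum-likelihood fit of the timepoint parameter with
#' the ON distribution held fixed: the transcription scale `s` in (0, 1] for
#' the gradual model, or the OFF fraction `w` in [0, 1] for the switch model.
#' The confidence interval is from the profile likelihood (likelihood-ratio
#' inversion), truncated at the parameter's domain boundaries.
#'
#' @param counts Integer vector of per-cell counts at one timepoint, or a
#'   `cell_counts` data frame.
#' @param on An [on_distribution()], typically from [fit_on_distribution()]
#'   on the pre-induction sample.
#' @param model `"gradual"` or `"switch"`.
#' @param conf_level Confidence level for the profile interval (default
#'   0.95); set `ci = FALSE` to skip.
#' @param ci Compute the profile-likelihood interval?
#' @param off_residual_mean Passed to [loglik_switch()].
#' @return A list of class `timepoint_fit`: `model`, `estimate`, `lower`,
#'   `upper`, `logLik`, `n`, `counts`, `on`.
#' @examples
#' on <- on_distribution(6, 0.3)
#' x <- simulate_counts_gradual(on, 0.4, 1, 500, seed = 2)
#' fit_timepoint(x, on, "gradual")$estimate
#' @export
fit_timepoint <- function(counts, on, model = c("gradual", "switch"),
                          conf_level = 0.95, ci = TRUE,
                          off_residual_mean = 0) {
  model <- match.arg(model)
  counts <- .as_count_vector(counts)
  if (length(counts) == 0L) stop("'counts' is empty")
  stopifnot(inherits(on, "on_distribution"))

  if (model == "gradual") {
    ll <- function(s) loglik_gradual(counts, on, s)
    lo <- 1e-9; hi <- 1
  } else {
    ll <- function(w) loglik_switch(counts, on, w, off_residual_mean)
    lo <- 0; hi <- 1
  }
  opt <- stats::optimize(ll, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-9)
  est <- opt$maximum
  llmax <- opt$objective
  # optimize() never returns the exact interval ends; snap when the boundary
  # beats the interior solution so boundary data give boundary estimates
  for (b in c(lo, hi)) {
    llb <- tryCatch(ll(b), error = function(e) -Inf)
    if (is.finite(llb) && llb >= llmax) { est <- b; llmax <- llb }
  }
  if (!is.finite(llmax))
    stop("log-likelihood is not finite at the optimum; ",
         "check the counts and the ON fit (diagnostics: estimate = ", est,
         ", n = ", length(counts), ")")

  bounds <- c(NA_real_, NA_real_)
  if (isTRUE(ci)) {
    drop <- stats::qchisq(conf_level, df = 1) / 2
    f <- function(p) ll(p) - (llmax - drop)
    bounds[1] <- if (est > lo && f(max(lo, 1e-12)) < 0) {
      stats::uniroot(f, c(max(lo, 1e-12), est), tol = 1e-8)$root
    } else lo
    bounds[2] <- if (est < hi && f(hi) < 0) {
      stats::uniroot(f, c(est, hi), tol = 1e-8)$root
    } else hi
  }
  structure(list(model = model, estimate = est, lower = bounds[1],
                 upper = bounds[2], logLik = llmax, n = length(counts),
                 counts = counts, on = on,
                 off_residual_mean = off_residual_mean),
            class = "timepoint_fit")
}

#' @export
print.timepoint_fit <- function(x, ...) {
  par_name <- if (x$model == "gradual") "scale s" else "w_off"
  cat(sprintf("%s-model fit at one timepoint (n = %d cells)\n",
              x$model, x$n))
  cat(sprintf("  %s = %.4f", par_name, x$estimate))
  if (!is.na(x$lower))
    cat(sprintf("  [%.4f, %.4f]", x$lower, x$upper))
  cat(sprintf("\n  logLik = %.3f\n", x$logLik))
  invisible(x)
}

#' Fit an establishment model across a silencing time course
#'
#' The central fitting function.  Counts at the baseline (pre-induction)
#' timepoint define the ON distribution, whose mean and dispersion are fit
#' once by maximum likelihood and held fixed; every later timepoint then
#' receives a single free parameter — the transcription scale `s` (gradual
#' model) or the OFF fraction `w` (switch model) — fit by bounded
#' one-dimensional maximum likelihood.  Holding the dispersion shared keeps
#' the two models at equal per-timepoint parameter count, so their
#' log-likelihoods are directly comparable.
#'
#' @param formula A formula `count ~ timepoint` naming the count column and
#'   the timepoint column of `data`.
#' @param data A data frame (e.g. a `cell_counts` table) with one row per
#'   cell.
#' @param model `"gradual"` or `"switch"`.
#' @param baseline Value of the timepoint variable identifying the
#'   pre-induction sample (default: its minimum).
#' @param on Optionally a known [on_distribution()]; if supplied the
#'   baseline sample is not used to fit the ON state (it is still reported).
#' @param conf_level,ci Passed to [fit_timepoint()].
#' @param off_residual_mean Residual OFF-cell mean for the switch model.
#' @return An object of class `establishment_fit` with components `model`,
#'   `on`, `timepoints` (a data frame of per-timepoint estimates, intervals,
#'   log-likelihoods and cell numbers), `logLik`, `baseline`, and `call`.
#'   Supported methods: `print`, `summary`, `coef`, `logLik`, `predict`,
#'   `simulate`, `plot`, `residuals`.
#' @examples
#' on <- on_distribution(6, 0.3)
#' tc <- rbind(simulate_counts_gradual(on, 1, 0, 300, seed = 1, timepoint = 0),
#'             simulate_counts_gradual(on, 0.4, 1, 300, seed = 2, timepoint = 2))
#' fit <- fit_establishment(count ~ timepoint_hr, tc, model = "gradual")
#' coef(fit)
#' @export
fit_establishment <- function(formula, data, model = c("gradual", "switch"),
                              baseline = NULL, on = NULL, conf_level = 0.95,
                              ci = TRUE, off_residual_mean = 0) {
  model <- match.arg(model)
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  mf <- stats::model.frame(formula, data)
  counts <- .as_count_vector(mf[[1L]])
  tp <- mf[[2L]]
  if (is.null(baseline)) baseline <- min(tp)
  if (!any(tp == baseline))
    stop("no rows at the baseline timepoint '", baseline, "'")

  pre <- counts[tp == baseline]
  if (is.null(on)) on <- fit_on_distribution(pre)
  stopifnot(inherits(on, "on_distribution"))

  later <- sort(unique(tp[tp != baseline]))
  fits <- lapply(later, function(t)
    fit_timepoint(counts[tp == t], on, model, conf_level = conf_level,
                  ci = ci, off_residual_mean = off_residual_mean))
  timepoints <- data.frame(
    timepoint = later,
    n_cells = vapply(fits, `[[`, 0L, "n"),
    estimate = vapply(fits, `[[`, 0, "estimate"),
    lower = vapply(fits, `[[`, 0, "lower"),
    upper = vapply(fits, `[[`, 0, "upper"),
    logLik = vapply(fits, `[[`, 0, "logLik")
  )
  structure(list(model = model, on = on, timepoints = timepoints,
                 fits = fits, logLik = sum(timepoints$logLik),
                 baseline = baseline, n_pre = length(pre),
                 off_residual_mean = off_residual_mean,
                 call = match.call()),
            class = "establishment_fit")
}

#' @export
print.establishment_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Silencing-establishment fit: %s model\n", x$model))
  cat(sprintf("  ON state (baseline %s, n = %d): mu = %.*g, alpha = %.*g\n",
              format(x$baseline), x$n_pre, digits, x$on$mu, digits,
              x$on$alpha))
  par_name <- if (x$model == "gradual") "scale_s" else "w_off"
  tab <- x$timepoints
  names(tab)[names(tab) == "estimate"] <- par_name
  print(tab, row.names = FALSE, digits = digits)
  cat(sprintf("Total logLik (timepoints after baseline): %.3f\n", x$logLik))
  invisible(x)
}

#' @export
summary.establishment_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.establishment_fit")
}

#' @export
print.summary.establishment_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  mu_t <- predict(fit)
  cat("Fitted mean transcripts/cell by timepoint:\n")
  print(data.frame(timepoint = fit$timepoints$timepoint, mean = mu_t$mean,
                   zero_fraction = mu_t$zero_fraction),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.establishment_fit <- function(object, ...) {
  stats::setNames(object$timepoints$estimate,
                  paste0(if (object$model == "gradual") "s_" else "w_",
                         object$timepoints$timepoint))
}

#' @export
logLik.establishment_fit <- function(object, ...) {
  # free parameters: one per post-baseline timepoint, plus the shared ON fit
  val <- object$logLik
  attr(val, "df") <- nrow(object$timepoints) + 2L
  attr(val, "nobs") <- sum(object$timepoints$n_cells)
  class(val) <- "logLik"
  val
}

#' Model-implied population summaries for a fitted establishment model
#'
#' Returns, per post-baseline timepoint, the expected mean transcripts per
#' cell and the expected fraction of zero-count cells under the fitted model.
#'
#' @param object An `establishment_fit`.
#' @param ... Unused.
#' @return A data frame with columns `timepoint`, `mean`, `zero_fraction`.
#' @export
predict.establishment_fit <- function(object, ...) {
  on <- object$on
  est <- object$timepoints$estimate
  if (object$model == "gradual") {
    mu <- est * on$mu
    zf <- vapply(mu, function(m) don(0L, on, mu = m), 0)
  } else {
    mu <- (1 - est) * on$mu + est * object$off_residual_mean
    p0_on <- don(0L, on)
    p0_off <- stats::dpois(0L, object$off_residual_mean)
    zf <- est * p0_off + (1 - est) * p0_on
  }
  data.frame(timepoint = object$timepoints$timepoint, mean = mu,
             zero_fraction = zf)
}

#' @export
simulate.establishment_fit <- function(object, nsim = 1, seed = NULL, ...) {
  .with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      tabs <- lapply(seq_len(nrow(object$timepoints)), function(j) {
        row <- object$timepoints[j, ]
        if (object$model == "gradual") {
          simulate_counts_gradual(object$on, retention = row$estimate,
                                  n_cycles = 1, n_cells = row$n_cells,
                                  timepoint = row$timepoint)
        } else {
          simulate_counts_switch(object$on, p_off = row$estimate,
                                 n_cycles = 1, n_cells = row$n_cells,
                                 off_residual_mean = object$off_residual_mean,
                                 timepoint = row$timepoint)
        }
      })
      do.call(rbind, tabs)
    })
  })
}

#' @export
residuals.establishment_fit <- function(object, ...) {
  # Pearson residuals of per-cell counts against the fitted timepoint mean
  unlist(lapply(object$fits, function(f) {
    on <- object$on
    if (object$model == "gradual") {
      mu <- f$estimate * on$mu
      v <- mu + on$alpha * mu^2
    } else {
      mu <- (1 - f$estimate) * on$mu + f$estimate * object$off_residual_mean
      m_on <- on$mu; v_on <- m_on + on$alpha * m_on^2
      m_off <- object$off_residual_mean
      w <- f$estimate
      # mixture variance
      v <- (1 - w) * (v_on + m_on^2) + w * (m_off + m_off^2) - mu^2
    }
    (f$counts - mu) / sqrt(pmax(v, .Machine$double.eps))
  }), use.names = FALSE)
}

#' @export
plot.establishment_fit <- function(x, ...) {
  tab <- x$timepoints
  ylab <- if (x$model == "gradual") "transcription scale s" else
    "OFF fraction w"
  graphics::plot(tab$timepoint, tab$estimate, type = "b", pch = 19,
                 ylim = c(0, 1), xlab = "timepoint", ylab = ylab, ...)
  if (!all(is.na(tab$lower)))
    graphics::arrows(tab$timepoint, tab$lower, tab$timepoint, tab$upper,
                     angle = 90, code = 3, length = 0.04)
  invisible(x)
}
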