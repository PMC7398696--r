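#' Parameters of H3K79-methylation dilution and turnover kinetics
#'
#' H3K79 methylation is deposited by Dot1 and has no demethylase, so at a
#' locus it can only fall by incorporation of unmethylated histones: dilution
#' by half at each replication, and replication-independent exchange with
#' the free nuclear H3 pool.  Outside S phase roughly 90% of nuclear H3 is
#' K79-methylated, so exchange alone pulls the locus toward 0.9; during
#' S phase the pool is diluted by newly synthesized unmethylated H3.
#'
#' @param lambda Fraction of locus histones exchanged per unit time outside
#'   replication, in [0, 1].
#' @param f_pool Methylated fraction of the free nuclear H3 pool outside
#'   S phase (default 0.9).
#' @param f_pool_s_phase Pool methylated fraction during S phase (default
#'   0.45: new synthesis roughly doubles the pool with unmethylated H3).
#' @param dot1_active Does Dot1 re-methylate resident histones?
#' @param k_me Dot1 re-methylation rate per unit time (toward full
#'   methylation) when active and the locus is not Sir-protected.
#' @return A list of class `turnover_params`.
#' @export
turnover_params <- function(lambda = 0.05, f_pool = 0.9,
                            f_pool_s_phase = 0.45, dot1_active = TRUE,
                            k_me = 0.1) {
  for (nm in c("lambda", "f_pool", "f_pool_s_phase"))
    .check_scalar(get(nm), nm, lower = 0, upper = 1)
  .check_scalar(k_me, "k_me", lower = 0)
  stopifnot(is.logical(dot1_active), length(dot1_active) == 1L)
  structure(list(lambda = lambda, f_pool = f_pool,
                 f_pool_s_phase = f_pool_s_phase,
                 dot1_active = dot1_active, k_me = k_me),
            class = "turnover_params")
}

#' Advance the locus methylation state by one event
#'
#' The mark state `m` is the fraction of locus nucleosomal H3 methylated at
#' K79, in [0, 1].  Three event types:
#' \describe{
#'   \item{replication}{Replication-coupled incorporation of new
#'     (unmethylated) histones halves the mark: `m' = m / 2`.}
#'   \item{turnover}{Replication-independent exchange over an interval `dt`
#'     relaxes the mark toward the pool fraction:
#'     `m' = (1 - lambda*dt) * m + lambda*dt * f_pool_current`, with the
#'     S-phase pool used when `s_phase = TRUE`.}
#'   \item{dot1}{Re-methylation of resident histones over `dt` when Dot1 is
#'     active and the locus is not Sir-protected:
#'     `m' = m + k_me*dt*(1 - m)`.}
#' }
#' The result is clipped to [0, 1].
#'
#' @param m Current methylated fraction in [0, 1].
#' @param event `"replication"`, `"turnover"`, or `"dot1"`.
#' @param params A [turnover_params()].
#' @param dt Time interval for turnover/dot1 events (>= 0; `lambda * dt`
#'   must not exceed 1).
#' @param s_phase Use the S-phase pool fraction for turnover?
#' @param sir_protected Is the locus protected from Dot1 by Sir binding?
#' @return The updated methylated fraction.
#' @examples
#' step_mark(0.9, "replication")  # 0.45
#' @export
step_mark <- function(m, event = c("replication", "turnover", "dot1"),
                      params = turnover_params(), dt = 1, s_phase = FALSE,
                      sir_protected = FALSE) {
  event <- match.arg(event)
  .check_scalar(m, "m", lower = 0, upper = 1)
  if (dt < 0) stop("'dt' must be non-negative, got ", dt)
  m2 <- switch(event,
    replication = m / 2,
    turnover = {
      frac <- params$lambda * dt
      if (frac > 1) stop("lambda * dt = ", frac, " exceeds 1: the whole ",
                         "locus cannot exchange more than once per step")
      pool <- if (s_phase) params$f_pool_s_phase else params$f_pool
      (1 - frac) * m + frac * pool
    },
    dot1 = {
      if (params$dot1_active && !sir_protected)
        m + params$k_me * dt * (1 - m)
      else m
    })
  min(max(m2, 0), 1)
}

#' Simulate a mark trajectory over discrete, phase-ordered cell cycles
#'
#' Each cycle applies G1 turnover, then S-phase replication (dilution by
#' half) together with S-phase turnover against the diluted pool, then G2
#' turnover; Dot1 re-methylation runs in every phase unless the locus is
#' Sir-protected.  This discrete phase ordering mirrors per-cell-cycle
#' reasoning rather than a continuous-time ODE.
#'
#' @param m0 Initial methylated fraction.
#' @param n_cycles Number of cell cycles to simulate.
#' @param params A [turnover_params()].
#' @param sir_protected Is the locus Sir-protected (blocks Dot1)?
#' @param replicate_locus Does the locus itself replicate?  (An excised
#'   non-replicating episome still exchanges with the S-phase pool.)
#' @param dt_phase Duration assigned to each of G1, S, G2 (units of
#'   `lambda`).
#' @param repression A [repression_map()] used to annotate each phase with
#'   the transcription scale; `sir_bound` is taken equal to `sir_protected`.
#' @return A data frame of class `mark_trajectory` with columns `cycle`,
#'   `phase`, `m`, `s` (one row per phase plus the initial state).
#' @examples
#' simulate_marks(0.9, 2, turnover_params(lambda = 0))
#' @export
simulate_marks <- function(m0, n_cycles, params = turnover_params(),
                           sir_protected = FALSE, replicate_locus = TRUE,
                           dt_phase = 1, repression = repression_map()) {
  .check_scalar(m0, "m0", lower = 0, upper = 1)
  .check_scalar(n_cycles, "n_cycles", lower = 0, integer = TRUE)
  m <- m0
  rows <- list(data.frame(cycle = 0L, phase = "initial", m = m,
                          s = transcription_scale(repression, sir_protected,
                                                  m)))
  for (k in seq_len(n_cycles)) {
    for (phase in c("G1", "S", "G2")) {
      if (phase == "S" && replicate_locus)
        m <- step_mark(m, "replication", params)
      m <- step_mark(m, "turnover", params, dt = dt_phase,
                     s_phase = phase == "S")
      m <- step_mark(m, "dot1", params, dt = dt_phase,
                     sir_protected = sir_protected)
      rows[[length(rows) + 1L]] <-
        data.frame(cycle = k, phase = phase, m = m,
                   s = transcription_scale(repression, sir_protected, m))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mark_trajectory", "data.frame")
  out
}

#' Map mark level and Sir binding to a transcription scale
#'
#' Sir binding alone achieves no repression: whenever `sir_bound` is FALSE
#' the scale is exactly 1 regardless of the mark.  When Sir proteins are
#' bound, repression deepens as the activating H3K79me mark is lost; the
#' mapping is monotone non-decreasing in `m` but its functional form is a
#' modelling choice, so it is pluggable: linear
#' `s = s_min + (1 - s_min) * m` (default) or logistic in `m`.
#'
#' @param form `"linear"` or `"logistic"`.
#' @param s_min Scale at a fully unmethylated, Sir-bound locus (default 0).
#' @param midpoint,steepness Logistic-form parameters.
#' @return A list of class `repression_map`.
#' @export
repression_map <- function(form = c("linear", "logistic"), s_min = 0,
                           midpoint = 0.5, steepness = 10) {
  form <- match.arg(form)
  .check_scalar(s_min, "s_min", lower = 0, upper = 1)
  structure(list(form = form, s_min = s_min, midpoint = midpoint,
                 steepness = steepness), class = "repression_map")
}

#' @rdname repression_map
#' @param map A `repression_map`.
#' @param sir_bound Are Sir proteins bound at the locus?
#' @param m Methylated fraction in [0, 1] (vectorized).
#' @export
transcription_scale <- function(map, sir_bound, m) {
  stopifnot(inherits(map, "repression_map"), is.logical(sir_bound),
            length(sir_bound) == 1L)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("'m' must lie in [0, 1]")
  if (!sir_bound) return(rep(1, length(m)))
  s <- switch(map$form,
    linear = map$s_min + (1 - map$s_min) * m,
    logistic = {
      raw <- stats::plogis(map$steepness * (m - map$midpoint))
      lo <- stats::plogis(map$steepness * (0 - map$midpoint))
      hi <- stats::plogis(map$steepness * (1 - map$midpoint))
      map$s_min + (1 - map$s_min) * (raw - lo) / (hi - lo)
    })
  pmin(pmax(s, 0), 1)
}

#' Write a mark trajectory as TSV
#'
#' @param x A `mark_trajectory` data frame.
#' @param path Output path.
#' @export
write_mark_trajectory <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
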