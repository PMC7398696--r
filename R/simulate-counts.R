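#' Simulate single-cell transcript counts under the gradual (tune-down) model
#'
#' In the gradual model every cell remains in a partially repressed state and
#' the mean transcript number falls multiplicatively each cell cycle: after
#' `n_cycles` cycles with per-cycle retention `r`, counts are drawn from the
#' ON distribution with mean `mu * r^n_cycles` and unchanged dispersion.
#'
#' @param on An [on_distribution()] describing pre-induction expression.
#' @param retention Per-cell-cycle multiplicative retention of the mean, in
#'   (0, 1].
#' @param n_cycles Number of completed cell cycles (integer >= 0).
#' @param n_cells Number of cells to draw (>= 1).
#' @param seed Integer seed; identical arguments and seed reproduce the draw
#'   exactly.
#' @param timepoint,probe,condition Labels copied into the output table.
#' @param detection_efficiency Probability that any one transcript is
#'   detected; applied as binomial thinning (default 1, no thinning).
#' @return A `cell_counts` data frame with columns `cell_id`, `probe`,
#'   `timepoint_hr`, `condition`, `count`.
#' @examples
#' head(simulate_counts_gradual(on_distribution(6), 0.5, 2, 10, seed = 1))
#' @export
simulate_counts_gradual <- function(on, retention, n_cycles, n_cells,
                                    seed = NULL, timepoint = n_cycles,
                                    probe = "HMRa1", condition = "simulated",
                                    detection_efficiency = 1) {
  stopifnot(inherits(on, "on_distribution"))
  .check_scalar(retention, "retention", lower = 0, upper = 1,
                lower_open = TRUE)
  .check_scalar(n_cycles, "n_cycles", lower = 0, integer = TRUE)
  .check_n_cells(n_cells)
  .with_seed(seed, {
    mu_t <- on$mu * retention^n_cycles
    counts <- ron(n_cells, on, mu = mu_t)
    counts <- .thin_counts(counts, detection_efficiency)
    .cell_counts(counts, probe, timepoint, condition)
  })
}

#' Simulate single-cell transcript counts under the switch (all-or-nothing)
#' model
#'
#' Each cycle a cell either stays fully ON or converts irreversibly to OFF
#' with probability `p_off`; after `n_cycles` cycles the OFF fraction is
#' `w = 1 - (1 - p_off)^n_cycles`.  ON cells draw from the unchanged
#' pre-induction distribution; OFF cells have `off_residual_mean` transcripts
#' on average (default exactly 0).
#'
#' @inheritParams simulate_counts_gradual
#' @param p_off Per-cycle ON-to-OFF transition probability, in [0, 1].
#' @param off_residual_mean Mean residual transcripts in OFF cells
#'   (default 0: OFF is a point mass at zero).
#' @return A `cell_counts` data frame; attribute `off` records which cells
#'   were OFF.
#' @examples
#' x <- simulate_counts_switch(on_distribution(6), 0.3, 1, 1000, seed = 1)
#' mean(x$count == 0)
#' @export
simulate_counts_switch <- function(on, p_off, n_cycles, n_cells,
                                   seed = NULL, off_residual_mean = 0,
                                   timepoint = n_cycles, probe = "HMRa1",
                                   condition = "simulated",
                                   detection_efficiency = 1) {
  stopifnot(inherits(on, "on_distribution"))
  .check_scalar(p_off, "p_off", lower = 0, upper = 1)
  .check_scalar(off_residual_mean, "off_residual_mean", lower = 0)
  .check_scalar(n_cycles, "n_cycles", lower = 0, integer = TRUE)
  .check_n_cells(n_cells)
  .with_seed(seed, {
    w <- 1 - (1 - p_off)^n_cycles
    off <- stats::runif(n_cells) < w
    counts <- integer(n_cells)
    counts[!off] <- ron(sum(!off), on)
    counts[off] <- if (off_residual_mean > 0) {
      stats::rpois(sum(off), off_residual_mean)
    } else 0L
    counts <- .thin_counts(counts, detection_efficiency)
    out <- .cell_counts(counts, probe, timepoint, condition)
    attr(out, "off") <- off
    out
  })
}

.thin_counts <- function(counts, efficiency) {
  .check_scalar(efficiency, "detection_efficiency", lower = 0, upper = 1,
                lower_open = TRUE)
  if (efficiency < 1) counts <- stats::rbinom(length(counts), counts,
                                              efficiency)
  counts
}

.cell_counts <- function(counts, probe, timepoint, condition) {
  out <- data.frame(
    cell_id = sprintf("cell_%05d", seq_along(counts)),
    probe = probe,
    timepoint_hr = timepoint,
    condition = condition,
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_counts", "data.frame")
  out
}

# Evaluate `expr` under a temporary seeded RNG state, restoring the caller's.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  .check_scalar(seed, "seed", integer = TRUE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          lower_open = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number")
  if (x < lower || (lower_open && x == lower) || x > upper)
    stop("'", name, "' = ", x, " is outside its valid range ",
         if (lower_open) "(" else "[", lower, ", ", upper, "]")
  if (integer && x != floor(x)) stop("'", name, "' must be an integer")
  invisible(x)
}

.check_n_cells <- function(n_cells) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || !is.finite(n_cells) ||
      n_cells < 1 || n_cells != floor(n_cells))
    stop("'n_cells' must be a positive integer, got ", n_cells)
}

#' Read and write per-cell transcript-count tables
#'
#' The TSV dialect has columns `cell_id`, `probe`, `timepoint_hr`,
#' `condition`, `count`.
#'
#' @param x A `cell_counts` data frame.
#' @param path File path.
#' @return `read_cell_counts()` returns a `cell_counts` data frame;
#'   `write_cell_counts()` returns `path` invisibly.
#' @export
write_cell_counts <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_counts
#' @export
read_cell_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "probe", "timepoint_hr", "condition", "count")
  if (!all(need %in% names(x)))
    stop("cell-counts file is missing columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  x$count <- as.integer(x$count)
  class(x) <- c("cell_counts", "data.frame")
  x
}
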