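#' Simulate an RT-qPCR plate with standards, triplicates, and no-RT controls
#'
#' Well Cq values follow the standard-curve model
#' `Cq = slope * log10(Q) + intercept + noise`.  For every target gene the
#' plate carries a serial-dilution standard series; every sample/target
#' combination is measured in `n_replicates` wells plus matched
#' non-reverse-transcribed (no-RT) wells whose signal is a stated leakage
#' fraction of the RT signal (genomic DNA carry-over).
#'
#' @param quantities Data frame with columns `sample`, `target`,
#'   `quantity` (> 0), the true relative cDNA abundances.
#' @param slope Standard-curve slope in Cq per decade (negative; default
#'   -log2(10) = -3.3219, i.e. perfect doubling).
#' @param intercept Cq at quantity 1.
#' @param cq_noise_sd Gaussian Cq noise SD (0 = noiseless).
#' @param standards Numeric vector of standard input quantities (default a
#'   5-point 10-fold dilution series from 1 down).
#' @param n_replicates Wells per sample/target (default 3, triplicate).
#' @param no_rt_leakage No-RT signal as a fraction of the RT quantity
#'   (default 1e-3); 0 makes no-RT wells non-detects.
#' @param max_cycles Detection limit: computed Cq above this is censored as
#'   a non-detect (`NA` Cq; default 40).
#' @param seed Integer seed.
#' @return A `qpcr_plate` data frame with columns `sample`, `target`,
#'   `replicate`, `cq`, `is_standard`, `std_quantity`, `is_no_rt`.
#' @examples
#' q <- data.frame(sample = "t0", target = "HMRa1", quantity = 1)
#' simulate_qpcr(q, cq_noise_sd = 0)[1:3, ]
#' @export
simulate_qpcr <- function(quantities, slope = -log2(10),
                          intercept = 30, cq_noise_sd = 0,
                          standards = 10^seq(0, -4), n_replicates = 3,
                          no_rt_leakage = 1e-3, max_cycles = 40,
                          seed = NULL) {
  stopifnot(is.data.frame(quantities),
            all(c("sample", "target", "quantity") %in% names(quantities)))
  if (any(quantities$quantity <= 0))
    stop("all true quantities must be positive")
  if (slope >= 0) stop("'slope' must be negative (Cq falls as input rises)")
  if (length(unique(standards)) < 3)
    stop("standards must span at least 3 distinct quantities")
  .check_scalar(cq_noise_sd, "cq_noise_sd", lower = 0)
  .with_seed(seed, {
    cq_of <- function(q) slope * log10(q) + intercept
    rows <- list()
    add <- function(sample, target, q, is_standard, std_q, is_no_rt) {
      cq <- cq_of(q) + stats::rnorm(n_replicates, 0, cq_noise_sd)
      cq[cq > max_cycles] <- NA_real_
      rows[[length(rows) + 1L]] <<- data.frame(
        sample = sample, target = target, replicate = seq_len(n_replicates),
        cq = cq, is_standard = is_standard, std_quantity = std_q,
        is_no_rt = is_no_rt, stringsAsFactors = FALSE)
    }
    for (tg in unique(quantities$target))
      for (s in standards)
        add(sprintf("std_%g", s), tg, s, TRUE, s, FALSE)
    for (i in seq_len(nrow(quantities))) {
      qi <- quantities[i, ]
      add(qi$sample, qi$target, qi$quantity, FALSE, NA_real_, FALSE)
      if (no_rt_leakage > 0) {
        add(qi$sample, qi$target, qi$quantity * no_rt_leakage, FALSE,
            NA_real_, TRUE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = qi$sample, target = qi$target,
          replicate = seq_len(n_replicates), cq = NA_real_,
          is_standard = FALSE, std_quantity = NA_real_, is_no_rt = TRUE,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("qpcr_plate", "data.frame")
    out
  })
}

#' Read and write qPCR plate tables
#'
#' @param x A `qpcr_plate` data frame.
#' @param path TSV path.
#' @export
write_qpcr_plate <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr_plate
#' @export
read_qpcr_plate <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "target", "replicate", "cq", "is_standard",
            "std_quantity", "is_no_rt")
  if (!all(need %in% names(x)))
    stop("qPCR plate file is missing columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  class(x) <- c("qpcr_plate", "data.frame")
  x
}

#' Fit a qPCR standard curve
#'
#' Least-squares line `Cq = slope * log10(Q) + intercept` through the
#' standard-dilution wells, reporting r-squared and the amplification
#' efficiency `10^(-1/slope) - 1` (1.0 = perfect per-cycle doubling, at
#' slope -3.3219).
#'
#' @param quantity Standard input quantities (> 0), or a `qpcr_plate`
#'   (standard wells of `target` are then used and `cq` is ignored).
#' @param cq Measured Cq values (same length as `quantity`).
#' @param target Target gene, when `quantity` is a plate.
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n`, and the underlying `lm` fit.
#' @examples
#' fit_standard_curve(10^(0:-4), -3.3219 * (0:-4) + 30)
#' @export
fit_standard_curve <- function(quantity, cq = NULL, target = NULL) {
  if (is.data.frame(quantity)) {
    plate <- quantity
    stopifnot(!is.null(target))
    sel <- plate$is_standard & plate$target == target & !is.na(plate$cq)
    quantity <- plate$std_quantity[sel]
    cq <- plate$cq[sel]
  }
  if (any(quantity <= 0)) stop("standard quantities must be positive")
  if (length(unique(quantity)) < 3)
    stop("need at least 3 distinct standard quantities, got ",
         length(unique(quantity)))
  fit <- stats::lm(cq ~ I(log10(quantity)))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("fitted standard-curve slope is not negative (", format(slope),
         "); check the dilution series")
  eff <- 10^(-1 / slope) - 1
  if (eff < 0.8 || eff > 1.1)
    warning(sprintf("amplification efficiency %.3f outside [0.8, 1.1]",
                    eff))
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 efficiency = eff, n = length(cq), lm = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve (%d wells)\n", x$n))
  cat(sprintf("  Cq = %.4f * log10(Q) + %.4f   (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  amplification efficiency: %.3f\n", x$efficiency))
  invisible(x)
}

#' Quantify input abundance from Cq via a standard curve
#'
#' Inverts the curve: `Q = 10^((Cq - intercept) / slope)`.  Non-detect
#' (`NA`) Cq values propagate as `NA` quantities — missing, never zero.
#'
#' @param cq Cq values (vectorized; `NA` = non-detect).
#' @param curve A [fit_standard_curve()] result.
#' @return Quantities on the standard's scale.
#' @export
quantify <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Replicate-aggregated relative abundance with QC
#'
#' For one sample: aggregates replicate wells on the Cq scale (mean of the
#' triplicate Cq; replicate SD above `sd_flag` is flagged), quantifies
#' target and reference through their standard curves, and reports the
#' target/reference ratio.  The matched no-RT wells are quantified the same
#' way and reported as a fraction of the RT-derived quantity; fractions
#' above `no_rt_threshold` are flagged as possible genomic-DNA
#' contamination.
#'
#' @param plate A `qpcr_plate`.
#' @param curves Named list of `standard_curve`s, one per gene (defaults to
#'   fitting from the plate's own standard wells).
#' @param target,reference Gene names (reference e.g. `"ALG9"`).
#' @param samples Samples to quantify (default: all non-standard samples).
#' @param no_rt_threshold Acceptable no-RT fraction (default 0.01).
#' @param sd_flag Replicate Cq SD flag threshold (default 0.5).
#' @return A data frame of class `relative_abundance` with one row per
#'   sample: quantities, `ratio`, `no_rt_fraction`, and logical QC flags
#'   `flag_replicate_sd`, `flag_no_rt`, `flag_non_detect`.
#' @export
relative_abundance <- function(plate, curves = NULL, target, reference,
                               samples = NULL, no_rt_threshold = 0.01,
                               sd_flag = 0.5) {
  stopifnot(is.data.frame(plate))
  if (!any(plate$target == reference & !plate$is_standard))
    stop("no reference-gene ('", reference, "') wells on the plate")
  if (is.null(curves))
    curves <- stats::setNames(
      lapply(c(target, reference), function(g)
        fit_standard_curve(plate, target = g)),
      c(target, reference))
  if (!all(c(target, reference) %in% names(curves)))
    stop("need standard curves for both '", target, "' and '", reference,
         "'")
  if (is.null(samples))
    samples <- unique(plate$sample[!plate$is_standard])

  agg_cq <- function(sample, gene, no_rt) {
    sel <- plate$sample == sample & plate$target == gene &
      plate$is_no_rt == no_rt & !plate$is_standard
    cqs <- plate$cq[sel]
    if (length(cqs) == 0L)
      return(list(cq = NA_real_, sd = NA_real_, any_nd = TRUE,
                  missing = TRUE))
    list(cq = mean(cqs, na.rm = TRUE),
         sd = stats::sd(cqs, na.rm = TRUE),
         any_nd = anyNA(cqs), missing = FALSE)
  }
  rows <- lapply(samples, function(s) {
    tg <- agg_cq(s, target, FALSE)
    rf <- agg_cq(s, reference, FALSE)
    if (rf$missing) stop("sample '", s, "' has no reference wells")
    nr <- agg_cq(s, target, TRUE)
    q_t <- quantify(tg$cq, curves[[target]])
    q_r <- quantify(rf$cq, curves[[reference]])
    q_nr <- if (is.na(nr$cq)) 0 else quantify(nr$cq, curves[[target]])
    no_rt_frac <- q_nr / q_t
    data.frame(sample = s, target = target, reference = reference,
               cq_target = tg$cq, cq_reference = rf$cq,
               quantity_target = q_t, quantity_reference = q_r,
               ratio = q_t / q_r, no_rt_fraction = no_rt_frac,
               flag_replicate_sd = isTRUE(tg$sd > sd_flag) ||
                 isTRUE(rf$sd > sd_flag),
               flag_no_rt = isTRUE(no_rt_frac > no_rt_threshold),
               flag_non_detect = tg$any_nd || rf$any_nd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("relative_abundance", "data.frame")
  out
}

#' Fold repression along a silencing time course
#'
#' Each sample is normalized to its own pre-induction value:
#' `fold_t = ratio_baseline / ratio_t`, so values above 1 mean repression
#' relative to baseline and the baseline itself is exactly 1.
#'
#' @param abundance A `relative_abundance` data frame (or any data frame
#'   with `sample` and `ratio`).
#' @param baseline Sample id of the pre-induction baseline.
#' @return The input with an added `fold_repression` column.
#' @examples
#' x <- data.frame(sample = c("t0", "t1", "t2"), ratio = c(0.8, 0.4, 0.08))
#' fold_repression(x, "t0")$fold_repression
#' @export
fold_repression <- function(abundance, baseline) {
  stopifnot(is.data.frame(abundance),
            all(c("sample", "ratio") %in% names(abundance)))
  b <- abundance$ratio[abundance$sample == baseline]
  if (length(b) != 1L)
    stop("baseline sample '", baseline, "' not found exactly once")
  if (!is.finite(b) || b == 0)
    stop("baseline ratio is zero or missing; cannot form fold changes")
  abundance$fold_repression <- b / abundance$ratio
  abundance
}
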