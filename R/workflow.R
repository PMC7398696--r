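#' Load and validate a run configuration
#'
#' Configurations are YAML or JSON with a fixed schema: top-level keys
#' `seed`, `out_dir`, `log_level`, and per-stage parameter blocks
#' `generator`, `models`, `inference`, `chip`, `qpcr`.  Unknown keys at the
#' top level or inside a block are rejected before any stage runs, so typos
#' fail fast rather than silently falling back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @param overrides Named list merged over the file's values (e.g.
#'   `list(seed = 7)` from a command line).
#' @return A validated list of class `run_config`.
#' @export
load_run_config <- function(path, overrides = list()) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(cfg, overrides)
  validate_run_config(cfg)
}

.config_schema <- list(
  seed = NULL, out_dir = NULL, log_level = NULL,
  generator = c("n_cells", "mu", "alpha", "truth", "retention", "p_off",
                "off_residual_mean", "n_cycles", "timepoints",
                "n_fragments", "frag_mean", "frag_sd", "subnuc_frac",
                "enrichment", "enriched_locus", "chrom_lengths",
                "spacing", "probe", "condition"),
  models = c("lambda", "f_pool", "f_pool_s_phase", "dot1_active", "k_me",
             "repression_form", "s_min"),
  inference = c("n_bootstrap", "conf_level", "tie_tol", "ci"),
  chip = c("min_len", "max_len", "subtelomere_width", "exclusions",
           "genes"),
  qpcr = c("slope", "intercept", "cq_noise_sd", "standards",
           "n_replicates", "no_rt_leakage", "no_rt_threshold")
)

#' @rdname load_run_config
#' @param cfg A configuration list.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (block in setdiff(names(.config_schema), c("seed", "out_dir",
                                                 "log_level"))) {
    if (!is.null(cfg[[block]])) {
      bad <- setdiff(names(cfg[[block]]), .config_schema[[block]])
      if (length(bad))
        stop("unknown key(s) in config block '", block, "': ",
             paste(bad, collapse = ", "))
    }
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  .check_scalar(cfg$seed, "seed", integer = TRUE)
  if (is.null(cfg$log_level)) cfg$log_level <- "INFO"
  structure(cfg, class = c("run_config", "list"))
}

# Deterministic per-stage child seeds, so any stage can be re-run in
# isolation from the manifest: child = (seed * 1000003 + stage index) mod
# 2^31 - 1, stages indexed in a fixed documented order.
.stage_order <- c("simulate_pre", "simulate_timepoints", "fit", "compare",
                  "simulate_ip", "simulate_input", "qpcr")

#' @rdname load_run_config
#' @param seed Parent seed.
#' @param stage Stage name (one of the documented stage ids).
#' @export
child_seed <- function(seed, stage) {
  i <- match(stage, .stage_order)
  if (is.na(i)) stop("unknown stage '", stage, "'")
  as.integer((as.numeric(seed) * 1000003 + i) %% (2^31 - 1))
}

.log_stage <- function(cfg, stage, ...) {
  if (identical(cfg$log_level, "QUIET")) return(invisible())
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

# md5 digest of a config list via its canonical JSON serialization
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

.manifest <- function(cfg, stage_files) {
  files <- unlist(stage_files, use.names = FALSE)
  structure(list(
    artifact_version = as.character(utils::packageVersion("silest")),
    config = unclass(cfg),
    config_hash = .config_hash(cfg),
    seed = cfg$seed,
    stages = lapply(stage_files, function(fs)
      lapply(stats::setNames(fs, basename(fs)), function(f)
        unname(tools::md5sum(f)))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest (seed ", x$seed, ", config ", x$config_hash, ")\n",
      sep = "")
  for (st in names(x$stages)) {
    cat("  ", st, ":\n", sep = "")
    for (f in names(x$stages[[st]]))
      cat("    ", f, "  ", x$stages[[st]][[f]], "\n", sep = "")
  }
  invisible(x)
}

#' Write a run manifest as JSON
#' @param manifest A `run_manifest`.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the single-cell (smRNA-FISH) workflow end to end
#'
#' Simulates a pre-induction sample and post-induction timepoints under the
#' configured truth (gradual or switch), writes the count tables, fits both
#' establishment models, compares them, and writes the fits, the
#' comparison, per-timepoint summary statistics, and a reproducibility
#' manifest of file digests into the run directory.
#'
#' @param cfg A `run_config` (or plain list passed through
#'   [validate_run_config()]).
#' @param out_dir Run directory (default `cfg$out_dir` or a tempdir).
#' @return The `run_manifest`, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_fish_workflow <- function(cfg, out_dir = NULL) {
  cfg <- validate_run_config(unclass(cfg))
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("fish_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- cfg$generator
  gv <- function(key, default) if (is.null(g[[key]])) default else g[[key]]
  mu <- gv("mu", 6); alpha <- gv("alpha", 0.3)
  n_cells <- gv("n_cells", 300L)
  truth <- gv("truth", "gradual")
  timepoints <- gv("timepoints", c(2, 4))
  on <- on_distribution(mu, alpha)

  .log_stage(cfg, "simulate", sprintf(
    "truth=%s mu=%g alpha=%g n_cells=%d timepoints=%s", truth, mu, alpha,
    n_cells, paste(timepoints, collapse = ",")))
  pre <- simulate_counts_gradual(on, 1, 0, n_cells,
                                 seed = child_seed(cfg$seed, "simulate_pre"),
                                 timepoint = 0,
                                 condition = "pre_induction")
  later <- lapply(seq_along(timepoints), function(i) {
    s <- child_seed(cfg$seed, "simulate_timepoints") + i
    if (truth == "gradual") {
      simulate_counts_gradual(on, gv("retention", 0.4), i, n_cells,
                              seed = s, timepoint = timepoints[i])
    } else {
      simulate_counts_switch(on, gv("p_off", 0.6), i, n_cells, seed = s,
                             off_residual_mean = gv("off_residual_mean", 0),
                             timepoint = timepoints[i])
    }
  })
  counts <- do.call(rbind, c(list(pre), later))
  counts_path <- file.path(out_dir, "cell_counts.tsv")
  write_cell_counts(counts, counts_path)

  .log_stage(cfg, "fit", "fitting gradual and switch models")
  inf <- cfg$inference
  iv <- function(key, default)
    if (is.null(inf[[key]])) default else inf[[key]]
  fg <- fit_establishment(count ~ timepoint_hr, counts, "gradual",
                          baseline = 0, conf_level = iv("conf_level", 0.95))
  fs <- fit_establishment(count ~ timepoint_hr, counts, "switch",
                          baseline = 0, conf_level = iv("conf_level", 0.95))
  cmp <- compare_models(fg, fs, n_bootstrap = iv("n_bootstrap", 0),
                        seed = child_seed(cfg$seed, "compare"),
                        tie_tol = iv("tie_tol", 1e-6))

  stats_tab <- do.call(rbind, lapply(c(0, timepoints), function(t) {
    st <- summary_stats(counts$count[counts$timepoint_hr == t],
                        reference = pre$count)
    data.frame(timepoint_hr = t, n = st$n, zero_fraction = st$zero_fraction,
               mean_all = st$mean_all, mean_nonzero = st$mean_nonzero,
               shape_distance = st$shape_distance,
               shape_p_value = st$shape_p_value)
  }))
  stats_path <- file.path(out_dir, "timepoint_stats.tsv")
  utils::write.table(stats_tab, stats_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  fits_path <- file.path(out_dir, "model_fits.json")
  jsonlite::write_json(list(
    on = list(mu = fg$on$mu, alpha = fg$on$alpha),
    gradual = fg$timepoints, switch = fs$timepoints,
    comparison = list(delta_loglik = cmp$delta_loglik,
                      aic = as.list(cmp$aic), selected = cmp$selected,
                      tie = cmp$tie, p_gradual = cmp$p_gradual,
                      p_switch = cmp$p_switch,
                      n_bootstrap = cmp$n_bootstrap, note = cmp$note)),
    fits_path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null", na = "null")

  manifest <- .manifest(cfg, list(simulate = counts_path,
                                  fit = c(fits_path, stats_path)))
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest, manifest_path)
  .log_stage(cfg, "done", sprintf("selected model: %s", cmp$selected))
  invisible(manifest)
}

#' Run the MNase ChIP workflow end to end
#'
#' Builds a toy genome with one enriched locus, simulates IP and input
#' fragment libraries, applies the mononucleosome size gate, computes
#' per-base coverage, normalizes both tracks to the non-heterochromatic
#' genome-wide median, and writes bedGraph tracks, a per-gene normalized
#' coverage table, and a manifest.
#'
#' @inheritParams run_fish_workflow
#' @return The `run_manifest`, invisibly.
#' @export
run_chip_workflow <- function(cfg, out_dir = NULL) {
  cfg <- validate_run_config(unclass(cfg))
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("chip_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- cfg$generator
  gv <- function(key, default) if (is.null(g[[key]])) default else g[[key]]
  ch <- cfg$chip
  cv <- function(key, default) if (is.null(ch[[key]])) default else
    ch[[key]]

  chrom_lengths <- unlist(gv("chrom_lengths",
                             list(chrI = 60000L, chrII = 40000L)))
  genome <- toy_genome(chrom_lengths, spacing = gv("spacing", 165L))
  locus <- gv("enriched_locus",
              list(chrom = names(chrom_lengths)[1], start = 30000L,
                   end = 33000L))
  enr <- gv("enrichment", 10)
  in_locus <- genome$nucleosomes$chrom == locus$chrom &
    genome$nucleosomes$dyad >= locus$start &
    genome$nucleosomes$dyad < locus$end
  genome$nucleosomes$enrichment[in_locus] <- enr

  n_frag <- gv("n_fragments", 50000L)
  .log_stage(cfg, "simulate", sprintf(
    "%d fragments, %gx enrichment at %s:%d-%d", n_frag, enr, locus$chrom,
    locus$start, locus$end))
  ip <- simulate_fragments(genome, n_frag,
                           subnuc_frac = gv("subnuc_frac", 0.1), ip = TRUE,
                           seed = child_seed(cfg$seed, "simulate_ip"))
  input <- simulate_fragments(genome, n_frag,
                              subnuc_frac = gv("subnuc_frac", 0.1),
                              ip = FALSE,
                              seed = child_seed(cfg$seed, "simulate_input"))
  ip_path <- file.path(out_dir, "ip_fragments.bed")
  input_path <- file.path(out_dir, "input_fragments.bed")
  write_fragments(ip, ip_path)
  write_fragments(input, input_path)

  excl <- subtelomere_exclusions(chrom_lengths,
                                 cv("subtelomere_width", 5000L))
  gate <- list(min_len = cv("min_len", 130L), max_len = cv("max_len", 180L))
  .log_stage(cfg, "normalize", sprintf(
    "size gate %d-%d bp, %d exclusion interval(s)", gate$min_len,
    gate$max_len, nrow(excl)))
  tracks <- lapply(list(ip = ip, input = input), function(fr) {
    fr <- filter_fragments(fr, gate$min_len, gate$max_len)
    tr <- coverage_track(fr, chrom_lengths)
    normalize_to_nonhet_median(tr, excl)
  })
  track_paths <- vapply(names(tracks), function(nm) {
    p <- file.path(out_dir, paste0(nm, "_normalized.bedgraph"))
    write_bedgraph(tracks[[nm]], p)
    p
  }, "")

  genes <- gv("genes", NULL)
  if (is.null(genes)) {
    starts <- seq.int(6000L, chrom_lengths[[1]] - 8000L, by = 2000L)
    genes <- data.frame(chrom = names(chrom_lengths)[1], start = starts,
                        end = starts + 1500L)
  }
  gene_tab <- gene_normalized_coverage(tracks$ip, genes)
  gene_path <- file.path(out_dir, "gene_coverage.tsv")
  utils::write.table(gene_tab, gene_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  enr_hat <- locus_enrichment(tracks$ip,
                              data.frame(chrom = locus$chrom,
                                         start = locus$start,
                                         end = locus$end), excl)
  .log_stage(cfg, "done", sprintf("recovered locus enrichment: %.2fx",
                                  enr_hat))
  manifest <- .manifest(cfg, list(
    simulate = c(ip_path, input_path),
    normalize = unname(track_paths),
    genes = gene_path))
  manifest$recovered_enrichment <- enr_hat
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
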