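# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: explicit per-cell / per-position loops over direct calls
# into stats, so that agreement with the vectorized implementations is a
# real check and not a tautology.

oracle_loglik_gradual <- function(counts, mu, alpha, s) {
  ll <- 0
  for (x in counts) {
    ll <- ll + if (alpha == 0) {
      dpois(x, lambda = s * mu, log = TRUE)
    } else {
      dnbinom(x, mu = s * mu, size = 1 / alpha, log = TRUE)
    }
  }
  ll
}

oracle_loglik_switch <- function(counts, mu, alpha, w) {
  ll <- 0
  for (x in counts) {
    p_on <- if (alpha == 0) dpois(x, mu) else
      dnbinom(x, mu = mu, size = 1 / alpha)
    ll <- ll + log(w * (x == 0) + (1 - w) * p_on)
  }
  ll
}

# grid-search NB MLE over (mu, alpha), the slow reference for fit_on_distribution
oracle_fit_on_grid <- function(counts, mu_grid, alpha_grid) {
  best <- c(mu = NA, alpha = NA, ll = -Inf)
  for (mu in mu_grid) for (a in alpha_grid) {
    ll <- if (a == 0) sum(dpois(counts, mu, log = TRUE)) else
      sum(dnbinom(counts, mu = mu, size = 1 / a, log = TRUE))
    if (ll > best["ll"]) best <- c(mu = mu, alpha = a, ll = ll)
  }
  best
}

oracle_filter <- function(frags, min_len, max_len) {
  keep <- logical(nrow(frags))
  for (i in seq_len(nrow(frags))) {
    len <- frags$end[i] - frags$start[i]
    keep[i] <- len >= min_len && len <= max_len
  }
  out <- frags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_coverage <- function(frags, seqlengths) {
  out <- lapply(seqlengths, function(len) numeric(len))
  for (i in seq_len(nrow(frags))) {
    chr <- frags$chrom[i]
    for (pos in frags$start[i]:(frags$end[i] - 1L)) {
      out[[chr]][pos + 1L] <- out[[chr]][pos + 1L] + 1
    }
  }
  out
}

oracle_nonexcluded_values <- function(track_list, seqlengths, excl) {
  vals <- c()
  for (chr in names(track_list)) {
    excluded <- rep(FALSE, seqlengths[[chr]])
    if (!is.null(excl)) {
      for (i in seq_len(nrow(excl))) {
        if (excl$chrom[i] == chr)
          excluded[(excl$start[i] + 1L):excl$end[i]] <- TRUE
      }
    }
    vals <- c(vals, track_list[[chr]][!excluded])
  }
  vals
}

oracle_gene_coverage <- function(track_list, genes) {
  dens <- numeric(nrow(genes))
  sums <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    v <- 0
    for (pos in genes$start[i]:(genes$end[i] - 1L))
      v <- v + track_list[[genes$chrom[i]]][pos + 1L]
    sums[i] <- v
    dens[i] <- v / (genes$end[i] - genes$start[i])
  }
  list(sums = sums, density = dens, normalized = dens / mean(dens))
}

random_fragments <- function(n, seqlengths, max_len = 250L) {
  chrom <- sample(names(seqlengths), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(seqlengths[[chrom[i]]] - len[i], 1L) - 1L, 0L)
  fragment_set(data.frame(chrom = chrom, start = start,
                          end = start + len),
               seqlengths = seqlengths)
}
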