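# Oracle equivalence on randomized small instances is the backbone here:
# every processing stage must agree with an explicit per-position /
# per-fragment loop.

test_that("the size gate keeps exactly the closed 130-180 bp window", {
  f <- fragment_set(data.frame(chrom = "c", start = 0L,
                               end = c(129L, 130L, 155L, 180L, 181L)))
  kept <- filter_fragments(f)
  expect_equal(kept$end, c(130L, 155L, 180L))
  expect_identical(filter_fragments(f[0, ]), f[0, ])
  # idempotence and order preservation
  expect_identical(filter_fragments(kept), kept)
  expect_error(filter_fragments(f, min_len = 0), "min_len")
  set.seed(20)
  sl <- c(chrA = 3000L, chrB = 1500L)
  r <- random_fragments(300, sl)
  expect_identical(as.data.frame(filter_fragments(r, 120, 200)),
                   as.data.frame(oracle_filter(r, 120, 200)))
})

test_that("per-base coverage uses half-open semantics and matches brute force", {
  sl <- c(c = 20L)
  f <- fragment_set(data.frame(chrom = "c", start = 10L, end = 13L))
  cov <- coverage_track(f, sl)
  expect_equal(which(cov$c == 1) - 1L, c(10L, 11L, 12L))
  expect_equal(sum(cov$c), 3)
  f2 <- fragment_set(data.frame(chrom = "c", start = c(10L, 10L),
                                end = c(13L, 13L)))
  expect_equal(max(coverage_track(f2, sl)$c), 2)
  # random instances vs the per-position loop
  set.seed(21)
  for (i in 1:5) {
    sl_i <- c(chrA = sample(500:900, 1), chrB = sample(200:400, 1))
    r <- random_fragments(200, sl_i, max_len = 150L)
    cov <- coverage_track(r, sl_i)
    oc <- oracle_coverage(r, sl_i)
    expect_identical(lapply(cov, as.numeric)[names(sl_i)], oc)
  }
  expect_error(coverage_track(
    fragment_set(data.frame(chrom = "nope", start = 1L, end = 5L)), sl),
    "unknown chromosome")
})

test_that("median normalization divides by the non-excluded median exactly", {
  sl <- c(c = 5L)
  f <- fragment_set(data.frame(chrom = rep("c", 5),
                               start = c(0L, 0L, 0L, 1L, 2L),
                               end = c(3L, 5L, 5L, 5L, 5L)))
  tr <- coverage_track(f, sl)
  expect_equal(as.numeric(tr$c), c(3, 4, 5, 4, 4))
  # hand-built track [2,4,6,8,10] via direct construction
  tr$c <- c(2, 4, 6, 8, 10)
  norm <- normalize_to_nonhet_median(tr, NULL)
  expect_equal(as.numeric(norm$c), c(2, 4, 6, 8, 10) / 6)
  expect_equal(attr(norm, "norm_factor"), 6)
  # excluding positions 3-4 (0-based): median over [2,4,6] = 4
  excl <- data.frame(chrom = "c", start = 3L, end = 5L, label = "rDNA")
  norm2 <- normalize_to_nonhet_median(tr, excl)
  expect_equal(as.numeric(norm2$c), c(0.5, 1, 1.5, 2, 2.5))
  expect_equal(attr(norm2, "norm_factor"), 4)
})

test_that("normalization matches the brute-force masked median on random data", {
  set.seed(22)
  for (i in 1:8) {
    sl <- c(chrA = sample(400:800, 1), chrB = sample(300:600, 1))
    r <- random_fragments(300, sl, max_len = 120L)
    tr <- coverage_track(r, sl)
    excl <- data.frame(
      chrom = c("chrA", "chrB"),
      start = c(0L, sample(0:100, 1)),
      end = c(sample(50:150, 1), sample(150:250, 1)),
      label = c("subtelomere", "rDNA"))
    norm <- normalize_to_nonhet_median(tr, excl)
    med <- median(oracle_nonexcluded_values(lapply(tr, as.numeric), sl,
                                            excl))
    expect_equal(attr(norm, "norm_factor"), med)
    expect_equal(as.numeric(norm$chrA), as.numeric(tr$chrA) / med)
    # post-normalization non-excluded median is exactly 1
    post <- oracle_nonexcluded_values(lapply(norm, as.numeric), sl, excl)
    expect_equal(median(post), 1, tolerance = 1e-12)
  }
})

test_that("exclusions change only the normalization factor, never coverage", {
  set.seed(23)
  sl <- c(chrA = 1000L)
  r <- random_fragments(400, sl, max_len = 100L)
  tr <- coverage_track(r, sl)
  n1 <- normalize_to_nonhet_median(tr, NULL)
  excl <- data.frame(chrom = "chrA", start = 0L, end = 300L,
                     label = "subtelomere")
  n2 <- normalize_to_nonhet_median(tr, excl)
  f1 <- attr(n1, "norm_factor"); f2 <- attr(n2, "norm_factor")
  expect_equal(as.numeric(n2$chrA) * f2, as.numeric(n1$chrA) * f1)
  # degenerate: empty library cannot be normalized
  empty <- coverage_track(r[0, ], sl)
  expect_error(normalize_to_nonhet_median(empty, NULL), "median")
  all_excl <- data.frame(chrom = "chrA", start = 0L, end = 1000L,
                         label = "chromosome")
  expect_error(normalize_to_nonhet_median(tr, all_excl), "excluded")
})

test_that("per-gene densities normalize to mean 1 and match brute force", {
  sl <- c(c = 400L)
  tr <- coverage_track(fragment_set(
    data.frame(chrom = "c", start = 0L, end = 400L)), sl)
  # gene A: length 100, summed coverage 200 after doubling track over it
  tr$c[1:100] <- 2
  genes <- data.frame(gene_id = c("A", "B"), chrom = "c",
                      start = c(0L, 100L), end = c(100L, 300L))
  gc <- gene_normalized_coverage(tr, genes)
  expect_equal(gc$coverage_sum, c(200, 200))
  expect_equal(gc$density, c(2, 1))
  expect_equal(gc$normalized_density, c(4 / 3, 2 / 3))
  expect_equal(mean(gc$normalized_density), 1)
  # all genes equal density
  tr$c[] <- 3
  gc2 <- gene_normalized_coverage(tr, genes)
  expect_equal(gc2$normalized_density, c(1, 1))
  # random instances vs the loop oracle
  set.seed(24)
  for (i in 1:5) {
    sl_i <- c(chrA = 2000L)
    r <- random_fragments(300, sl_i, max_len = 180L)
    tr_i <- coverage_track(r, sl_i)
    starts <- sort(sample(0:1800, 50))
    genes_i <- data.frame(chrom = "chrA", start = starts,
                          end = starts + sample(20:150, 50, replace = TRUE))
    genes_i$end <- pmin(genes_i$end, 2000L)
    gc_i <- gene_normalized_coverage(tr_i, genes_i)
    oc <- oracle_gene_coverage(lapply(tr_i, as.numeric), genes_i)
    expect_equal(gc_i$coverage_sum, oc$sums)
    expect_equal(gc_i$density, oc$density)
    expect_equal(gc_i$normalized_density, oc$normalized)
    expect_equal(mean(gc_i$normalized_density), 1, tolerance = 1e-12)
  }
  expect_error(gene_normalized_coverage(tr, genes[0, ]), "empty")
  bad <- data.frame(chrom = "c", start = 10L, end = 10L)
  expect_error(gene_normalized_coverage(tr, bad), "interval")
})

test_that("programmed IP enrichment is recovered after gating and normalization", {
  g <- toy_genome(c(chrI = 60000L, chrII = 40000L))
  locus <- data.frame(chrom = "chrI", start = 30000L, end = 33000L)
  sel <- g$nucleosomes$chrom == "chrI" &
    g$nucleosomes$dyad >= locus$start & g$nucleosomes$dyad < locus$end
  g$nucleosomes$enrichment[sel] <- 10
  ip <- simulate_fragments(g, 50000, subnuc_frac = 0.1, ip = TRUE,
                           seed = 30)
  excl <- subtelomere_exclusions(g$seqlengths, 5000L)
  tr <- normalize_to_nonhet_median(
    coverage_track(filter_fragments(ip), g$seqlengths), excl)
  enr <- locus_enrichment(tr, locus, excl)
  expect_lt(abs(enr - 10) / 10, 0.10)
  # a flat input library recovers ~1x
  input <- simulate_fragments(g, 50000, subnuc_frac = 0.1, ip = FALSE,
                              seed = 31)
  tri <- normalize_to_nonhet_median(
    coverage_track(filter_fragments(input), g$seqlengths), excl)
  expect_lt(abs(locus_enrichment(tri, locus, excl) - 1), 0.1)
})

test_that("normalized tracks export to bedGraph and re-import intact", {
  set.seed(25)
  sl <- c(chrA = 800L, chrB = 500L)
  r <- random_fragments(150, sl, max_len = 120L)
  tr <- normalize_to_nonhet_median(coverage_track(r, sl), NULL)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  bg <- read_bed(path)
  rebuilt <- lapply(sl, function(len) numeric(len))
  gr <- rtracklayer::import(path, format = "bedGraph")
  for (i in seq_along(gr)) {
    chr <- as.character(GenomicRanges::seqnames(gr)[i])
    idx <- GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]
    rebuilt[[chr]][idx] <- gr$score[i]
  }
  expect_equal(rebuilt$chrA, as.numeric(tr$chrA))
  expect_equal(rebuilt$chrB, as.numeric(tr$chrB))
})
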