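test_that("standard curves recover exact lines, efficiency, and r-squared", {
  q <- 10^(0:-4)
  curve <- fit_standard_curve(q, -3.3219 * log10(q) + 30)
  expect_equal(curve$slope, -3.3219, tolerance = 1e-9)
  expect_equal(curve$intercept, 30, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1)
  expect_equal(curve$efficiency, 10^(1 / 3.3219) - 1, tolerance = 1e-9)
  expect_equal(curve$efficiency, 1, tolerance = 1e-4)  # 10^(1/3.3219) = 2
  # slope -3.5: closed-form efficiency
  c2 <- suppressWarnings(fit_standard_curve(q, -3.5 * log10(q) + 28))
  expect_equal(c2$efficiency, 10^(1 / 3.5) - 1, tolerance = 1e-9)
  expect_error(fit_standard_curve(c(1, 1, 1), c(30, 30, 30)), "distinct")
  expect_error(fit_standard_curve(c(1, 0, 0.1), c(30, 31, 32)), "positive")
  expect_warning(fit_standard_curve(q, -5 * log10(q) + 30), "efficiency")
})

test_that("slope estimation is unbiased under Cq noise", {
  set.seed(40)
  q <- rep(10^(0:-4), each = 3)
  slopes <- vapply(1:100, function(i) {
    cq <- -3.3219 * log10(q) + 30 + rnorm(length(q), 0, 0.2)
    fit_standard_curve(q, cq)$slope
  }, 0)
  se <- sd(slopes) / sqrt(100)
  expect_lt(abs(mean(slopes) - (-3.3219)), 3 * se)
})

test_that("quantify inverts the Cq model exactly; non-detects stay missing", {
  curve <- fit_standard_curve(10^(0:-4), -3.3219 * log10(10^(0:-4)) + 30)
  expect_equal(quantify(30, curve), 1, tolerance = 1e-9)
  expect_equal(quantify(30 + curve$slope, curve), 10, tolerance = 1e-9)
  expect_true(is.na(quantify(NA_real_, curve)))
  # full noiseless round trip through the plate simulator
  truth <- data.frame(sample = c("a", "b", "c"),
                      target = "HMRa1",
                      quantity = c(0.8, 0.05, 0.004))
  plate <- simulate_qpcr(truth, cq_noise_sd = 0, no_rt_leakage = 0,
                         seed = 41)
  crv <- fit_standard_curve(plate, target = "HMRa1")
  for (i in seq_len(nrow(truth))) {
    cq <- plate$cq[plate$sample == truth$sample[i] & !plate$is_no_rt][1]
    expect_lt(abs(quantify(cq, crv) - truth$quantity[i]) /
                truth$quantity[i], 1e-9)
  }
})

test_that("the plate simulator reproduces the stated Cq model and noise", {
  q <- data.frame(sample = "s1", target = "g", quantity = 1)
  plate <- simulate_qpcr(q, slope = -3.3219, intercept = 30,
                         cq_noise_sd = 0, no_rt_leakage = 0, seed = 42)
  expect_equal(plate$cq[plate$sample == "s1" & !plate$is_no_rt],
               rep(30, 3))
  q10 <- data.frame(sample = "s1", target = "g", quantity = 10)
  p10 <- simulate_qpcr(q10, slope = -3.3219, intercept = 30,
                       cq_noise_sd = 0, no_rt_leakage = 0, seed = 42)
  expect_equal(p10$cq[p10$sample == "s1" & !p10$is_no_rt],
               rep(26.6781, 3))
  # replicate SD tracks the stated noise SD
  set.seed(43)
  sds <- vapply(1:200, function(i) {
    p <- simulate_qpcr(q, cq_noise_sd = 0.2, no_rt_leakage = 0)
    sd(p$cq[p$sample == "s1" & !p$is_no_rt])
  }, 0)
  # E[S] for n=3 normal: sigma * sqrt(2/(n-1)) * gamma(n/2)/gamma((n-1)/2)
  expect_lt(abs(mean(sds) - 0.2 * sqrt(2 / 2) * gamma(1.5) / gamma(1)),
            3 * sd(sds) / sqrt(200))
  expect_error(simulate_qpcr(data.frame(sample = "s", target = "g",
                                        quantity = 0)), "positive")
  expect_error(simulate_qpcr(q, slope = 2), "slope")
  expect_error(simulate_qpcr(q, standards = c(1, 0.1)), "3 distinct")
})

test_that("relative abundance aggregates triplicates and applies QC flags", {
  truth <- data.frame(sample = rep(c("t0", "t1"), each = 2),
                      target = rep(c("HMRa1", "ALG9"), 2),
                      quantity = c(4, 2, 1, 2))
  plate <- simulate_qpcr(truth, cq_noise_sd = 0, seed = 44)
  ra <- relative_abundance(plate, target = "HMRa1", reference = "ALG9")
  expect_equal(ra$ratio[ra$sample == "t0"], 2, tolerance = 1e-9)
  expect_equal(ra$ratio[ra$sample == "t1"], 0.5, tolerance = 1e-9)
  # default 0.1% leakage is under the 1% threshold: no flag
  expect_false(any(ra$flag_no_rt))
  expect_false(any(ra$flag_replicate_sd))
  # strong leakage trips the flag
  plate2 <- simulate_qpcr(truth, cq_noise_sd = 0, no_rt_leakage = 0.05,
                          seed = 45)
  ra2 <- relative_abundance(plate2, target = "HMRa1", reference = "ALG9")
  expect_true(all(ra2$flag_no_rt))
  expect_equal(ra2$no_rt_fraction, rep(0.05, 2), tolerance = 1e-6)
  expect_error(relative_abundance(plate, target = "HMRa1",
                                  reference = "SNR52"), "reference")
})

test_that("target/reference ratios are invariant to global scaling", {
  truth <- data.frame(sample = rep(c("t0", "t1"), each = 2),
                      target = rep(c("HMRa1", "ALG9"), 2),
                      quantity = c(0.9, 1.5, 0.2, 1.5))
  r1 <- relative_abundance(simulate_qpcr(truth, cq_noise_sd = 0,
                                         seed = 46),
                           target = "HMRa1", reference = "ALG9")
  truth$quantity <- truth$quantity * 37
  r2 <- relative_abundance(simulate_qpcr(truth, cq_noise_sd = 0,
                                         seed = 46),
                           target = "HMRa1", reference = "ALG9")
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-9)
})

test_that("fold repression is baseline-anchored and matches the generator means", {
  x <- data.frame(sample = c("t0", "t1", "t2"),
                  ratio = c(0.8, 0.4, 0.08))
  f <- fold_repression(x, "t0")
  expect_equal(f$fold_repression, c(1, 2, 10))
  flat <- data.frame(sample = c("t0", "t1"), ratio = c(0.5, 0.5))
  expect_equal(fold_repression(flat, "t0")$fold_repression, c(1, 1))
  expect_error(fold_repression(x, "t9"), "baseline")
  expect_error(fold_repression(data.frame(sample = "t0", ratio = 0), "t0"),
               "zero")
  # gradual-model population means: mu r^k gives folds r^-k = 1, 2.5, 6.25
  on <- on_distribution(6, 0)
  means <- vapply(0:2, function(k) {
    mean(simulate_counts_gradual(on, 0.4, k, 50000,
                                 seed = 47 + k)$count)
  }, 0)
  truth <- data.frame(sample = c("t0", "t1", "t2"), target = "HMRa1",
                      quantity = means)
  truth <- rbind(truth, data.frame(sample = truth$sample, target = "ALG9",
                                   quantity = 1))
  plate <- simulate_qpcr(truth, cq_noise_sd = 0, seed = 48)
  ra <- relative_abundance(plate, target = "HMRa1", reference = "ALG9")
  f <- fold_repression(ra, "t0")
  expect_equal(f$fold_repression[order(f$sample)], c(1, 2.5, 6.25),
               tolerance = 0.05)
})

test_that("qPCR plates round-trip through TSV", {
  truth <- data.frame(sample = "t0", target = "g", quantity = 0.5)
  plate <- simulate_qpcr(truth, cq_noise_sd = 0.1, seed = 49)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qpcr_plate(plate, path)
  p2 <- read_qpcr_plate(path)
  expect_equal(p2$cq, plate$cq, tolerance = 1e-10)
  expect_equal(p2$is_no_rt, plate$is_no_rt)
})
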