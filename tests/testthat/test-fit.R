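test_that("ON-distribution fit recovers Poisson and NB parameters", {
  set.seed(10)
  # Poisson data: mu near 6, alpha driven to the Poisson edge
  x <- rpois(5000, 6)
  fit <- fit_on_distribution(x)
  expect_lt(abs(fit$mu - 6), 3 * sqrt(6 / 5000))
  expect_lt(fit$alpha, 0.02)
  # NB data: alpha recovered, checked against a grid-search MLE oracle
  y <- rnbinom(5000, mu = 6, size = 1 / 0.5)
  fit <- fit_on_distribution(y)
  expect_equal(fit$mu, mean(y))
  expect_lt(abs(fit$alpha - 0.5), 0.08)
  grid <- oracle_fit_on_grid(y, mu_grid = mean(y),
                             alpha_grid = seq(0.3, 0.7, by = 0.005))
  expect_lt(abs(fit$alpha - grid["alpha"]), 0.01)
  expect_gte(fit$logLik, grid["ll"] - 1e-6)
  # independent library cross-check of the joint MLE
  fd <- suppressWarnings(MASS::fitdistr(y, "negative binomial"))
  expect_equal(fit$alpha, unname(1 / fd$estimate["size"]), tolerance = 0.02)
})

test_that("ON-distribution fit handles degenerate and invalid samples", {
  # constant positive sample: mu = k, alpha = 0
  fit <- suppressWarnings(fit_on_distribution(rep(4L, 10)))
  expect_equal(fit$mu, 4)
  expect_identical(fit$alpha, 0)
  expect_error(fit_on_distribution(integer(0)), "empty")
  expect_error(fit_on_distribution(rep(0L, 100)), "ON state")
  expect_warning(fit_on_distribution(c(1L, 2L, 3L)), "20 cells")
})

test_that("timepoint fits recover the generating scale and OFF fraction", {
  on <- on_distribution(6, 0.3)
  hits_s <- hits_w <- logical(60)
  for (i in 1:60) {
    xg <- simulate_counts_gradual(on, 0.4, 1, 1000, seed = 1000 + i)
    fg <- fit_timepoint(xg, on, "gradual", ci = FALSE)
    hits_s[i] <- abs(fg$estimate - 0.4) <= 0.05
    xs <- simulate_counts_switch(on, 0.6, 1, 1000, seed = 2000 + i)
    fs <- fit_timepoint(xs, on, "switch", ci = FALSE)
    hits_w[i] <- abs(fs$estimate - 0.6) <= 0.05
  }
  expect_gte(mean(hits_s), 0.95)
  expect_gte(mean(hits_w), 0.95)
})

test_that("no-change data fit near the boundary with honest intervals", {
  on <- on_distribution(6, 0.3)
  x <- simulate_counts_gradual(on, 1, 0, 800, seed = 3)
  fg <- fit_timepoint(x, on, "gradual")
  fs <- fit_timepoint(x, on, "switch")
  expect_gt(fg$estimate, 0.9)
  expect_lt(fs$estimate, 0.05)
  expect_lte(fg$upper, 1)
  expect_gte(fs$lower, 0)
  # profile interval covers the MLE
  expect_true(fg$lower <= fg$estimate && fg$estimate <= fg$upper)
})

test_that("profile-likelihood intervals approximately cover the truth", {
  on <- on_distribution(6, 0.3)
  covered <- vapply(1:40, function(i) {
    x <- simulate_counts_gradual(on, 0.5, 1, 400, seed = 4000 + i)
    f <- fit_timepoint(x, on, "gradual", conf_level = 0.95)
    f$lower <= 0.5 && 0.5 <= f$upper
  }, TRUE)
  expect_gte(mean(covered), 0.85)
})

test_that("the formula interface fits a full time course with methods", {
  on <- on_distribution(6, 0.3)
  tc <- rbind(
    simulate_counts_gradual(on, 1, 0, 400, seed = 51, timepoint = 0),
    simulate_counts_gradual(on, 0.6, 1, 400, seed = 52, timepoint = 2),
    simulate_counts_gradual(on, 0.6, 2, 400, seed = 53, timepoint = 4))
  fit <- fit_establishment(count ~ timepoint_hr, tc, model = "gradual")
  expect_s3_class(fit, "establishment_fit")
  expect_equal(fit$timepoints$timepoint, c(2, 4))
  expect_equal(unname(coef(fit)), fit$timepoints$estimate)
  expect_equal(names(coef(fit)), c("s_2", "s_4"))
  # estimates track s^k
  expect_lt(abs(fit$timepoints$estimate[1] - 0.6), 0.1)
  expect_lt(abs(fit$timepoints$estimate[2] - 0.36), 0.1)
  # logLik method bookkeeping
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 4)
  expect_equal(attr(ll, "nobs"), 800)
  # predict returns model-implied means
  pr <- predict(fit)
  expect_equal(pr$mean, fit$timepoints$estimate * fit$on$mu)
  expect_true(all(pr$zero_fraction > 0 & pr$zero_fraction < 1))
  # simulate returns a time course of the same shape
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_equal(nrow(sim[[1]]), 800)
  expect_identical(sim, simulate(fit, nsim = 2, seed = 1))
  # residuals are roughly centred
  r <- residuals(fit)
  expect_length(r, 800)
  expect_lt(abs(mean(r)), 0.2)
  expect_output(print(summary(fit)), "ON state")
  expect_silent(grDevices::pdf(NULL))
  plot(fit)
  grDevices::dev.off()
})

test_that("fits are invariant to row order and cell relabeling", {
  on <- on_distribution(6, 0.3)
  tc <- rbind(
    simulate_counts_gradual(on, 1, 0, 300, seed = 61, timepoint = 0),
    simulate_counts_switch(on, 0.5, 1, 300, seed = 62, timepoint = 2))
  set.seed(1)
  perm <- sample(nrow(tc))
  tc2 <- tc[perm, ]
  tc2$cell_id <- paste0("relabel_", seq_len(nrow(tc2)))
  for (model in c("gradual", "switch")) {
    f1 <- fit_establishment(count ~ timepoint_hr, tc, model, baseline = 0)
    f2 <- fit_establishment(count ~ timepoint_hr, tc2, model, baseline = 0)
    expect_identical(f1$timepoints, f2$timepoints)
    expect_identical(f1$on$mu, f2$on$mu)
    expect_identical(f1$on$alpha, f2$on$alpha)
  }
})

test_that("a supplied ON distribution bypasses the baseline fit", {
  on <- on_distribution(6, 0.3)
  tc <- rbind(
    simulate_counts_gradual(on, 1, 0, 100, seed = 71, timepoint = 0),
    simulate_counts_gradual(on, 0.4, 1, 100, seed = 72, timepoint = 2))
  fit <- fit_establishment(count ~ timepoint_hr, tc, "gradual", on = on)
  expect_identical(fit$on$mu, 6)
  expect_identical(fit$on$alpha, 0.3)
})
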