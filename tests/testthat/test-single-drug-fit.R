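test_that("normalised log-likelihood matches analytic and brute-force values", {
  n <- 6
  # zero residuals: each point contributes log(1/sqrt(2*pi))
  expect_equal(log_likelihood_normalized(rep(0, n), rep(0.2, n)),
               n * log(1 / sqrt(2 * pi)))
  # a residual equal to its sd contributes log(1/sqrt(2*pi)) - 1/2
  expect_equal(log_likelihood_normalized(c(0.3, rep(0, n - 1)),
                                         c(0.3, rep(0.1, n - 1))),
               n * log(1 / sqrt(2 * pi)) - 0.5)
  # brute-force density product on arbitrary points
  set.seed(11)
  res <- rnorm(5, 0, 0.2)
  sds <- runif(5, 0.05, 0.3)
  expect_equal(log_likelihood_normalized(res, sds),
               log(prod(exp(-(res / sds)^2 / 2) / sqrt(2 * pi))),
               tolerance = 1e-12)
  expect_error(log_likelihood_normalized(c(0, 0), c(0.1, -1)), "positive")
})

test_that("pooled AIC bookkeeping reproduces the analytic penalty cases", {
  # 3 drugs x 2 cell lines: 24 free params with death vs 12 without
  deaths <- lapply(1:6, function(i) fake_fit(-10 * i, 4))
  nodeaths <- lapply(1:6, function(i) fake_fit(-10 * i, 2))
  cmp <- compare_aic(deaths, nodeaths)
  expect_identical(cmp$k_death, 24L)
  expect_identical(cmp$k_nodeath, 12L)
  # identical likelihoods: pure parameter penalty
  expect_equal(cmp$delta_aic, 24)

  # likelihood improvement of exactly 12 log-units with 12 extra params
  deaths2 <- lapply(1:6, function(i) fake_fit(-10 * i + 2, 4))
  expect_equal(compare_aic(deaths2, nodeaths)$delta_aic, 0)

  # mismatched data refused
  bad <- fake_fit(-1, 4, doses = c(0, 1, 2, 9))
  expect_error(compare_aic(c(deaths[1:5], list(bad)), nodeaths),
               "identical data")
})

test_that("goodness of fit is the sample Pearson correlation", {
  x <- c(1, 0.8, 0.55, 0.3, 0.2)
  expect_equal(goodness_of_fit(x, x), 1)
  expect_equal(goodness_of_fit(x, -x + 2), -1)
  set.seed(5)
  y <- x + rnorm(5, 0, 0.1)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(goodness_of_fit(x, y), r_manual, tolerance = 1e-12)
  expect_error(goodness_of_fit(x, rep(1, 5)), "zero variance")
})

test_that("noise-free generate-and-refit recovers arbitrary drug parameters", {
  base <- cached_calibration("U87")$params
  truth <- drug_params("toy", 2, ec50 = 0.05, hill_n = 1.3,
                       emax_phi = 0.004, ec50_phi = 0.6)
  doses <- default_doses("toy", "single")
  counts <- cyclecombo:::predict_counts_for_fit(base, 2, doses, truth$ec50,
                                                truth$hill_n, truth$emax_phi,
                                                truth$ec50_phi)
  data <- dose_response_data("toy", "U87", doses, counts)
  fit <- fit_drug_params(data, base, 2, include_death = TRUE, seed = 3)
  expect_lt(fit$sse, 1e-10)
  for (p in c("ec50", "hill_n", "emax_phi", "ec50_phi"))
    expect_equal(fit$params[[p]], truth[[p]], tolerance = 0.01)
  # nested models: adding death terms never lowers the likelihood
  fit0 <- fit_drug_params(data, base, 2, include_death = FALSE, seed = 3)
  expect_gte(fit$log_likelihood, fit0$log_likelihood - 1e-6)
  expect_identical(fit$n_free_params, 4L)
  expect_identical(fit0$n_free_params, 2L)
})

test_that("flat no-effect data fit exactly without death terms", {
  base <- cached_calibration("U87")$params
  doses <- c(0, 0.01, 0.1, 1, 10)
  data <- dose_response_data("inert", "U87", doses, rep(1, 5))
  fit <- fit_drug_params(data, base, 1, include_death = FALSE, seed = 2,
                         n_starts = 10)
  expect_lt(fit$sse, 1e-8)
  expect_equal(fit$predicted, rep(1, 5), tolerance = 1e-4)
})

test_that("fits are reproducible given the seed", {
  base <- cached_calibration("U87")$params
  doses <- default_doses()
  counts <- cyclecombo:::predict_counts_for_fit(base, 1, doses, 0.1, 0.5,
                                                0.011, 0.4)
  data <- dose_response_data("PD0325901", "U87", doses,
                             counts * exp(rnorm(length(counts), 0, 0.02)))
  f1 <- fit_drug_params(data, base, 1, seed = 9, n_starts = 6)
  f2 <- fit_drug_params(data, base, 1, seed = 9, n_starts = 6)
  expect_identical(unlist(f1$params[3:6]), unlist(f2$params[3:6]))
})

test_that("dose-response container validates its contract", {
  expect_error(dose_response_data("d", "c", c(0, 1, 2), c(1, 1, 1)),
               "4 distinct doses")
  expect_error(dose_response_data("d", "c", c(1, 2, 3, 4), rep(1, 4)),
               "control")
  expect_error(dose_response_data("d", "c", c(0, 1, 2, 3), c(1, 1, 0, 1)),
               "positive")
})
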