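test_that("bias_summary implements mean bias with MC standard error", {
  b <- bias_summary(rep(5, 10), 5)
  expect_equal(b$mean_bias, 0)
  expect_equal(b$mc_se, 0)
  expect_equal(b$ci95_of_mean, c(0, 0))
  expect_equal(bias_summary(c(1, 3), 2)$mean_bias, 0)
  x <- c(1.8, 2.2, 2.4, 1.9)
  b2 <- bias_summary(x, 2)
  expect_equal(b2$mc_se, sd(x - 2) / 2)
  expect_equal(b2$n_used, 4)
  expect_error(bias_summary(numeric(0), 2), "no estimates")
})

test_that("coverage_summary counts closed-interval hits", {
  expect_equal(coverage_summary(cbind(-Inf, Inf), 7)$coverage, 1)
  # truth on an endpoint counts as covered
  expect_equal(coverage_summary(rbind(c(2, 5), c(5, 9), c(6, 7)), 5)$coverage,
               2 / 3)
  cs <- coverage_summary(rbind(c(0, 1), c(0, 1), c(2, 3), c(0, 1)), 0.5)
  expect_equal(cs$coverage, 0.75)
  expect_equal(cs$mc_se, sqrt(0.75 * 0.25 / 4))
  expect_error(coverage_summary(matrix(0, 0, 2), 1), "no intervals")
})

test_that("adjusted R-squared follows its degrees-of-freedom formula", {
  d <- noisy_dataset(9)
  f <- fit_linear(d, "P")
  y <- d$feno
  r2 <- 1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  expect_equal(adjusted_r2(f), 1 - (1 - r2) * 7 / 5)
  # a fit no better than the mean (R^2 = 0) is penalized below zero
  expect_equal(1 - (1 - 0) * (8 - 1) / (8 - 2 - 1), -0.4)
  # perfect fit
  nf <- fit_linear(subject_dataset("s", rep(c(50, 100, 300), 2),
                                   3 + 500 / rep(c(50, 100, 300), 2)), "P")
  expect_equal(adjusted_r2(nf), 1, tolerance = 1e-9)
})

test_that("standardized residual SDs expose the error structure by scale", {
  sc <- make_scenario("main", n_datasets = 250, seed = 31)
  b <- simulate_batch(sc)
  fit_all <- function(method) {
    Filter(Negate(is.null),
           lapply(b, function(d) tryCatch(fit_method(d, method),
                                          error = function(e) NULL)))
  }
  # natural-scale fits inherit the decreasing-with-flow error SD
  sds_nat <- pooled_standardized_residual_sd(fit_all("nonLin"))
  expect_gt(sds_nat[["30"]], sds_nat[["300"]])
  expect_true(all(diff(as.numeric(sds_nat)) < 0.05))
  # the log transform approximately flattens the per-flow SDs
  sds_log <- pooled_standardized_residual_sd(fit_all("nonLinLog"))
  expect_lt(max(sds_log) / min(sds_log), 1.6)
  expect_lt(max(sds_log) / min(sds_log),
            sds_nat[["30"]] / sds_nat[["300"]])
})

test_that("Shapiro-Wilk rejection is near alpha for normal errors", {
  sc <- make_scenario("main", n_datasets = 300, seed = 17)
  b <- simulate_batch(sc)
  fits <- lapply(b, fit_linear, formulation = "P")
  rate <- normality_rejection_rate(fits, alpha = 0.05)
  expect_lt(abs(as.numeric(rate) - 0.05), 0.04)
  expect_equal(as.numeric(normality_rejection_rate(fits, alpha = 0)), 0)
  # heavy-tailed errors are rejected more often than alpha
  set.seed(4)
  heavy <- lapply(1:300, function(i) {
    y <- feno_two_compartment(truth_main, std_flows) + 1.5 * rt(8, df = 2)
    fit_linear(subject_dataset("s", std_flows, y), "P")
  })
  expect_gt(as.numeric(normality_rejection_rate(heavy)), 0.1)
})

test_that("spearman_matrix has rank-correlation structure", {
  set.seed(6)
  a <- rnorm(40)
  m <- cbind(a = a, b = exp(a), c = -a, d = rnorm(40))
  r <- spearman_matrix(m)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(r["a", "b"], 1)      # monotone transform
  expect_equal(r["a", "c"], -1)     # anti-ranked
  expect_equal(r, t(r))
  expect_true(all(abs(r) <= 1 + 1e-12))
  # too few complete pairs -> NA entry
  m2 <- cbind(x = c(1, 2, NA, NA, NA), y = c(2, 1, NA, NA, NA))
  expect_true(is.na(spearman_matrix(m2)["x", "y"]))
  ci <- spearman_ci(0.9, 100)
  expect_true(ci[1] < 0.9 && 0.9 < ci[2])
})

test_that("zero-noise study recovers truth for the nonlinear methods", {
  sc <- make_scenario(NULL, noise_sd_per_flow = rep(1e-9, 4),
                      n_datasets = 3, seed = 5)
  st <- run_study(sc, c("quadP", "nonLin", "nonLinLog"))
  nl <- st$bias[st$bias$method %in% c("nonLin", "nonLinLog"), ]
  expect_true(all(abs(nl$mean_bias) < 1e-5))
})

test_that("run_study is deterministic and validates its inputs", {
  sc <- make_scenario("main", n_datasets = 25, seed = 41)
  s1 <- run_study(sc, c("linP", "quadT"))
  s2 <- run_study(sc, c("linP", "quadT"))
  expect_identical(s1$bias, s2$bias)
  expect_identical(s1$coverage, s2$coverage)
  expect_error(run_study(sc, character(0)), "empty")
  expect_error(run_study(sc, "bogus"), "unknown")
  # linear methods contribute no daw rows; HMA has no coverage rows
  s3 <- run_study(make_scenario("main", n_datasets = 20, seed = 2),
                  c("linP", "HMA"))
  expect_false(any(s3$bias$method == "linP" &
                   s3$bias$parameter == "daw_no"))
  expect_false(any(s3$coverage$method == "HMA"))
  expect_true(any(s3$bias$method == "HMA" & s3$bias$parameter == "daw_no"))
})
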