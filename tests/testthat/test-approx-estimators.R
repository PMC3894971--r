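test_that("noise-free linear fits match the closed-form OLS oracle", {
  d <- noise_free_dataset()
  # oracle: normal equations on the exact model values, one value per flow
  fl <- c(30, 50, 100, 300)
  y <- unname(FENO_EXACT)
  bP <- ols_oracle(cbind(1, 1 / fl), y)
  fitP <- fit_linear(d, "P")
  expect_equal(unname(fitP$estimates), c(bP[1], bP[2]), tolerance = 1e-10)
  bT <- ols_oracle(cbind(1, fl), y * fl)
  fitT <- fit_linear(d, "T")
  expect_equal(unname(fitT$estimates), c(bT[2], bT[1]), tolerance = 1e-10)
  # flow-subset variant drops the 30 ml/s maneuvers (strict inequality)
  fitP30 <- fit_linear(d, "P", min_flow_exclusive = 30)
  expect_setequal(fitP30$flows_used, c(50, 100, 300))
  b30 <- ols_oracle(cbind(1, 1 / fl[-1]), y[-1])
  expect_equal(unname(fitP30$estimates), c(b30[1], b30[2]), tolerance = 1e-10)
})

test_that("data on an exact line are recovered exactly with zero residuals", {
  fl <- rep(c(50, 100, 300), each = 2)
  y <- 3 + 500 / fl                       # exact linP mean function
  d <- subject_dataset("s", fl, y)
  f <- fit_linear(d, "P")
  expect_equal(unname(f$estimates), c(3, 500), tolerance = 1e-9)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-10)
  expect_equal(f$adj_r2, 1, tolerance = 1e-9)
})

test_that("design checks reject degenerate inputs", {
  one_flow <- subject_dataset("s", rep(100, 4), c(9, 10, 9, 10))
  expect_error(fit_linear(one_flow, "P"), "insufficient design")
  expect_error(fit_quadratic(one_flow, "P"), "insufficient design")
  two_flows <- subject_dataset("s", c(50, 100, 50, 100), c(17, 10, 16, 9))
  expect_error(fit_quadratic(two_flows, "T"), "insufficient design")
  expect_s3_class(fit_linear(two_flows, "T"), "feno_fit")
})

test_that("quadratic coefficient and parameter maps are exact inverses", {
  # forward map at truth (2, 800, 5): beta = (2, 790, -1975)
  expect_equal(unname(recover_params_quadratic(c(2, 790, -1975), "P")),
               c(2, 800, 5))
  # T-scale coefficient order: (intercept, flow slope, inverse-flow slope)
  expect_equal(unname(recover_params_quadratic(c(790, 2, -1975), "T")),
               c(2, 800, 5))
  # beta2 = 0 degenerates to the linear interpretation
  expect_equal(unname(recover_params_quadratic(c(2, 790, 0), "P")),
               c(2, 790, 0))
  expect_warning(recover_params_quadratic(c(2, 0, -5), "P"), "undefined")
})

test_that("exact quadratic mean-function data reproduce the coefficients", {
  fl <- rep(c(30, 50, 100, 300), each = 2)
  yP <- 2 + 790 / fl - 1975 / fl^2
  fP <- fit_quadratic(subject_dataset("s", fl, yP), "P")
  expect_equal(unname(fP$coefficients), c(2, 790, -1975), tolerance = 1e-8)
  expect_equal(unname(fP$estimates), c(2, 800, 5), tolerance = 1e-8)
  yT <- (2 * fl + 790 + (-1975) / fl) / fl   # NO output scale / flow = FeNO
  fT <- fit_quadratic(subject_dataset("s", fl, yT), "T")
  expect_equal(unname(fT$estimates), c(2, 800, 5), tolerance = 1e-8)
})

test_that("noise-free quadratic fits show the small truncation bias", {
  d <- noise_free_dataset()
  fP <- fit_quadratic(d, "P")
  # second-order truncation biases daw slightly downward
  expect_lt(fP$estimates[["daw_no"]], 5)
  expect_gt(fP$estimates[["daw_no"]], 4.3)
  expect_equal(fP$estimates[["ca_no"]], 2, tolerance = 0.05)
})

test_that("delta method reproduces projections and propagated variance", {
  V <- matrix(c(4, 1, 0, 1, 9, 2, 0, 2, 16), 3, 3)
  expect_equal(delta_method(c(1, 0, 0), V), 4)
  expect_equal(delta_method(c(0, 0, 0), V), 0)
  expect_error(delta_method(c(1, 0), V), "dimension")
  # daw = -2 b2/b1 at (790, -1975), diag cov (25, 100): frozen from a
  # finite-difference + Monte Carlo propagation oracle (agreement < 0.1%)
  g <- c(2 * (-1975) / 790^2, -2 / 790)
  expect_equal(delta_method(g, diag(c(25, 100))), 0.001642365,
               tolerance = 1e-6)
})

test_that("delta-method SE for quadP ca equals the OLS intercept SE", {
  d <- noisy_dataset(11)
  f <- fit_quadratic(d, "P")
  expect_equal(f$std_errors[["ca_no"]], sqrt(f$vcov[1, 1]))
})

test_that("mean of OLS estimates over noise equals the noise-free fit", {
  # OLS is linear in the outcome, so E[beta_hat] is the noiseless fit
  nf <- fit_linear(noise_free_dataset(), "P")$estimates
  set.seed(42)
  nrep <- 3000
  mu <- feno_two_compartment(truth_main, std_flows)
  sds <- rep(c(3.1, 1.4, 0.8, 0.5), each = 2)
  X <- cbind(1, 1 / std_flows)
  H <- solve(crossprod(X), t(X))
  est <- matrix(0, nrep, 2)
  for (i in seq_len(nrep))
    est[i, ] <- H %*% (mu + rnorm(8, 0, sds))
  mc_se <- apply(est, 2, sd) / sqrt(nrep)
  expect_lt(abs(mean(est[, 1]) - nf[["ca_no"]]), 3 * mc_se[1])
  expect_lt(abs(mean(est[, 2]) - nf[["jaw_no"]]), 3 * mc_se[2])
})
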