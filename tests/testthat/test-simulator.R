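test_that("named scenarios encode the study conditions", {
  sc <- make_scenario("main")
  expect_equal(sc$flow_levels, c(30, 50, 100, 300))
  expect_equal(sc$reps_per_flow, 2L)
  expect_equal(sc$noise_sd_per_flow, c(3.1, 1.4, 0.8, 0.5))
  expect_equal(unname(as.numeric(sc$truth)), c(2, 800, 5))
  expect_equal(sc$n_datasets, 10000L)
  expect_equal(make_scenario("ca1")$truth[["ca_no"]], 1)
  expect_equal(make_scenario("ca4")$truth[["ca_no"]], 4)
  expect_equal(make_scenario("constant_sd")$noise_sd_per_flow, rep(1, 4))
  lf <- make_scenario("lowflow20")
  expect_equal(lf$flow_levels, c(20, 50, 100, 300))
  expect_equal(lf$noise_sd_per_flow[1], 4)
  expect_error(make_scenario("nope"), "arg")
  expect_error(make_scenario(NULL, noise_sd_per_flow = c(1, 1)), "parallel")
})

test_that("simulated datasets have the design shape and model means", {
  sc <- make_scenario("main", n_datasets = 5, seed = 3)
  d <- simulate_dataset(sc, 1)
  expect_equal(nrow(d), 8)
  expect_equal(as.numeric(table(d$target_flow)), rep(2, 4))
  expect_true(all(is.na(d$achieved_flow)))
  # near-zero noise: every maneuver equals the exact model value
  sc0 <- make_scenario(NULL, noise_sd_per_flow = rep(1e-12, 4),
                       n_datasets = 1, seed = 1)
  d0 <- simulate_dataset(sc0, 1)
  expect_equal(d0$feno, feno_two_compartment(truth_main, d0$target_flow),
               tolerance = 1e-9)
})

test_that("batches are reproducible and substream-stable", {
  sc <- make_scenario("main", n_datasets = 6, seed = 123)
  b1 <- simulate_batch(sc)
  b2 <- simulate_batch(sc)
  expect_identical(lapply(b1, `[[`, "feno"), lapply(b2, `[[`, "feno"))
  # dataset i is independent of batch size (per-dataset substreams)
  sc_small <- make_scenario("main", n_datasets = 3, seed = 123)
  b3 <- simulate_batch(sc_small)
  expect_identical(b1[[3]]$feno, b3[[3]]$feno)
  expect_identical(b1[[2]]$feno, simulate_dataset(sc, 2)$feno)
  # a different seed changes values but not shape
  b4 <- simulate_batch(make_scenario("main", n_datasets = 6, seed = 124))
  expect_false(identical(b1[[1]]$feno, b4[[1]]$feno))
  expect_equal(nrow(b4[[1]]), 8)
})

test_that("per-flow noise matches the scenario SDs within chi-square bounds", {
  n <- 400
  sc <- make_scenario("main", n_datasets = n, seed = 11)
  b <- simulate_batch(sc)
  y <- do.call(rbind, lapply(b, function(d) d$feno))
  v <- b[[1]]$target_flow
  for (k in seq_along(sc$flow_levels)) {
    cols <- which(v == sc$flow_levels[k])
    x <- as.vector(y[, cols])
    s2 <- var(x)
    m <- length(x) - 1
    lo <- sc$noise_sd_per_flow[k]^2 * qchisq(0.0005, m) / m
    hi <- sc$noise_sd_per_flow[k]^2 * qchisq(0.9995, m) / m
    expect_gt(s2, lo)
    expect_lt(s2, hi)
    # empirical mean sits at the model value
    mu <- feno_two_compartment(truth_main, sc$flow_levels[k])
    expect_lt(abs(mean(x) - mu),
              3.5 * sc$noise_sd_per_flow[k] / sqrt(length(x)))
  }
  # errors independent across maneuvers: cross-flow correlations ~ 0
  cors <- cor(y)
  off <- abs(cors[upper.tri(cors)])
  expect_lt(max(off), 4 / sqrt(n))
  # no non-positive redraws at main-scenario noise levels
  expect_identical(attr(b, "n_redraws"), 0L)
})

test_that("main-scenario batch has the expected total maneuver count", {
  sc <- make_scenario("main", n_datasets = 50, seed = 2)
  b <- simulate_batch(sc)
  expect_equal(sum(vapply(b, nrow, 0L)), 50 * 8)
})

test_that("non-positive draws are redrawn and counted", {
  # low mean + huge SD forces redraws but keeps the dataset size fixed
  sc <- make_scenario(NULL, truth = no_params(2, 40, 5, is_truth = TRUE),
                      flow_levels = c(100, 200, 300),
                      noise_sd_per_flow = c(8, 8, 8),
                      reps_per_flow = 2, n_datasets = 20, seed = 4)
  b <- simulate_batch(sc)
  expect_true(all(vapply(b, function(d) all(d$feno > 0), TRUE)))
  expect_gt(attr(b, "n_redraws"), 0)
  expect_equal(unique(vapply(b, nrow, 0L)), 6L)
})
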