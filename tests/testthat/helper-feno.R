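# Shared fixtures: the canonical truth used throughout the estimator
# comparisons and builders for noise-free and noisy datasets.

truth_main <- no_params(ca_no = 2, jaw_no = 800, daw_no = 5, is_truth = TRUE)

# Exact model values at the canonical truth, frozen from an independent
# 30-digit arbitrary-precision evaluation of the closed form.
FENO_EXACT <- c(`30` = 26.2558874672830, `50` = 17.0356879503184,
                `100` = 9.70575092888719, `300` = 4.61151029618444)

std_flows <- rep(c(30, 50, 100, 300), each = 2)

noise_free_dataset <- function(truth = truth_main, flows = std_flows,
                               id = "nf") {
  subject_dataset(id, flows, feno_two_compartment(truth, flows))
}

noisy_dataset <- function(seed, truth = truth_main, flows = std_flows,
                          sds = rep(c(3.1, 1.4, 0.8, 0.5), each = 2),
                          id = "sim") {
  set.seed(seed)
  mu <- feno_two_compartment(truth, flows)
  subject_dataset(id, flows, mu + rnorm(length(flows), 0, sds))
}

# Brute-force OLS oracle via the normal equations, independent of lm()
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))
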