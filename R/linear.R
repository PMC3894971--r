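#' Linear-approximation estimators (linP, linT)
#'
#' First-order approximation of the two-compartment model, assuming the
#' alveolar concentration is small relative to the airway wall
#' concentration, fit by ordinary least squares:
#'
#' * formulation `"P"` (linP): regress FeNO on inverse flow; the intercept
#'   estimates `ca_no` and the slope estimates `jaw_no`.
#' * formulation `"T"` (linT): regress NO output (`FeNO * flow`) on flow;
#'   the slope estimates `ca_no` and the intercept estimates `jaw_no`.
#'
#' Under the small-`ca_no` assumption the flux parameter is reported as
#' the maximum airway flux `jaw_no`; `daw_no` is not estimable from these
#' models. The approximation requires `daw_no/flow <= 0.1`, so these
#' models are usually fit to the higher flows only: `min_flow_exclusive =
#' 30` keeps the 50/100/300 ml/s maneuvers of the standard design
#' (subsetting is by protocol target flow).
#'
#' @param data A [subject_dataset].
#' @param formulation `"P"` (FeNO outcome) or `"T"` (NO output outcome).
#' @param min_flow_exclusive Drop maneuvers with target flow at or below
#'   this value (ml/s) before fitting; `NULL` keeps all maneuvers.
#' @return A `feno_fit` with estimates of `ca_no` and `jaw_no`, classical
#'   OLS standard errors, and t-based 95% CIs on `n - 2` degrees of
#'   freedom.
#' @examples
#' truth <- no_params(2, 800, 5, is_truth = TRUE)
#' flows <- rep(c(30, 50, 100, 300), each = 2)
#' d <- subject_dataset("s1", flows, feno_two_compartment(truth, flows))
#' fit_linear(d, "P", min_flow_exclusive = 30)
#' @export
fit_linear <- function(data, formulation = c("P", "T"),
                       min_flow_exclusive = NULL) {
  formulation <- match.arg(formulation)
  data <- subset_flows(data, min_flow_exclusive)
  check_design(data, 2)
  w <- flow_used(data)
  if (formulation == "P") {
    y <- data$feno
    x <- 1 / w
    scale <- "feno"
  } else {
    y <- no_output(data$feno, w)
    x <- w
    scale <- "no_output"
  }
  if (max(x) - min(x) < .Machine$double.eps * max(abs(x)))
    stop("singular fit: no variation in the regressor")
  fit <- stats::lm(y ~ x)
  # noise-free data trip summary.lm's perfect-fit warning; SEs of 0 are fine
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  # P: intercept -> ca, slope -> jaw.  T: slope -> ca, intercept -> jaw.
  idx <- if (formulation == "P") c(1L, 2L) else c(2L, 1L)
  est <- c(ca_no = cf[idx[1], 1], jaw_no = cf[idx[2], 1])
  se <- c(ca_no = cf[idx[1], 2], jaw_no = cf[idx[2], 2])
  df <- fit$df.residual
  new_feno_fit(method = paste0("lin", formulation,
                               if (!is.null(min_flow_exclusive))
                                 paste0(">", min_flow_exclusive) else ""),
               estimates = est, std_errors = se,
               ci95 = ci_matrix(est, se, df),
               n_obs = nrow(data), n_params = 2,
               flows_used = unique(data$target_flow),
               outcome_scale = scale,
               residuals = stats::residuals(fit),
               target_flow = data$target_flow,
               adj_r2 = compute_adj_r2(stats::residuals(fit), y, 2),
               coefficients = stats::coef(fit),
               vcov = suppressWarnings(stats::vcov(fit)),
               df_residual = df)
}

#' Quadratic-approximation estimators (quadP, quadT)
#'
#' Second-order approximation of the two-compartment model, valid down to
#' much lower flows (`daw_no/flow <= 1/3`) and with no small-`ca_no`
#' assumption, fit by ordinary least squares:
#'
#' * `"P"` (quadP): regress FeNO on inverse flow and inverse flow squared.
#' * `"T"` (quadT): regress NO output on flow and inverse flow.
#'
#' All three NO parameters are recovered from the regression coefficients
#' via [recover_params_quadratic()]; their standard errors use the delta
#' method and the CIs a t quantile on `n - 3` degrees of freedom.
#'
#' @inheritParams fit_linear
#' @return A `feno_fit` with estimates of `ca_no`, `jaw_no` and `daw_no`.
#' @export
fit_quadratic <- function(data, formulation = c("P", "T")) {
  formulation <- match.arg(formulation)
  check_design(data, 3)
  w <- flow_used(data)
  if (formulation == "P") {
    y <- data$feno
    fit <- stats::lm(y ~ I(1 / w) + I(1 / w^2))
    scale <- "feno"
  } else {
    y <- no_output(data$feno, w)
    fit <- stats::lm(y ~ w + I(1 / w))
    scale <- "no_output"
  }
  beta <- stats::coef(fit)
  V <- suppressWarnings(stats::vcov(fit))
  rec <- recover_params_quadratic(beta, formulation)
  grads <- quad_param_gradients(beta, formulation)
  se <- vapply(grads, function(g) sqrt(delta_method(g, V)), 0)
  est <- c(ca_no = rec[["ca_no"]], jaw_no = rec[["jaw_no"]],
           daw_no = rec[["daw_no"]])
  df <- fit$df.residual
  new_feno_fit(method = paste0("quad", formulation),
               estimates = est, std_errors = se,
               ci95 = ci_matrix(est, se, df),
               converged = all(is.finite(est)),
               n_obs = nrow(data), n_params = 3,
               flows_used = unique(data$target_flow),
               outcome_scale = scale,
               residuals = stats::residuals(fit),
               target_flow = data$target_flow,
               adj_r2 = compute_adj_r2(stats::residuals(fit), y, 3),
               coefficients = beta, vcov = V, df_residual = df)
}

#' Map quadratic regression coefficients to NO parameters
#'
#' The second-order expansion of the closed-form model gives, on the P
#' scale, mean FeNO `b0 + b1/V + b2/V^2` with `b0 = ca_no`,
#' `b1 = jaw_no - ca_no * daw_no`, `b2 = -b1 * daw_no / 2`; on the T
#' scale, mean NO output `ca_no * V + b1 + b2 / V` with the same `b1`,
#' `b2`. Inverting:
#' `daw_no = -2 b2 / b1`, `jaw_no = b1 + ca_no * daw_no`.
#'
#' @param coefficients Regression coefficients: for `"P"` in the order
#'   (intercept, inverse flow, inverse flow squared); for `"T"` (intercept,
#'   flow, inverse flow), as returned by the quadT least-squares fit.
#' @param formulation `"P"` or `"T"`.
#' @return Named vector `ca_no`, `jaw_no`, `daw_no`. When the leading
#'   coefficient `b1` is exactly zero the quadratic term carries no
#'   information on `daw_no`: if `b2` is also zero the model degenerates
#'   to the linear interpretation (`daw_no = 0`, `jaw_no = b1`); otherwise
#'   `daw_no` is undefined and returned non-finite.
#' @export
recover_params_quadratic <- function(coefficients, formulation = c("P", "T")) {
  formulation <- match.arg(formulation)
  b <- unname(coefficients)
  if (formulation == "P") {
    ca <- b[1]; b1 <- b[2]; b2 <- b[3]
  } else {
    ca <- b[2]; b1 <- b[1]; b2 <- b[3]
  }
  if (b1 == 0) {
    if (!is.na(b2) && b2 == 0)
      return(c(ca_no = ca, jaw_no = b1, daw_no = 0))
    warning("undefined daw_no: leading coefficient is zero")
    return(c(ca_no = ca, jaw_no = NA_real_, daw_no = NA_real_))
  }
  daw <- -2 * b2 / b1
  jaw <- b1 + ca * daw
  c(ca_no = ca, jaw_no = jaw, daw_no = daw)
}

# Gradients of (ca, jaw, daw) w.r.t. the regression coefficients, in the
# coefficient order of the corresponding lm fit.
quad_param_gradients <- function(beta, formulation) {
  b <- unname(beta)
  if (formulation == "P") {
    ca <- b[1]; b1 <- b[2]; b2 <- b[3]
    g_ca <- c(1, 0, 0)
    g_daw <- c(0, 2 * b2 / b1^2, -2 / b1)
    g_jaw <- c(-2 * b2 / b1, 1 + 2 * ca * b2 / b1^2, -2 * ca / b1)
  } else {
    b1 <- b[1]; ca <- b[2]; b2 <- b[3]
    g_ca <- c(0, 1, 0)
    g_daw <- c(2 * b2 / b1^2, 0, -2 / b1)
    g_jaw <- c(1 + 2 * ca * b2 / b1^2, -2 * b2 / b1, -2 * ca / b1)
  }
  list(ca_no = g_ca, jaw_no = g_jaw, daw_no = g_daw)
}

#' Delta-method variance
#'
#' First-order variance of a smooth function of estimated coefficients:
#' `gradient' %*% covariance %*% gradient`.
#'
#' @param gradient Gradient of the function at the estimate.
#' @param covariance Coefficient covariance matrix (same dimension).
#' @return Approximate variance (nonnegative for PSD covariance).
#' @export
delta_method <- function(gradient, covariance) {
  covariance <- as.matrix(covariance)
  if (length(gradient) != nrow(covariance) ||
      nrow(covariance) != ncol(covariance))
    stop("gradient length must match covariance dimension")
  drop(t(gradient) %*% covariance %*% gradient)
}
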