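# Construction and printing of estimator results. A feno_fit stores the
# parameter estimates (only the parameters the method actually estimates),
# their standard errors and t-based 95% CIs, convergence and boundary
# flags, the residuals on the method's own fitting scale, and adjusted R^2.

new_feno_fit <- function(method, estimates, std_errors = NULL, ci95 = NULL,
                         converged = TRUE, at_boundary = FALSE,
                         n_obs = NA_integer_, n_params = NA_integer_,
                         flows_used = numeric(0), outcome_scale = NA_character_,
                         residuals = NULL, target_flow = NULL,
                         adj_r2 = NA_real_, coefficients = NULL,
                         vcov = NULL, df_residual = NA_integer_) {
  structure(list(method = method, estimates = estimates,
                 std_errors = std_errors, ci95 = ci95,
                 converged = converged, at_boundary = at_boundary,
                 n_obs = n_obs, n_params = n_params,
                 flows_used = flows_used, outcome_scale = outcome_scale,
                 residuals = residuals, target_flow = target_flow,
                 adj_r2 = adj_r2, coefficients = coefficients,
                 vcov = vcov, df_residual = df_residual),
            class = "feno_fit")
}

# t-based CI matrix (lower, upper) for a named estimate/SE pair
ci_matrix <- function(estimates, std_errors, df, level = 0.95) {
  tq <- stats::qt(1 - (1 - level) / 2, df)
  ci <- cbind(lower = estimates - tq * std_errors,
              upper = estimates + tq * std_errors)
  rownames(ci) <- names(estimates)
  ci
}

#' @export
print.feno_fit <- function(x, ...) {
  cat(sprintf("<%s fit>  n = %d, flows: %s\n", x$method, x$n_obs,
              paste(sort(unique(x$flows_used)), collapse = "/")))
  if (!x$converged) {
    cat("  did not converge; no estimates\n")
    return(invisible(x))
  }
  tab <- data.frame(estimate = x$estimates,
                    se = if (is.null(x$std_errors)) NA else x$std_errors,
                    lower95 = if (is.null(x$ci95)) NA else x$ci95[, "lower"],
                    upper95 = if (is.null(x$ci95)) NA else x$ci95[, "upper"])
  print(round(tab, 4))
  if (isTRUE(x$at_boundary)) cat("  C_A_NO estimate at the constraint boundary\n")
  if (is.finite(x$adj_r2)) cat(sprintf("  adjusted R^2 = %.4f (%s scale)\n",
                                       x$adj_r2, x$outcome_scale))
  invisible(x)
}

#' Confidence intervals for estimated NO parameters
#'
#' Classical Wald intervals `estimate +/- t(level, n - p) * SE` on the
#' parameter scale, with the Student t quantile on the fit's residual
#' degrees of freedom.
#'
#' @param result A `feno_fit` with finite standard errors.
#' @param level Confidence level (default 0.95).
#' @return Matrix with one row per estimated parameter, columns
#'   `lower`/`upper`.
#' @export
parameter_ci <- function(result, level = 0.95) {
  if (!inherits(result, "feno_fit")) stop("result must be a feno_fit")
  if (!isTRUE(result$converged)) stop("cannot form intervals: fit did not converge")
  if (is.null(result$std_errors)) stop("fit carries no standard errors")
  ci_matrix(result$estimates, result$std_errors, result$df_residual, level)
}

# Adjusted R^2 on the method's own outcome scale; residuals and outcome
# must live on the same scale.
compute_adj_r2 <- function(residuals, outcome, n_params) {
  n <- length(residuals)
  if (n <= n_params + 1) return(NA_real_)
  rss <- sum(residuals^2)
  tss <- sum((outcome - mean(outcome))^2)
  r2 <- 1 - rss / tss
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}
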