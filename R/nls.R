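#' Nonlinear least-squares estimators (nonLin, nonLinLog, nonLinLogC)
#'
#' Direct least-squares estimation of the two-compartment closed form from
#' all maneuvers. On the natural scale (nonLin) the residual sum of
#' squares is on FeNO; on the log scale (nonLinLog) both sides are
#' natural-log transformed, which simultaneously accommodates the right
#' skew of FeNO at a given flow and the decrease of its variance with
#' flow, while keeping the physiologic meaning of the parameters.
#' Supplying `ca_lower_bound` gives the constrained variant (nonLinLogC
#' when `scale = "log"`): `ca_no` is bound-constrained from below, and an
#' estimate landing on the bound is flagged `at_boundary`.
#'
#' Fitting uses Gauss-Newton ([stats::nls()]), falling back to the
#' `"port"` (nl2sol) algorithm when Gauss-Newton fails; bound-constrained
#' fits always use `"port"`. Starting values default to the quadP
#' (natural scale) or quadT (log scale) estimates, replaced by the
#' fallback `(ca = 2, jaw = 800, daw = 10)` when the quadratic start is
#' non-finite or has `daw_no <= 0`. A fit that no algorithm can complete
#' is returned with `converged = FALSE` and no estimates.
#'
#' @param data A [subject_dataset] with at least 3 distinct flows and 4
#'   maneuvers; for `scale = "log"` all FeNO values must be positive.
#' @param scale `"natural"` or `"log"`.
#' @param ca_lower_bound Optional lower bound for `ca_no` (ppb); the
#'   conventional choice 0.1 reflects analyzer detection limits.
#' @param start Optional [no_params] (or named vector) of starting values.
#' @return A `feno_fit` with estimates of all three NO parameters,
#'   asymptotic standard errors from the Jacobian at the solution, t-based
#'   95% CIs on `n - 3` degrees of freedom, residuals on the fitting
#'   scale, and adjusted R^2 on the fitting scale.
#' @examples
#' truth <- no_params(2, 800, 5, is_truth = TRUE)
#' flows <- rep(c(30, 50, 100, 300), each = 2)
#' d <- subject_dataset("s1", flows, feno_two_compartment(truth, flows))
#' fit_nls(d, scale = "log")
#' @export
fit_nls <- function(data, scale = c("natural", "log"),
                    ca_lower_bound = NULL, start = NULL) {
  scale <- match.arg(scale)
  check_design(data, 3)
  w <- flow_used(data)
  feno <- data$feno
  if (scale == "log" && any(feno <= 0))
    stop("log-scale fit requires all FeNO values > 0")

  if (is.null(start)) {
    qstart <- tryCatch(
      fit_quadratic(data, if (scale == "natural") "P" else "T")$estimates,
      error = function(e) NULL)
    start <- if (!is.null(qstart)) {
      c(ca = unname(qstart[["ca_no"]]), jaw = unname(qstart[["jaw_no"]]),
        daw = unname(qstart[["daw_no"]]))
    } else c(ca = NA_real_, jaw = NA_real_, daw = NA_real_)
  } else {
    start <- c(ca = start[["ca_no"]], jaw = start[["jaw_no"]],
               daw = start[["daw_no"]])
  }
  if (!all(is.finite(start)) || start[["daw"]] <= 0)
    start <- c(ca = 2, jaw = 800, daw = 10)
  if (!is.null(ca_lower_bound))
    start[["ca"]] <- max(start[["ca"]], ca_lower_bound)

  df_fit <- data.frame(w = w, y = if (scale == "natural") feno else log(feno))
  form <- if (scale == "natural")
    y ~ jaw / daw + (ca - jaw / daw) * exp(-daw / w)
  else
    y ~ log(jaw / daw + (ca - jaw / daw) * exp(-daw / w))

  fit <- NULL
  if (is.null(ca_lower_bound)) {
    # scaleOffset makes the relative-offset criterion usable on
    # zero-residual (noise-free) data
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(form, data = df_fit, start = as.list(start),
                   control = stats::nls.control(maxiter = 100, tol = 1e-9,
                                                scaleOffset = 1))),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    lower <- if (is.null(ca_lower_bound)) -Inf
             else c(ca = ca_lower_bound, jaw = -Inf, daw = -Inf)
    fit <- tryCatch(
      stats::nls(form, data = df_fit, start = as.list(start),
                 algorithm = "port", lower = lower,
                 control = stats::nls.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      # nl2sol's "false convergence" near an active bound still returns
      # the minimizer to within tolerance; accept it when finite and
      # feasible
      fit <- tryCatch(
        suppressWarnings(
          stats::nls(form, data = df_fit, start = as.list(start),
                     algorithm = "port", lower = lower,
                     control = stats::nls.control(maxiter = 200,
                                                  warnOnly = TRUE))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- stats::coef(fit)
        ok <- all(is.finite(cf)) && all(is.finite(stats::residuals(fit))) &&
          (is.null(ca_lower_bound) || cf[["ca"]] >= ca_lower_bound - 1e-10) &&
          fit$convInfo$stopCode %in% c(7L, 8L)
        if (!ok) fit <- NULL
      }
    }
  }

  method <- switch(scale, natural = "nonLin",
                   log = if (is.null(ca_lower_bound)) "nonLinLog" else "nonLinLogC")
  if (is.null(fit)) {
    return(new_feno_fit(method = method, estimates = NULL, converged = FALSE,
                        n_obs = nrow(data), n_params = 3,
                        flows_used = unique(data$target_flow),
                        outcome_scale = if (scale == "natural") "feno" else "log_feno"))
  }

  cf <- stats::coef(fit)
  est <- c(ca_no = unname(cf[["ca"]]), jaw_no = unname(cf[["jaw"]]),
           daw_no = unname(cf[["daw"]]))
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, 3) else sqrt(pmax(diag(V), 0))
  names(se) <- names(est)
  res <- stats::residuals(fit)
  df <- nrow(data) - 3L
  at_boundary <- !is.null(ca_lower_bound) &&
    abs(est[["ca_no"]] - ca_lower_bound) < 1e-8
  new_feno_fit(method = method, estimates = est, std_errors = se,
               ci95 = ci_matrix(est, se, df),
               converged = TRUE, at_boundary = at_boundary,
               n_obs = nrow(data), n_params = 3,
               flows_used = unique(data$target_flow),
               outcome_scale = if (scale == "natural") "feno" else "log_feno",
               residuals = as.numeric(res), target_flow = data$target_flow,
               adj_r2 = compute_adj_r2(as.numeric(res), df_fit$y, 3),
               coefficients = cf, vcov = V, df_residual = df)
}
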