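#' Estimation method registry
#'
#' The estimation methods are addressed by the labels conventional in the
#' multiple-flow FeNO literature: `"linP"`, `"linT"`, `"linP>30"`,
#' `"linT>30"`, `"quadP"`, `"quadT"`, `"nonLin"`, `"nonLinLog"`,
#' `"nonLinLogC"`, `"HMA"`, `"HMA+criteria"`, `"condorelli"`, `"kerckx"`.
#'
#' @return Character vector of the registered method labels.
#' @export
feno_methods <- function() {
  c("linP", "linT", "linP>30", "linT>30", "quadP", "quadT",
    "nonLin", "nonLinLog", "nonLinLogC", "HMA", "HMA+criteria",
    "condorelli", "kerckx")
}

#' Fit one estimation method to one subject dataset
#'
#' Dispatches a registered method label to the corresponding fitting
#' function ([fit_linear()], [fit_quadratic()], [fit_nls()],
#' [fit_hma_dataset()], [fit_condorelli()], [fit_kerckx()]).
#'
#' @param data A [subject_dataset].
#' @param method A label from [feno_methods()].
#' @param hma_flows Low/medium/high flows for the HMA methods.
#' @return A `feno_fit`, `hma_fit` or `refined_fit`.
#' @export
fit_method <- function(data, method, hma_flows = c(30, 100, 300)) {
  switch(method,
    "linP" = fit_linear(data, "P"),
    "linT" = fit_linear(data, "T"),
    "linP>30" = fit_linear(data, "P", min_flow_exclusive = 30),
    "linT>30" = fit_linear(data, "T", min_flow_exclusive = 30),
    "quadP" = fit_quadratic(data, "P"),
    "quadT" = fit_quadratic(data, "T"),
    "nonLin" = fit_nls(data, scale = "natural"),
    "nonLinLog" = fit_nls(data, scale = "log"),
    "nonLinLogC" = fit_nls(data, scale = "log", ca_lower_bound = 0.1),
    "HMA" = fit_hma_dataset(data, flows = hma_flows),
    "HMA+criteria" = fit_hma_dataset(data, flows = hma_flows,
                                     impose_consistency = TRUE,
                                     impose_nonnegative_ca = TRUE),
    "condorelli" = fit_condorelli(data),
    "kerckx" = fit_kerckx(data),
    stop("unknown method: ", method)
  )
}

# Uniform extraction of the (ca, jaw, daw) estimates, or NAs when the
# method produced none / does not estimate the parameter.
extract_estimates <- function(fit) {
  out <- c(ca_no = NA_real_, jaw_no = NA_real_, daw_no = NA_real_)
  if (inherits(fit, "feno_fit")) {
    if (isTRUE(fit$converged))
      out[names(fit$estimates)] <- fit$estimates
  } else if (inherits(fit, "hma_fit")) {
    if (isTRUE(fit$converged) && isTRUE(fit$available))
      out[] <- c(fit$ca_no, fit$jaw_no, fit$daw_no)
  } else if (inherits(fit, "refined_fit")) {
    if (isTRUE(fit$available)) {
      out["ca_no"] <- fit$ca_no
      if (!is.null(fit$jaw_no)) out["jaw_no"] <- fit$jaw_no
    }
  }
  out
}

# 95% CI bounds per parameter as a 3x2 matrix (NA where no interval
# exists: linear methods for daw, HMA and refined methods throughout).
extract_ci <- function(fit) {
  out <- matrix(NA_real_, 3, 2,
                dimnames = list(c("ca_no", "jaw_no", "daw_no"),
                                c("lower", "upper")))
  if (inherits(fit, "feno_fit") && isTRUE(fit$converged) &&
      !is.null(fit$ci95))
    out[rownames(fit$ci95), ] <- fit$ci95
  out
}
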