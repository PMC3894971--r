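#' Two-compartment model for exhaled NO
#'
#' Closed-form solution of the two-compartment model of NO exchange in the
#' lower respiratory tract: at a constant exhalation flow `flow` (ml/s),
#'
#' \deqn{FeNO(V) = C_{aw} + (C_A - C_{aw}) e^{-D_{aw}/V},
#'       \quad C_{aw} = J'_{aw}/D_{aw}}
#'
#' FeNO tends to the airway wall concentration `caw_no` as flow goes to
#' zero and to the alveolar concentration `ca_no` as flow grows; whenever
#' `caw_no > ca_no` the curve is strictly decreasing in flow.
#'
#' @param params An [no_params] object.
#' @param flow Exhalation flow rate(s), ml/s; must be positive.
#' @return Model-predicted FeNO in ppb, one value per flow.
#' @examples
#' truth <- no_params(2, 800, 5, is_truth = TRUE)
#' feno_two_compartment(truth, c(30, 50, 100, 300))
#' @export
feno_two_compartment <- function(params, flow) {
  p <- as_no_params(params)
  if (any(!is.finite(flow)) || any(flow <= 0))
    stop("flow must be positive and finite")
  if (p[["daw_no"]] == 0)
    stop("degenerate model: daw_no = 0")
  caw <- p[["jaw_no"]] / p[["daw_no"]]
  caw + (p[["ca_no"]] - caw) * exp(-p[["daw_no"]] / flow)
}

#' NO output
#'
#' The elimination rate of NO, `feno * flow`. With FeNO in ppb (1 pl NO per
#' ml of air) and flow in ml/s the product is in pl/s. Regressions with NO
#' output as the outcome are the "T" (Tsoukias) formulation.
#'
#' @param feno FeNO in ppb.
#' @param flow Exhalation flow in ml/s; must be positive.
#' @return NO output in pl/s.
#' @export
no_output <- function(feno, flow) {
  if (any(!is.finite(flow)) || any(flow <= 0))
    stop("flow must be positive and finite")
  feno * flow
}

#' Validity of low-order approximations to the two-compartment model
#'
#' The linear (first-order) approximation to the exponential is adequate
#' when `daw_no / flow <= 0.1`; the quadratic (second-order) approximation
#' when `daw_no / flow <= 0.33`. For example, with `daw_no = 5` the linear
#' approximation holds for flows of at least 50 ml/s and the quadratic one
#' down to about 15 ml/s.
#'
#' @param params An [no_params] object (only `daw_no` is used).
#' @param flow Exhalation flow in ml/s.
#' @param order Approximation order, 1 (linear) or 2 (quadratic).
#' @return A list with `ratio` (`daw_no/flow`) and `valid` (logical).
#' @export
approximation_validity <- function(params, flow, order = 1) {
  p <- as_no_params(params)
  if (any(!is.finite(flow)) || any(flow <= 0))
    stop("flow must be positive and finite")
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  ratio <- p[["daw_no"]] / flow
  threshold <- if (order == 1) 0.1 else 1 / 3
  list(ratio = ratio, valid = ratio <= threshold)
}
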