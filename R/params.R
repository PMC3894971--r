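#' NO parameter triple
#'
#' Container for the three physiologic parameters of the two-compartment
#' model of NO exchange: the alveolar NO concentration `ca_no` (ppb), the
#' maximum airway NO flux `jaw_no` (pl/s), and the airway tissue diffusing
#' capacity `daw_no` (pl.s^-1.ppb^-1). Units are fixed package-wide
#' (flow in ml/s, FeNO in ppb) and no unit conversion is performed.
#'
#' When `is_truth = TRUE` the triple is validated as a simulation truth
#' (`daw_no > 0`, `jaw_no >= 0`, `ca_no >= 0`). Estimates are allowed to
#' violate nonnegativity: unconstrained estimators can and do return
#' negative alveolar concentrations, and those values are kept.
#'
#' @param ca_no Alveolar NO concentration, ppb.
#' @param jaw_no Maximum airway NO flux, pl/s.
#' @param daw_no Airway tissue diffusing capacity, pl.s^-1.ppb^-1.
#' @param is_truth Validate as simulation truth (enforce nonnegativity)?
#' @return An object of class `no_params`: a named numeric vector with
#'   elements `ca_no`, `jaw_no`, `daw_no` and attribute `is_truth`.
#' @examples
#' truth <- no_params(ca_no = 2, jaw_no = 800, daw_no = 5, is_truth = TRUE)
#' caw_no(truth)  # airway wall concentration, 160 ppb
#' @export
no_params <- function(ca_no, jaw_no, daw_no, is_truth = FALSE) {
  stopifnot(length(ca_no) == 1, length(jaw_no) == 1, length(daw_no) == 1)
  x <- c(ca_no = as.numeric(ca_no), jaw_no = as.numeric(jaw_no),
         daw_no = as.numeric(daw_no))
  if (is_truth) {
    if (!is.finite(x["daw_no"]) || x["daw_no"] <= 0)
      stop("simulation truth requires daw_no > 0")
    if (is.na(x["jaw_no"]) || x["jaw_no"] < 0)
      stop("simulation truth requires jaw_no >= 0")
    if (is.na(x["ca_no"]) || x["ca_no"] < 0)
      stop("simulation truth requires ca_no >= 0")
  }
  structure(x, is_truth = is_truth, class = "no_params")
}

#' Airway wall NO concentration
#'
#' The derived fourth parameter `caw_no = jaw_no / daw_no` (ppb), the
#' low-flow limit of FeNO. Only defined for `daw_no != 0`.
#'
#' @param params An [no_params] object (or named vector with `jaw_no`,
#'   `daw_no`).
#' @return Airway wall concentration in ppb.
#' @export
caw_no <- function(params) {
  if (params[["daw_no"]] == 0)
    stop("caw_no is undefined for daw_no = 0")
  unname(params[["jaw_no"]] / params[["daw_no"]])
}

#' @export
print.no_params <- function(x, ...) {
  kind <- if (isTRUE(attr(x, "is_truth"))) "truth" else "estimate"
  cat(sprintf("NO parameters (%s):\n", kind))
  cat(sprintf("  C_A_NO  = %g ppb\n", x[["ca_no"]]))
  cat(sprintf("  J'aw_NO = %g pl/s\n", x[["jaw_no"]]))
  cat(sprintf("  D_aw_NO = %g pl.s^-1.ppb^-1\n", x[["daw_no"]]))
  if (is.finite(x[["daw_no"]]) && x[["daw_no"]] != 0)
    cat(sprintf("  C_aw_NO = %g ppb (derived)\n", caw_no(x)))
  invisible(x)
}

as_no_params <- function(x) {
  if (inherits(x, "no_params")) return(x)
  no_params(x[["ca_no"]], x[["jaw_no"]], x[["daw_no"]])
}
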