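#' Multiple-flow FeNO data for one subject
#'
#' A subject's collection of exhalation maneuvers. Each maneuver is one
#' constant-flow exhalation yielding a single plateau FeNO reading (ppb)
#' at one target flow (ml/s), optionally with the flow actually achieved
#' during the plateau. Model fitting uses the achieved flow where present
#' and the target flow otherwise; flow-subset rules (e.g. "flows above
#' 30 ml/s") are always applied to the protocol target flow.
#'
#' @param subject_id Subject identifier (scalar).
#' @param target_flow Target flow per maneuver, ml/s (positive).
#' @param feno Measured FeNO per maneuver, ppb.
#' @param achieved_flow Optional achieved flow per maneuver, ml/s.
#' @return A `subject_dataset`: a data frame with columns `subject_id`,
#'   `maneuver_index`, `target_flow`, `achieved_flow`, `feno`, in maneuver
#'   order.
#' @examples
#' d <- subject_dataset("s1", rep(c(30, 50, 100, 300), each = 2),
#'                      c(27, 25, 17.2, 16.8, 9.9, 9.6, 4.7, 4.5))
#' @export
subject_dataset <- function(subject_id, target_flow, feno,
                            achieved_flow = NULL) {
  stopifnot(length(subject_id) == 1)
  n <- length(target_flow)
  if (length(feno) != n)
    stop("target_flow and feno must have the same length")
  if (any(!is.finite(target_flow)) || any(target_flow <= 0))
    stop("target_flow must be positive and finite")
  if (is.null(achieved_flow)) {
    achieved_flow <- rep(NA_real_, n)
  } else {
    if (length(achieved_flow) != n)
      stop("achieved_flow must match the number of maneuvers")
    if (any(!is.na(achieved_flow) & achieved_flow <= 0))
      stop("achieved_flow must be positive where present")
  }
  d <- data.frame(subject_id = as.character(subject_id),
                  maneuver_index = seq_len(n),
                  target_flow = as.numeric(target_flow),
                  achieved_flow = as.numeric(achieved_flow),
                  feno = as.numeric(feno),
                  stringsAsFactors = FALSE)
  class(d) <- c("subject_dataset", "data.frame")
  d
}

#' Flow values used in model evaluation and fitting
#'
#' Achieved flow where recorded, otherwise the target flow.
#'
#' @param data A [subject_dataset].
#' @return Numeric vector of flows, ml/s.
#' @export
flow_used <- function(data) {
  ifelse(is.na(data$achieved_flow), data$target_flow, data$achieved_flow)
}

# Design checks shared by the fitting functions. p = 3 fits need >= 3
# distinct flows and n >= 4; p = 2 linear fits need >= 2 distinct flows
# and n >= 3.
check_design <- function(data, n_params) {
  n <- nrow(data)
  k <- length(unique(data$target_flow))
  if (n_params >= 3 && (k < 3 || n < 4))
    stop("insufficient design: a 3-parameter fit needs >= 3 distinct flows and >= 4 maneuvers")
  if (n_params == 2 && (k < 2 || n < 3))
    stop("insufficient design: a 2-parameter fit needs >= 2 distinct flows and >= 3 maneuvers")
  invisible(TRUE)
}

subset_flows <- function(data, min_flow_exclusive) {
  if (is.null(min_flow_exclusive)) return(data)
  out <- data[data$target_flow > min_flow_exclusive, , drop = FALSE]
  class(out) <- class(data)
  out
}
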