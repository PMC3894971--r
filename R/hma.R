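#' Mean FeNO by target flow
#'
#' Arithmetic mean of the observed FeNO values at each target flow, the
#' input format of the three-flow iterative algorithm ([fit_hma()]).
#'
#' @param data A [subject_dataset].
#' @return Named numeric vector of mean FeNO (ppb), names the target
#'   flows, in increasing flow order.
#' @export
mean_feno_by_target_flow <- function(data) {
  m <- tapply(data$feno, data$target_flow, mean)
  flows <- as.numeric(names(m))
  out <- as.numeric(m)[order(flows)]
  names(out) <- sort(flows)
  out
}

#' Hogman-Merilainen algorithm (HMA)
#'
#' Iterative three-flow estimator built on a third-order approximation of
#' the T formulation (NO output scale) of the two-compartment model.
#' Writing `g(V) = V * FeNO(V)` and `f(d, V) = 1 - d/(2V) + d^2/(6V^2)`,
#' the third-order model is
#' `g(V) = ca * V + (jaw - ca * d) * f(d, V)`.
#'
#' Starting from a linT fit to the medium and high flow means (slope =
#' `ca_no`, intercept = `jaw_no`, i.e. `d = 0`), each iteration (i) solves
#' the cubic low-flow equation for `daw_no`, tracking the root nearest
#' the previous iterate (first pass: the smallest positive root), with a
#' damping factor of 0.5 on the update, and (ii) re-solves the two
#' medium/high equations exactly for `ca_no` and `jaw_no` given the new
#' `daw_no`. Iteration stops when `daw_no` changes by less than `tol`.
#' Datasets for which the iteration has no stable fixed point (divergence
#' or no real root) are returned with `converged = FALSE` and no
#' estimates.
#'
#' The standard implementation additionally screens results through two
#' criteria: an internal data consistency check (the converged solution
#' must have `daw_no > 0` with an airway wall concentration above the
#' observed low-flow plateau, so that `caw_no` is reasonably estimable)
#' and nonnegativity of `ca_no`. Both are reported but by default not
#' imposed, since imposing them discards datasets informatively and
#' biases the retained estimates; with `impose_consistency` or
#' `impose_nonnegative_ca` set, a result failing the corresponding check
#' is returned as missing (`available = FALSE`), not as an error.
#'
#' No fit statistics or standard errors are produced: the algorithm has
#' no explicit regression form, so measures of fit and of uncertainty are
#' deliberately absent from the result.
#'
#' @param means Mean FeNO (ppb) at the low, medium and high target flows,
#'   in that order (see [mean_feno_by_target_flow()]).
#' @param flows The three target flows, ml/s, increasing; default
#'   `c(30, 100, 300)`.
#' @param impose_consistency Drop results failing the consistency check?
#' @param impose_nonnegative_ca Drop results with `ca_no < 0`?
#' @param tol Convergence tolerance on `daw_no` (default 1e-6).
#' @param maxit Maximum iterations (default 200).
#' @return An `hma_fit` list: `ca_no`, `jaw_no`, `daw_no`, `caw_no`,
#'   `consistent`, `ca_nonnegative`, `converged`, `available`,
#'   `iterations`.
#' @examples
#' truth <- no_params(2, 800, 5, is_truth = TRUE)
#' m <- feno_two_compartment(truth, c(30, 100, 300))
#' fit_hma(m)
#' @export
fit_hma <- function(means, flows = c(30, 100, 300),
                    impose_consistency = FALSE,
                    impose_nonnegative_ca = FALSE,
                    tol = 1e-6, maxit = 200) {
  if (length(means) != 3 || length(flows) != 3)
    stop("fit_hma needs FeNO means and flows at exactly 3 flow levels")
  if (any(!is.finite(means))) stop("FeNO means must be finite")
  if (is.unsorted(flows, strictly = TRUE))
    stop("flows must be strictly increasing (low, medium, high)")

  Vl <- flows[1]
  gl <- means[1] * Vl
  V <- flows[2:3]
  g <- means[2:3] * V
  f3 <- function(d, v) 1 - d / (2 * v) + d^2 / (6 * v^2)

  failed <- function(it) {
    structure(list(ca_no = NA_real_, jaw_no = NA_real_, daw_no = NA_real_,
                   caw_no = NA_real_, consistent = NA, ca_nonnegative = NA,
                   converged = FALSE, available = FALSE, iterations = it),
              class = "hma_fit")
  }

  # linT start on the medium/high means: slope -> ca, intercept -> jaw
  ca <- (g[2] - g[1]) / (V[2] - V[1])
  jaw <- g[1] - ca * V[1]
  d <- 0
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    # third-order low-flow equation as a cubic in daw:
    # gl = ca*Vl + (jaw - ca*d) * f3(d, Vl)
    cub <- polyroot(c(ca * Vl + jaw - gl,
                      -(jaw / (2 * Vl) + ca),
                      jaw / (6 * Vl^2) + ca / (2 * Vl),
                      -ca / (6 * Vl^2)))
    cub <- Re(cub[abs(Im(cub)) < 1e-8 * (1 + abs(cub))])
    if (!length(cub)) return(failed(it))
    dn <- if (it == 1L) {
      pos <- cub[cub > 0]
      if (length(pos)) min(pos) else cub[which.min(abs(cub))]
    } else cub[which.min(abs(cub - d))]
    if (it > 1L) dn <- d + 0.5 * (dn - d)   # damped update
    if (!is.finite(dn) || abs(dn) > 1e4) return(failed(it))
    fV <- f3(dn, V)
    sol <- tryCatch(solve(cbind(V - dn * fV, fV), g),
                    error = function(e) NULL)
    if (is.null(sol)) return(failed(it))
    ca <- sol[1]
    jaw <- sol[2]
    if (abs(dn - d) < tol) {
      d <- dn
      converged <- TRUE
      break
    }
    d <- dn
  }
  if (!converged) return(failed(it))

  caw <- if (d != 0) jaw / d else NA_real_
  consistent <- is.finite(d) && d > 0 && is.finite(caw) && caw > means[1]
  ca_nonneg <- is.finite(ca) && ca >= 0
  available <- !(impose_consistency && !consistent) &&
    !(impose_nonnegative_ca && !ca_nonneg)
  out <- list(ca_no = unname(ca), jaw_no = unname(jaw), daw_no = unname(d),
              caw_no = unname(caw), consistent = consistent,
              ca_nonnegative = ca_nonneg, converged = TRUE,
              available = available, iterations = it)
  if (!available) {
    out$ca_no <- NA_real_
    out$jaw_no <- NA_real_
    out$daw_no <- NA_real_
    out$caw_no <- NA_real_
  }
  structure(out, class = "hma_fit")
}

#' @export
print.hma_fit <- function(x, ...) {
  cat("<HMA fit>\n")
  if (!x$converged) {
    cat("  iteration did not converge; no estimates\n")
    return(invisible(x))
  }
  if (!x$available) {
    cat("  result withheld by the imposed screening criteria\n")
    return(invisible(x))
  }
  cat(sprintf("  C_A_NO  = %.3f ppb\n", x$ca_no))
  cat(sprintf("  J'aw_NO = %.1f pl/s\n", x$jaw_no))
  cat(sprintf("  D_aw_NO = %.3f pl.s^-1.ppb^-1\n", x$daw_no))
  cat(sprintf("  C_aw_NO = %.1f ppb\n", x$caw_no))
  cat(sprintf("  consistent: %s, ca_no >= 0: %s (%d iterations)\n",
              x$consistent, x$ca_nonnegative, x$iterations))
  invisible(x)
}

#' HMA from a subject dataset
#'
#' Convenience wrapper: computes mean FeNO at the three `flows` via
#' [mean_feno_by_target_flow()] and runs [fit_hma()]. All three flow
#' levels must be present in the data.
#'
#' @inheritParams fit_hma
#' @param data A [subject_dataset].
#' @param ... Passed on to [fit_hma()].
#' @export
fit_hma_dataset <- function(data, flows = c(30, 100, 300), ...) {
  m <- mean_feno_by_target_flow(data)
  if (!all(as.character(flows) %in% names(m)))
    stop("dataset lacks maneuvers at one of the required target flows: ",
         paste(flows, collapse = "/"))
  fit_hma(unname(m[as.character(flows)]), flows = flows, ...)
}
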