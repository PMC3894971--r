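#' Read maneuver-level multiple-flow FeNO data
#'
#' Reads a delimited text file with one row per exhalation maneuver and
#' header columns `subject_id`, `maneuver_index`, `target_flow_ml_s`,
#' `achieved_flow_ml_s` (optional), `feno_ppb`. Extra columns are ignored
#' with a warning; rows with missing FeNO or non-numeric fields raise an
#' error naming the offending line.
#'
#' @param path Path to a CSV file (UTF-8, decimal point).
#' @return Named list of [subject_dataset]s, grouped by `subject_id`,
#'   file order preserved within subject.
#' @export
read_maneuvers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) stop("empty maneuver file: ", path)
  required <- c("subject_id", "target_flow_ml_s", "feno_ppb")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  known <- c(required, "maneuver_index", "achieved_flow_ml_s")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))

  num_field <- function(col, allow_na = FALSE) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !(allow_na & (is.na(x) | x == "")))
    if (length(bad))
      stop(sprintf("malformed %s at line %d of %s", col, bad[1] + 1, path))
    out
  }
  target <- num_field("target_flow_ml_s")
  feno <- num_field("feno_ppb")
  achieved <- if ("achieved_flow_ml_s" %in% names(raw))
    num_field("achieved_flow_ml_s", allow_na = TRUE) else rep(NA_real_, nrow(raw))
  if (any(target <= 0))
    stop(sprintf("nonpositive target flow at line %d of %s",
                 which(target <= 0)[1] + 1, path))
  ids <- raw$subject_id
  out <- lapply(unique(ids), function(id) {
    k <- which(ids == id)
    subject_dataset(id, target[k], feno[k],
                    achieved_flow = if (all(is.na(achieved[k]))) NULL
                                    else achieved[k])
  })
  names(out) <- unique(ids)
  out
}

#' Write maneuver-level data
#'
#' Inverse of [read_maneuvers()]: writes a list of [subject_dataset]s (or
#' a single one) to the maneuver CSV schema.
#'
#' @param datasets A [subject_dataset] or list of them.
#' @param path Output CSV path.
#' @export
write_maneuvers <- function(datasets, path) {
  if (inherits(datasets, "subject_dataset")) datasets <- list(datasets)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  rows <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(subject_id = d$subject_id, maneuver_index = d$maneuver_index,
               target_flow_ml_s = fmt(d$target_flow),
               achieved_flow_ml_s = fmt(d$achieved_flow),
               feno_ppb = fmt(d$feno), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write estimator results
#'
#' One row per subject and method with a fixed column order:
#' `subject_id`, `method`, per-parameter estimate/SE/CI bounds (empty
#' where the method produces none), `converged`, `at_boundary`,
#' `n_maneuvers`, `flows_used`, `adj_r2`. HMA and refined methods carry
#' no SEs, CIs or fit statistics, so those cells are empty.
#'
#' @param results Named or unnamed list of fit objects (`feno_fit`,
#'   `hma_fit`, `refined_fit`); names (or each fit's stored data) give
#'   the subject ids via the `subject_id` attribute if set.
#' @param path Output CSV path.
#' @param subject_ids Optional character vector of subject ids, parallel
#'   to `results` (defaults to the list names, else `"s1"`, `"s2"`, ...).
#' @export
write_results <- function(results, path, subject_ids = NULL) {
  if (!length(results)) stop("no results to write")
  if (inherits(results, c("feno_fit", "hma_fit", "refined_fit")))
    results <- list(results)
  if (is.null(subject_ids)) {
    subject_ids <- names(results)
    if (is.null(subject_ids))
      subject_ids <- sprintf("s%d", seq_along(results))
  }
  rows <- vector("list", length(results))
  for (i in seq_along(results)) {
    f <- results[[i]]
    est <- extract_estimates(f)
    ci <- extract_ci(f)
    se <- c(ca_no = NA_real_, jaw_no = NA_real_, daw_no = NA_real_)
    if (inherits(f, "feno_fit") && isTRUE(f$converged) &&
        !is.null(f$std_errors))
      se[names(f$std_errors)] <- f$std_errors
    method <- if (inherits(f, "feno_fit")) f$method
              else if (inherits(f, "hma_fit")) "HMA" else f$method
    rows[[i]] <- data.frame(
      subject_id = subject_ids[i], method = method,
      ca_no = est["ca_no"], ca_no_se = se["ca_no"],
      ca_no_lo = ci["ca_no", 1], ca_no_hi = ci["ca_no", 2],
      jaw_no = est["jaw_no"], jaw_no_se = se["jaw_no"],
      jaw_no_lo = ci["jaw_no", 1], jaw_no_hi = ci["jaw_no", 2],
      daw_no = est["daw_no"], daw_no_se = se["daw_no"],
      daw_no_lo = ci["daw_no", 1], daw_no_hi = ci["daw_no", 2],
      converged = isTRUE(f$converged) ||
        (inherits(f, "refined_fit") && isTRUE(f$available)),
      at_boundary = isTRUE(f$at_boundary),
      n_maneuvers = if (!is.null(f$n_obs)) f$n_obs else NA_integer_,
      flows_used = if (!is.null(f$flows_used) && length(f$flows_used))
        paste(sort(f$flows_used), collapse = "/") else "",
      adj_r2 = if (inherits(f, "feno_fit")) f$adj_r2 else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
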