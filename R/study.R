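#' Monte Carlo comparison of NO-parameter estimators
#'
#' Simulates `scenario$n_datasets` datasets, applies every requested
#' estimation method to each, and summarizes per method and parameter:
#' empirical bias (mean of estimate minus truth, with a 95% CI of the
#' mean and its Monte Carlo standard error) and, for methods that carry
#' confidence intervals, the coverage of the nominal 95% CI (the
#' proportion of datasets whose interval contains the truth). Datasets
#' where a method fails to converge (or, for screened methods, withholds
#' a result) are excluded from that method's summaries, with counts
#' reported. Linear methods contribute no `daw_no` rows; HMA and the
#' refined methods appear in the bias table only.
#'
#' @param scenario A `feno_scenario` (see [make_scenario()]).
#' @param methods Method labels from [feno_methods()].
#' @param keep_estimates Keep the per-dataset estimates (needed for
#'   [spearman_matrix()] and residual diagnostics)? Default `TRUE`.
#' @return A `feno_study` list: `bias` and `coverage` data frames,
#'   `n_unavailable` (named count of excluded datasets per method),
#'   `estimates` (list of per-method n x 3 matrices, if kept), and the
#'   scenario.
#' @examples
#' sc <- make_scenario("main", n_datasets = 50, seed = 7)
#' st <- run_study(sc, c("linP", "quadT"))
#' st$bias
#' @export
run_study <- function(scenario, methods = feno_methods(),
                      keep_estimates = TRUE) {
  if (!length(methods)) stop("empty method list")
  bad <- setdiff(methods, feno_methods())
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "))
  hma_flows <- scenario$flow_levels[c(1, length(scenario$flow_levels) - 1,
                                      length(scenario$flow_levels))]
  n <- scenario$n_datasets
  params <- c("ca_no", "jaw_no", "daw_no")
  est <- lapply(methods, function(m) matrix(NA_real_, n, 3,
                                            dimnames = list(NULL, params)))
  names(est) <- methods
  cover <- lapply(methods, function(m) {
    list(lower = matrix(NA_real_, n, 3, dimnames = list(NULL, params)),
         upper = matrix(NA_real_, n, 3, dimnames = list(NULL, params)))
  })
  names(cover) <- methods

  streams <- rng_streams(scenario$seed, n)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  for (i in seq_len(n)) {
    assign(".Random.seed", streams[[i]], envir = globalenv())
    d <- draw_dataset(scenario, sprintf("sim%05d", i))
    for (m in methods) {
      fit <- tryCatch(fit_method(d, m, hma_flows = hma_flows),
                      error = function(e) NULL)
      if (is.null(fit)) next
      est[[m]][i, ] <- extract_estimates(fit)
      ci <- extract_ci(fit)
      cover[[m]]$lower[i, ] <- ci[, "lower"]
      cover[[m]]$upper[i, ] <- ci[, "upper"]
    }
  }

  truth <- scenario$truth
  bias_rows <- list()
  cov_rows <- list()
  n_unavail <- integer(0)
  for (m in methods) {
    em <- est[[m]]
    avail <- rowSums(!is.na(em)) > 0
    n_unavail[m] <- sum(!avail)
    for (p in params) {
      x <- em[, p]
      x <- x[!is.na(x)]
      if (!length(x)) next
      bs <- bias_summary(x, truth[[p]])
      bias_rows[[length(bias_rows) + 1]] <-
        data.frame(method = m, parameter = p, mean_bias = bs$mean_bias,
                   ci_lower = bs$ci95_of_mean[1],
                   ci_upper = bs$ci95_of_mean[2],
                   mc_se = bs$mc_se, n_used = bs$n_used,
                   stringsAsFactors = FALSE)
      lo <- cover[[m]]$lower[, p]
      hi <- cover[[m]]$upper[, p]
      ok <- !is.na(lo) & !is.na(hi)
      if (any(ok)) {
        cs <- coverage_summary(cbind(lo[ok], hi[ok]), truth[[p]])
        cov_rows[[length(cov_rows) + 1]] <-
          data.frame(method = m, parameter = p, coverage = cs$coverage,
                     mc_se = cs$mc_se, n_used = cs$n_used,
                     stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(bias = do.call(rbind, bias_rows),
                 coverage = do.call(rbind, cov_rows),
                 n_unavailable = n_unavail,
                 estimates = if (keep_estimates) est else NULL,
                 scenario = scenario),
            class = "feno_study")
}

#' @export
print.feno_study <- function(x, ...) {
  cat(sprintf("<feno_study '%s', %d datasets>\n", x$scenario$name,
              x$scenario$n_datasets))
  cat("Bias (estimate - truth):\n")
  b <- x$bias
  b$mean_bias <- signif(b$mean_bias, 3)
  b$ci_lower <- signif(b$ci_lower, 3)
  b$ci_upper <- signif(b$ci_upper, 3)
  b$mc_se <- signif(b$mc_se, 2)
  print(b, row.names = FALSE)
  if (!is.null(x$coverage)) {
    cat("95% CI coverage:\n")
    cv <- x$coverage
    cv$coverage <- round(cv$coverage, 3)
    cv$mc_se <- signif(cv$mc_se, 2)
    print(cv, row.names = FALSE)
  }
  if (any(x$n_unavailable > 0)) {
    cat("Datasets without estimates:\n")
    print(x$n_unavailable[x$n_unavailable > 0])
  }
  invisible(x)
}

#' Empirical bias of a set of estimates
#'
#' Mean of (estimate minus truth), with the Monte Carlo standard error
#' (sample SD over the square root of the number of estimates) and a
#' normal-theory 95% CI of the mean (multiplier 1.96).
#'
#' @param estimates Numeric vector of estimates (NAs dropped).
#' @param truth True parameter value.
#' @return List: `mean_bias`, `ci95_of_mean` (length 2), `mc_se`,
#'   `n_used`.
#' @export
bias_summary <- function(estimates, truth) {
  estimates <- estimates[!is.na(estimates)]
  if (!length(estimates)) stop("no estimates supplied")
  b <- estimates - truth
  m <- mean(b)
  se <- if (length(b) > 1) stats::sd(b) / sqrt(length(b)) else 0
  list(mean_bias = m, ci95_of_mean = c(m - 1.96 * se, m + 1.96 * se),
       mc_se = se, n_used = length(b))
}

#' Coverage of nominal confidence intervals
#'
#' Fraction of closed intervals containing the truth (an endpoint hit
#' counts as covered), with the binomial Monte Carlo standard error.
#'
#' @param intervals Two-column matrix (lower, upper), one row per
#'   interval.
#' @param truth True parameter value.
#' @return List: `coverage`, `mc_se`, `n_used`.
#' @export
coverage_summary <- function(intervals, truth) {
  intervals <- as.matrix(intervals)
  if (!nrow(intervals)) stop("no intervals supplied")
  hit <- intervals[, 1] <= truth & truth <= intervals[, 2]
  p <- mean(hit)
  list(coverage = p, mc_se = sqrt(p * (1 - p) / length(hit)),
       n_used = length(hit))
}

#' Adjusted R-squared of a fit on its own outcome scale
#'
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)`, with R^2 computed on the
#' method's fitting scale (FeNO for P-formulation and nonLin, NO output
#' for T-formulation, log FeNO for nonLinLog). Adjusting for the number
#' of estimated parameters makes fits with different parameter counts
#' comparable.
#'
#' @param fit A `feno_fit`.
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(fit) {
  if (!inherits(fit, "feno_fit")) stop("fit must be a feno_fit")
  if (is.null(fit$residuals)) stop("fit carries no residuals")
  if (fit$n_obs <= fit$n_params + 1)
    stop("degenerate degrees of freedom for adjusted R^2")
  fit$adj_r2
}

#' Pooled standardized residual SD by target flow
#'
#' Within each fit the residuals are standardized by that fit's residual
#' SD (so subjects are comparable); the standardized residuals are then
#' pooled across fits and their SD computed per target flow. Under
#' homoscedasticity on the fitting scale the per-flow SDs are
#' approximately equal (about 1).
#'
#' @param fits List of `feno_fit`s with residuals and target-flow labels.
#' @return Named numeric vector: SD of pooled standardized residuals per
#'   target flow. Fits without residuals are skipped with a warning.
#' @export
pooled_standardized_residual_sd <- function(fits) {
  res <- list(); fl <- list()
  skipped <- 0
  for (f in fits) {
    if (!inherits(f, "feno_fit") || is.null(f$residuals) ||
        !isTRUE(f$converged)) {
      skipped <- skipped + 1
      next
    }
    s <- stats::sd(f$residuals)
    if (!is.finite(s) || s == 0) {
      skipped <- skipped + 1
      next
    }
    res[[length(res) + 1]] <- f$residuals / s
    fl[[length(fl) + 1]] <- f$target_flow
  }
  if (skipped) warning(skipped, " fit(s) without usable residuals skipped")
  if (!length(res)) stop("no fits with residuals")
  r <- unlist(res); v <- unlist(fl)
  out <- tapply(r, v, stats::sd)
  flows <- as.numeric(names(out))
  res_sd <- as.numeric(out)[order(flows)]
  names(res_sd) <- sort(flows)
  res_sd
}

#' Shapiro-Wilk rejection rate across fits
#'
#' Proportion of fits whose residuals reject the normality null at level
#' `alpha`. Under correctly specified normal errors the rate is close to
#' `alpha` (the type-I error rate).
#'
#' @param fits List of `feno_fit`s.
#' @param alpha Test level (default 0.05).
#' @return Proportion of fits rejecting normality; fits with fewer than
#'   3 residuals are skipped (count in attribute `"n_skipped"`).
#' @export
normality_rejection_rate <- function(fits, alpha = 0.05) {
  p <- numeric(0)
  skipped <- 0
  for (f in fits) {
    r <- f$residuals
    if (is.null(r) || length(r) < 3 || stats::sd(r) == 0) {
      skipped <- skipped + 1
      next
    }
    p <- c(p, stats::shapiro.test(r)$p.value)
  }
  if (!length(p)) stop("no fits with enough residuals")
  structure(mean(p < alpha), n_skipped = skipped)
}

#' Spearman correlation of estimates across methods
#'
#' Rank correlation matrix of per-subject (or per-dataset) estimates
#' between methods, using pairwise-complete observations; entries with
#' fewer than 3 complete pairs are set to `NA`. An approximate CI for a
#' single correlation can be formed with the Fisher z transform
#' ([spearman_ci()]).
#'
#' @param estimates_by_method Data frame or matrix, one column per
#'   method, one row per subject/dataset.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(estimates_by_method) {
  x <- as.matrix(estimates_by_method)
  if (ncol(x) < 2) stop("need at least 2 methods")
  r <- stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
  np <- crossprod(!is.na(x))
  r[np < 3] <- NA_real_
  diag(r)[diag(np) >= 3] <- 1
  r
}

#' Fisher-z confidence interval for a Spearman correlation
#'
#' Approximate CI via the Fisher z transform with variance `1.06/(n-3)`.
#'
#' @param rho Estimated Spearman correlation.
#' @param n Number of complete pairs.
#' @param level Confidence level (default 0.95).
#' @return Length-2 vector (lower, upper).
#' @export
spearman_ci <- function(rho, n, level = 0.95) {
  if (n <= 3) return(c(NA_real_, NA_real_))
  z <- atanh(rho)
  se <- sqrt(1.06 / (n - 3))
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}
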