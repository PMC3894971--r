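#' Simulation scenarios for multiple-flow FeNO
#'
#' Defines the synthetic-data generating conditions: true NO parameters,
#' the flow design, the per-flow standard deviation of the additive
#' normal measurement error, and replicate counts. The named scenarios
#' encode the standard study conditions:
#'
#' * `"main"`: truth `ca_no = 2` ppb, `jaw_no = 800` pl/s, `daw_no = 5`
#'   pl.s^-1.ppb^-1; 2 maneuvers at each target flow 30/50/100/300 ml/s;
#'   error SDs 3.1/1.4/0.8/0.5 ppb (decreasing with flow, as observed in
#'   field data); 10,000 datasets.
#' * `"ca1"`, `"ca4"`: as main with `ca_no = 1` or `4` ppb.
#' * `"constant_sd"`: as main with a constant 1 ppb error SD.
#' * `"lowflow20"`: lowest flow 20 ml/s with error SD 4 ppb there.
#'
#' @param name One of `"main"`, `"ca1"`, `"ca4"`, `"constant_sd"`,
#'   `"lowflow20"`, or `NULL` to build a scenario from the remaining
#'   arguments.
#' @param truth An [no_params] truth triple.
#' @param flow_levels Target flows, ml/s.
#' @param reps_per_flow Maneuvers per flow level.
#' @param noise_sd_per_flow Error SD (ppb) per flow level, parallel to
#'   `flow_levels`.
#' @param n_datasets Number of datasets in a batch.
#' @param seed Master RNG seed for [simulate_batch()].
#' @return A `feno_scenario` list.
#' @examples
#' make_scenario("main")
#' @export
make_scenario <- function(name = NULL,
                          truth = no_params(2, 800, 5, is_truth = TRUE),
                          flow_levels = c(30, 50, 100, 300),
                          reps_per_flow = 2,
                          noise_sd_per_flow = c(3.1, 1.4, 0.8, 0.5),
                          n_datasets = 10000,
                          seed = 1L) {
  if (!is.null(name)) {
    name <- match.arg(name, c("main", "ca1", "ca4", "constant_sd",
                              "lowflow20"))
    if (name == "ca1") truth <- no_params(1, 800, 5, is_truth = TRUE)
    if (name == "ca4") truth <- no_params(4, 800, 5, is_truth = TRUE)
    if (name == "constant_sd") noise_sd_per_flow <- rep(1, 4)
    if (name == "lowflow20") {
      flow_levels <- c(20, 50, 100, 300)
      noise_sd_per_flow <- c(4, 1.4, 0.8, 0.5)
    }
  } else {
    name <- "custom"
  }
  truth <- as_no_params(truth)
  if (length(noise_sd_per_flow) != length(flow_levels))
    stop("noise_sd_per_flow must parallel flow_levels")
  if (any(noise_sd_per_flow <= 0)) stop("noise SDs must be positive")
  if (reps_per_flow < 1) stop("reps_per_flow must be >= 1")
  if (n_datasets < 1) stop("n_datasets must be >= 1")
  structure(list(name = name, truth = truth, flow_levels = flow_levels,
                 reps_per_flow = as.integer(reps_per_flow),
                 noise_sd_per_flow = noise_sd_per_flow,
                 n_datasets = as.integer(n_datasets),
                 seed = as.integer(seed)),
            class = "feno_scenario")
}

#' @export
print.feno_scenario <- function(x, ...) {
  cat(sprintf("<feno_scenario '%s'>\n", x$name))
  cat(sprintf("  truth: ca=%g ppb, jaw=%g pl/s, daw=%g\n",
              x$truth[["ca_no"]], x$truth[["jaw_no"]], x$truth[["daw_no"]]))
  cat(sprintf("  flows (ml/s): %s x %d maneuvers\n",
              paste(x$flow_levels, collapse = "/"), x$reps_per_flow))
  cat(sprintf("  error SD (ppb): %s\n",
              paste(x$noise_sd_per_flow, collapse = "/")))
  cat(sprintf("  %d datasets, seed %d\n", x$n_datasets, x$seed))
  invisible(x)
}

# Draw one dataset given a current .Random.seed state already set.
draw_dataset <- function(scenario, subject_id) {
  v <- rep(scenario$flow_levels, each = scenario$reps_per_flow)
  s <- rep(scenario$noise_sd_per_flow, each = scenario$reps_per_flow)
  mu <- feno_two_compartment(scenario$truth, v)
  y <- mu + stats::rnorm(length(v), 0, s)
  redraws <- 0L
  while (any(y <= 0)) {
    # non-positive FeNO is physically impossible and breaks log-scale
    # fits; redraw those values with the next stream draws and count
    bad <- which(y <= 0)
    y[bad] <- mu[bad] + stats::rnorm(length(bad), 0, s[bad])
    redraws <- redraws + length(bad)
    if (redraws > 1e6) stop("runaway redraw loop; check the scenario")
  }
  d <- subject_dataset(subject_id, v, y)
  attr(d, "n_redraws") <- redraws
  d
}

#' Simulate one multiple-flow FeNO dataset
#'
#' Theoretical FeNO is computed from the two-compartment closed form at
#' the scenario truth and perturbed with independent zero-mean normal
#' error whose SD is the scenario's per-flow value. Target flows are the
#' design points (no achieved-flow jitter). Non-positive draws are
#' redrawn with the next stream draw and counted in the `"n_redraws"`
#' attribute; under the standard scenarios the model means are at least
#' ~4.6 ppb and redraws essentially never occur.
#'
#' @param scenario A `feno_scenario`.
#' @param dataset_index Which substream (1-based) of the scenario's
#'   master seed to draw from; dataset `i` of a batch is identical to
#'   `simulate_dataset(scenario, i)`.
#' @return A [subject_dataset] with `reps_per_flow` maneuvers per flow.
#' @export
simulate_dataset <- function(scenario, dataset_index = 1L) {
  streams <- rng_streams(scenario$seed, dataset_index)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  assign(".Random.seed", streams[[dataset_index]], envir = globalenv())
  draw_dataset(scenario, sprintf("sim%05d", dataset_index))
}

#' Simulate a batch of datasets
#'
#' Draws `scenario$n_datasets` independent datasets, each from its own
#' RNG substream of the master seed (L'Ecuyer-CMRG streams), so a batch
#' is bit-reproducible from the seed and dataset `i` does not depend on
#' how many datasets precede it.
#'
#' @param scenario A `feno_scenario`.
#' @return List of [subject_dataset]s with attribute `"n_redraws"` (total
#'   non-positive redraws across the batch).
#' @export
simulate_batch <- function(scenario) {
  n <- scenario$n_datasets
  streams <- rng_streams(scenario$seed, n)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  out <- vector("list", n)
  total_redraws <- 0L
  for (i in seq_len(n)) {
    assign(".Random.seed", streams[[i]], envir = globalenv())
    out[[i]] <- draw_dataset(scenario, sprintf("sim%05d", i))
    total_redraws <- total_redraws + attr(out[[i]], "n_redraws")
  }
  attr(out, "n_redraws") <- total_redraws
  out
}

# Per-dataset L'Ecuyer-CMRG substreams derived from one master seed.
rng_streams <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(seed %% .Machine$integer.max, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
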