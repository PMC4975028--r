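#' Cohort size of the first fixation event
#'
#' The number of mutations that reached frequency 1 simultaneously at the
#' earliest fixation event of a run.
#'
#' @param sim An `fgm_sim`.
#' @return Integer cohort size, or `NA_integer_` if the run had no fixation.
#' @export
first_fixation_cohort_size <- function(sim) {
  stopifnot(inherits(sim, "fgm_sim"))
  ev <- sim$fixation_events
  if (!nrow(ev)) return(NA_integer_)
  first <- ev[ev$cohort_id == min(ev$cohort_id), ]
  first$cohort_size[1L]
}

# Coerce a simset or plain list of sims to a list of fgm_sim, checking that
# the model parameters (everything but the seed) are shared.
.as_sim_list <- function(x) {
  sims <- if (inherits(x, "fgm_simset")) x$sims
          else if (inherits(x, "fgm_sim")) list(x)
          else x
  if (!length(sims) || !all(vapply(sims, inherits, logical(1), "fgm_sim")))
    stop("expected an fgm_simset or a list of fgm_sim objects", call. = FALSE)
  strip <- function(p) unclass(p)[setdiff(names(p), "seed")]
  ref <- strip(sims[[1L]]$params)
  same <- vapply(sims, function(s) identical(strip(s$params), ref), logical(1))
  if (!all(same))
    stop("replicates were run with different model parameters; ",
         "summaries across mixed parameter sets are refused", call. = FALSE)
  sims
}

#' Distribution of first-fixation cohort sizes across replicates
#'
#' Tabulates [first_fixation_cohort_size()] over replicate runs. Replicates
#' in which no mutation fixed within the horizon are not silently dropped:
#' they are counted in a separate "none" bin, and both the distribution
#' conditional on fixation (`prob`, summing to 1 over observed sizes) and
#' the unconditional one (`prob_all`, summing with the none-bin to 1) are
#' reported.
#'
#' @param x An `fgm_simset` or list of `fgm_sim` objects sharing parameters.
#' @return A data frame of class `fgm_cohort_dist` with columns `cohort_size`,
#'   `count`, `prob`, `prob_all`; attributes `n_runs` and `n_none`.
#' @export
cohort_size_distribution <- function(x) {
  sims <- .as_sim_list(x)
  sizes <- vapply(sims, first_fixation_cohort_size, integer(1))
  none <- sum(is.na(sizes))
  obs <- sizes[!is.na(sizes)]
  tab <- table(obs)
  out <- data.frame(cohort_size = as.integer(names(tab)),
                    count = as.integer(tab))
  out$prob <- if (length(obs)) out$count / length(obs) else numeric(0)
  out$prob_all <- out$count / length(sizes)
  attr(out, "n_runs") <- length(sizes)
  attr(out, "n_none") <- none
  class(out) <- c("fgm_cohort_dist", "data.frame")
  out
}

#' @export
print.fgm_cohort_dist <- function(x, ...) {
  cat(sprintf(
    "First-fixation cohort sizes over %d runs (%d with no fixation)\n",
    attr(x, "n_runs"), attr(x, "n_none")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Fixation events along the adaptive walk
#'
#' One row per fixation event, in chronological order: the census generation
#' and the number of mutations that co-fixed (the cohort size).
#'
#' @param sim An `fgm_sim`.
#' @return Data frame `(generation, cohort_size)`, possibly with zero rows.
#' @export
cohorts_along_walk <- function(sim) {
  stopifnot(inherits(sim, "fgm_sim"))
  ev <- sim$fixation_events
  if (!nrow(ev))
    return(data.frame(generation = integer(0), cohort_size = integer(0)))
  first <- !duplicated(ev$cohort_id)
  out <- data.frame(generation = ev$generation[first],
                    cohort_size = ev$cohort_size[first])
  out[order(out$generation), , drop = FALSE]
}

#' Across-replicate mean-fitness series
#'
#' Pointwise average of the replicate mean-fitness curves on their common
#' generation grid, with an optional dispersion band.
#'
#' @param x An `fgm_simset` or list of `fgm_sim` sharing parameters.
#' @param band Dispersion measure: standard error of the mean (default),
#'   standard deviation, or none.
#' @return Data frame `(generation, mean_w, band)` (`band` column absent for
#'   `band = "none"`, zero for a single replicate under `"se"`/`"sd"`).
#' @export
mean_fitness_series <- function(x, band = c("se", "sd", "none")) {
  band <- match.arg(band)
  sims <- .as_sim_list(x)
  grids <- lapply(sims, function(s) s$mean_fitness$generation)
  g <- grids[[1L]]
  if (!all(vapply(grids, identical, logical(1), g)))
    stop("replicates have mismatched generation grids", call. = FALSE)
  mat <- vapply(sims, function(s) s$mean_fitness$mean_w,
                numeric(length(g)))
  mat <- matrix(mat, nrow = length(g))
  out <- data.frame(generation = g, mean_w = rowMeans(mat))
  if (band != "none") {
    s <- apply(mat, 1L, stats::sd)
    if (ncol(mat) == 1L) s <- rep(0, length(g))
    out$band <- if (band == "se") s / sqrt(ncol(mat)) else s
  }
  out
}

#' Number of segregating mutations over time
#'
#' @param sim An `fgm_sim`.
#' @return Data frame `(generation, n_segregating)` at every recorded census.
#' @export
segregating_count_series <- function(sim) {
  stopifnot(inherits(sim, "fgm_sim"))
  sim$mean_fitness[, c("generation", "n_segregating")]
}

#' Add Gaussian observation noise to a trajectory table
#'
#' Perturbs each recorded frequency by an independent Normal(0, `variance`)
#' draw and clips the result to [0, 1], mimicking the measurement error of
#' sequencing-based allele-frequency estimates. Purely a post-processing of
#' the output table: the noise is never fed back into a simulation.
#'
#' @param trajectories Data frame with a `frequency` column (as produced in
#'   `fgm_sim$trajectories`).
#' @param variance Noise variance (>= 0); 0 returns the table unchanged.
#' @return A copy of the table with perturbed, clipped frequencies.
#' @export
add_observation_noise <- function(trajectories, variance) {
  if (!is.numeric(variance) || length(variance) != 1L || !is.finite(variance) ||
      variance < 0)
    stop("'variance' must be a single finite number >= 0", call. = FALSE)
  out <- trajectories
  if (variance == 0 || !nrow(out)) return(out)
  f <- out$frequency + stats::rnorm(nrow(out), 0, sqrt(variance))
  out$frequency <- pmin(1, pmax(0, f))
  out
}
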