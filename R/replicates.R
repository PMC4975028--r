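#' Run replicate simulations from a master seed
#'
#' Replicate `r` runs with the child seed `fgm_child_seed(master_seed, r)`,
#' so results are reproducible replicate-by-replicate and adding replicates
#' never perturbs earlier ones.
#'
#' @param params An [fgm_params()] object; its `seed` field is used as the
#'   master seed (required here).
#' @param replicates Number of replicate runs (>= 1).
#' @param ... Passed to [fgm_simulate()] (e.g. `record_trajectories`,
#'   `stop_at_first_fixation`).
#' @return An object of class `fgm_simset`: list with `sims` (list of
#'   `fgm_sim`), `params`, `master_seed`, `child_seeds` and `manifest` (a
#'   list recording parameters, seeds, package version and wall time).
#' @examples
#' p <- fgm_params(n = 3, m = 3, E_S = -0.02, U = 0.001, N = 500,
#'                 generations = 200, seed = 11)
#' rs <- fgm_replicates(p, 3)
#' sapply(rs$sims, first_fixation_cohort_size)
#' @export
fgm_replicates <- function(params, replicates, ...) {
  stopifnot(inherits(params, "fgm_params"), replicates >= 1)
  if (is.null(params$seed))
    stop("replicate runs need a master seed: set 'seed' in fgm_params()",
         call. = FALSE)
  master <- params$seed
  kids <- fgm_child_seed(master, seq_len(replicates))
  t0 <- proc.time()[["elapsed"]]
  sims <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    pr <- params
    pr$seed <- kids[r]
    sims[[r]] <- fgm_simulate(pr, ...)
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  manifest <- list(
    params = unclass(params)[setdiff(names(params), "seed")],
    master_seed = master,
    replicates = as.integer(replicates),
    child_seeds = kids,
    package_version = as.character(utils::packageVersion("fgmcohorts")),
    wall_time_sec = elapsed
  )
  structure(list(sims = sims, params = params, master_seed = master,
                 child_seeds = kids, manifest = manifest),
            class = "fgm_simset")
}

#' @export
print.fgm_simset <- function(x, ...) {
  cat(sprintf("%d replicate FGM Wright-Fisher runs (master seed %d)\n",
              length(x$sims), x$master_seed))
  print(x$params)
  ff <- vapply(x$sims, function(s) {
    ev <- s$fixation_events
    if (nrow(ev)) ev$generation[1L] else NA_integer_
  }, integer(1))
  cat(sprintf("  replicates with >=1 fixation: %d/%d\n",
              sum(!is.na(ff)), length(ff)))
  if (any(!is.na(ff)))
    cat(sprintf("  first fixation generations: %s\n",
                paste(ff, collapse = " ")))
  invisible(x)
}

#' Plot replicate mean-fitness dynamics
#'
#' Draws every replicate's mean-fitness curve plus the across-replicate
#' average on the recorded grid.
#'
#' @param x An `fgm_simset`.
#' @param ... Passed to `plot`.
#' @return `x`, invisibly.
#' @export
plot.fgm_simset <- function(x, ...) {
  avg <- mean_fitness_series(x)
  graphics::plot(NA, xlim = range(avg$generation), ylim = c(0, 1),
                 xlab = "generation", ylab = "mean fitness", ...)
  for (s in x$sims)
    graphics::lines(s$mean_fitness$generation, s$mean_fitness$mean_w,
                    col = "grey70")
  graphics::lines(avg$generation, avg$mean_w, lwd = 2)
  invisible(x)
}
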