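#' Run a forward-time simulation
#'
#' Initializes a monomorphic population at fitness `w0` and iterates the
#' Wright-Fisher generation cycle (multinomial selection + drift, then
#' Poisson mutational input), censusing every segregating mutation each
#' generation. Mutations first reaching frequency 1 at the same census form
#' one fixation event (a mutation cohort); they are then pruned into the
#' fixed background. Mean fitness, maximum fitness and the number of
#' segregating mutations are recorded every generation; per-mutation
#' frequency trajectories are recorded at the cadence `params$record_every`
#' (fixation and loss generations are always recorded).
#'
#' @param params An [fgm_params()] object. If `params$seed` is non-NULL the
#'   RNG is seeded at the start of the run.
#' @param record_trajectories Record the per-mutation frequency table? Set to
#'   `FALSE` for long runs where only fitness dynamics and fixation events
#'   are needed.
#' @param stop_at_first_fixation Stop the run at the census of the first
#'   fixation event (used, e.g., for waiting-time experiments); the horizon
#'   `params$generations` still caps the run.
#' @param verbose Print progress at every 10% of the horizon.
#' @return An object of class `fgm_sim`: list with elements
#'   \describe{
#'     \item{params, seed}{the run configuration and the seed used (NA when
#'       run from the ambient RNG state).}
#'     \item{generations_run, completed}{generations actually simulated, and
#'       whether the run reached its stopping rule normally.}
#'     \item{mean_fitness}{data frame `(generation, mean_w, max_w,
#'       n_segregating)`, covering generation 0 and the final generation.}
#'     \item{trajectories}{data frame `(generation, mutation_id, frequency)`.}
#'     \item{fixation_events}{data frame `(generation, cohort_id,
#'       cohort_size, mutation_id)`, one row per cohort member.}
#'     \item{mutations}{the registry summary (see [registry_summary()]).}
#'   }
#' @examples
#' p <- fgm_params(n = 3, m = 3, E_S = -0.01, U = 0.001, N = 1000,
#'                 generations = 300, seed = 7)
#' sim <- fgm_simulate(p)
#' sim
#' @export
fgm_simulate <- function(params, record_trajectories = TRUE,
                         stop_at_first_fixation = FALSE, verbose = FALSE) {
  stopifnot(inherits(params, "fgm_params"))
  pop <- fgm_population(params)          # seeds RNG if params$seed set
  reg <- pop$registry
  G <- params$generations
  N <- params$N
  cadence <- params$record_every

  # per-generation fitness summaries, preallocated over the full horizon
  mf_gen <- integer(G + 1L)
  mf_mean <- numeric(G + 1L)
  mf_max <- numeric(G + 1L)
  mf_seg <- integer(G + 1L)
  mf_gen[1L] <- 0L
  mf_mean[1L] <- mean_fitness(pop)
  mf_max[1L] <- exp(max(pop$logw))
  mf_seg[1L] <- 0L

  traj_gen <- list(); traj_id <- list(); traj_fr <- list(); tk <- 0L
  ev_gen <- integer(0); ev_ids <- list()

  milestone <- if (verbose && G >= 10L) seq(G %/% 10L, G, by = G %/% 10L)
               else integer(0)
  gen <- 0L
  while (gen < G) {
    advance_generation(pop, reg)
    gen <- pop$generation

    cen <- .census_fast(pop)
    newly_fixed <- cen$ids[cen$counts == N]
    newly_lost <- setdiff(reg$active, cen$ids)
    .reg_mark(reg, newly_fixed, newly_lost, gen)

    if (record_trajectories) {
      on_grid <- gen %% cadence == 0L
      if (on_grid || length(newly_fixed) || length(newly_lost)) {
        if (on_grid) {
          ids <- c(cen$ids, newly_lost)
          fr <- c(cen$counts / N, numeric(length(newly_lost)))
        } else {
          keep <- cen$ids %in% newly_fixed
          ids <- c(cen$ids[keep], newly_lost)
          fr <- c(cen$counts[keep] / N, numeric(length(newly_lost)))
        }
        if (length(ids)) {
          tk <- tk + 1L
          traj_gen[[tk]] <- rep.int(gen, length(ids))
          traj_id[[tk]] <- ids
          traj_fr[[tk]] <- fr
        }
      }
    }

    if (length(newly_fixed)) {
      ev_gen <- c(ev_gen, gen)
      ev_ids <- c(ev_ids, list(newly_fixed))
      prune_fixed(pop, newly_fixed)
    }

    mf_gen[gen + 1L] <- gen
    mf_mean[gen + 1L] <- mean_fitness(pop)
    mf_max[gen + 1L] <- exp(max(pop$logw))
    mf_seg[gen + 1L] <- length(reg$active)

    if (gen %in% milestone)
      message(sprintf(
        "generation %d/%d: %d classes, %d segregating, %d fixation events",
        gen, G, length(pop$counts), length(reg$active), length(ev_gen)))

    if (stop_at_first_fixation && length(ev_gen)) break
  }

  used <- seq_len(gen + 1L)
  nmemb <- lengths(ev_ids)
  structure(list(
    params = params,
    seed = if (is.null(params$seed)) NA_integer_ else params$seed,
    generations_run = gen,
    completed = TRUE,
    mean_fitness = data.frame(generation = mf_gen[used],
                              mean_w = mf_mean[used],
                              max_w = mf_max[used],
                              n_segregating = mf_seg[used]),
    trajectories = data.frame(
      generation = as.integer(unlist(traj_gen, use.names = FALSE)),
      mutation_id = as.integer(unlist(traj_id, use.names = FALSE)),
      frequency = as.numeric(unlist(traj_fr, use.names = FALSE))),
    fixation_events = data.frame(
      generation = rep.int(ev_gen, nmemb),
      cohort_id = rep.int(seq_along(ev_gen), nmemb),
      cohort_size = rep.int(nmemb, nmemb),
      mutation_id = as.integer(unlist(ev_ids, use.names = FALSE))),
    mutations = registry_summary(reg)
  ), class = "fgm_sim")
}

#' @export
print.fgm_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "FGM Wright-Fisher run: n = %d, m = %d, sigma2 = %g (E(S) = %g)\n",
    p$n, p$m, p$sigma2, p$E_S))
  cat(sprintf("  N = %d, U = %g, w0 = %g, placement %s, seed %s\n",
              p$N, p$U, p$w0, p$placement, format(x$seed)))
  nev <- length(unique(x$fixation_events$cohort_id))
  nfix <- nrow(x$fixation_events)
  last <- x$mean_fitness[nrow(x$mean_fitness), ]
  cat(sprintf("  %d generations run; final mean fitness %.4f (%d segregating)\n",
              x$generations_run, last$mean_w, last$n_segregating))
  cat(sprintf("  %d fixation event%s, %d mutation%s fixed, %d created\n",
              nev, if (nev == 1L) "" else "s",
              nfix, if (nfix == 1L) "" else "s", nrow(x$mutations)))
  invisible(x)
}

#' @export
summary.fgm_sim <- function(object, ...) {
  ev <- cohorts_along_walk(object)
  fates <- table(factor(object$mutations$fate,
                        levels = c("segregating", "fixed", "lost")))
  out <- list(
    params = object$params,
    generations_run = object$generations_run,
    final_mean_fitness = object$mean_fitness$mean_w[nrow(object$mean_fitness)],
    n_mutations = nrow(object$mutations),
    fates = fates,
    n_fixation_events = nrow(ev),
    first_fixation_generation = if (nrow(ev)) ev$generation[1L] else NA_integer_,
    first_fixation_cohort_size = first_fixation_cohort_size(object),
    cohort_sizes = if (nrow(ev)) ev$cohort_size else integer(0)
  )
  class(out) <- "summary.fgm_sim"
  out
}

#' @export
print.summary.fgm_sim <- function(x, ...) {
  print(x$params)
  cat(sprintf("generations run: %d; final mean fitness: %.4f\n",
              x$generations_run, x$final_mean_fitness))
  cat(sprintf("mutations created: %d (%d fixed, %d lost, %d segregating)\n",
              x$n_mutations, x$fates[["fixed"]], x$fates[["lost"]],
              x$fates[["segregating"]]))
  if (x$n_fixation_events) {
    cat(sprintf("fixation events: %d; first at generation %d (cohort size %d)\n",
                x$n_fixation_events, x$first_fixation_generation,
                x$first_fixation_cohort_size))
    cat("cohort sizes:", paste(x$cohort_sizes, collapse = " "), "\n")
  } else {
    cat("no fixation event within the simulated horizon\n")
  }
  invisible(x)
}

#' Plot a simulation
#'
#' `type = "fitness"` draws the mean (and maximum) fitness against time;
#' `type = "trajectories"` draws every recorded mutation-frequency
#' trajectory (optionally with Gaussian observation noise, as used when
#' comparing with evolve-and-resequence data); `type = "cohorts"` draws
#' cohort size against the generation of each fixation event.
#'
#' @param x An `fgm_sim`.
#' @param type Panel to draw.
#' @param noise_variance Observation-noise variance for `"trajectories"`
#'   (0 = none).
#' @param ... Passed to the underlying base-graphics call.
#' @return `x`, invisibly.
#' @export
plot.fgm_sim <- function(x, type = c("fitness", "trajectories", "cohorts"),
                         noise_variance = 0, ...) {
  type <- match.arg(type)
  if (type == "fitness") {
    graphics::plot(x$mean_fitness$generation, x$mean_fitness$mean_w,
                   type = "l", xlab = "generation", ylab = "mean fitness",
                   ylim = c(0, 1), ...)
    graphics::lines(x$mean_fitness$generation, x$mean_fitness$max_w,
                    lty = 2, col = "grey50")
  } else if (type == "trajectories") {
    tr <- x$trajectories
    if (noise_variance > 0) tr <- add_observation_noise(tr, noise_variance)
    graphics::plot(NA, xlim = range(tr$generation, 0),
                   ylim = c(0, 1), xlab = "generation",
                   ylab = "mutation frequency", ...)
    ids <- unique(tr$mutation_id)
    cols <- grDevices::hcl.colors(max(length(ids), 2L), "Dark 3")
    for (k in seq_along(ids)) {
      sub <- tr[tr$mutation_id == ids[k], ]
      graphics::lines(sub$generation, sub$frequency, col = cols[k])
    }
  } else {
    ev <- cohorts_along_walk(x)
    graphics::plot(ev$generation, ev$cohort_size, pch = 19,
                   xlab = "generation of fixation event",
                   ylab = "cohort size", ...)
  }
  invisible(x)
}
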