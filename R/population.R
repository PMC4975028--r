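#' Initialize a monomorphic Wright-Fisher population
#'
#' Creates a population of `N` identical individuals at the initial phenotype
#' implied by `params` (fitness `w0`), with an empty mutation registry
#' attached. The population is represented by genotype classes: each class is
#' a distinct genotype (set of segregating mutation ids) with its phenotype,
#' cached log-fitness and individual count. Classes are stored in parallel
#' vectors/lists inside an environment, so engine steps update in place.
#'
#' If `params$seed` is non-NULL the global RNG is seeded here, before the
#' initial phenotype is drawn (the `"random_direction"` placement consumes
#' random numbers).
#'
#' @param params An [fgm_params()] object.
#' @return An object of class `fgm_pop`: environment with fields `params`,
#'   `generation`, `counts`, `logw`, `pheno` (list of phenotype vectors),
#'   `muts` (list of integer id vectors), `fixed_ids`, and `registry`.
#' @export
fgm_population <- function(params) {
  stopifnot(inherits(params, "fgm_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  z0 <- initial_phenotype(params)
  pop <- new.env(parent = emptyenv())
  pop$params <- params
  pop$generation <- 0L
  pop$counts <- params$N
  pop$logw <- fgm_log_fitness(z0)
  pop$pheno <- list(z0)
  pop$muts <- list(integer(0))
  pop$fixed_ids <- integer(0)
  pop$registry <- new_registry()
  class(pop) <- "fgm_pop"
  pop
}

#' Selection and drift: one multinomial resampling of the population
#'
#' The contribution of each genotype class to the next generation is
#' proportional to its count times its fitness; new class counts are one
#' multinomial draw with `N` trials. Weights are computed from log-fitness
#' with a max-shift before exponentiation, so far-from-optimum classes cannot
#' underflow. Classes drawn to count 0 are dropped.
#'
#' @param pop An `fgm_pop` (modified in place).
#' @return The population, invisibly.
#' @export
selection_drift_step <- function(pop) {
  stopifnot(inherits(pop, "fgm_pop"))
  w <- exp(pop$logw - max(pop$logw))
  newc <- stats::rmultinom(1L, pop$params$N, pop$counts * w)[, 1L]
  keep <- newc > 0L
  if (all(keep)) {
    pop$counts <- newc
  } else {
    pop$counts <- newc[keep]
    pop$logw <- pop$logw[keep]
    pop$pheno <- pop$pheno[keep]
    pop$muts <- pop$muts[keep]
  }
  invisible(pop)
}

#' Mutational input: Poisson number of new mutations, uniformly assigned
#'
#' The total number of new mutations in the generation is one
#' Poisson(`N * U`) draw; each mutation lands on a uniformly chosen
#' individual. This is distributionally identical to independent Poisson(`U`)
#' draws per individual, so a single individual can receive two or more
#' mutations in one generation. Each mutated individual is split off its
#' parent class into a new class of count 1 carrying the parent's mutation
#' set plus the new id(s), with the phenotype updated additively and the
#' registry extended (the selection coefficient of each mutation against the
#' background it arose on is stored).
#'
#' @param pop An `fgm_pop` (modified in place).
#' @param registry Registry to record new mutations in; defaults to the
#'   population's own.
#' @return The population, invisibly.
#' @export
mutation_step <- function(pop, registry = pop$registry) {
  stopifnot(inherits(pop, "fgm_pop"))
  prm <- pop$params
  M <- stats::rpois(1L, prm$N * prm$U)
  if (M == 0L) return(invisible(pop))
  sd_ <- sqrt(prm$sigma2)
  individuals <- sample.int(prm$N, M, replace = TRUE)
  cum <- cumsum(pop$counts)
  K <- length(pop$counts)
  counts <- pop$counts
  # registry entries are collected locally and committed in one batch
  traits_list <- vector("list", M)
  deltas_list <- vector("list", M)
  s0 <- numeric(M)
  next_id <- registry$n
  for (grp in split(seq_len(M), individuals)) {
    cl <- findInterval(individuals[grp[1L]] - 1L, cum) + 1L
    z <- pop$pheno[[cl]]
    lw_parent <- pop$logw[cl]
    new_ids <- integer(length(grp))
    for (j in seq_along(grp)) {
      traits <- sample.int(prm$n, prm$m)
      deltas <- stats::rnorm(prm$m, 0, sd_)
      z[traits] <- z[traits] + deltas
      lw <- -sum(z * z)
      next_id <- next_id + 1L
      k <- next_id - registry$n
      traits_list[[k]] <- traits
      deltas_list[[k]] <- deltas
      s0[k] <- exp(lw - lw_parent) - 1
      new_ids[j] <- next_id
      lw_parent <- lw
    }
    K <- K + 1L
    counts[cl] <- counts[cl] - 1L
    counts[K] <- 1L
    pop$logw[K] <- lw_parent
    pop$pheno[[K]] <- z
    pop$muts[[K]] <- c(pop$muts[[cl]], new_ids)
  }
  .reg_add_batch(registry, pop$generation + 1L, traits_list, deltas_list, s0)
  keep <- counts > 0L
  if (all(keep)) {
    pop$counts <- counts
  } else {
    pop$counts <- counts[keep]
    pop$logw <- pop$logw[keep]
    pop$pheno <- pop$pheno[keep]
    pop$muts <- pop$muts[keep]
  }
  invisible(pop)
}

#' Advance the population by one Wright-Fisher generation
#'
#' Offspring are sampled first (selection + drift), then mutation acts on the
#' newborn generation; the generation counter then advances. Census-based
#' bookkeeping (fixation/loss detection, pruning, recording) is performed by
#' the run driver after this step, on the population that begins the next
#' generation.
#'
#' @inheritParams mutation_step
#' @return The population, invisibly.
#' @export
advance_generation <- function(pop, registry = pop$registry) {
  selection_drift_step(pop)
  mutation_step(pop, registry)
  pop$generation <- pop$generation + 1L
  invisible(pop)
}

#' Population mean fitness
#' @param pop An `fgm_pop`.
#' @return Mean fitness of the `N` individuals.
#' @export
mean_fitness <- function(pop) {
  sum(pop$counts * exp(pop$logw)) / pop$params$N
}

#' @export
print.fgm_pop <- function(x, ...) {
  cat(sprintf(
    "Wright-Fisher population: generation %d, N = %d, %d genotype class%s\n",
    x$generation, x$params$N, length(x$counts),
    if (length(x$counts) == 1L) "" else "es"))
  cat(sprintf("  mean fitness %.6g, max fitness %.6g\n",
              mean_fitness(x), exp(max(x$logw))))
  cat(sprintf("  segregating mutations: %d; fixed: %d\n",
              length(x$registry$active), length(x$fixed_ids)))
  invisible(x)
}
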