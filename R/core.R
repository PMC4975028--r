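#' Gaussian fitness of a phenotype
#'
#' Fitness on Fisher's geometric landscape declines as a Gaussian function of
#' the distance to the optimum (placed at the origin):
#' `w = exp(-sum(z^2))`.
#'
#' @param z Numeric phenotype vector (trait values; all entries finite).
#' @return Fitness in (0, 1]; 1 exactly at the optimum.
#' @examples
#' fgm_fitness(c(0, 0))          # 1 at the optimum
#' fgm_fitness(c(0.5, 0.5))      # exp(-0.5)
#' @export
fgm_fitness <- function(z) {
  exp(fgm_log_fitness(z))
}

#' Log-fitness of a phenotype
#'
#' Numerically stable companion of [fgm_fitness()]: returns `-sum(z^2)`.
#' Selection weights inside the engine are computed from log-fitness with a
#' max-shift before exponentiation, so genotypes far from the optimum never
#' underflow to weight zero relative to one another.
#'
#' @inheritParams fgm_fitness
#' @return `-sum(z^2)`, a non-positive real.
#' @export
fgm_log_fitness <- function(z) {
  if (!is.numeric(z) || length(z) < 1L)
    stop("phenotype must be a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(z)))
    stop("phenotype has non-finite entries", call. = FALSE)
  -sum(z * z)
}

#' Initial phenotype at a prescribed fitness
#'
#' Places the founding phenotype at distance `d = sqrt(log(1 / w0))` from the
#' optimum, so that its fitness is exactly `w0`. Placement `"axis"` puts the
#' whole displacement on trait 1; `"random_direction"` scales a uniformly
#' random direction on the unit sphere (drawn from the current RNG stream) to
#' that distance. The norm, and hence the fitness, is identical for both.
#'
#' @param params An [fgm_params()] object.
#' @return Numeric phenotype vector of length `params$n` with fitness
#'   `params$w0`.
#' @examples
#' p <- fgm_params(n = 3, m = 3, sigma2 = 0.004, seed = 1)
#' z <- initial_phenotype(p)   # fitness(z) == 0.5
#' @export
initial_phenotype <- function(params) {
  stopifnot(inherits(params, "fgm_params"))
  d <- sqrt(log(1 / params$w0))
  if (d == 0) return(numeric(params$n))
  if (params$placement == "axis") {
    z <- numeric(params$n)
    z[1L] <- d
    z
  } else {
    u <- stats::rnorm(params$n)
    nrm <- sqrt(sum(u * u))
    while (nrm == 0) {            # astronomically unlikely; be safe
      u <- stats::rnorm(params$n)
      nrm <- sqrt(sum(u * u))
    }
    d * u / nrm
  }
}

#' Draw a random mutation under partial pleiotropy
#'
#' A mutation alters `m` distinct traits chosen uniformly without replacement
#' from the `n` traits; the change on each affected trait is an independent
#' Normal(0, `sigma2`) deviate.
#'
#' @param params An [fgm_params()] object.
#' @param id Unique non-negative integer identifier for the new mutation.
#' @param gen Generation of origin (integer >= 0).
#' @return An object of class `fgm_mutation`: list with fields `id`,
#'   `origin_generation`, `trait_indices` (1-based, distinct) and `deltas`.
#' @examples
#' p <- fgm_params(n = 10, m = 3, sigma2 = 0.004, seed = 1)
#' set.seed(1)
#' sample_mutation(p, id = 1, gen = 0)
#' @export
sample_mutation <- function(params, id, gen = 0L) {
  stopifnot(inherits(params, "fgm_params"))
  structure(list(
    id = as.integer(id),
    origin_generation = as.integer(gen),
    trait_indices = sample.int(params$n, params$m),
    deltas = stats::rnorm(params$m, 0, sqrt(params$sigma2))
  ), class = "fgm_mutation")
}

#' Apply a mutation to a phenotype
#'
#' Mutational effects are additive on trait values: each affected trait `i`
#' becomes `z[i] + delta_i`; other traits are untouched. The input vector is
#' not modified (R copy semantics).
#'
#' @param z Numeric phenotype vector.
#' @param mut An `fgm_mutation` (from [sample_mutation()]).
#' @return The mutated phenotype vector.
#' @export
apply_mutation <- function(z, mut) {
  stopifnot(inherits(mut, "fgm_mutation"))
  idx <- mut$trait_indices
  if (any(idx < 1L) || any(idx > length(z)))
    stop("mutation trait indices out of range for this phenotype",
         call. = FALSE)
  z[idx] <- z[idx] + mut$deltas
  z
}

#' Selection coefficient of an offspring genotype relative to its parent
#'
#' The standard definition `s = w_offspring / w_parent - 1`.
#'
#' @param w_parent Parent fitness (> 0).
#' @param w_offspring Offspring fitness.
#' @return The selection coefficient; vectorized over both arguments.
#' @export
selection_coefficient <- function(w_parent, w_offspring) {
  if (any(w_parent <= 0))
    stop("'w_parent' must be positive", call. = FALSE)
  w_offspring / w_parent - 1
}

#' First-order mean selective effect of a random mutation at the optimum
#'
#' For an optimum-resident parent, a random mutation multiplies fitness by
#' `exp(-sum(delta^2))` with `delta` a vector of `m` iid Normal(0, `sigma2`)
#' deviates. To first order in `sigma2` the mean selection coefficient is
#' `-m * sigma2`; this is the conventional summary `E(S)` of the model's
#' distribution of fitness effects. The exact mean multiplicative factor is
#' given by [expected_fitness_factor()].
#'
#' @param m Pleiotropy (>= 1).
#' @param sigma2 Per-trait mutational variance (>= 0).
#' @return `-m * sigma2`.
#' @examples
#' expected_mean_effect(3, 0.004)  # -0.012
#' @export
expected_mean_effect <- function(m, sigma2) {
  stopifnot(m >= 1, sigma2 >= 0)
  -m * sigma2
}

#' Exact mean multiplicative fitness factor of a random mutation at the optimum
#'
#' With `delta_i ~ Normal(0, sigma2)` iid, `E[exp(-sum(delta^2))]` follows
#' from the moment-generating function of a chi-square variable:
#' `(1 + 2 * sigma2)^(-m / 2)`. The exact mean selection coefficient at the
#' optimum is this factor minus 1, which agrees with `-m * sigma2`
#' (see [expected_mean_effect()]) to first order in `sigma2`.
#'
#' @inheritParams expected_mean_effect
#' @return `(1 + 2 * sigma2)^(-m / 2)`.
#' @examples
#' expected_fitness_factor(3, 0.004) - 1   # approx -0.01188
#' @export
expected_fitness_factor <- function(m, sigma2) {
  stopifnot(m >= 1, sigma2 >= 0)
  (1 + 2 * sigma2)^(-m / 2)
}

#' Monte-Carlo sample of selection coefficients of random mutations
#'
#' Draws `nsim` mutations as in [sample_mutation()] and returns the selection
#' coefficient of each applied to a fixed parent phenotype. For the default
#' optimum-resident parent the computation is vectorized (trait identities do
#' not change the fitness of a mutant of the origin).
#'
#' @param params An [fgm_params()] object.
#' @param nsim Number of mutations to draw.
#' @param z Parent phenotype; default the optimum (all-zero vector).
#' @return Numeric vector of `nsim` selection coefficients.
#' @examples
#' p <- fgm_params(n = 10, m = 3, sigma2 = 0.004, seed = 1)
#' set.seed(1)
#' mean(sample_selection_coefficients(p, 1e4))  # near -0.0119
#' @export
sample_selection_coefficients <- function(params, nsim, z = NULL) {
  stopifnot(inherits(params, "fgm_params"), nsim >= 1)
  if (is.null(z)) z <- numeric(params$n)
  if (length(z) != params$n)
    stop("parent phenotype has wrong length", call. = FALSE)
  sd_ <- sqrt(params$sigma2)
  if (all(z == 0)) {
    # at the optimum the affected trait identities are irrelevant
    d2 <- stats::rnorm(nsim * params$m, 0, sd_)^2
    dim(d2) <- c(params$m, nsim)
    return(exp(-.colSums(d2, params$m, nsim)) - 1)
  }
  wp <- fgm_fitness(z)
  s <- numeric(nsim)
  for (i in seq_len(nsim)) {
    idx <- sample.int(params$n, params$m)
    zi <- z
    zi[idx] <- zi[idx] + stats::rnorm(params$m, 0, sd_)
    s[i] <- fgm_fitness(zi) / wp - 1
  }
  s
}
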