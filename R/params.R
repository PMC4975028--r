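#' Simulation parameters for the geometric fitness landscape
#'
#' Bundles and validates the parameters of a Wright-Fisher run on Fisher's
#' geometric landscape: the phenotype dimensionality (complexity) `n`, the
#' pleiotropy `m` (traits altered per mutation), the per-trait mutational
#' variance `sigma2`, the genomic mutation rate `U`, the population size `N`,
#' the initial fitness `w0`, the run horizon and recording cadence, the RNG
#' seed, and the initial-phenotype placement rule.
#'
#' Exactly one of `sigma2` and `E_S` must be supplied. `E_S` is the mean
#' selection coefficient of a random mutation arising in an optimum-resident
#' genotype, equal to `-m * sigma2` to first order, so supplying `E_S` sets
#' `sigma2 = abs(E_S) / m`.
#'
#' @param n Number of traits under selection (positive integer).
#' @param m Pleiotropy: traits altered by a single mutation, `1 <= m <= n`.
#'   Defaults to `n` (full pleiotropy).
#' @param sigma2 Per-trait variance of mutational effects (>= 0).
#' @param E_S Mean selective effect of a random mutation at the optimum; a
#'   non-positive number. Mutually exclusive with `sigma2`.
#' @param U Genomic mutation rate per individual per generation (>= 0).
#' @param N Population size (positive integer).
#' @param w0 Initial fitness, in (0, 1].
#' @param generations Number of generations to simulate (>= 0).
#' @param record_every Trajectory recording cadence in generations (>= 1).
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param placement Initial-phenotype placement rule: `"random_direction"`
#'   (default) places the starting phenotype at the distance implied by `w0`
#'   along a uniformly random direction; `"axis"` concentrates the whole
#'   displacement on the first trait. With partial pleiotropy (`m < n`) the
#'   two are not equivalent: mutations act on coordinate axes, so the
#'   landscape is anisotropic and an axis-aligned start gives rare mutations
#'   an unrealistically large radial component.
#'
#' @return An object of class `fgm_params`: a validated list with the fields
#'   above plus the derived `E_S = -m * sigma2`.
#' @examples
#' p <- fgm_params(n = 10, m = 3, E_S = -0.012, U = 0.003, N = 1e5, seed = 1)
#' p$sigma2  # 0.004
#' @export
fgm_params <- function(n, m = n, sigma2 = NULL, E_S = NULL, U = 0.001,
                       N = 10000, w0 = 0.5, generations = 1000,
                       record_every = 1, seed = NULL,
                       placement = c("random_direction", "axis")) {
  placement <- match.arg(placement)
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
    x == trunc(x)
  is_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

  if (!is_count(n) || n < 1) note("'n' must be a positive integer")
  if (!is_count(m) || m < 1) note("'m' must be a positive integer")
  if (is_count(n) && is_count(m) && m > n)
    note(sprintf("'m' (%d) must not exceed 'n' (%d)", as.integer(m),
                 as.integer(n)))
  if (!is.null(sigma2) && !is.null(E_S))
    note("supply exactly one of 'sigma2' and 'E_S', not both")
  if (is.null(sigma2) && is.null(E_S))
    note("one of 'sigma2' or 'E_S' is required")
  if (!is.null(E_S)) {
    if (!is_num(E_S) || E_S > 0)
      note("'E_S' must be a finite number <= 0")
    else if (is_count(m) && m >= 1)
      sigma2 <- abs(E_S) / m
  }
  if (!is.null(sigma2) && (!is_num(sigma2) || sigma2 < 0))
    note("'sigma2' must be a finite number >= 0")
  if (!is_num(U) || U < 0) note("'U' must be a finite number >= 0")
  if (!is_count(N) || N < 1) note("'N' must be a positive integer")
  if (!is_num(w0) || w0 <= 0 || w0 > 1) note("'w0' must lie in (0, 1]")
  if (!is_count(generations) || generations < 0)
    note("'generations' must be a non-negative integer")
  if (!is_count(record_every) || record_every < 1)
    note("'record_every' must be a positive integer")
  if (!is.null(seed) && !is_count(seed)) note("'seed' must be an integer")

  if (length(problems))
    stop("invalid parameters:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)

  structure(list(
    n = as.integer(n), m = as.integer(m), sigma2 = as.numeric(sigma2),
    E_S = -as.integer(m) * as.numeric(sigma2),
    U = as.numeric(U), N = as.integer(N), w0 = as.numeric(w0),
    generations = as.integer(generations),
    record_every = as.integer(record_every),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    placement = placement
  ), class = "fgm_params")
}

#' @export
print.fgm_params <- function(x, ...) {
  cat("Fisher geometric model / Wright-Fisher run parameters\n")
  cat(sprintf("  traits n = %d, pleiotropy m = %d (%s)\n", x$n, x$m,
              if (x$m == x$n) "full" else "partial"))
  cat(sprintf("  sigma2 = %g per trait, E(S) = -m*sigma2 = %g\n",
              x$sigma2, x$E_S))
  cat(sprintf("  N = %d, U = %g (NU = %g), w0 = %g\n",
              x$N, x$U, x$N * x$U, x$w0))
  cat(sprintf("  horizon %d generations, recording every %d; placement: %s\n",
              x$generations, x$record_every, x$placement))
  cat(sprintf("  seed: %s\n", if (is.null(x$seed)) "<current RNG state>"
              else format(x$seed)))
  invisible(x)
}

# Largest prime below 2^31; keeps derived seeds valid 32-bit integers.
.seed_modulus <- 2147483629

#' Deterministic child seed for a replicate
#'
#' Derives the RNG seed of replicate `r` from a master seed by fixed modular
#' arithmetic, so adding replicates never perturbs the seeds of earlier ones
#' and every derived seed is a valid positive 32-bit integer.
#'
#' @param master_seed Integer master seed.
#' @param r Replicate index (positive integer); vectorized.
#' @return Integer vector of child seeds, `(master_seed + 1000003 * r)` modulo
#'   the largest prime below 2^31 (mapped away from 0).
#' @examples
#' fgm_child_seed(42, 1:3)
#' @export
fgm_child_seed <- function(master_seed, r) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(r), all(r >= 1))
  # exact in double arithmetic: |master| + 1000003*r << 2^53 for any sane r
  s <- (abs(master_seed) + 1000003 * as.numeric(r)) %% .seed_modulus
  as.integer(ifelse(s == 0, 1, s))
}
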