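#' Naive individual-based reference population
#'
#' A deliberately simple per-individual representation of the same model as
#' the genotype-class engine, kept as an independent cross-check: each of the
#' `N` individuals stores its own phenotype and mutation set, offspring draw
#' their parents one by one with fitness-proportional probabilities, and each
#' offspring mutates with an independent Poisson(`U`) number of mutations.
#' It is distributionally identical to the class-based engine, and far
#' slower; use only at small `N`.
#'
#' @param params An [fgm_params()] object (seeds the RNG if `seed` set).
#' @return An object of class `fgm_refpop`: environment with fields `params`,
#'   `generation`, `pheno` (list of `N` phenotypes), `muts` (list of `N`
#'   integer id vectors), `logw` (length-`N` log-fitness), `registry`.
#' @export
reference_population <- function(params) {
  stopifnot(inherits(params, "fgm_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  z0 <- initial_phenotype(params)
  rp <- new.env(parent = emptyenv())
  rp$params <- params
  rp$generation <- 0L
  rp$pheno <- rep(list(z0), params$N)
  rp$muts <- rep(list(integer(0)), params$N)
  rp$logw <- rep(fgm_log_fitness(z0), params$N)
  rp$registry <- new_registry()
  class(rp) <- "fgm_refpop"
  rp
}

#' One Wright-Fisher generation of the reference engine
#'
#' Parents are sampled individual-by-individual with probability
#' proportional to fitness (max-shifted exponentials of log-fitness), then
#' each offspring receives `rpois(1, U)` new mutations.
#'
#' @param rp An `fgm_refpop` (modified in place).
#' @return The reference population, invisibly.
#' @export
reference_step <- function(rp) {
  stopifnot(inherits(rp, "fgm_refpop"))
  prm <- rp$params
  N <- prm$N
  w <- exp(rp$logw - max(rp$logw))
  parents <- sample.int(N, N, replace = TRUE, prob = w)
  pheno <- rp$pheno[parents]
  muts <- rp$muts[parents]
  logw <- rp$logw[parents]
  nmut <- stats::rpois(N, prm$U)
  sd_ <- sqrt(prm$sigma2)
  for (i in which(nmut > 0L)) {
    z <- pheno[[i]]
    lw_parent <- logw[i]
    for (k in seq_len(nmut[i])) {
      traits <- sample.int(prm$n, prm$m)
      deltas <- stats::rnorm(prm$m, 0, sd_)
      z[traits] <- z[traits] + deltas
      lw <- -sum(z * z)
      id <- .reg_add(rp$registry, rp$generation + 1L, traits, deltas,
                     exp(lw - lw_parent) - 1)
      muts[[i]] <- c(muts[[i]], id)
      lw_parent <- lw
    }
    pheno[[i]] <- z
    logw[i] <- lw_parent
  }
  rp$pheno <- pheno
  rp$muts <- muts
  rp$logw <- logw
  rp$generation <- rp$generation + 1L
  invisible(rp)
}

#' Mean fitness of a reference population
#' @param rp An `fgm_refpop`.
#' @return Mean fitness across the `N` individuals.
#' @export
reference_mean_fitness <- function(rp) mean(exp(rp$logw))

#' Carrier count of a mutation id in a reference population
#' @param rp An `fgm_refpop`.
#' @param id Mutation id.
#' @return Number of individuals carrying `id`.
#' @export
reference_carrier_count <- function(rp, id) {
  sum(vapply(rp$muts, function(s) id %in% s, logical(1)))
}
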