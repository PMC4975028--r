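# Small shared builders for engine tests.

# Default tiny parameter set; override fields via ...
tiny_params <- function(...) {
  args <- list(n = 2, m = 2, sigma2 = 0.01, U = 0.001, N = 100,
               generations = 100, seed = 1)
  args[names(list(...))] <- list(...)
  do.call(fgm_params, args)
}

# Build a population with prescribed genotype classes, bypassing the normal
# monomorphic start. Each class i gets counts[i] individuals, phenotype
# phenos[[i]] and mutation set muts[[i]]; every distinct mutation id is
# registered as segregating (origin generation 0, effects unused by the
# engine once the phenotype is set).
make_pop <- function(params, counts, phenos, muts) {
  stopifnot(sum(counts) == params$N, length(counts) == length(phenos),
            length(counts) == length(muts))
  pop <- fgm_population(fgm_params(
    n = params$n, m = params$m, sigma2 = params$sigma2, U = params$U,
    N = params$N, w0 = 1, generations = params$generations,
    record_every = params$record_every, seed = NULL,
    placement = params$placement))
  pop$params <- params
  pop$counts <- as.integer(counts)
  pop$pheno <- phenos
  pop$logw <- vapply(phenos, fgm_log_fitness, numeric(1))
  pop$muts <- lapply(muts, as.integer)
  ids <- sort(unique(unlist(muts)))
  if (length(ids)) {
    stopifnot(identical(ids, seq_along(ids)))  # registry ids are 1..k
    for (id in ids)
      fgmcohorts:::.reg_add(pop$registry, 0L, seq_len(params$m),
                            numeric(params$m), 0)
  }
  pop
}

# Two equally fit classes at the optimum, the focal one carrying mutation 1.
neutral_two_class_pop <- function(N, k_focal, n = 1) {
  params <- fgm_params(n = n, m = 1, sigma2 = 0, U = 0, N = N,
                       generations = 1, w0 = 1)
  make_pop(params, c(N - k_focal, k_focal),
           list(numeric(n), numeric(n)),
           list(integer(0), 1L))
}

# Run selection/drift until a single class remains; returns TRUE if the
# focal class (carrying mutation 1) fixed, FALSE if it was lost.
run_to_absorption <- function(pop, max_gen = 1e6) {
  for (i in seq_len(max_gen)) {
    selection_drift_step(pop)
    if (length(pop$counts) == 1L)
      return(length(pop$muts[[1L]]) > 0L)
  }
  stop("no absorption within max_gen")
}
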