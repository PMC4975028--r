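test_that("a single genotype class is resampled to exactly N", {
  pop <- make_pop(tiny_params(N = 73), 73, list(c(0.2, 0.1)), list(integer(0)))
  set.seed(1)
  for (i in 1:5) selection_drift_step(pop)
  expect_identical(pop$counts, 73L)
  expect_length(pop$logw, 1L)
})

test_that("multinomial resampling has the fitness-weighted mean", {
  # equal fitness: expected counts stay at N/2
  set.seed(42)
  R <- 1e4
  focal <- numeric(R)
  for (i in seq_len(R)) {
    pop <- neutral_two_class_pop(N = 100, k_focal = 50)
    selection_drift_step(pop)
    k <- which(vapply(pop$muts, length, integer(1)) > 0)
    focal[i] <- if (length(k)) pop$counts[k] else 0L
  }
  se <- sqrt(100 * 0.25) / sqrt(R)
  expect_lt(abs(mean(focal) - 50), 3 * se)

  # 2:1 fitness ratio at 50/50: expected share 2/3
  set.seed(43)
  p <- tiny_params(N = 100, n = 1, m = 1, U = 0)
  z_fit <- 0                      # w = 1
  z_unfit <- sqrt(log(2))         # w = 1/2
  focal <- numeric(R)
  for (i in seq_len(R)) {
    pop <- make_pop(p, c(50, 50), list(z_unfit, z_fit), list(integer(0), 1L))
    selection_drift_step(pop)
    k <- which(vapply(pop$muts, length, integer(1)) > 0)
    focal[i] <- if (length(k)) pop$counts[k] else 0L
  }
  p_exp <- (50 * 1) / (50 * 1 + 50 * 0.5)
  se <- sqrt(100 * p_exp * (1 - p_exp)) / sqrt(R)
  expect_lt(abs(mean(focal) - 100 * p_exp), 3 * se)
})

test_that("a neutral lineage at count k fixes with probability k/N", {
  set.seed(7)
  R <- 1e4
  fixed <- logical(R)
  for (i in seq_len(R))
    fixed[i] <- run_to_absorption(neutral_two_class_pop(N = 100, k_focal = 10))
  se <- sqrt(0.1 * 0.9 / R)
  expect_lt(abs(mean(fixed) - 0.1), 3 * se)
})

test_that("without mutation the class count collapses to monomorphism", {
  set.seed(8)
  N <- 30
  for (rep in 1:200) {
    p <- tiny_params(N = N, n = 1, m = 1, U = 0, sigma2 = 0)
    # classes: one founder without id + N-1 single-id classes, all neutral
    pop <- make_pop(p, rep(1L, N), rep(list(0), N),
                    c(list(integer(0)), as.list(seq_len(N - 1))))
    stopifnot(length(pop$counts) == N)
    monotone <- TRUE
    for (g in seq_len(20 * N)) {
      prev <- length(pop$counts)
      selection_drift_step(pop)
      monotone <- monotone && length(pop$counts) <= prev
      if (length(pop$counts) == 1L) break
    }
    expect_true(monotone)                    # non-increasing under U = 0
    expect_identical(length(pop$counts), 1L)
  }
})

test_that("mutational input is Poisson with mean N*U", {
  set.seed(9)
  p <- fgm_params(n = 2, m = 2, sigma2 = 0.01, U = 0.001, N = 10000,
                  generations = 1)
  iters <- 2000
  pop <- make_pop(p, p$N, list(c(0, 0)), list(integer(0)))
  before <- integer(iters)
  for (i in seq_len(iters)) {
    n0 <- registry_size(pop$registry)
    mutation_step(pop)
    before[i] <- registry_size(pop$registry) - n0
    # reset to a single pristine class; registry keeps accumulating
    pop$counts <- p$N
    pop$logw <- 0
    pop$pheno <- list(c(0, 0))
    pop$muts <- list(integer(0))
  }
  lambda <- p$N * p$U
  se <- sqrt(lambda / iters)
  expect_lt(abs(mean(before) - lambda), 3 * se)
  expect_identical(sum(before), registry_size(pop$registry))
})

test_that("one individual can collect several mutations in one generation", {
  set.seed(10)
  p <- fgm_params(n = 2, m = 1, sigma2 = 0.001, U = 1, N = 20,
                  generations = 1)
  seen_multi <- FALSE
  for (try in 1:20) {
    pop <- make_pop(p, p$N, list(c(0, 0)), list(integer(0)))
    mutation_step(pop)
    expect_identical(sum(pop$counts), p$N)
    if (any(lengths(pop$muts) >= 2L)) { seen_multi <- TRUE; break }
  }
  expect_true(seen_multi)   # P(>=2 on someone) = 1 - (e^-U (1+U))^N, large at U = 1
})

test_that("U = 0 leaves a monomorphic population unchanged forever", {
  p <- fgm_params(n = 3, m = 3, sigma2 = 0.01, U = 0, N = 200,
                  generations = 50, seed = 12)
  sim <- fgm_simulate(p)
  expect_true(all(sim$mean_fitness$mean_w == sim$mean_fitness$mean_w[1]))
  expect_equal(sim$mean_fitness$mean_w[1], p$w0, tolerance = 1e-12)
  expect_true(all(sim$mean_fitness$n_segregating == 0L))
  expect_identical(nrow(sim$mutations), 0L)
  expect_identical(nrow(sim$fixation_events), 0L)
})

test_that("population size is conserved across many generations", {
  p <- fgm_params(n = 3, m = 2, E_S = -0.01, U = 0.01, N = 300,
                  generations = 1, seed = 13)
  pop <- fgm_population(p)
  sums <- integer(1000)
  for (g in 1:1000) {
    advance_generation(pop)
    sums[g] <- sum(pop$counts)
  }
  expect_true(all(sums == p$N))
  expect_identical(pop$generation, 1000L)
})

test_that("identical seeds give bit-identical simulation results", {
  p <- fgm_params(n = 4, m = 2, E_S = -0.015, U = 0.005, N = 250,
                  generations = 200, seed = 99)
  s1 <- fgm_simulate(p)
  s2 <- fgm_simulate(p)
  expect_identical(s1, s2)
  # and a different seed gives (generically) different dynamics
  p2 <- fgm_params(n = 4, m = 2, E_S = -0.015, U = 0.005, N = 250,
                   generations = 200, seed = 100)
  s3 <- fgm_simulate(p2)
  expect_false(identical(s1$mean_fitness, s3$mean_fitness))
})

test_that("generations = 0 returns only the initial census", {
  p <- fgm_params(n = 2, m = 2, sigma2 = 0.01, U = 0.01, N = 100,
                  generations = 0, seed = 5)
  sim <- fgm_simulate(p)
  expect_identical(nrow(sim$mean_fitness), 1L)
  expect_equal(sim$mean_fitness$mean_w, p$w0, tolerance = 1e-12)
  expect_identical(sim$generations_run, 0L)
})

test_that("class-based and individual-based engines agree on mean fitness", {
  # same model, two independently coded engines: compare mean fitness after
  # 50 generations across replicates (3-SE band on the difference)
  R <- 500
  w_class <- numeric(R)
  w_ref <- numeric(R)
  base <- list(n = 2, m = 2, sigma2 = 0.01, U = 0.05, N = 50,
               generations = 50)
  for (i in seq_len(R)) {
    p <- do.call(fgm_params, c(base, list(seed = fgm_child_seed(1234, i))))
    sim <- fgm_simulate(p, record_trajectories = FALSE)
    w_class[i] <- sim$mean_fitness$mean_w[51]
    p2 <- do.call(fgm_params, c(base, list(seed = fgm_child_seed(5678, i))))
    rp <- reference_population(p2)
    for (g in 1:50) reference_step(rp)
    w_ref[i] <- reference_mean_fitness(rp)
  }
  se <- sqrt(var(w_class) / R + var(w_ref) / R)
  expect_lt(abs(mean(w_class) - mean(w_ref)), 3 * se)
})

test_that("reference engine conserves N and reproduces trivial cases", {
  p <- fgm_params(n = 2, m = 1, sigma2 = 0.01, U = 0, N = 30,
                  generations = 5, seed = 3)
  rp <- reference_population(p)
  z0 <- rp$pheno[[1]]
  for (g in 1:5) reference_step(rp)
  expect_length(rp$pheno, 30L)
  # U = 0, identical individuals: the population cannot have changed
  expect_true(all(vapply(rp$pheno, identical, logical(1), z0)))
  expect_identical(rp$generation, 5L)
  expect_identical(registry_size(rp$registry), 0L)
})
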