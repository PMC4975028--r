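test_that("census sums carrier counts across classes and reports zeros", {
  p <- tiny_params(N = 10, n = 2, m = 2)
  pop <- make_pop(p, c(3, 4, 3),
                  list(c(0.1, 0), c(0.2, 0), c(0, 0.1)),
                  list(c(1L, 2L), 2L, integer(0)))
  cen <- census(pop)
  expect_identical(cen[["1"]], 3L)
  expect_identical(cen[["2"]], 7L)     # additive over classes
  # a registered id carried by no class is reported as 0
  fgmcohorts:::.reg_add(pop$registry, 0L, 1:2, c(0, 0), 0)
  cen <- census(pop)
  expect_identical(cen[["3"]], 0L)
  # monomorphic population carrying an id: count N
  pop2 <- make_pop(tiny_params(N = 25), 25, list(c(0, 0)), list(1L))
  expect_identical(unname(census(pop2)), 25L)
  # empty registry, no segregating mutations: empty census
  pop3 <- make_pop(tiny_params(N = 5), 5, list(c(0, 0)), list(integer(0)))
  expect_length(census(pop3), 0L)
})

test_that("fixation requires count exactly N; loss is count zero", {
  counts <- c(`1` = 50L, `2` = 49L, `3` = 0L)
  res <- detect_fixation_and_loss(counts, N = 50)
  expect_identical(res$newly_fixed, 1L)
  expect_identical(res$newly_lost, 3L)
  expect_error(detect_fixation_and_loss(c(`1` = 51L), N = 50),
               "exceeds population size")
  # simultaneous arrivals form one multi-mutation event
  res2 <- detect_fixation_and_loss(c(`4` = 20L, `7` = 20L, `9` = 3L), N = 20)
  ev <- make_fixation_event(100L, res2$newly_fixed)
  expect_identical(ev$cohort_size, 2L)
  expect_setequal(ev$mutation_ids, c(4L, 7L))
  expect_identical(ev$generation, 100L)
})

test_that("fixation events update registry statuses one way only", {
  reg <- new_registry()
  for (i in 1:3) fgmcohorts:::.reg_add(reg, 0L, 1L, 0, 0)
  detect_fixation_and_loss(c(`1` = 10L, `2` = 4L, `3` = 0L), N = 10,
                           registry = reg, generation = 7L)
  s <- registry_summary(reg)
  expect_identical(s$fate, c("fixed", "segregating", "lost"))
  expect_identical(s$fate_generation, c(7L, NA_integer_, 7L))
  expect_identical(reg$active, 2L)
  # a decided fate can never be re-decided
  expect_error(detect_fixation_and_loss(c(`1` = 10L), N = 10,
                                        registry = reg, generation = 9L),
               "non-segregating")
})

test_that("make_fixation_event returns NULL for no fixations", {
  expect_null(make_fixation_event(5L, integer(0)))
  expect_identical(make_fixation_event(5L, 3L)$cohort_size, 1L)
  expect_identical(make_fixation_event(5L, c(1L, 2L, 9L))$cohort_size, 3L)
})

test_that("pruning fixed mutations leaves the population unchanged", {
  p <- tiny_params(N = 10, n = 2, m = 2)
  # id 1 carried by every class; classes 1 and 3 become identical after prune
  pop <- make_pop(p, c(3, 4, 3),
                  list(c(0.1, 0), c(0.2, 0), c(0.1, 0)),
                  list(c(1L, 2L), 1L, c(1L, 2L)))
  w_before <- mean_fitness(pop)
  prune_fixed(pop, 1L)
  expect_identical(pop$fixed_ids, 1L)
  expect_false("1" %in% names(census(pop)))
  expect_identical(census(pop)[["2"]], 6L)
  expect_equal(mean_fitness(pop), w_before, tolerance = 1e-15)
  # classes {2} (counts 3 and 3) merged, {} (count 4) kept: N preserved
  expect_identical(sum(pop$counts), 10L)
  expect_identical(length(pop$counts), 2L)
  expect_identical(sort(pop$counts), c(4L, 6L))
  # pruning a non-fixed id is an internal-consistency error
  expect_error(prune_fixed(pop, 2L), "not fixed")
})

test_that("trajectory recording obeys cadence but never misses a fate", {
  counts <- c(`1` = 5L, `2` = 0L, `3` = 10L)
  # on the cadence grid: all carried ids plus the newly lost id
  r <- record_trajectories(counts, generation = 20L, cadence = 10L, N = 10,
                           newly_fixed = 3L, newly_lost = 2L)
  expect_identical(r$mutation_id, c(1L, 2L, 3L))
  expect_identical(r$frequency, c(0.5, 0, 1))
  # off the grid with no event: nothing
  r0 <- record_trajectories(counts, generation = 7L, cadence = 10L, N = 10)
  expect_identical(nrow(r0), 0L)
  # off the grid with an event: only the fated ids
  r1 <- record_trajectories(counts, generation = 7L, cadence = 10L, N = 10,
                            newly_fixed = 3L, newly_lost = 2L)
  expect_identical(r1$mutation_id, c(2L, 3L))
  expect_identical(r1$frequency, c(0, 1))
})

test_that("every mutation ends in exactly one fate and events are ordered", {
  p <- fgm_params(n = 3, m = 3, E_S = -0.02, U = 0.002, N = 400,
                  generations = 800, seed = 21)
  sim <- fgm_simulate(p)
  fates <- table(factor(sim$mutations$fate,
                        levels = c("segregating", "fixed", "lost")))
  expect_identical(sum(fates), nrow(sim$mutations))
  ev <- cohorts_along_walk(sim)
  expect_gt(nrow(ev), 0L)
  expect_true(all(diff(ev$generation) > 0))             # strictly increasing
  expect_false(anyDuplicated(sim$fixation_events$mutation_id) > 0)
  # fixed mutations and fixation-event members coincide
  expect_setequal(sim$fixation_events$mutation_id,
                  sim$mutations$mutation_id[sim$mutations$fate == "fixed"])
})

test_that("recorded trajectories confirm fixation is absorbing and final", {
  p <- fgm_params(n = 3, m = 3, E_S = -0.02, U = 0.002, N = 400,
                  generations = 800, seed = 22)
  sim <- fgm_simulate(p)
  fixed <- sim$mutations[sim$mutations$fate == "fixed", ]
  expect_gt(nrow(fixed), 0L)
  for (i in seq_len(nrow(fixed))) {
    tr <- sim$trajectories[sim$trajectories$mutation_id ==
                             fixed$mutation_id[i], ]
    # last record is at the fixation census with frequency exactly 1
    expect_identical(max(tr$generation), fixed$fate_generation[i])
    expect_identical(tr$frequency[which.max(tr$generation)], 1)
    # frequency 1 is first reached at the stamped fixation generation
    expect_identical(min(tr$generation[tr$frequency == 1]),
                     fixed$fate_generation[i])
  }
  # brute-force first-fixation scan of the trajectory table agrees with the
  # event log (recording cadence 1 makes the table exhaustive)
  at_one <- sim$trajectories[sim$trajectories$frequency == 1, ]
  expect_identical(min(at_one$generation),
                   sim$fixation_events$generation[1L])
  first_ids <- at_one$mutation_id[at_one$generation == min(at_one$generation)]
  first_ev <- sim$fixation_events[sim$fixation_events$cohort_id == 1L, ]
  expect_setequal(first_ids, first_ev$mutation_id)
  expect_identical(first_fixation_cohort_size(sim), nrow(first_ev))
})
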