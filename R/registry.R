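#' Create an empty mutation registry
#'
#' The registry records every mutation ever created in a run: its origin
#' generation, affected traits and effect sizes, its selection coefficient on
#' the background it arose in, and its fate (segregating, fixed or lost, with
#' the generation of fixation/loss). Status transitions are one-way —
#' `segregating -> fixed` or `segregating -> lost` — since the model has no
#' back mutation.
#'
#' Implemented as an environment with preallocated, doubling columns so that
#' appending stays O(1) amortized over runs creating hundreds of thousands of
#' mutations.
#'
#' @return An object of class `fgm_registry`.
#' @export
new_registry <- function() {
  reg <- new.env(parent = emptyenv())
  cap <- 256L
  reg$n <- 0L
  reg$origin <- integer(cap)
  reg$status <- integer(cap)      # 0 segregating, 1 fixed, 2 lost
  reg$fate_gen <- rep(NA_integer_, cap)
  reg$s_origin <- numeric(cap)
  reg$traits <- vector("list", cap)
  reg$deltas <- vector("list", cap)
  reg$active <- integer(0)        # ids currently segregating
  class(reg) <- "fgm_registry"
  reg
}

.reg_grow <- function(reg, need) {
  cap <- length(reg$origin)
  if (need <= cap) return(invisible(reg))
  new_cap <- cap
  while (new_cap < need) new_cap <- new_cap * 2L
  length(reg$origin) <- new_cap
  length(reg$status) <- new_cap
  fg <- reg$fate_gen; length(fg) <- new_cap; reg$fate_gen <- fg
  length(reg$s_origin) <- new_cap
  length(reg$traits) <- new_cap
  length(reg$deltas) <- new_cap
  invisible(reg)
}

# Append one mutation; returns its id. Internal helper.
.reg_add <- function(reg, gen, traits, deltas, s0) {
  .reg_add_batch(reg, gen, list(traits), list(deltas), s0)
}

# Append a batch of mutations sharing one origin generation; returns their
# ids. One call per generation keeps subassignment cost amortized.
.reg_add_batch <- function(reg, gen, traits_list, deltas_list, s0) {
  k <- length(traits_list)
  ids <- reg$n + seq_len(k)
  .reg_grow(reg, reg$n + k)
  reg$n <- reg$n + k
  reg$origin[ids] <- gen
  reg$status[ids] <- 0L
  reg$fate_gen[ids] <- NA_integer_
  reg$s_origin[ids] <- s0
  reg$traits[ids] <- traits_list
  reg$deltas[ids] <- deltas_list
  reg$active <- c(reg$active, ids)
  ids
}

#' Number of mutations ever created in a registry
#' @param reg An `fgm_registry`.
#' @return Integer count.
#' @export
registry_size <- function(reg) reg$n

#' Registry contents as a data frame
#'
#' @param reg An `fgm_registry`.
#' @return A data frame with one row per mutation: `mutation_id`,
#'   `origin_generation`, `fate` (`"segregating"`, `"fixed"` or `"lost"`),
#'   `fate_generation` (NA while segregating), `s_at_origin`, and list columns
#'   `trait_indices` and `deltas`.
#' @export
registry_summary <- function(reg) {
  stopifnot(inherits(reg, "fgm_registry"))
  k <- reg$n
  idx <- seq_len(k)
  out <- data.frame(
    mutation_id = idx,
    origin_generation = reg$origin[idx],
    fate = c("segregating", "fixed", "lost")[reg$status[idx] + 1L],
    fate_generation = reg$fate_gen[idx],
    s_at_origin = reg$s_origin[idx],
    stringsAsFactors = FALSE
  )
  out$trait_indices <- reg$traits[idx]
  out$deltas <- reg$deltas[idx]
  out
}

#' Per-mutation carrier counts in a population
#'
#' Counts, for every segregating mutation, the number of individuals whose
#' genotype carries it: the sum of class counts over the genotype classes
#' whose mutation set contains the id. Mutations known to the registry as
#' segregating but present in no class are reported with count 0.
#'
#' @param pop An `fgm_pop` population.
#' @return Named integer vector mapping mutation id to carrier count.
#' @export
census <- function(pop) {
  stopifnot(inherits(pop, "fgm_pop"))
  cen <- .census_fast(pop)
  act <- pop$registry$active
  zero <- setdiff(act, cen$ids)
  counts <- c(cen$counts, integer(length(zero)))
  ids <- c(cen$ids, zero)
  o <- order(ids)
  stats::setNames(as.integer(counts[o]), ids[o])
}

# Fast census: list(ids, counts) for mutations present in >= 1 class only.
.census_fast <- function(pop) {
  ids <- unlist(pop$muts, use.names = FALSE)
  if (!length(ids)) return(list(ids = integer(0), counts = integer(0)))
  agg <- rowsum(rep.int(pop$counts, lengths(pop$muts)), ids, reorder = TRUE)
  list(ids = as.integer(rownames(agg)), counts = as.integer(agg[, 1L]))
}

#' Detect fixation and loss from a census
#'
#' A mutation is newly fixed when its carrier count equals `N` (frequency 1)
#' and newly lost when its count is 0, at an end-of-generation census. When a
#' registry is supplied, statuses and fate generations are stamped in place.
#'
#' @param counts Named integer vector from [census()] (id -> carrier count).
#' @param N Population size.
#' @param registry Optional `fgm_registry` to update.
#' @param generation Census generation, required when `registry` is given.
#' @return List with integer vectors `newly_fixed` and `newly_lost`.
#' @export
detect_fixation_and_loss <- function(counts, N, registry = NULL,
                                     generation = NULL) {
  if (any(counts > N))
    stop("census count exceeds population size; internal inconsistency",
         call. = FALSE)
  ids <- as.integer(names(counts))
  fixed <- ids[counts == N]
  lost <- ids[counts == 0L]
  if (!is.null(registry)) {
    stopifnot(inherits(registry, "fgm_registry"), !is.null(generation))
    .reg_mark(registry, fixed, lost, as.integer(generation))
  }
  list(newly_fixed = fixed, newly_lost = lost)
}

# Stamp fates; only segregating ids may transition.
.reg_mark <- function(reg, fixed, lost, generation) {
  if (length(fixed)) {
    if (any(reg$status[fixed] != 0L))
      stop("fixation of a non-segregating mutation; internal inconsistency",
           call. = FALSE)
    reg$status[fixed] <- 1L
    reg$fate_gen[fixed] <- generation
  }
  if (length(lost)) {
    if (any(reg$status[lost] != 0L))
      stop("loss of a non-segregating mutation; internal inconsistency",
           call. = FALSE)
    reg$status[lost] <- 2L
    reg$fate_gen[lost] <- generation
  }
  if (length(fixed) || length(lost))
    reg$active <- setdiff(reg$active, c(fixed, lost))
  invisible(reg)
}

#' Build a fixation event from newly fixed ids
#'
#' A cohort is the set of mutations first reaching frequency 1 at the same
#' census; its size is the event's cohort size.
#'
#' @param generation Census generation of first arrival at frequency 1.
#' @param newly_fixed Integer vector of mutation ids (possibly empty).
#' @return `NULL` when no mutation fixed; otherwise a list
#'   `(generation, mutation_ids, cohort_size)` of class `fgm_fixation_event`.
#' @export
make_fixation_event <- function(generation, newly_fixed) {
  if (!length(newly_fixed)) return(NULL)
  structure(list(generation = as.integer(generation),
                 mutation_ids = as.integer(newly_fixed),
                 cohort_size = length(newly_fixed)),
            class = "fgm_fixation_event")
}

#' Prune fixed mutations into the population background
#'
#' A fixed mutation is carried by every individual, so removing its id from
#' every genotype class changes nothing observable: phenotypes (which already
#' include its effect) and counts are untouched. Classes that become
#' identical in their remaining segregating set are merged, summing counts.
#'
#' @param pop An `fgm_pop` population (modified in place).
#' @param newly_fixed Integer ids with carrier count `N` at the last census.
#' @return The population, invisibly.
#' @export
prune_fixed <- function(pop, newly_fixed) {
  stopifnot(inherits(pop, "fgm_pop"))
  if (!length(newly_fixed)) return(invisible(pop))
  cen <- .census_fast(pop)
  pos <- match(newly_fixed, cen$ids)
  if (anyNA(pos) || any(cen$counts[pos] != pop$params$N))
    stop("attempt to prune a mutation that is not fixed", call. = FALSE)
  pop$muts <- lapply(pop$muts, function(s) s[!(s %in% newly_fixed)])
  pop$fixed_ids <- c(pop$fixed_ids, as.integer(newly_fixed))
  # stamp fates for ids not already recorded by detect_fixation_and_loss
  still_open <- newly_fixed[pop$registry$status[newly_fixed] == 0L]
  if (length(still_open))
    .reg_mark(pop$registry, as.integer(still_open), integer(0),
              pop$generation)
  # merge classes whose segregating sets have become identical
  key <- vapply(pop$muts, function(s) paste(sort(s), collapse = ","), "")
  if (anyDuplicated(key)) {
    grp <- match(key, key)
    keep <- !duplicated(grp)
    merged <- as.integer(rowsum(pop$counts, grp, reorder = FALSE))
    pop$counts <- merged
    pop$logw <- pop$logw[keep]
    pop$pheno <- pop$pheno[keep]
    pop$muts <- pop$muts[keep]
  }
  invisible(pop)
}

#' Trajectory records for one census
#'
#' Emits `(generation, mutation_id, frequency)` rows for every mutation with
#' a positive carrier count when the generation falls on the recording
#' cadence. Generations at which a fixation or loss occurred are always
#' recorded (for the ids involved) regardless of cadence, so no fate is ever
#' missing from the output: a fixing mutation appears with frequency exactly
#' 1 and a lost one with frequency 0.
#'
#' @param counts Named integer census vector (id -> count).
#' @param generation Census generation.
#' @param cadence Recording cadence (>= 1).
#' @param N Population size.
#' @param newly_fixed,newly_lost Ids whose fate was decided this generation.
#' @return A data frame with columns `generation`, `mutation_id`,
#'   `frequency` (possibly zero rows).
#' @export
record_trajectories <- function(counts, generation, cadence, N,
                                newly_fixed = integer(0),
                                newly_lost = integer(0)) {
  stopifnot(cadence >= 1)
  ids <- as.integer(names(counts))
  if (generation %% cadence == 0L) {
    sel <- counts > 0L | ids %in% newly_lost
  } else {
    sel <- ids %in% c(newly_fixed, newly_lost)
  }
  data.frame(generation = rep.int(as.integer(generation), sum(sel)),
             mutation_id = ids[sel],
             frequency = as.numeric(counts[sel]) / N)
}
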