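#' Load and validate a run configuration
#'
#' Reads a plain-text configuration (YAML by `.yaml`/`.yml` extension, JSON
#' by `.json`) describing one replicate experiment, applies any overrides,
#' and validates everything at once: violations are collected and reported
#' together, not one at a time. Exactly one of `sigma2` and `E_S` must be
#' present; when `E_S` is given the derived `sigma2 = abs(E_S) / m` is stored
#' in the configuration (and later in the run manifest).
#'
#' Recognized keys: the [fgm_params()] fields (`n`, `m`, `sigma2`, `E_S`,
#' `U`, `N`, `w0`, `generations`, `record_every`, `seed`, `placement`) plus
#' `replicates` (>= 1), `out_dir` (output directory), `noise_variance`
#' (>= 0; Gaussian observation noise applied only to the exported noisy
#' trajectory table) and `emit` (named logical list switching individual
#' output tables on or off).
#'
#' @param path Path to a YAML or JSON configuration file, or `NULL` to build
#'   the configuration from `...` alone.
#' @param ... Overrides (or the full configuration when `path` is `NULL`);
#'   keys as above. Overrides take precedence over the file.
#' @return An object of class `fgm_run_config`: list with `params`
#'   (an `fgm_params`), `replicates`, `out_dir`, `noise_variance`, `emit`.
#' @examples
#' cfg <- load_run_config(NULL, n = 3, m = 3, E_S = -0.012, U = 0.001,
#'                        N = 1000, generations = 100, seed = 5,
#'                        replicates = 2, out_dir = tempdir())
#' @export
load_run_config <- function(path = NULL, ...) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("config file not found: ", path, call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    raw <- switch(ext,
      yaml = , yml = .read_yaml_config(path),
      json = jsonlite::fromJSON(path, simplifyVector = TRUE),
      stop("unsupported config format '.", ext, "' (use .yaml/.yml/.json)",
           call. = FALSE))
    if (!is.list(raw)) stop("malformed config file: ", path, call. = FALSE)
  }
  over <- list(...)
  raw[names(over)] <- over

  param_keys <- c("n", "m", "sigma2", "E_S", "U", "N", "w0", "generations",
                  "record_every", "seed", "placement")
  extra_keys <- c("replicates", "out_dir", "noise_variance", "emit")
  problems <- character(0)
  unknown <- setdiff(names(raw), c(param_keys, extra_keys))
  if (length(unknown))
    problems <- c(problems,
                  paste0("unknown key(s): ", paste(unknown, collapse = ", ")))

  params <- tryCatch(do.call(fgm_params, raw[intersect(names(raw), param_keys)]),
                     error = function(e) {
                       problems <<- c(problems, conditionMessage(e))
                       NULL
                     })

  replicates <- raw$replicates %||% 1L
  if (!is.numeric(replicates) || length(replicates) != 1L ||
      replicates < 1 || replicates != trunc(replicates))
    problems <- c(problems, "'replicates' must be a positive integer")
  noise_variance <- raw$noise_variance %||% 0
  if (!is.numeric(noise_variance) || length(noise_variance) != 1L ||
      !is.finite(noise_variance) || noise_variance < 0)
    problems <- c(problems, "'noise_variance' must be a finite number >= 0")
  emit <- list(mean_fitness = TRUE, trajectories = TRUE,
               trajectories_noisy = noise_variance > 0,
               fixations = TRUE, mutations = TRUE)
  if (!is.null(raw$emit)) {
    bad <- setdiff(names(raw$emit), names(emit))
    if (length(bad))
      problems <- c(problems,
                    paste0("unknown emit flag(s): ", paste(bad, collapse = ", ")))
    emit[names(raw$emit)] <- lapply(raw$emit, isTRUE)
  }

  if (length(problems))
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)

  structure(list(params = params,
                 replicates = as.integer(replicates),
                 out_dir = raw$out_dir %||% ".",
                 noise_variance = as.numeric(noise_variance),
                 emit = emit),
            class = "fgm_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML 1.1 interprets the bare scalars n/N/y/Y as booleans, which clobbers
# the parameter keys 'n', 'N' and 'U'-style single letters when used as map
# keys. Quote every mapping key before parsing so keys always stay strings.
.read_yaml_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^(\\s*)([A-Za-z_][A-Za-z0-9_]*)(\\s*):", '\\1"\\2"\\3:',
               lines)
  yaml::yaml.load(paste(lines, collapse = "\n"))
}

#' Run a configured replicate experiment and write its tables
#'
#' Runs `config$replicates` simulations with deterministic child seeds (see
#' [fgm_child_seed()]), writes all enabled result tables and a JSON manifest
#' to `config$out_dir`, and returns the simulation set. Rerunning with the
#' same configuration reproduces every table byte for byte (the manifest's
#' wall-time entry is the only field that varies).
#'
#' @param config An `fgm_run_config` from [load_run_config()].
#' @param ... Passed to [fgm_simulate()].
#' @return The `fgm_simset`, invisibly.
#' @export
run_replicates <- function(config, ...) {
  stopifnot(inherits(config, "fgm_run_config"))
  if (is.null(config$params$seed))
    stop("a master 'seed' is required for a replicate experiment",
         call. = FALSE)
  sims <- fgm_replicates(config$params, config$replicates, ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tables(sims, config$out_dir, noise_variance = config$noise_variance,
               emit = config$emit)
  manifest <- sims$manifest
  manifest$noise_variance <- config$noise_variance
  manifest$emit <- config$emit
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sims)
}

# 17 significant digits: doubles round-trip exactly through this format.
.fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_tsv <- function(cols, path) {
  n <- if (length(cols)) length(cols[[1L]]) else 0L
  lines <- paste(names(cols), collapse = "\t")
  if (n) {
    body <- do.call(paste, c(unname(cols), list(sep = "\t")))
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")  # fixed \n endings on every platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

#' Write result tables for a set of replicate runs
#'
#' Serializes a simulation set to tab-separated files with fixed column
#' orders: `mean_fitness.tsv` (replicate, generation, mean_w, max_w,
#' n_segregating), `trajectories.tsv` (replicate, generation, mutation_id,
#' frequency), optionally `trajectories_noisy.tsv` (the same table with
#' Gaussian observation noise of variance `noise_variance`, drawn from a
#' deterministic seed derived from the master seed so reruns are
#' byte-identical), `fixations.tsv` (replicate, generation, cohort_id,
#' cohort_size, mutation_id — one row per cohort member) and `mutations.tsv`
#' (replicate, mutation_id, origin_generation, fate, fate_generation,
#' trait_indices, deltas, s_at_origin; within-cell lists semicolon-joined).
#' All floating-point values are written with 17 significant digits, so a
#' read-back reproduces them exactly.
#'
#' @param x An `fgm_simset`.
#' @param out_dir Output directory (created if missing).
#' @param noise_variance Variance of the observation noise for the noisy
#'   trajectory table (0 disables the table unless explicitly enabled).
#' @param emit Named logical list selecting tables (see
#'   [load_run_config()]); `NULL` writes all applicable tables.
#' @return Invisibly, the character vector of files written.
#' @export
write_tables <- function(x, out_dir, noise_variance = 0, emit = NULL) {
  stopifnot(inherits(x, "fgm_simset"))
  if (is.null(emit))
    emit <- list(mean_fitness = TRUE, trajectories = TRUE,
                 trajectories_noisy = noise_variance > 0,
                 fixations = TRUE, mutations = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  sims <- x$sims
  rep_of <- function(field) rep.int(seq_along(sims),
                                    vapply(sims, function(s) nrow(s[[field]]),
                                           integer(1)))
  bindf <- function(field) do.call(rbind, lapply(sims, `[[`, field))

  if (isTRUE(emit$mean_fitness)) {
    mf <- bindf("mean_fitness")
    p <- file.path(out_dir, "mean_fitness.tsv")
    .write_tsv(list(replicate = rep_of("mean_fitness"),
                    generation = mf$generation,
                    mean_w = .fmt17(mf$mean_w),
                    max_w = .fmt17(mf$max_w),
                    n_segregating = mf$n_segregating), p)
    written <- c(written, p)
  }
  if (isTRUE(emit$trajectories) || isTRUE(emit$trajectories_noisy)) {
    tr <- bindf("trajectories")
    reps <- rep_of("trajectories")
    if (isTRUE(emit$trajectories)) {
      p <- file.path(out_dir, "trajectories.tsv")
      .write_tsv(list(replicate = reps, generation = tr$generation,
                      mutation_id = tr$mutation_id,
                      frequency = .fmt17(tr$frequency)), p)
      written <- c(written, p)
    }
    if (isTRUE(emit$trajectories_noisy)) {
      set.seed(fgm_child_seed(abs(x$master_seed) + 777667, 1L))
      trn <- add_observation_noise(tr, noise_variance)
      p <- file.path(out_dir, "trajectories_noisy.tsv")
      .write_tsv(list(replicate = reps, generation = trn$generation,
                      mutation_id = trn$mutation_id,
                      frequency = .fmt17(trn$frequency)), p)
      written <- c(written, p)
    }
  }
  if (isTRUE(emit$fixations)) {
    fx <- bindf("fixation_events")
    p <- file.path(out_dir, "fixations.tsv")
    .write_tsv(list(replicate = rep_of("fixation_events"),
                    generation = fx$generation, cohort_id = fx$cohort_id,
                    cohort_size = fx$cohort_size,
                    mutation_id = fx$mutation_id), p)
    written <- c(written, p)
  }
  if (isTRUE(emit$mutations)) {
    mu <- bindf("mutations")
    p <- file.path(out_dir, "mutations.tsv")
    .write_tsv(list(
      replicate = rep_of("mutations"),
      mutation_id = mu$mutation_id,
      origin_generation = mu$origin_generation,
      fate = mu$fate,
      fate_generation = ifelse(is.na(mu$fate_generation), "NA",
                               mu$fate_generation),
      trait_indices = vapply(mu$trait_indices, paste, "", collapse = ";"),
      deltas = vapply(mu$deltas,
                      function(d) paste(.fmt17(d), collapse = ";"), ""),
      s_at_origin = .fmt17(mu$s_at_origin)), p)
    written <- c(written, p)
  }
  invisible(written)
}

#' Read back a result table
#'
#' Parses a TSV written by [write_tables()]; numeric fields recover their
#' in-memory values exactly (17-significant-digit round trip).
#'
#' @param path Path to a `.tsv` file written by this package.
#' @return A data frame.
#' @export
read_fgm_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}
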