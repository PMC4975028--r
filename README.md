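# fgmcohorts

Forward-time simulation of **mutation cohorts** — sets of mutations that
segregate and reach fixation simultaneously — in asexual populations adapting
on **Fisher's geometric model** (FGM) under strong clonal interference.

## The model

Each individual is a point `z = (z_1, …, z_n)` in an `n`-dimensional trait
space with the optimum at the origin; fitness is a Gaussian function of the
distance to the optimum,

```
w(z) = exp(-Σ_i z_i²).
```

Generations are discrete Wright–Fisher: offspring counts are one multinomial
draw with probabilities proportional to `count × fitness` at fixed population
size `N`, followed by Poisson mutational input with genomic rate `U` per
individual per generation. A mutation alters `m` traits (the *pleiotropy*,
`m ≤ n`) chosen uniformly at random, adding an independent `Normal(0, σ²)`
deviate to each; the mean selection coefficient of a random mutation in an
optimum-resident genotype is

```
E(S) = -m σ²       (first order; exactly (1 + 2σ²)^(-m/2) - 1)
```

so the supply of beneficial versus deleterious mutations is controlled by
`E(S)`, `U`, `N`, and the dimensionalities `n` and `m`. With `NU ≫ 1` many
lineages compete (clonal interference) and mutations fix in cohorts: the
package censuses every mutation every generation, logs each fixation event
with the set of co-fixing mutation ids, and records per-mutation frequency
trajectories.

The population is represented by genotype classes (distinct sets of
segregating mutations) rather than individuals, so `N = 10⁴–10⁵` runs over
tens of thousands of generations are practical; a deliberately naive
individual-based engine is included as an independent cross-check and is used
in the test suite.

## Worked example

```r
library(fgmcohorts)

p <- fgm_params(n = 3, m = 3, E_S = -0.02, U = 0.001, N = 1000,
                generations = 500, seed = 7)
sim <- fgm_simulate(p)
sim
#> FGM Wright-Fisher run: n = 3, m = 3, sigma2 = 0.00666667 (E(S) = -0.02)
#>   N = 1000, U = 0.001, w0 = 0.5, placement random_direction, seed 7
#>   500 generations run; final mean fitness 0.9653 (10 segregating)
#>   4 fixation events, 5 mutations fixed, 537 created

summary(sim)$cohort_sizes
#> [1] 2 1 1 1
```

Over 500 generations this population climbed from fitness 0.5 to 0.965; of
537 mutations that arose, 5 fixed in 4 events — the first event was a cohort
of 2 mutations fixing in the same generation. `plot(sim, "trajectories")`
draws the per-mutation frequency paths (add `noise_variance = 0.02` to mimic
sequencing noise), `plot(sim, "cohorts")` the cohort sizes along the walk.

Replicate experiments with deterministic per-replicate seeds:

```r
rs <- fgm_replicates(p, 100, record_trajectories = FALSE)
cohort_size_distribution(rs)   # first-fixation cohort size histogram
mean_fitness_series(rs)        # across-replicate fitness dynamics
```

`run_replicates(load_run_config("config.yaml"))` runs a configured experiment
and writes `mean_fitness.tsv`, `trajectories.tsv`, `fixations.tsv`,
`mutations.tsv` and a manifest; `inst/cli/fgm-sim.R` is a thin command-line
wrapper (`run`, `summarize`) over the same functions.

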