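---
title: "Simulating mutation cohorts on Fisher's geometric landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mutation cohorts on Fisher's geometric landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmcohorts)
```

## The model and its assumptions

Evolve-and-resequence experiments with microbes routinely show *mutation
cohorts*: groups of mutations that rise in frequency together and fix
simultaneously. This package simulates the simplest phenotypic model that
produces such dynamics — Fisher's geometric model (FGM) — forward in time
under a Wright–Fisher regime of strong clonal interference, tracking every
mutation individually from origin to fixation or loss.

An individual is a phenotype $z \in \mathbb{R}^n$; the optimum sits at the
origin and fitness is Gaussian in the distance to it,
$w(z) = \exp(-\sum_i z_i^2)$. Each generation:

1. **Selection and drift.** Offspring counts are a single multinomial draw
   with $N$ trials and class probabilities proportional to
   $\text{count} \times w$. $N$ is strictly constant.
2. **Mutation.** The number of new mutations is Poisson($NU$); each lands on
   a uniformly chosen newborn, which is equivalent to independent
   Poisson($U$) draws per individual (so one individual can gain several
   mutations in a generation). A mutation adds independent
   $\mathcal{N}(0, \sigma^2)$ deviates to $m$ of the $n$ traits, chosen
   uniformly without replacement; its action on the phenotype is additive,
   the standard geometric-model convention. There is no back mutation, no
   recombination, and every mutation event is a unique lineage marker
   (infinite-sites at the lineage level).

The census runs after mutation, on the population that begins the next
generation. A mutation whose carrier count reaches exactly $N$ is *fixed*;
all mutations first reaching count $N$ at the same census form one fixation
event — a cohort. Fixed mutations are pruned into a background set: since
every individual carries them, removing the ids from every genotype class
changes nothing observable, and classes whose remaining sets coincide are
merged. A count of zero is *loss*; both fates are absorbing.

The model deliberately omits frequency-dependent selection, ecology,
recombination and mutator dynamics; it is a null model asking how much
cohort structure clonal interference alone produces.

## Parameters

| parameter | meaning | default / convention |
|---|---|---|
| `n` | traits under selection (complexity) | — |
| `m` | traits altered per mutation (pleiotropy), $1 \le m \le n$ | `n` |
| `sigma2` | per-trait variance of mutational effects | — |
| `E_S` | mean selection coefficient at the optimum, $-m\sigma^2$ | alternative to `sigma2` |
| `U` | genomic mutation rate / individual / generation | 0.001 (microbial order of magnitude) |
| `N` | population size | $10^4$ |
| `w0` | initial fitness | 0.5 |
| `record_every` | trajectory recording cadence (generations) | 1 |
| `placement` | initial-phenotype placement rule | `"random_direction"` |

Exactly one of `sigma2` and `E_S` may be given; `E_S` is converted by
$\sigma^2 = |E(S)|/m$. The first-order relation $E(S) = -m\sigma^2$ is
accompanied by the exact mean multiplicative factor
$(1+2\sigma^2)^{-m/2}$ (`expected_fitness_factor()`), which follows from the
moment-generating function of a chi-square variable; at $\sigma^2 = 0.004$,
$m = 3$ the two differ by under 1%.

## Initial placement: why the default is a random direction

The initial fitness fixes only the distance $d = \sqrt{\ln(1/w_0)}$ from the
optimum, not the direction. Under full pleiotropy ($m = n$) the model is
isotropic and the direction is irrelevant. Under partial pleiotropy it is
not: mutations act on $m$ *coordinate axes*, so concentrating the whole
displacement on one axis (placement `"axis"`) makes the landscape's hardest
direction coincide with a single trait. Only the fraction $m/n$ of mutations
can then touch the displaced trait, but those that do carry an
unrealistically large radial effect ($\approx 2d\delta$), producing rare,
strong, fast sweeps. Spreading the displacement uniformly over a random
direction gives every trait displacement $\sim d/\sqrt{n}$, so every
mutation has a small radial component — many weak, slow, interfering
sweeps. At high dimensionality (large $n$, small $m$) the axis placement
therefore produces markedly faster first fixations, at odds with the slow
adaptation expected of high-dimensional landscapes; only the
random-direction start shows the long waiting times that the test suite
checks. `"random_direction"` is therefore the default; `"axis"` remains
available for studying the anisotropic corner case.

## Numerical choices

* Selection weights are computed from cached log-fitness with a max-shift
  before exponentiation, so genotypes far from the optimum never underflow.
* Fixation is carrier count exactly $N$ at an end-of-generation census — the
  only unambiguous definition at finite $N$; cohort membership is defined
  solely by simultaneous first arrival at count $N$. Fixations in adjacent
  generations are distinct events.
* Trait indices are 1-based throughout, the R convention.
* Replicate $r$ of a replicate set uses the child seed
  $(\text{master} + 1000003\,r) \bmod p$ with $p$ the largest prime below
  $2^{31}$: adding replicates never perturbs earlier ones, and every derived
  seed is a valid 32-bit integer.
* Tables are written as TSV with 17 significant digits, so numeric fields
  round-trip exactly; reruns from the same configuration are byte-identical
  (observation noise for the exported noisy table is drawn from a
  deterministic offset stream of the master seed).
* Gaussian observation noise (variance 0.02 mimics sequencing error in
  frequency estimates) is applied only to output tables and plots, clipped
  to $[0,1]$, and never fed back into the simulation.

## What the engine's bookkeeping buys

The population is stored as genotype classes — distinct sets of segregating
mutation ids with a cached phenotype and log-fitness — rather than $N$
individuals. All per-generation work is then $O(\text{classes})$, which at
$NU \approx 10$ stays in the hundreds even for $N = 10^5$. The package also
ships a naive individual-based engine (`reference_population()`,
`reference_step()`) that implements the same model with per-individual
parent sampling and per-individual Poisson mutation. The two are
distributionally identical by construction, and the test suite checks this
on small instances: the carrier-count distribution of a focal beneficial
mutation after 10 generations at $N = 50$ (chi-square two-sample test), and
across-replicate mean fitness after 50 generations (3-standard-error band).

## Scales used in the tests

The headline experiments behind this model family run to $10^5$ individuals,
100 replicates and 30,000 generations; the test suite reproduces the same
qualitative surfaces at desk scale, with fixed seeds and 20–30 replicates
per condition:

* **Mean-effect recovery.** $10^6$ mutations applied to an optimum-resident
  parent recover $E(S) = -0.012$ (at $n=10$, $m=3$, $\sigma^2=0.004$) within
  Monte-Carlo error of the exact $(1+2\sigma^2)^{-3/2}-1$.
* **High-dimensionality waiting times.** At $n = 500$, $m = 3$, $N = 10^4$,
  $U = 0.001$, $E(S) = -0.001$, the median first-fixation generation across
  replicates exceeds 2,000.
* **Cohort trends.** At $N = 2000$: raising $U$ from $10^{-4}$ to $10^{-2}$
  shifts first-fixation cohort sizes up (means $\approx 1$ versus
  $\approx 2.5$); shrinking $|E(S)|$ from 0.1 to 0.001 at $U = 10^{-2}$
  shifts them up (means $\approx 2$ versus $\approx 3.5$); and deep into a
  walk (beyond generation 900 of an $N = 2000$, $U = 0.01$ run) cohorts
  under $E(S) = -0.003$ remain large while those under $E(S) = -0.1$ have
  shrunk.

On that last point: the claim "cohort sizes shrink along the walk, faster
for strong effects" is tested as a cross-condition contrast at a fixed late
time rather than as a within-condition early-versus-late comparison. With
strong effects the approach phase is so short that few fixation events fall
in it, and the rare fixations near the drift-load equilibrium are often
compensatory pairs (a deleterious mutation co-fixing with a compensating
one), which makes within-condition averages noisy at desk scale. The
scale-robust signature of the faster shrink is that, at the same late walk
time, weak-effect walks still fix large cohorts and strong-effect walks do
not.

## What the synthetic conditions do and do not show

All inputs are parameters; no biological data enters the simulations. The
generator reproduces the *mechanisms* behind cohort dynamics — clonal
interference, hitchhiking, simultaneous fixation — under Gaussian isotropic
trait effects, a static optimum and strict asexuality. Passing tests
therefore show that the implementation is a correct Wright–Fisher/FGM
sampler at the stated parameters; they do not show that real populations
satisfy FGM's assumptions (real adaptation involves frequency dependence,
ecology, mutators and recombination, all deliberately outside this model).

## Known limitations

* Census cost grows with the number of segregating lineages, so very large
  $NU$ (≫ 100) runs are slow in this pure-R engine.
* Runs are single-threaded; replicate-level parallelism is left to the
  caller.
* Cohort *inference* from noisy frequency trajectories (clustering of
  co-moving mutations, as done for experimental data) is out of scope: the
  simulator knows true cohort membership and emits it directly.
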