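# gcies — gene-circuit reverse engineering with island Evolution Strategies

`gcies` infers gene regulatory networks from quantitative spatial
expression data by fitting connectionist **gene-circuit** ODE models, the
approach used for the *Drosophila* gap-gene system, with a
(μ, λ) **island Evolution Strategy** in serial, synchronous-parallel and
asynchronous buffered forms, a simplified simulated-annealing baseline,
and the benchmarking metrics used to compare such optimisers. It is aimed
at computational biologists studying spatio-temporal network inference
and at anyone benchmarking population-based global optimisers on ODE
parameter-estimation problems.

## The model and the fit

Protein concentrations $g_i^a$ of $N_g$ gene products in a row of nuclei
$i$ obey

$$\frac{dg_i^a}{dt} = R^a\,\Phi\!\Big(\sum_b W^{ab} g_i^b + m^a\,\mathrm{bcd}_i + h^a\Big) + D^a(n)\big[(g_{i-1}^a - g_i^a) + (g_{i+1}^a - g_i^a)\big] - \lambda^a g_i^a,$$

with $\Phi(u) = \frac12(u/\sqrt{u^2+1} + 1)$, Bcd an external maternal
input, zero-flux diffusion boundaries, and a mitotic schedule that
switches production off during mitosis and doubles the nuclei (and
quadruples $D$, since internuclear distance halves) at each division.
The signed weights $W^{ab}$ are the network: positive = activation,
negative = repression.

Fitting minimises the summed squared difference between simulated and
observed per-nucleus concentrations, subject to hard bounds
($10 < R^a < 30$, $0 < D^a < 0.3$, half-lives between 5 and 20 min) and
a soft penalty that is zero while each gene's worst-case regulatory
input stays inside a band set by $\Lambda = 10^{-4}$. The optimiser is a
(μ, λ)-ES with stochastic-ranking constraint handling
($P_f = 0.45$), intermediate recombination (χ = 0.85), non-isotropic
self-adaptive mutation with exponentially smoothed step sizes
(α = 0.2), and island migration every 200 generations — defaults
matching the standard gap-gene configuration (λ = 125, μ = 25). The
synchronous parallel mode is bit-identical to the serial mode for the
same seed; the asynchronous mode exchanges migrants through capped
buffers under a deterministic virtual-time scheduler. See the methods
vignette (`vignettes/gene-circuit-methods.Rmd`) for the full model,
operator and design documentation.

## Worked example

Simulate a known 2-gene mutual-repression circuit, score its own
parameters, then re-fit from scratch with a 2-island synchronous ES:

```r
library(gcies)

truth   <- toy_circuit_2g()                       # known ground truth
dataset <- simulate_dataset(truth, noise_sd = 0)  # FlyEx-style table
dataset
#> Expression data set: 2 genes ( geneA, geneB ) at time classes 0, 10, 30, 40 min
#>    48 observations; 4 nuclei at the initial time class

theta <- pack_parameters(truth$params, truth$space)
E  <- objective_E(theta, dataset, truth$schedule, truth$space)
Pi <- penalty_regulatory(theta, dataset$gene_maxima, dataset$bcd_max)
sprintf("E(truth) = %.3g   penalty = %g", E, Pi)
#> "E(truth) = 0.0101   penalty = 0"

problem <- circuit_problem(dataset, truth$schedule, truth$space)
cfg <- es_config(lambda_pop = 20, mu = 4, migration_interval = 100,
                 log_interval = 100, max_generations = 1000)
fit <- run_ies(problem, cfg, mode = "sync", n_islands = 2, seed = 1)
sprintf("best E after %d generations: %.4g", fit$generations,
        fit$best$fitness)
#> "best E after 1000 generations: 278.5"
```

`E(truth) ≈ 0.01` is the solver-tolerance floor of a perfect fit (the
data sum of squares is ≈ 1.4 × 10⁵, so this is a relative residual of
~10⁻⁷); the 1000-generation fit reaches E ≈ 278, a relative residual of
0.2%, and longer multi-island runs drive it below 10⁻³ of the data sum
of squares (see the recovery experiment below). Logs feed the metrics
layer directly:

```r
time_to_target(list(fit$log), target = 0.01 * problem$data_ss,
               time_col = "generation")
#> Target 1407.53: 1/1 runs reached (rate 1.00, 95% CI 0.025-1.000)
#>   mean time 100 (SE 0, 95% CI 100-100)
```

A thin command-line wrapper covers the same workflow from a shell
(`inst/cli/gcies.R`): `gen-data`, `simulate`, `evaluate`,
`fit --algorithm ies|pies-sync|pies-async|sa`, and `metrics` over a
directory of run logs. All file formats are '#'-commented TSV
(expression tables, parameter files, run logs) plus a YAML run
configuration; every output carries a seed/version metadata header.

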