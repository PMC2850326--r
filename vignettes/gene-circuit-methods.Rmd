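---
title: "Gene-circuit reverse engineering with island Evolution Strategies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-circuit reverse engineering with island Evolution Strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcies)
```

# The model

`gcies` fits connectionist gene-circuit models to quantitative spatial
gene-expression data, the formalism used for the *Drosophila* gap-gene
system. The state variables are protein concentrations $g_i^a$ of $N_g$
gene products in a one-dimensional row of $N_{nuc}$ nuclei along the
antero-posterior axis. Each concentration obeys

$$
\frac{dg_i^a}{dt} \;=\; R^a\,\Phi(u_i^a)
\;+\; D^a(n)\left[(g_{i-1}^a - g_i^a) + (g_{i+1}^a - g_i^a)\right]
\;-\; \lambda^a g_i^a ,
$$

with total regulatory input

$$
u_i^a \;=\; \sum_b W^{ab} g_i^b \;+\; m^a\,\mathrm{bcd}_i \;+\; h^a .
$$

The three terms are production, Fickian diffusion between neighbouring
nuclei, and first-order decay. $W^{ab}$ is the genetic interconnectivity
matrix (positive = activation, negative = repression, near zero =
absence of an interaction); Bcd is the maternal Bicoid gradient, an
external input with regulatory weight $m^a$; $h^a$ is a threshold
summarising ubiquitous maternal factors; $R^a$ is the maximum production
rate; $\lambda^a$ the decay rate, so each product's half-life is
$\ln 2/\lambda^a$. The regulation-expression function is the bounded,
strictly increasing sigmoid

$$
\Phi(u) = \tfrac12\!\left(\frac{u}{\sqrt{u^2+1}} + 1\right),
$$

with $\Phi(0) = 1/2$ and limits 0 and 1. A logistic alternative can be
selected through `gene_circuit_params(..., sigmoid = "logistic")`; the
ratio form is the default because it is the classical choice of the
gene-circuit formalism.

## The mitotic schedule

Development is modelled by three rules over a user-specified
`mitotic_schedule()`: during **interphase** the full equation applies;
during **mitosis** the production term is set exactly to zero; at an
instantaneous **division** every nucleus splits in two, daughters copy
the mother's concentrations, and the division counter $n$ increments.
Because internuclear distance halves at each division and diffusion
scales with the inverse square of distance, the effective diffusion rate
quadruples: $D^a(n) = 4\,D^a(n-1)$. Bcd is an external input rather
than a state variable, so each division epoch carries its own Bcd
profile, supplied by the data set or fixture. An output time that
coincides with a division instant reports the post-division state, which
matches the rule ordering (apply the discrete rule, then resume
integration).

Boundary conditions are zero-flux at both ends of the nuclear row. With
production off and no decay, diffusion then conserves per-gene mass,
which the test suite checks to solver tolerance.

The packaged two-cycle toy schedule (interphase 0–16 min, mitosis 16–21,
division at 21, interphase 21–40) is deliberately small; the exact
published gap-gene cleavage-cycle timetable is not reproduced, and any
schedule can be supplied.

## Numerical integration

The reference solver is a Bulirsch–Stoer scheme (modified midpoint with
Richardson extrapolation in the squared substep, up to eight
extrapolation levels) with adaptive macro-steps. A step is accepted when
the difference between the two highest extrapolation columns is below
`rtol` on the scale $|y| + 1$ taken at the step start — i.e. the
tolerance is relative to the current concentration magnitude with a unit
absolute floor, the convention of classical Bulirsch–Stoer
implementations. Consequences worth knowing:

* The default tolerance is `rtol = 1e-3`, configurable everywhere. At
  that tolerance one objective evaluation of the 2-gene toy costs tens
  of microseconds, which is what makes million-evaluation optimiser runs
  practical.
* Error is controlled per step at the step-start scale; over an interval
  with strong decay the error relative to the (much smaller) final value
  is correspondingly larger. The solver-fidelity tests therefore measure
  error on the controller's own scale.
* The first macro-step attempt spans the whole interval; the controller
  shrinks it as needed. A step-count budget (100 000 macro-steps per
  interval) turns pathologically stiff parameter sets — which global
  search inevitably proposes — into a clean failure, which the objective
  reports as an infinite value rather than an abort.
* Tiny negative concentrations produced by extrapolation are clamped to
  zero when states are returned to R.

# The objective and the search space

The objective $E(\theta)$ is the unweighted sum of squared differences
between model output and data over all observed (time class, gene,
nucleus) cells. The earliest time class serves as the initial condition
and is excluded from the sum (it would contribute exactly zero). No
per-gene weighting is applied.

The parameter vector packs, in order, the rows of $W$, then $m$, the
free entries of $h$, then $R$, $D$, $\lambda$: $n = N_g(N_g+5)$
parameters when all thresholds are free (66 for the 6-gene circuit).
Thresholds may be pinned per gene at $-2.5$; pinning four of six (the
trunk gap genes, leaving the two strongly maternally-driven genes free)
gives the 62-parameter configuration, and pinning all six gives
$N_g(N_g+4) = 60$. `search_space(h_fixed = )` accepts `NULL`, a scalar,
or a per-gene vector with `NA` marking free entries to express all
three.

## Hard bounds

Production, diffusion and decay rates have strict box constraints:
$10 < R^a < 30$, $0 < D^a < 0.3$, and half-lives $5 < \ln 2/\lambda^a <
20$ minutes. Any violating vector is unacceptable: inside the ES it is
kept in the population but cached with infinite fitness and penalty, so
it ranks last without biasing step-size self-adaptation by resampling;
inside the annealer the move is rejected outright.

## Soft penalty on regulatory parameters

Regulatory weights should not run off along the saturated arms of the
sigmoid. The penalty used here is, per gene,
$$
\Pi(\theta) = \sum_a \max\!\left(0,\; \Lambda\,(u^a_{cap})^2 - 1\right),
\qquad
u^a_{cap} = \sum_b |W^{ab}|\,v_{max}^b + |m^a|\,bcd_{max} + |h^a|,
$$
where $v^b_{max}$ is the maximum observed intensity of gene $b$ in the
data and $\Lambda = 10^{-4}$ the control parameter. $u^a_{cap}$ bounds
the total regulatory input attainable over the observed data range, so
$\Pi$ is exactly zero while every gene's worst-case input stays inside
the band $|u| \le 1/\sqrt{\Lambda}$, is continuous, and grows
quadratically once any regulatory parameter scales beyond it. Tying the
band and the slope to the single control parameter $\Lambda$ keeps the
design one-knob; the penalty never depends on $R$, $D$ or $\lambda$.
This explicit algebraic form is this package's design (the qualitative
contract — zero inside a threshold band on total regulatory input,
steeply rising outside, controlled by $\Lambda$ — is what it
implements).

# The (μ, λ) island Evolution Strategy

Each island holds $\lambda$ individuals (default 125) and selects $\mu =
\lambda/5$ parents per generation by **stochastic ranking**: a
bubble-sort-like pass structure of $\lambda$ sweeps over adjacent pairs
with early exit. A pair with both penalties $\le 0$ is compared by
fitness; when the upper individual's penalty is positive the comparison
uses fitness with probability $P_f = 0.45$ and penalty otherwise. The
case "upper feasible, lower infeasible" is not covered by the published
rule; here it compares by penalty, deterministically keeping the
feasible individual on top. That choice also means ranking a fully
feasible population consumes no random draws — which the determinism
guarantees below exploit — and reduces exactly to a fitness sort.

Offspring are produced as $\lambda-\mu$ direct copies of the parents
(each parent copied $(\lambda-\mu) \div \mu$ times, the fittest parents
receiving the remainder) plus $\mu$ recombinants. Parent $k$'s
recombinant combines its own vector with the next-fittest parent's and
the overall fittest parent's,
$x' = \chi x_k + (1-\chi)\,(x_{k+1} + x_1)/2$ with $\chi = 0.85$; the
worst parent's "next fittest" wraps to the fittest so the operator is
total. Any affine combination with these three inputs satisfies the
identical-parents identity, which is the portable invariant the tests
pin. Recombinants inherit the primary parent's step sizes and are not
mutated.

The copies undergo non-isotropic self-adaptive mutation: with
$\tau_g = \varphi^*/\sqrt{2n}$ and $\tau_l = \varphi^*/\sqrt{2\sqrt n}$
(Schwefel's rates, $\varphi^* = 1$),

$$
\sigma'_{ij} = \sigma_{ij}\, e^{\tau_g N_i + \tau_l N_{ij}}, \qquad
\theta'_{ij} = \theta_{ij} + \sigma'_{ij}\,N'_{ij},
$$

followed by exponential smoothing of the retained step sizes,
$\sigma \leftarrow \alpha\,\sigma' + (1-\alpha)\,\sigma$ with $\alpha =
0.2$, which damps fluctuation at the cost of slower late-stage
adaptation. All normal deviates are drawn fresh each generation. Initial
populations sample kinetic parameters uniformly inside their open hard
bounds and regulatory parameters uniformly in $[-L, L]$ with $L$ sized
from the data maxima so the penalty is zero at initialisation; initial
step sizes are 10% of each parameter's sampled range (self-adaptation
corrects this choice quickly).

## Islands, migration and parallel semantics

Every $m$ generations (default 200) each island's best individual is
copied into another island chosen uniformly at random (never itself),
replacing the receiver's worst individual; an island chosen by several
senders loses its several worst. Bests are snapshotted before any
replacement, so the rule reads as a simultaneous exchange.

Three execution modes share one engine:

* **serial** — islands advance round-robin in one process;
* **sync** — models the synchronous parallel algorithm: a master stream
  draws the migration schedule, islands exchange under barrier
  semantics. Because the barrier changes nothing algorithmic, sync runs
  are bit-identical to serial runs with the same seed — the package
  treats this determinism guarantee as a hard, tested property;
* **async** — islands run under a deterministic virtual-time scheduler
  with buffered exchange: at a migration point an island deposits its
  best into the chosen receiver's buffer (deposit first, then absorb),
  absorbs everything in its own buffer into the population (transiently
  $\lambda + k$, restored at the next selection) and clears it. A sender
  may leave at most 10 migrants in any one buffer and 50 messages in the
  master's statistics buffer; full buffers defer the deposit, never drop
  it, and the run returns message-conservation counters so tests can
  prove nothing was lost. Per-island start lags emulate heterogeneous
  node speed. True process-based concurrency (the original setting is
  MPI on a cluster) is deliberately not exercised: the asynchronous
  semantics live in the buffers, not the wall clock.

RNG discipline makes all this reproducible: island $i$ evolves on its
own stream (`seed + i`); migration receiver draws come from a dedicated
master stream in serial/sync and from per-island migration streams in
async, so island streams consume identical sequences in every mode. With
a fully feasible population (e.g. the unconstrained sphere toy used in
tests) stochastic ranking draws nothing, and a zero-lag async run is
bit-identical to the sync run on two islands. With hard-bound violations
present the ranking of a $\lambda+k$ transient population can consume a
different number of draws than the $\lambda$-sized sync population, so
bit-equality across async/sync is only claimed for penalty-free
problems; sync–serial bit-equality holds unconditionally.

Wall-clock stamps in run logs come from an injectable clock; tests and
the acceptance script use a virtual clock (elapsed = generation) so logs
are bit-comparable. The recorded `best_objective` series is the running
best-so-far across all islands (non-increasing by construction), logged
every $\tau = 20$ generations, where termination is also checked: either
a fixed generation count (40 000 by default) or "threshold hold" (best
$\le E^*$ for $\rho$ consecutive checks).

# The simulated-annealing baseline

The baseline implements exactly the elements that define the family:
Metropolis acceptance on the energy $E + \Pi$ (downhill always, uphill
with probability $e^{-\Delta E/T}$ — the standard sign convention; a
printed form with a positive exponent would exceed one), Boltzmann
mixing of the $K$ chains' states every $m$ iterations (each chain is
independently reassigned state $i$ with probability $\propto
e^{-E_i/T}$, computed shifted by the minimum energy; assignment, never
averaging), an initial burn of $n_{init}$ iterations at constant $T_0$,
and the freeze stopping rule (relative change of the best energy below a
set fraction for a set number of checks). The adaptive Lam temperature
schedule and its running statistical estimators are intentionally out of
scope; a geometric cooling schedule and acceptance-ratio-targeted
Gaussian proposal scales stand in, and both stand-ins are labelled as
such. Runs with this baseline support qualitative comparisons
(descent-curve shape, freeze behaviour), not quantitative reproduction
of published annealing timings.

# Synthetic fixtures and what they do (and do not) show

`make_toy_circuit()` and the canonical `toy_circuit_2g()` generate
ground-truth circuits whose kinetic parameters sit inside the open hard
bounds and whose regulatory weights follow a mutual-repression motif
small enough that the worst-case regulatory input stays in the
penalty-free band. `simulate_dataset()` integrates the truth at high
accuracy (`rtol = 1e-6`), samples all nuclei and genes at the time
classes (default 0, 10, 30, 40 minutes over the two-cycle schedule) and
adds independent Gaussian noise clipped at zero; the earliest class is
the noise-free initial condition, so at zero noise the truth scores
$E \approx 0$ and at noise level $s$ it scores approximately $M s^2$
over $M$ observed cells (exactly: the clipped-Gaussian second moment,
which the tests use as the oracle). The Bcd input is an exponential
gradient over the 35–92% egg-length window with amplitude 120 and length
scale 20 percent-egg-length — a shape chosen to resemble the published
gradient's range, not a fit to it.

The canonical recovery experiment fits the zero-noise 2-gene, 4-nucleus
toy with 4 islands of $\lambda = 20$ ($\mu = 4$), migration every 100
generations, and a cap of 8000 generations per run with threshold-hold
early stopping at the success level ($E < 10^{-3}\times$ the data sum of
squares): runs that reach the target stop there, mirroring
time-to-target benchmarking, and the equal-budget random-search baseline
receives exactly the evaluations the ES consumed. These sizes were fixed
after pilot runs as a configuration whose budget is genuinely generous
for this landscape; the small toy is multimodal, and single small
populations reliably stall in compensating local optima — the island
structure is what rescues reliability, neatly recapitulating at desk
scale why island models are used at all. What passing recovery shows is
that the full stack (simulator, objective, constrained ES, logging)
can drive the residual to the solver-noise floor on data generated by
the model family itself; it does not show identifiability of individual
parameters (sign agreement of recovered $W$ is reported but typically
partial — several near-equivalent circuits fit 2-gene data), and it says
nothing about model error on real embryo data, which has registration
artefacts, non-Gaussian noise and out-of-model biology.

# Performance metrics

Run logs (generation, elapsed seconds, best objective) feed the
benchmarking suite: mean descent curves with standard errors and
empirical 95% ranges; time-to-target at the conventional "good"
($E^* = 350\,000$) and "good-enough" ($E^* = 550\,000$) levels of the
6-gene problem, with the mean and SE computed over the runs that reached
the target (the SE denominator is the number of reaching runs — the
statistically coherent reading of the published prose, which names the
number of attempts) and the success rate given an exact Clopper–Pearson
binomial interval (the published description says only "using the
binomial distribution"); and parallel speed-up. Relative speed-up
divides the mean serial time with $K$ islands by the mean parallel time
on $K$ nodes (communication overhead); absolute speed-up divides the
best serial configuration's time ($K^* = 1$ island) by the parallel time
(practical gain). Confidence intervals for these ratios use Fieller's
theorem for ratios of independent Gaussian means (zero covariance —
separate run sets), returning an unbounded interval when the denominator
is not significantly nonzero.

The packaged benchmark table ships the previously reported wall-clock
means ("H:MM") and printed half-widths for the serial island-ES at 1–50
islands and both parallel variants at 10–50 nodes. Whether a printed
half-width is an SE or a 95% interval is ambiguous in the source
material (figure captions say 95% CI); the table stores the raw
half-width and `speedup_table()` treats it as a 95% interval, so
reproduced interval bounds are an approximate check while the speed-up
point values are exact arithmetic on the printed times. Rows without a
matching serial island count (10- and 20-node runs) get no relative
speed-up rather than an interpolated one.

# Problem sizes used in the packaged experiments

All tests and the acceptance script run on one CPU with fixed seeds. The
sizes are the package's chosen study conditions: solver fidelity over
100 random decay-only fixtures; ranking equivalence over 1000 random
populations and the $P_f$ branch rate over $10^5$ comparisons;
serial-vs-sync bit-identity for 1, 2 and 4 islands at 3 seeds and 200
generations of the 2-gene toy; async-vs-sync equivalence on a 2-island,
50-generation sphere run plus message-conservation stress runs with caps
of 1 migrant and 2 master messages; the 10-run recovery experiment
described above; $10^4$ Monte-Carlo draws for Fieller coverage and
Boltzmann mixing and $10^5$ for Metropolis acceptance.

# Known limitations

* No true multi-process execution: parallelism is modelled (faithfully
  at the algorithmic level) under a virtual scheduler.
* The Lam schedule is not implemented; the annealing baseline is
  structural, not a tuned competitor.
* The 1-D nuclear row has no 2-D/3-D geometry and no stochastic gene
  expression; A–P positions are metadata.
* The packed-parameter layout fixes gene order; data sets must observe
  every division epoch's Bcd profile in at least one time class.
* On multimodal landscapes the ES's late convergence is slow (the
  smoothed step sizes adapt conservatively); the recovery experiment
  relies on island diversity rather than restarts.
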