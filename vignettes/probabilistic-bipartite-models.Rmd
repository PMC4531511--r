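---
title: "From reaction-contingency networks to probabilistic Boolean simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From reaction-contingency networks to probabilistic Boolean simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbbn)
```

## The modeling problem

Signaling networks are awkward for both classical modeling styles. Ordinary
differential equations need rate constants that are mostly unknown at genome
scale, and enumerating every specific molecular state explodes
combinatorially. Plain Boolean networks scale, but they flatten every
regulatory influence to an absolute requirement or an absolute block, which
discards the common case where a modifier merely makes a reaction more or
less likely.

The reaction-contingency formalism sidesteps the state explosion by
describing a network as *elemental reactions* — decontextualized statements
such as `A_ppi_B` (A and B can bind) — together with *elemental states*
(`A--B`, `Hog1-{P}`: one bond or one modification, regardless of everything
else about the molecules) and *contingencies* that constrain a reaction by a
state. Contingencies come in several strengths:

| sign | meaning |
|------|---------------------------------------------|
| `!`  | absolute requirement |
| `x`  | absolute inhibition |
| `K+` | positive quantitative modifier |
| `K-` | negative quantitative modifier |
| `0`, `?` | no effect / unknown (both treated as inert) |

`pbbn` implements the pipeline from such a definition to a simulation-ready
model in two stages: a deterministic *bipartite Boolean model*, and its
probabilistic extension in which the quantitative modifiers — which the
deterministic model must ignore — become update-function probabilities
governed by just two global parameters.

## The bipartite Boolean model

Nodes come in two classes. *Reaction nodes* read only states and
component-presence nodes:

```
A_ppi_B(t+1) = A(t) & B(t) & (! effectors) & !(x effectors)
```

*State nodes* read only the reactions that produce or consume them. Products
of reversible reactions (interactions) persist only while their producing
reaction fires; products of irreversible reactions (modifications) have
memory, implemented as self-dependence:

```
B--C(t+1)  = B_ppi_C(t)                               # reversible
X-{P}(t+1) = A_P+_X(t) | (X-{P}(t) & !Y_P-_X(t))      # irreversible
```

The memory form is the unique rule satisfying two constraints: a TRUE
modification persists unless a consumer fires while no producer does, and a
FALSE one turns TRUE only by production (`tests/testthat/test-bbn.R` checks
this against a brute-force truth-table oracle). When a network contains
synthesis or degradation reactions, every state rule is additionally
multiplied by an availability factor `!(deg_c & !syn_c)` per member
component `c`: a state cannot hold if its component is being degraded and
not resynthesized. We reify one presence node per component to make this
expressible as an ordinary Boolean factor; presence nodes are constant at
their initial value unless synthesis/degradation reactions target them.

The default start state sets presence nodes TRUE and everything else FALSE.

## The probabilistic extension

A reaction with `n` quantitative modifiers receives `n + 2` ordered update
functions. `f0` is the base rule above (absolute contingencies are never
relaxed and appear in every non-false rule). `f_i` additionally requires at
least `i` modifiers to be *fulfilled* — a `K+` effector TRUE, a `K-`
effector FALSE — via the disjunction over all `i`-subsets of modifier
conjunctions, so `f_i` implies `f_{i-1}` by construction. The last rule is
constant FALSE: random failure of the whole reaction. Probabilities are

$$p_0 = \frac{1 - p_\mathrm{FALSE}}{\sum_{i=0}^{n} k^i}, \qquad
  p_i = p_0 \, k^i,$$

plus $p_\mathrm{FALSE}$ for the FALSE rule. The two global parameters are:

* `p_false` (false-rate, in `[0, 1)`): noise level; 0 means no spontaneous
  failure, and values of a few percent already desynchronize oscillating
  ensembles noticeably.
* `k_base` (`k > 0`, dimensionless): each more restrictive update function
  is `k` times more probable than the previous. `k = 1` weights all
  non-false rules equally; `k -> infinity` recovers the qualitative
  absolute-contingency model. Values below 1 are accepted with a warning
  (they invert the preference ordering).

At every time step, each node independently samples one of its update
functions by these probabilities, and all nodes update synchronously from
the pre-step state — an instantaneously random probabilistic Boolean
network, hence a Markov chain over the $2^N$ Boolean states.

### Reported-probability rounding

Exported probabilities follow a sum-to-one convention: `p0` is rounded to
six decimals, intermediate probabilities are computed as `p0 * k^i` *from
the rounded* `p0`, and the most restrictive non-false rule absorbs the
residue `1 - p_false - sum(others)`. For the bundled worked example
(`n = 2`, `k = 10`, `p_false = 0.1`) this yields `0.008108`, `0.08108`,
`0.810812`, `0.1` — summing to exactly 1. Internal computation, and the
simulator, use full precision.

```{r}
assign_probabilities(2, p_false = 0.1, k_base = 10)
```

## Simulation and reproducibility

`simulate_ensemble()` runs independent realizations and either keeps the
full runs x time x node Boolean array or accumulates only per-step means
(`keep = "mean"`, constant memory in the ensemble size). Run `r` draws its
randomness from the `r`-th L'Ecuyer-CMRG substream derived from the master
seed, a counter-based scheme with three consequences: ensembles are
bit-identical across chunkings and across sequential/parallel execution;
a single `simulate_run()` equals run 1 of the ensemble; and runs are
statistically independent. (Seeding the default generator with consecutive
integers per run is *not* sufficient: it produced cross-run correlations
detectable against the exact oracle at 20&nbsp;000 runs.)

Perturbations are hard clamps: a `clamp_events()` entry holds a node at a
fixed value from its event time until the next event on that node,
overriding its rules. This models input switching (turgor off at one time,
on again later); the alternative set-once-then-free semantics was rejected
because a switched input must stay switched to drive a sustained response.
Time 0 is the initial state; a simulation of `steps` steps reports
`steps + 1` time points.

### The exact Markov oracle

For models with at most 16 nodes, `exact_markov_distribution()` propagates
the full state distribution through the transition kernel assembled from
the per-node rule probabilities and returns exact per-node marginals per
step. It exists to *verify the sampler*: ensemble means must converge to
these marginals at rate $1/\sqrt{\text{runs}}$. The test suite checks this
on every bundled fixture small enough, with a family-wise error band
(no comparison beyond 4.5 standard errors, at most 1% beyond 3, degenerate
marginals exact) because ~900 simultaneous Monte-Carlo comparisons are
involved.

## Ensemble analysis conventions

`ensemble_mean()` averages the Boolean state per (time, node) into an
activation probability. On top of it:

* **Amplitude/phase per period** (`period_amplitude_phase()`): the period
  grid comes from the deterministic reference model's exact cycle
  (`detect_cycle()`), not from spectral estimation — the deterministic
  system has an exact cycle, the stochastic ensemble does not. Within the
  window of period `i`, amplitude is max − min of the mean trace and phase
  is the offset of the maximum (ties to the earliest step). These are
  conventions chosen for determinism and testability, not claims about any
  particular plotting pipeline.
* **Convergence** (`detect_convergence()`, `first_convergence_time()`): a
  trace has converged when its trailing-window spread is at most a
  tolerance; the level is the trailing-window mean. For oscillation
  *breakdown* analyses we fix tolerance 0.5 — swing below half the Boolean
  scale — with a 50-step window, once, as the package's convention.
* **Desynchronization index**: `4 p (1 - p)` at a (time, node), 0 when all
  runs agree and 1 at maximal disagreement. Damping of the ensemble mean
  while individual runs still oscillate is desynchronization, not decay of
  the single-cell oscillation; this index makes that distinction
  measurable.

## The bundled HOG oscillator fixture

The package ships a minimal two-module model of the yeast
high-osmolarity-glycerol pathway as its oscillator benchmark
(`fixture_hog()`; five reactions, 15 nodes):

```
Sln1_ppi_Turgor; ! Hog1-{P}     # turgor sensing, maintained by glycerol drive
Sln1_P+_Ssk1;    ! Sln1--Turgor # phosphotransfer module on
Ypd1_P-_Ssk1;    x Sln1--Turgor # ... and reset
Pbs2_P+_Hog1;    x Ssk1-{P}     # MAPK module on while phosphotransfer is off
Ptp2_P-_Hog1;    ! Ssk1-{P}     # ... and reset
```

This is a *synthetic transcription*, not a reproduction of any published
line set: the fixture compresses each module of the classic simplified HOG
architecture to one essential state while preserving that architecture — a phosphotransfer module that suppresses the MAPK module,
and negative feedback closing through glycerol/turgor back to the sensor.
The compression choices were made once, so that the qualitative model shows
the architecture's characteristic behavior: a sustained deterministic
oscillation (period 12 here) from the components-TRUE start state. The
quantitative variant is derived programmatically by substituting `! -> K+`
and `x -> K-`, never hand-edited.

What the fixture reproduces, and what it does not: with `p_false = 0.01`
the 1000-run ensemble mean of `Hog1-{P}` oscillates with decaying amplitude
and a trailing mean near 0.5; with `p_false = 0.03` the oscillation breaks
down much earlier; with `p_false = 0` the single-run oscillation is exactly
stable. These are the architecture-level phenomena. Exact trajectories,
the published model's period, and per-node amplitudes are transcription
artifacts, which is why the package's own checks on this fixture are
interval and ordinal assertions only. Desynchronization in this compressed
ring is also somewhat slower than in a deeper cascade — at `p_false = 0.01`
the amplitude has decayed to roughly 0.65 of full scale by step 280 rather
than vanishing — so "breakdown" comparisons across false-rates use the
half-scale threshold above.

```{r, fig.width = 6, fig.height = 3}
fx <- fixture_hog("qualitative")
pbn <- build_pbn(fx$network, p_false = 0.01, k_base = 100)
sm <- simulate_ensemble(pbn, steps = 280, runs = 200, seed = 1, keep = "mean")
autoplot(sm, nodes = "Hog1-{P}")
```

## Scalability surrogate

The published application at full scale is a curated yeast MAP-kinase
network of 142 components and 273 elemental reactions; that curation is
external supplementary data and is not bundled. `random_network()` emulates
its *size* instead: a connected random network of `ppi`/`P+` reactions with
contingencies drawn only among produced states. At the 142/273 scale the
generated probabilistic model has ~650 nodes and a 1000-run, 125-step
ensemble completes in well under a minute in the mean-accumulation mode.
Random networks emit only `ppi` and `P+` types: enough for scale and
property sweeps without inventing semantics for types the examples never
exercise.

## Numerical and design notes

* Probability sampling uses one uniform per (run, step, stochastic node),
  pre-drawn per run, with rule choice by `findInterval` on the cumulative
  exact probabilities (normalized to remove float residue).
* Degenerate inputs: an empty definition parses to an empty network; a
  state that is consumed but never produced warns and keeps its initial
  value via the memory rule (boundary states are legitimate in curated
  networks); `p_false = 0` makes the FALSE rule unreachable and single runs
  of absolute-only networks reproduce the deterministic trajectory exactly.
* When a state has both reversible and irreversible producers, the memory
  form is used (memory wins, since any irreversible producer implies the
  product outlives the reaction).
* Per-rule probability overrides are accepted per node, must sum to 1, and
  replace both reported and simulation probabilities.
* Problem sizes used throughout the documentation and checks — 1000 runs x
  280 steps for the oscillator analyses, 50 000 runs x 20 steps for oracle
  verification, 1000 x 125 at the MAPK scale — are the sizes at which the
  reported phenomena are stable; the simulator itself is limited only by
  memory in `keep = "runs"` mode.

## Known limitations

* Synchronous updating only; no asynchronous or continuous-time semantics,
  and no attractor analysis beyond cycle detection on deterministic runs.
* One elemental state per contingency line; Boolean combinations of
  effectors are outside the dialect.
* Site labels (`Hog1_[(T174)]`) are carried opaquely in identifiers with no
  structural semantics.
* The probabilities are fixed over time (no context-sensitive switching of
  rule sets).
* The reaction-type ontology is open: unknown codes must be declared with
  their properties via `reaction_registry()` rather than guessed.
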