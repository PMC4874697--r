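---
title: "Detecting trait-combination-dependent diversification on binary-character hypercubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting trait-combination-dependent diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypersse)
```

## The problem

Some trait combinations are everywhere and others are vanishingly rare.
Three processes shape that distribution on a phylogeny: the rate at which
combinations arise (character transitions), differences in speciation and
extinction between lineages carrying different combinations, and time — a
clade may simply not have reached the equilibrium its rates imply.
`hypersse` estimates transition and diversification rates jointly for sets
of binary characters, searches over which *combination set* carries a
diversification effect, and uses stochastic simulation and eigen-analysis to
ask whether observed frequencies are anywhere near equilibrium.

## State coding

K binary characters become one multistate character with 2^K states. The
combination string is read as a binary numeral with character 1 leftmost, so
for K = 3 the combination `000` is state 0, `001` is state 1, `010` is
state 2. Two states are neighbors when they differ in exactly one
character; multi-character jumps have rate zero. The transition network is
therefore the K-dimensional hypercube, with K·2^(K−1) undirected edges
(192 for K = 6).

## The tied-rate model family

A full multistate model at K = 6 would need 512 parameters (one rate per
directed edge plus per-state speciation and extinction). Instead, a
*bipartition mask* over `{0,1,*}` — e.g. `"0*11**"`, matching every state
with character 1 ancestral and characters 3 and 4 derived — splits the
states into a focal set F and complement N, and rates are tied at the set
level. The five transition schemes (`onerate`, `within.between`, `equal`,
`outflow`, `free`) constrain `(q_FF, q_NN, q_FN, q_NF)` with 1–4
parameters; the six diversification schemes (`equal`, `free.lambda`,
`free.mu`, `free`, `two.one`, `equal.r`) constrain `(λ_F, λ_N, μ_F, μ_N)`
with 2–4, so the richest model has 8 parameters. The cross product is a
30-model grid per mask; at K = 6 there are 3^6 − 1 = 728 masks, hence
21,840 candidate models before viability filtering (a mask is viable only
if observed tip states fall on both sides). Two registry choices deserve
comment, as the tie schemes are conventions of this package:

* `two.one` fixes λ_F = 2·λ_N with a shared μ. A doubled-speciation model
  is the natural "twice as fast" hypothesis and keeps the scheme at two
  parameters; any other multiplier can be supplied as a custom registry
  entry, since the grid accepts ordinary named lists.
* `equal.r` parameterizes equal net diversification with free turnover as
  `(r, μ_F, μ_N)`, λ = r + μ. This keeps all parameters non-negative
  without coupled constraints.

Grouping states never alters the data (the K characters at the tips), so
log-likelihoods are comparable across every mask and model fitted to the
same tree and matrix; the all-tied model (`onerate` + `equal`) is
mask-invariant by construction, which is a useful internal consistency
check.

## Likelihood

The likelihood is the standard state-dependent speciation–extinction
(SSE) pruning computation. Along each branch, integrating toward the root:

\[
\frac{dE_i}{dt} = \mu_i - (\lambda_i + \mu_i) E_i + \lambda_i E_i^2 + \textstyle\sum_j Q_{ij} E_j,
\qquad
\frac{dD_i}{dt} = -(\lambda_i + \mu_i) D_i + 2 \lambda_i D_i E_i + \textstyle\sum_j Q_{ij} D_j,
\]

where `E_i(t)` is the probability that a lineage in state i leaves no
sampled descendants and `D_i(t)` the density of the observed subtree. Tips
start at `D_i = f_i` for the observed state (zero elsewhere; `f` across all
states when missing) and `E_i = 1 − f_i`, which is how incomplete sampling
enters: the study design uses a uniform `f = 464/250000`. At an internal
node the daughters combine as `λ_i D^L_i D^R_i`. The root is fixed at the
all-ancestral combination by default (a `given-weights` mode exists for
sensitivity analysis), and conditioning on survival of the two root
lineages is available but off by default, since the original analysis does
not state that it conditioned.

Numerical choices: branches are integrated with an adaptive Dormand–Prince
5(4) scheme in compiled code (`rtol = 1e-8`, `atol = 1e-10`, both
adjustable); `D` is renormalized at every node with an accumulated
log-compensation, so trees of hundreds of tips do not underflow; a zero
likelihood at the fixed root is reported as `-Inf` with a warning rather
than an error, so a model search can continue past infeasible corners. One
degenerate-case convention matters: when *every* speciation rate is zero the
node factors λ_i would annihilate the likelihood, so they are omitted and
the computation reduces exactly to the Mk (character-only) pruning
likelihood — this is also what makes the matrix-exponential oracle
comparison in the tests exact.

Marginal ancestral reconstructions clamp each internal node to each state
in turn and propagate the clamped vector to the root, reusing stored
branch-top vectors for the off-path subtrees. This is exact (the D-system
is linear in D for fixed E) at O(depth) integrations per node and state;
it favors simplicity over the asymptotically faster uppass recursion.

## Model search, ranking, averaging

Each (mask, model) pair is optimized by bounded quasi-Newton (`L-BFGS-B`)
on log-transformed rates, bounds `[1e-9, 10]` per Myr, from up to three
starting points: a crown birth–death heuristic (net rate from tip count and
depth at turnover 0.5) with a parsimony-flavored transition guess, a
transition-inflated variant, and a jittered variant. The best optimum is
kept; non-convergence is recorded per fit and failed fits are retained in a
log rather than silently dropped. Fits are independent jobs run in
deterministic order, so results do not depend on scheduling. Ranking uses
Akaike weights `w_m ∝ exp(−ΔAIC_m/2)`; model averaging expands every fit to
full per-state λ, μ and per-edge q and takes the weighted elementwise mean
over *all* fitted models (no top-N truncation, matching a plain reading of
AIC-weighted averaging).

## Simulation and equilibrium

Two exact Gillespie simulators share the event logic (waiting times
exponential in the total rate; event type proportional to per-state λ, μ
and q): a full-tree recorder, whose lineage segments convert to an
ultrametric `phylo` after dropping extinct tips and subsampling, and a
counts-only process on the per-state count vector for long or species-rich
horizons. Both are bit-reproducible under `set.seed()`.

Expected counts follow the linear dynamics `dn/dt = A n` with
`A = diag(r) + Qᵀ`; the stationary combination frequencies are the
normalized dominant right eigenvector of `A`, invariant to a uniform
rescaling of time. The counts simulator caps the population (default
5×10⁵) and by default stops there with a truncation flag. For genuinely
long horizons an optional renormalization is provided instead: at the cap,
every state count is binomially thinned by 1/2 and the cumulative log-scale
correction is recorded. Thinning preserves expected frequencies (it is the
standard device for following a supercritical branching process to large
times), so frequency trajectories and growth-rate estimates — after adding
back the recorded correction — remain valid while the realized population
stays bounded.

First-origin summaries report the median and a 95% interval of the first
time any state in a query set acquires a positive count; replicates in
which the set never appears are counted as censored and excluded from the
quantiles. "Origin" here means first appearance, not fixation; with
transition rates this low the first appearance of a three-derived-character
combination routinely takes most of the clade's history.

## The synthetic-data generator

The generator reproduces the *shape* of the motivating study: a single
lineage evolving for 136 Myr (the approximate crown age of the angiosperms)
under six binary characters, with the focal set `"0*11**"` (corolla
present, bilateral symmetry, reduced stamens) at roughly twice the net
diversification of the rest — λ_F = 0.07, μ_F = 0.006, λ_N = 0.042,
μ_N = 0.004 per lineage per Myr (r_F = 0.064, r_N = 0.038, the magnitudes
of the study's top model) — and equal transition rates of 0.001/Myr on
every hypercube edge. Runs are retried until one reaches the target extant
count, then pruned uniformly at random to 464 tips. The stratified sampler
converts family richness to expected sample counts and rounds the
fractional part stochastically (probability equal to the fraction), which
keeps the design unbiased; a log-series-flavored synthetic family table is
included for exercising it.

What the generator does *not* emulate: phylogenetic and scoring error (the
tree and states are known without error), database availability bias in
which species can be sampled, diversity-dependence, rate variation through
time or among clades, and cladogenetic (at-speciation) character change.
Passing tests on synthetic data therefore demonstrate the estimator's
internal correctness and power under the model's own assumptions, not
robustness to the ways real comparative data violate them.

## Problem sizes used in the checks

The shipped checks favor small, oracle-verifiable instances: likelihood
agreement uses 8-tip trees at K = 2 against a matrix-exponential Mk oracle
and 4-tip trees against brute-force `deSolve` integration at tight
tolerance; the stationary/simulation consistency check uses a two-state
system (r_F = 0.064, r_N = 0.038, q = 0.001, equilibrium focal frequency
0.963 from the hand-solved 2×2 eigenproblem) followed to 500 Myr with
thinning; parameter recovery uses 20 replicates of 400-tip K = 3 datasets
fitted with a reduced grid (all-equal, free-λ and free diversification under
one-rate transitions on the true mask); the non-equilibrium check uses 20
counts-only replicates of the K = 6 generator over 136 Myr. These sizes
were chosen to make each scientific property measurable in minutes on a
single core while keeping every expected value independently computable.

## Known limitations

* The exhaustive 728 × 30 search at K = 6 on a 464-tip tree is an
  overnight-scale computation on one core; the pipeline exposes mask and
  grid subsets, and fits parallelize trivially since they are independent.
* Marginal reconstruction is quadratic-ish in tree depth per node; for very
  large trees an uppass implementation would be preferable.
* The bipartition family only expresses two-set rate structure; a
  combination whose effect requires three or more distinct rate classes
  will be approximated by the closest bipartition.
* Equilibrium frequencies come from the linearized mean dynamics; they
  describe long-run expectations of an unbounded process, not a
  diversity-regulated clade.
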