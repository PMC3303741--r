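---
title: "Inferring gene regulatory networks by triplet decomposition and union"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene regulatory networks by triplet decomposition and union}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trigrn)
```

## The problem and the model

Gene regulatory relationships are commonly summarised as a directed network
over genes, and Bayesian networks (BNs) are a standard tool for estimating
such networks from continuous expression profiles: a DAG `D = (V, E)` plus
local conditional distributions factorises the joint density of expression
levels as a product of per-gene terms `p(x_v | x_pa(v))`. How well a
structure explains data `d` is measured by the network score `p(D, d) =
p(d | D) p(D)`; searches work with its logarithm `N(D)`. Two obstacles make
whole-network search painful: the space of DAGs grows super-exponentially in
the number of genes, and a DAG can never represent feedback, which real
regulatory circuits contain.

`trigrn` implements a divide-and-unite strategy that addresses both at
once. Every 3-gene subset ("triplet") of the gene set is scored
exhaustively — with three states per gene pair (forward edge, backward
edge, no edge) a triplet has `3^3 = 27` candidate configurations, of which
25 are acyclic and scoreable — and the ranked candidates of all `C(n, 3)`
triplets are collected into a tuple store of (network, score, rank)
entries. A single whole-gene network is then stitched together by edge-type
voting: for each gene pair, each triplet containing the pair contributes
the weight of its best-ranked network to whichever state that network
assigns the pair, and the state with the strictly largest total wins. The
per-pair decisions are made independently across pairs, so the united
network can contain directed cycles even though every ingredient was a DAG
— by design, not by accident. Work scales as `C(n, 3)` times a constant
(27 candidate scores), i.e. cubically in the number of genes, instead of
super-exponentially.

## The score

The package scores continuous data with the Gaussian-equivalent (BGe)
marginal likelihood: expression of a gene given its parents is linear
Gaussian, and coefficients, means and variances are integrated out under a
conjugate normal–Wishart prior. Scores are computed as differences of
subset marginals, `score(v | Pa) = f(Pa ∪ {v}) − f(Pa)`, which makes two
structural properties hold by construction rather than by numerical
accident:

* **decomposability** — editing one gene's parent set changes only that
  gene's term, which is what makes triplet locality and cheap hill-climbing
  moves sound;
* **score equivalence** — Markov-equivalent DAGs (same skeleton, same
  unshielded colliders) receive identical scores under the uniform
  structure prior, so rankings never depend on which member of an
  equivalence class is enumerated first.

Hyperparameters (`score_params()`), with defaults chosen as the standard
weakly-informative configuration:

| parameter | default | meaning |
|---|---|---|
| `am` | 1 | prior precision on the mean (pseudo-observations) |
| `aw` | `n_vars + 2` | Wishart degrees of freedom; must exceed `n_vars − 1` |
| `prior_mean` | per-gene sample means | centre of the mean prior |
| `prior_scale` | `am (aw − n_vars − 1)/(am + 1) · I` | makes the implied prior covariance per gene the identity |
| `structure_prior` | uniform | cancels in every ranking |

The prior dimension `n_vars` is resolved against the gene set being scored:
3 inside a triplet, `n` for the whole-set searches. Scores from different
scopes are therefore never mixed, and `log_node_score()` takes an explicit
`scope` argument so that summed contributions always share one prior.
Absolute score values are implementation-defined (they depend on these
hyperparameters, which published applications typically do not report);
only rankings are treated as reproducible, and all tests and benchmarks are
ranking-level. With per-gene sample means as the prior mean the
mean-correction term of the posterior scale vanishes, which also makes
scores invariant to sample reordering — time points are deliberately
treated as i.i.d. samples, mirroring how static BNs are applied to
time-course microarray data.

Numerical choices: everything stays in log space (raw `p(D, d)` values for
62-sample data underflow double precision); subset marginals are evaluated
through Cholesky log-determinants and cached per scope, so exhaustively
scoring the 29,281 five-gene DAGs touches only `2^5` subset marginals; an
ill-conditioned posterior matrix (e.g. duplicated constant columns) raises
an error naming the offending genes rather than silently pseudo-inverting,
because a silently wrong score corrupts every downstream rank.

## Voting, ties, and rank escalation

Candidate scores from different triplets live on incomparably different
likelihood scales, so the default aggregation converts each triplet's 25
log scores into normalised posterior weights (softmax within the triplet)
before summing across triplets. This preserves each triplet's internal
ordering while making triplets commensurable, and it keeps the vote counts
in floating-point range. `raw_scores = TRUE` restores literal raw-score
summation in log-sum-exp arithmetic for comparison.

An exact tie between edge states escalates in two stages, processed over
pairs in lexicographic order while the partial network grows:

1. **context first** — among triplets `{x, y, w}` whose third gene `w`
   already has an edge with `x` or `y` in the partially built network, the
   current-rank network with the single highest weight dictates the pair's
   state ("x or y" is read literally: either endpoint qualifies);
2. **then deeper ranks** — if no triplet qualifies (or the qualifying votes
   conflict at equal weight), the pair is revoted with the rank-2 networks,
   then rank-3, and so on.

A pair still tied past `max_rank` is set to *absent* with a warning:
absence is the conservative call for a regulatory-network output, and it
guarantees termination, which the bare escalation loop does not. With
continuous data exact ties are measure-zero, so ranks beyond 1 are almost
never consulted on real input; `max_rank` exists so the deterministic
tie-break path is still fully specified and testable. The full decision
audit (totals per state, deciding rank, tie-break flag) is returned as a
tidy table by `tidy()` on the fitted object.

One counting subtlety: with three states per pair a 5-gene problem has
`10 × 27 = 270` candidate slots across its 10 triplets, while only
`10 × 25 = 250` of those candidates are acyclic and hence scoreable. The
tuple store reports both numbers (`$candidate_slots`, `$scored_entries`)
so either bookkeeping convention can be checked.

## The greedy hill-climbing baseline

`ghc_search()` is the classical single-edge local search: from a random
initial DAG, evaluate all neighbours reachable by adding, deleting or
reversing one edge (discarding cycle-creating moves), accept the strictly
best improvement, and stop when stuck or when the action budget is spent.
The default budget — 50 accepted actions, 0 restarts — is the
default parameter set used for head-to-head comparisons; 100 actions with
10 restarts is the "high accuracy" variant. "Actions" counts accepted
moves, not neighbour evaluations. The initial DAG is drawn by sampling a
uniform topological order and including each order-respecting edge with
probability 1/2 — cheap, covering all DAGs with positive probability,
though deliberately *not* uniform over DAGs (no uniformity is claimed for
it; the sampler's distribution affects only how often the baseline starts
near a good optimum). Neighbour ties break by fixed enumeration order, so
every run is a pure function of its seed.

## The synthetic benchmark

Real microarray compendia used in published evaluations of this family of
methods are generally not deposited, so the package ships a planted-truth
generator instead. `random_planted_model()` draws a DAG by the same
order-plus-edge-probability scheme, assigns each edge a coefficient of
random sign with magnitude uniform in `beta_range`, and
`simulate_expression()` propagates independent Gaussian noise through the
graph in topological order: `x_v = Σ β_uv x_u + ε_v`. The linear-Gaussian
forward model is chosen to match the score family; defaults define the
strong-signal regime used throughout the benchmarks — `|β| ∈ [0.8, 1.2]`,
`σ = 0.5`, `m = 100` samples, edge probability 0.3 (a moderately sparse
network, roughly 3 edges on 5 genes, chosen once as a realistic density
for small regulatory modules).

Two instruments evaluate an estimate. `rank_in_exhaustive()` locates it in
the full score ranking of all DAGs on the same genes (29,281 for five
genes); a cyclic union output has no position in a DAG ranking and is
reported as not rankable — summary medians charge such replicates the
worst rank plus one, which is conservative against the union method.
`sensitivity_selectivity()` scores directed-edge recovery against the
planted truth under strict direction matching (`tp/(tp+fn)` and
`tp/(tp+fp)`); estimated edges whose reverse is a true edge are counted
separately as `reversed_edges` but remain false positives, since published
evaluations in this area do not state whether reversals earned partial
credit and strict matching is the harsher, unambiguous choice.

`run_comparison()` runs both methods on identical data over seeded
replicates. The shipped problem sizes — 100 replicates at 5 genes with the
exhaustive ranking, 20 replicates at 8 genes for edge recovery — keep a
full benchmark around two minutes on one core while leaving standard
errors small enough for the qualitative comparisons to be stable.

## What the benchmark does and does not show

Passing tests on this generator demonstrate the machinery is correct (the
3-gene union provably equals the exhaustive optimum, and the test suite
checks exactly that over 50 replicates), but clean linear-Gaussian data is
*kind* to greedy search: the score surface at `m = 100` with strong
coefficients has few local optima, so default hill climbing usually climbs
straight to the top of the exhaustive ranking. The benchmark consistently
shows the union method recovering more true directed edges than default
GHC at both 5 and 8 genes, while GHC attains better exhaustive-rank
medians — unsurprising, as GHC directly maximises the ranked score. The
union's characteristic failure mode is visible and worth knowing: for a
true path `a → b → c`, the triplets containing `a` and `c` but not the
mediator `b` see a genuine marginal dependence and outvote the single
triplet that can explain it away, so transitive "indirect regulation"
edges accumulate as the gene set grows, depressing selectivity. Noisy real
expression data shifts this trade-off: local optima multiply and trap
greedy search, which is precisely the regime where a deterministic
decomposition that never gets stuck earns its keep. None of this is
visible in the synthetic strong-signal regime, so conclusions about real
data should rest on the sensitivity/selectivity instrument, not on rank
medians alone. What the generator also does not emulate: measurement-error
structure of microarrays, temporal autocorrelation of time courses,
nonlinear regulation, and hidden confounders.

## Degenerate inputs and other contracts

* Expression input needs at least 2 samples; duplicate gene or sample ids,
  missing cells and non-numeric cells are errors that name the offender.
* Self-loops and duplicated directed edges are rejected at network
  construction; acyclicity is enforced exactly when a structure claims it.
* Exhaustive enumeration is capped at 6 genes (the 3-gene triplet is the
  method's operating point; 5 genes is the evaluation size; beyond 6 the
  configuration table is no longer worth materialising).
* All randomness flows through explicit integer seeds; stage-specific
  sub-seeds are derived from the global seed plus a stable label, so
  adding a stage never reshuffles another stage's draws.

## Known limitations

* Scores assume continuous, jointly Gaussian-ish data; no discrete or
  hybrid scoring.
* The union step decides each pair independently; it neither enforces nor
  forbids global acyclicity, and it cannot represent bidirected pairs
  (the three-state encoding forces exactly one state per pair).
* Absolute scores depend on prior hyperparameters and are not comparable
  across scopes of different size.
* The benchmark's generative model shares the score's assumptions, which
  flatters both methods equally but says nothing about model misfit.
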