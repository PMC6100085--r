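---
title: "Order-space structure learning with K2 and brain-storm optimization: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order-space structure learning with K2 and brain-storm optimization: models and design}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(k2bso)
```

This vignette is the package's own account of the statistics it implements:
the scoring model and its assumptions, the search operators, the
direction-learning stage, the numerical choices that are not forced by the
mathematics, and what the bundled simulators can and cannot tell you about
real data.

## 1. The K2 score

For discrete data the package scores a node $X_i$ with parent set $\pi_i$
by the Cooper–Herskovits marginal likelihood under uniform Dirichlet
priors,

$$g(X_i, \pi_i) = \prod_{j=1}^{q_i} \frac{(r_i-1)!}{(N_{ij}+r_i-1)!}
  \prod_{k=1}^{r_i} N_{ijk}!$$

with $r_i$ states, $q_i$ parent configurations, and counts $N_{ijk}$,
$N_{ij} = \sum_k N_{ijk}$. `local_log_score()` evaluates $\ln g$ through
`lgamma()`: the literal factorials overflow double precision once any count
passes 170, while the log-gamma form is exact to machine precision — the
suite verifies agreement with integer factorial arithmetic to a relative
$10^{-9}$ on small datasets, and observed error is near $10^{-15}$. Parent
configurations never observed contribute $\ln 1 = 0$ and are skipped by
compressing to observed configurations, so $q_i$ can be astronomically
large without cost. The structure-prior constant shared by every candidate
structure is dropped; it cannot change any argmax.

The total score of a DAG is $\sum_i \ln g(X_i, \pi_i)$. It is
*decomposable*: each term depends only on the counts of its own columns,
which is what makes both the greedy parent search and the score cache
correct.

**Greedy parent search** (`k2_parent_search()`): given an order, each
node's candidates are its predecessors; the single best strict improvement
is added until no candidate improves the score or the in-degree cap is
reached. Two numerical conventions make this deterministic: an addition
must improve the score by more than $10^{-12}$ (guarding against ties
produced by floating-point noise), and among equally good candidates the
one earliest in the order wins. The cap defaults to `max_parents = 4`: the
method's natural habitat is sparse biological and diagnostic networks
whose in-degrees rarely exceed a handful, and an uncapped greedy search on
small samples mostly adds spurious parents.

**Score cache** (`score_cache()`): local scores are memoised on
(node, parent set). Orders explored during a search overwhelmingly revisit
the same local queries, so the cache — shared across a whole run — is the
dominant cost saver; the suite checks cached values are bit-identical to
fresh recomputation.

## 2. Searching the order space

The order space ($n!$) is much smaller than the DAG space, and the K2
score of an order is a well-defined fitness. The package's main searcher
is a brain-storm optimizer; random restarts and a permutation GA are kept
as baselines with a common evaluation counter so all three can be compared
at a matched budget.

**Order distance.** Clustering needs a distance between permutations. For
every variable $v$ we count how many variables precede $v$ in *both*
orders and subtract the summed overlap from $n(n-1)/2$. A summed overlap
itself is a similarity — identical orders maximise it — so the
subtraction is what makes the quantity a genuine metric; it equals the
Kendall-tau pair-disagreement count, which the suite verifies exhaustively
for $n \le 4$ and on random pairs up to $n = 15$. Two orders are close
exactly when K2 would assign them similar admissible parent structures,
which is why this is the right geometry for clustering candidate orders.

**Clustering.** Permutations have no mean, so k-means is replaced by a
PAM-style k-medoids (seeded initialisation, 50-sweep cap, ties broken by
lowest index, empty clusters repopulated with the member farthest from its
medoid). After partitioning, each cluster's *best-scoring* member — not
its medoid — is marked as the center, implementing the rule that the
optimal individual represents the cluster.

**Candidate generation.** Each iteration, every member proposes one
candidate built from one of four sources: a single cluster's center, a
random member of a single cluster, the fusion of two clusters' centers, or
the fusion of two random members (cluster choice always weighted by
cluster size). Fusion is rank-averaging: each variable's key is the mean
of its two positions plus a $10^{-9}$-scale uniform jitter that breaks
exact ties uniformly; fusing an order with itself is the identity. The
candidate is then perturbed by $\max(1, \mathrm{round}(\xi n))$ random
insertion moves, the permutation analogue of additive noise, with the step
size

$$\xi = \mathrm{logsig}\!\left(\frac{0.5\,T - t}{k}\right)\cdot u, \qquad
  u \sim U(0,1),$$

large in early iterations (exploration) and decaying to zero late
(exploitation); the slope defaults to $k = 20$, the customary value in the
BSO literature. A candidate replaces its member only if strictly better,
so the best-score trace is non-decreasing. The population is re-clustered
every iteration, and with probability `p_replace_center` (default 0.2) a
random cluster's center is re-seeded with a fresh random order to escape
local optima. The four generation probabilities default to 0.8 / 0.4 /
0.5, the standard BSO settings; none of them is critical on the problem
sizes the suite exercises.

**Baselines.** `random_search()` scores batches of uniform orders and
stops after 10 consecutive non-improving batches. `ga_search()` is a
permutation GA with order crossover (OX), insertion mutation, tournament
selection and one-elite survival. All searchers accept `max_evals` so
comparisons can be made at a fixed number of score evaluations; the
acceptance script compares BSO and random restarts at 2,000 evaluations on
an 8-node problem, 10 seeds each.

## 3. Direction learning by additive-noise models

Score-based search identifies structures only up to Markov equivalence.
On continuous data the package breaks ties with the additive-noise
mechanism $X_i = f(\text{parents}) + \varepsilon$, $\varepsilon$
independent of the parents: the fit is (generically) possible only in the
causal direction, so residual independence is evidence of orientation.

The skeleton is split into per-node **sub-skeletons** (target plus
neighbors); for each candidate parent set (subsets of the neighbors up to
`max_set = 3`, smallest first) the target is regressed on the set and the
residual tested for independence. *Every* passing set is accepted and the
union of accepted sets is oriented toward the target. Accepting all
passing sets, rather than stopping at the first, is deliberate: at a
collider each single parent already yields an independent residual
(the other parent's contribution acts as noise), so a first-passing-set
rule could never orient both parents. The price — occasional spurious
acceptances on anti-causal sets — is paid at the merge step, where a pair
directed both ways across sub-skeletons is demoted to undirected.

**Regression** is kernel ridge with an RBF kernel, median-heuristic
bandwidth, and ridge penalty selected from the grid $10^{-8}, \dots, 1$ by
exact leave-one-out error (computed from one eigendecomposition). Kernel
ridge is the posterior mean of a GP regression with fixed hyperparameters;
the package prefers it because it is deterministic and cheap. A fit whose
residual standard deviation falls below $10^{-3}$ of the response's is
treated as an exact functional relationship and accepted outright: the
leftover is shrinkage bias, not noise, and because the HSIC bandwidth
adapts to the residual scale, testing that bias would reject a perfect
fit at any precision.

**Independence testing** is a permutation HSIC test: RBF kernels on both
arguments, the statistic $\mathrm{tr}(HKH\,HLH)/n^2$, and a null built by
permuting the residual vector, valid without distributional assumptions.
The p-value uses the add-one convention $(1 + \#\{\text{perm} \ge
\text{obs}\})/(1 + P)$, so it is never exactly zero. Defaults:
$\alpha = 0.05$, 200 permutations; the suite checks type-I error
calibration and the near-uniformity of null p-values.

Discrete data is a different regime: the ANM asymmetry as fitted here is a
continuous-data mechanism, so on discrete inputs the pipeline returns the
K2 network's own directions (the best-scoring DAG in the equivalence
class) rather than pretending the ANM stage applies.

## 4. The split/merge framework

`k2bso_run()` solves problems with fewer than `threshold_k = 50` variables
whole. Above the threshold it builds a provisional skeleton with a
reduced-budget search pass (population 10, 20 iterations), forms one block
per node from its provisional neighborhood, re-learns each block at full
budget, orients each block (ANM on continuous data, K2 directions on
discrete), and merges the partial PDAGs. Per-node neighborhood blocks are
the natural split rule here: they mirror the sub-skeleton definition the
direction stage already uses, and no coarser partition is canonical. Merging resolves a
directed-vs-undirected pair to directed (information preserving), demotes
bidirectional conflicts to undirected with a log entry, and — should the
union of block orientations create a directed cycle — demotes the most
recently contributed cyclic edge until the directed part is acyclic, an
invariant asserted after every merge.

Continuous inputs are discretised (equal-frequency, 3 bins) for the K2
skeleton phase only; the ANM stage always sees the raw values. Three bins
keep the count tables well-populated at the sample sizes the package
targets; finer binning dilutes counts faster than it adds information.

## 5. The simulators, and what passing tests mean

`random_dag()` draws DAGs edge-by-edge under a hidden uniform order with
flat-Dirichlet CPT rows; `forward_sample()` is exact ancestral sampling;
`anm_sample()` generates continuous data with per-parent cubic-plus-linear
mechanisms (coefficients of magnitude 0.3–1, signs random) and
non-Gaussian noise — uniform by default, Laplace as an option — because
additive-noise identifiability fails for linear-Gaussian pairs. All
generators take a seed and restore the global RNG state on exit.

These simulators match the method's assumptions *by construction*:
discrete data really is multinomial given the parents, continuous noise
really is additive, independent and non-Gaussian. Real data offers no such
guarantees — hidden confounders, selection, measurement error,
near-deterministic relations and temporal structure are all outside the
generators' scope (and the package's: there is no latent-variable or
time-series support). Passing the suite therefore demonstrates
correctness of the implementation under the model, not robustness to
violations of it.

Problem sizes used by the suite and the acceptance script — exhaustive
oracles at 3–4 variables, search problems at 5–8 variables with 1,000–2,000
samples, pairwise ANM at 300 samples, budgets of 2,000 evaluations — are
chosen so every stochastic claim can be checked against brute-force
enumeration or closed forms while keeping a full run in the low minutes.
The method itself has no such limits; the split/merge path exists
precisely for problems far beyond them.

## 6. Known limitations

- K2 needs informative marginal dependence to add a parent greedily; pure
  XOR-type colliders defeat greedy addition (no single parent improves the
  score). This is a property of greedy K2, not of the order search.
- ANM orientation weakens when one mechanism's contribution is small
  against the combined noise of the others; conflicting orientations then
  fall back to undirected edges rather than guessing.
- The BIF reader/writer covers the discrete table-form subset only —
  enough to exchange standard benchmark networks, not the full grammar.
- Scores assume complete data; missing values are not handled.
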