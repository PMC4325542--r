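---
title: "Aggregating crowd-submitted signaling networks without a gold standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregating crowd-submitted signaling networks without a gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdnet)
```

## The problem

Network-inference challenges collect many independently constructed
candidate networks — say, M teams each submitting a directed signaling
network for the same cell system, built by adding and removing edges from
a shared literature-derived reference map. When the true network is
unknown, two questions arise that this package addresses:

1. **Evaluation without a gold standard.** How do we rank submissions when
   the prior knowledge was handed to everyone up front and no independent
   truth exists?
2. **Aggregation.** How many "votes" should an edge need before we include
   it in a consensus network, and what does the distribution of votes tell
   us about the fraction of true edges?

Both are attacked with surrogates: an algorithmically derived *silver
standard* (a Boolean-logic pruning of the reference network against
perturbation data), and a generative model of the voting process itself.

## The vote-count mixture model

Each submission j is a binary vector \(x_j = (x_{1j}, \dots, x_{Nj})\) over
an ordered universe of N candidate edges; the unknown truth is
\(y \in \{0,1\}^N\). Writing \(P_T\) for a predictor's probability of
including a true edge and \(P_F\) for including a false one, and assuming
predictions independent given the edge label, the vote count
\(X = \sum_j X_j\) of an edge is binomial given its label. Predictors are
not equally good, so \(P_T \sim \mathrm{Beta}(a_1, b_1)\) and
\(P_F \sim \mathrm{Beta}(a_2, b_2)\) vary across the crowd, which turns the
conditional vote-count distributions into beta-binomials:

\[
\Pr(X = k \mid Y = 1) = \binom{M}{k}
  \frac{B(k + a_1,\, M - k + b_1)}{B(a_1, b_1)},
\]

and analogously with \((a_2, b_2)\) for false edges. Marginally,

\[
\Pr(X = k) = \pi_1 \Pr(X = k \mid Y = 1)
           + (1 - \pi_1) \Pr(X = k \mid Y = 0),
\qquad \pi_1 = \Pr(Y = 1) = E/N,
\]

with E the number of true edges. `dbetabinom()` and `dvotemix()` implement
these densities in log space; `bbmix()` fits the five free parameters to
the observed per-edge vote counts by maximum likelihood. The consensus
rule then keeps every edge whose votes reach the smallest \(k^*\) with

\[
\Pr(Y = 1 \mid X = k) > \Pr(Y = 0 \mid X = k)
\iff
\pi_1 \Pr(k \mid Y{=}1) > (1 - \pi_1) \Pr(k \mid Y{=}0),
\]

found by direct evaluation over \(k = 0, \dots, M\)
(`optimal_threshold()`). The strict inequality means a tie (posterior odds
exactly 1) does not admit an edge.

```{r fit-example}
set.seed(7)
truth <- rbinom(2000, 1, 0.16)
rate <- ifelse(truth == 1, rbeta(2000, 40, 10), rbeta(2000, 15, 35))
votes <- vote_counts(rbinom(2000, 15, rate), M = 15)
fit <- bbmix(votes, n_starts = 2, seed = 1)
fit
optimal_threshold(fit)
```

### How the fit works, and why

The likelihood surface of a two-component beta-binomial mixture is
multimodal and the mixing weight is weakly identified from a single
histogram over \(0..M\). Three choices stabilize it:

* **A profiled grid on \(\pi_1\)** (default 0.01–0.5 in steps of 0.01).
  For each grid value the four shapes are optimized; the reported fit is
  the best grid point. This makes the "different mixing constants" search
  explicit and reproducible, and `fit$profile` exposes the whole
  profile likelihood for inspection.
* **A (mean, concentration) re-parameterization,**
  \(\mu = a/(a+b)\) on the logit scale and \(s = a + b\) on the log scale.
  Real crowds can be so consistent that a component collapses toward a
  point mass (fitted shapes of order \(10^6\) and larger); on the
  \((\mu, s)\) scale this is a benign boundary, capped at \(s = 10^9\) and
  reported via a `binomial_limit` flag instead of overflowing.
* **Seeded multi-start L-BFGS-B** (a moment-based start, random restarts,
  and a warm start from the neighbouring grid point), because single
  starts routinely land in the wrong mode.

Label switching is resolved by convention: component 1 is the one with the
larger mean (true edges attract more votes). If the data prefer the
opposite orientation the components are swapped, \(\pi_1 \mapsto
1 - \pi_1\), and the fit carries an `orientation_swapped` flag;
`optimal_threshold()` similarly flags `reversed_components` rather than
silently returning a threshold that favors *few* votes. If the posterior
condition holds for no k the result is flagged `no_threshold`; if the
condition is non-monotone in k (possible when the components have very
different concentrations) the smallest k past the last sign change is
returned with a `non_monotone` flag.

The conditional-independence assumption (predictions independent given
the edge label) is inherited from the model, not tested; correlated
submissions (teams sharing code) violate it, which is why vote counting
supports excluding near-duplicate submissions (`count_votes(exclude=)`).
As a cheap diagnostic, `summary()` of a fit reports the observed
vote-count variance next to the model-implied one.

## Scoring submissions

`score_submissions()` evaluates each submission against a standard (for
instance the silver standard) restricted, by default, to the positions of
reference-network edges — predictions are comparable only on the shared
part of the candidate universe. Three complementary metrics are computed
from the contingency table:

* **Jaccard z-score**: the Jaccard similarity standardized against a null
  in which the predicted edge set is resampled uniformly with its size
  preserved. Under that null the overlap count is hypergeometric, so the
  Monte-Carlo default draws overlaps directly, and `method = "exact"`
  computes the null mean and SD by summation over the hypergeometric
  support — exact for any universe size. A degenerate null (zero SD) is
  flagged rather than returning an arbitrary z.
* **MCC**: with the standard convention that a zero denominator factor
  yields 0, flagged via an attribute.
* **TPR − FPR**: undefined (NA) when the standard has an empty class.

Final ranks average the per-metric ranks (rank 1 best, mid-rank ties), so
the ordering is invariant to monotone transformations of any single
metric. Undefined metric values are excluded pairwise with a warning —
degenerate submissions stay visible instead of silently scoring zero.

## The silver standard: Boolean logic + exact integer programming

Perturbation readouts (gene-expression fold-changes, phosphoprotein and
cytokine residuals) are ternarized by symmetric double thresholds — by
default ±2 on the signed fold-change scale, ±3 and ±2 standard residuals
respectively (`discretize()`). Values exactly at a threshold are called
(inclusive boundary, stated explicitly because "±2-fold" alone does not
fix the convention), and the map is odd-symmetric by construction.

Signal transduction on the unsigned reference map uses activating-OR
Boolean semantics: a node is active iff at least one retained incoming
edge starts at an active node, with the experiment's stimuli clamped on
(`propagate()`). Activation is *forced*, not permissive — if a retained
edge can activate a node, it does — so the only way to reconcile a node
called inactive is to remove edges. That is precisely the pruning
interpretation: reactions contradicted by the data leave the network.
Since the map carries no inhibitory annotations, both 0 and −1 calls are
treated as "not activated" for mismatch purposes, and a +1 call expects
the node active.

`prune_ilp()` minimizes (number of mismatched experiment × readout pairs)
\(+\ \varepsilon \times\) (kept edges) over all \(2^{|E|}\) edge subsets.
The default \(\varepsilon = 1/(10|E|)\) makes parsimony a pure tie-break
that can never trade against a single mismatch. The 0/1 program (with the
usual linearization of the OR constraints) is solved exactly by a
specialized branch-and-bound: under forced-OR semantics the node states
are simply the reachability closure of the kept edge set, so bounds come
from two reachability passes per experiment (optimistic and pessimistic),
strengthened by counting edges that must still be added for
required-active readouts. A greedy-descent incumbent from the keep-all
model makes the search a tight verification, and solutions are replaced
only when strictly better in a fixed top-down branching order, so results
are deterministic including ties. `max_iter` bounds the search; exceeding
it raises an error carrying the best incumbent. Correctness is tested
against exhaustive enumeration on randomized toy instances.

`sensitivity_sweep()` re-runs discretization and pruning over a grid of
thresholds and reports each kept-edge set's Jaccard similarity to the
base-threshold result, which is how robustness of the pruned network to
the discretization choice is quantified.

## Consensus-score analyses

The consensus score of an edge is the fraction of voters including it,
\(k_i/M\). `layer_consensus()` averages scores between consecutive layers
of the cascade (stimulus → receptor → adaptor → signaling → TF → target →
cytokine) with standard errors — the analysis that shows, for example,
whether edges downstream of transcription factors gather systematically
less consensus. Edges that skip layers are collected into an `other`
group with a warning rather than dropped. `node_consensus()` summarizes
the edges adjacent to, upstream of, or downstream of a single node, and
`compare_species()` compares two score sets over an edge subset — Welch's
unequal-variance t test by default, with a label-shuffling permutation
test (exhaustive enumeration when feasible) as the distribution-free
reference, since small per-node edge sets rarely justify the parametric
assumptions.

## What the synthetic generators emulate

`gen_layered_network()` draws a layered reference map with edges only
between consecutive layers, oriented top-down, every non-stimulus node
guaranteed an incoming edge. The defaults (24 nodes, roughly 25–35 edges)
are a deliberately desk-sized version of a realistic reference map (a few
hundred nodes and edges); they keep the exact ILP verification and the
end-to-end pipeline fast while preserving the cascade structure.

`gen_truth()` marks exactly `round(pi1 * N)` candidate edges true
(default \(\pi_1 = 0.16\), a realistic true-edge fraction for a curated
reference map), so recovery experiments are sharp; an i.i.d. Bernoulli
variant exists behind `method = "bernoulli"`. `gen_crowd()` implements
the generative model of the mixture exactly — per-predictor rates drawn
from Beta distributions, defaults \(\mu_T = 0.8\), \(\mu_F = 0.3\) at
concentration 50, M = 15 predictors — which makes
`count_votes() |> bbmix()` a parameter-recovery experiment with known
truth. One nuance is worth knowing: the crowd draws one rate per
*predictor*, shared across edges, so each edge's vote count is
Poisson-binomial — nearly binomial at the mean rate — and fits to such
crowds typically collapse to the binomial limit (flagged), recovering
\(\pi_1\) and the component means but not the concentration. That
mirrors the behaviour of fits to real crowds. The compound model proper
(rate redrawn per edge) is what the recovery tests simulate when they
check that all five parameters are identified. `gen_subnetwork()` draws the "biologically active" sub-map used to
generate perturbation data, keeping each edge with probability 0.7 but
preserving at least one incoming edge per node so stimuli still reach
readouts. `gen_panel()` propagates each experiment's stimuli through that
truth network and emits continuous readouts at 1.5× the discretization
threshold (active) or 0 (inactive) plus Gaussian noise (default SD 0.3),
with an optional flip rate for spurious calls.

What these generators do *not* emulate: platform-specific artefacts
(probe effects, detection limits), correlated submissions, feedback
loops, inhibitory edges, and time-course structure. Tests passing on this
synthetic family therefore demonstrate correctness of the machinery and
statistical behaviour under the model's own assumptions — not performance
on any particular real dataset.

All generators are pure functions of their seed: they save and restore
the caller's RNG state, and the pipeline derives a distinct sub-seed per
stage from one master seed, so adding a stage never perturbs another.

## Numerical choices and degenerate inputs

* Probability computations run in log space throughout (`lchoose` +
  `lbeta`); mixtures combine via log-sum-exp.
* `bbmix()` refuses constant vote vectors (nothing to separate) and flags
  grid-boundary fits (`pi_grid_boundary`), which is how
  single-component data announce themselves.
* Jaccard of two empty sets is NA in scoring (flagged), but 1 when
  comparing kept-edge sets in the sensitivity sweep (two identical empty
  networks are identical).
* Empty survivor sets in `precision_at_threshold()` yield NA precision
  with `defined = FALSE` rather than an error.
* Single-edge groups report NA standard errors; empty node
  neighbourhoods return a flagged empty result.

## Problem sizes used by the tests

The shipped test-suite exercises: mixture recovery on 20 replicates of
N = 10000 edges at M = 15; threshold correctness against brute force on
1000 random parameter draws; ILP-versus-enumeration equality on 100
random instances of up to 12 edges and 4 experiments; and a fully
self-contained pipeline (simulate → silver → score → fit → threshold →
build) on the default 24-node synthetic map, checked byte-identical
across reruns. These sizes were chosen as the smallest at which the
statistical claims are comfortably testable.

## Known limitations

* The mixture assumes exchangeable, conditionally independent
  predictors; correlated crowds bias \(\pi_1\) upward and the threshold
  downward. Exclusion of near-duplicates is manual.
* The Boolean model is unsigned and acyclic in spirit; cycles are handled
  by least-fixed-point propagation but feedback biology is out of scope.
* The exact pruning solver is exponential in the worst case; it is meant
  for desk-scale reference maps (up to roughly 50 edges with informative
  panels). Beyond that, expect the `max_iter` budget to bind.
* With few voters (small M) the vote histogram carries little
  information about four shape parameters; expect wide profile
  likelihoods and occasional component collapse, both reported as flags.
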