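---
title: "Benchmarking phylogenetic inference with phybench: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking phylogenetic inference with phybench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phybench)
```

## What the package measures

Benchmarking a phylogenetic inference tool requires three ingredients: data
whose true tree is known, a way to score an inferred tree against that truth,
and a way to stratify results by how hard each dataset actually is.
`phybench` provides all three as a self-contained toolkit: a GTR+Γ sequence
simulator with a calibrated insertion/deletion process, topological and
likelihood-based scoring (Robinson-Foulds, normalized tree distance, quartet
distance, log-likelihood differences, AU-test plausibility), and a
ground-truth difficulty score computed from replicate tree searches.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data generator does
and does not emulate.

## The substitution model

Sequences evolve under the general time-reversible (GTR) model with discrete
Gamma rate heterogeneity and an optional invariant-site class. The
instantaneous rate matrix is built from stationary frequencies
$\pi = (\pi_A, \pi_C, \pi_G, \pi_T)$ and six exchangeabilities $s_{ij}$ as
$q_{ij} = s_{ij}\,\pi_j$, then rescaled so that
$-\sum_i \pi_i q_{ii} = 1$: branch lengths are expected substitutions per
site. Transition matrices $P(t) = e^{Qt}$ are computed through the
symmetrized eigendecomposition $D^{1/2} Q D^{-1/2}$ (with $D =
\mathrm{diag}(\pi)$), which is numerically stable for reversible models and
is cached inside the model object.

Rate heterogeneity uses the standard mean-of-bin discretization: the
Gamma$(\alpha, \alpha)$ distribution (mean 1) is cut into $k$
equal-probability bins and each category rate is the bin's conditional mean,
so the category rates always average exactly to 1. We use category means
rather than medians because the mean discretization preserves the overall
expected rate without further rescaling; $k = 4$ is the default, matching
common tool defaults. The `p_inv` class (default 0) mixes in a zero-rate
category for invariant sites.

## Simulation with a Zipfian indel process

`simulate_msa()` evolves a root sequence of `n_sites` columns down the tree.
Each column carries a rate category; states move through `P(t r_c)` per
edge. The indel process is deliberately simple and testable:

* event counts per edge are Poisson with mean
  `rate × branch length × current sequence length`, for insertions and
  deletions separately — a per-site event-rate parameterization;
* event positions are uniform (insertions over `positions + 1`, deletion
  start positions over the current sequence);
* event lengths follow a truncated Zipf law $P(L=\ell) \propto
  \ell^{-s}$, $\ell = 1..\texttt{max\_len}$.

Insertions create fresh alignment columns registered in a global column
order, so the returned alignment is consistent across lineages: a lineage
that never carried a column shows `-` there. Inserted residues draw their
state from $\pi$ and their own rate category. Columns surviving in no leaf
are dropped. Substitutions are applied before indels on each edge; at the
event rates relevant here (well below 0.1 per site per unit length) the
ordering is immaterial for the matched statistics.

With both rates zero the indel machinery performs no random draws at all,
so gapless simulation and zero-rate indel simulation are bit-identical under
the same seed — a property the tests rely on.

What the generator does *not* emulate: alignment error, branch-heterogeneous
composition, codon structure, and realistic gap geometry beyond the three
matched statistics (see below). Conclusions from simulated benchmarks
therefore speak to inference behavior under the model class the tools
themselves assume, not to artifacts of real alignment pipelines.

## Calibrating the indel parameters

Empirical alignments are matched through three statistics: number of sites,
number of distinct site patterns, and gap fraction. `calibrate_indels()`
minimizes the weighted mean relative error

$$L(\theta) = \tfrac{1}{\sum w_i}\left[ w_1 \frac{|S - S^*|}{S^*} + w_2
\frac{|P - P^*|}{P^*} + w_3 \frac{|G - G^*|}{\max(G^*, [G^*{=}0])}\right]$$

with default weights $(1,1,1)$. The root sequence length is tuned per
candidate from a pilot simulation so the expected output length matches the
target, and each candidate is scored by the mean loss over a few replicate
simulations (default 3) to damp sampling noise.

The optimizer is a seeded sequential strategy with four stages:

1. the zero-indel candidate first, so gapless targets resolve immediately;
2. an analytically informed start — one indel event of mean length $m$ per
   site per unit branch length leaves roughly $m \cdot T$ gap cells per
   alignment cell on a tree of total length $T$, so rates near
   $G^*/(mT)$ land in the right basin — followed by random exploration
   within about a decade of that guess ($s \in [1.01, 4]$,
   `max_len` $\in 1..50$, rates clipped to $[10^{-3}, 0.5]$);
3. closed-loop refinement around the incumbent: both rates are rescaled
   toward the target gap fraction and the insertion/deletion balance is
   tilted toward the target pattern count (insertions add columns and hence
   patterns), with log-normal jitter whose width anneals on a fixed
   trial-index schedule; the root length is recentred using the incumbent's
   own observed sites-per-root-column ratio;
4. a deterministic coordinate polish: greedy single-parameter moves with
   shrinking steps.

All candidates are scored on the *same* seeded replicates (common random
numbers), which pairs the comparisons and turns the search into descent on
one fixed objective landscape. Candidates are drawn lazily from one seeded
stream and the stage boundaries are fixed trial indices, so runs with a
larger budget extend — never replace — the trial sequence of smaller
budgets, and the best-so-far loss is non-increasing in the budget. A
model-based proposal engine could be substituted without changing the
interface.

The loss has an intrinsic floor set by replicate sampling noise: with three
replicates, the mean absolute deviation of the simulated gap fraction from
its own expectation contributes of order $\mathrm{sd}(G)/G \cdot w_3/\sum w$
even at the true parameters, and this relative noise shrinks with alignment
area roughly as $1/\sqrt{\text{cells}}$. Self-recovery checks therefore use
gene-scale targets (12 taxa, 1000 sites), where calibration reaches losses
below 0.05 on at least 80% of targets at budget 60; at toy sizes
(8 taxa, 300 sites) the floor itself straddles that level.

## Likelihood engine

`site_log_likelihoods()` implements Felsenstein pruning with
pattern compression, per-node rescaling against underflow, and gap/ambiguity
cells treated as fully undetermined (partial likelihood 1 for every
compatible state — the convention of standard ML tools; there is no gap
state). Per-site values are exactly what the AU test resamples.

Branch-length optimization works edge-locally: one sweep computes lower
(tip-side) and upper (root-side) conditional likelihoods once, then solves
each branch's one-dimensional problem by bracketed line search on the log
scale within $[10^{-9}, 100]$. Because all edges update from the same sweep
state (a Jacobi-style update), a joint overshoot is possible along
near-degenerate directions (e.g. the two root-adjacent edges of a two-taxon
tree, where only their sum is identified); the optimizer therefore
re-evaluates the joint update and damps it by log-space halving until the
log-likelihood improves, so the reported likelihood never decreases.
`evaluate_tree()` adds coordinate descent over the Gamma shape,
exchangeabilities (GT fixed as reference) and frequencies (softmax
parameterization), in that order, with a default outer tolerance of
$10^{-3}$ log-likelihood units. Whether model parameters are re-optimized
per tree or held fixed is the caller's choice via the flags; the pipeline
default optimizes branch lengths only, holding the generating model fixed so
that scores are comparable across topologies.

## The AU test

`plausible_set()` runs the multiscale RELL bootstrap jointly over all
candidate trees: for each scale $r \in \{0.5, 0.6, \ldots, 1.4\}$ (the
CONSEL-style default) it resamples $\lfloor r\,n \rceil$ sites with
replacement $B$ times and records each tree's winning proportion, exact ties
sharing credit equally so the proportions form a partition. The
approximately unbiased p-value comes from the weighted least-squares fit of

$$\Phi^{-1}(1 - \mathrm{bp}_r) = d\sqrt{r} + c/\sqrt{r}$$

with delta-method binomial weights, and $p_{AU} = 1 - \Phi(d - c)$.
Proportions are clamped to $[1/(B+1), B/(B+1)]$ before the probit
transform. Two degenerate configurations carry no usable slope information
and are assigned their limits by convention: a tree that wins at most one
replicate per scale at every scale gets $p = 0$, and one that loses at most
one gets $p = 1$. The maximum-likelihood tree is always flagged plausible,
so the plausible set is never empty. Default $B$ is 10,000 in CONSEL-style
use; the package's own tests and pipeline default use $B = 1000$, which
resolves the 0.05 decision threshold to a standard error of about 0.007.
Testing is joint over the full candidate set (not pairwise against the best
tree), which matches how the plausible count enters the difficulty score.

## Ground-truth difficulty

From $N_{all}$ replicate searches with plausibility flags, with
$N^*$ counting unique topologies and $RF$ the mean pairwise normalized
Robinson-Foulds distance within a set,

$$d = \frac{1}{5}\left[ RF_{all} + RF_{pl} + \frac{N^*_{all}}{N_{all}} +
\frac{N^*_{pl}}{N_{pl}} + \left(1 - \frac{N_{pl}}{N_{all}}\right) \right].$$

A single easy likelihood peak gives values near 0 (100 identical, all
plausible searches give exactly 0.004); a rugged landscape of many
statistically indistinguishable topologies approaches 0.8–1. Scores are
bucketed into five cells of width 0.2 (bucket 4 closed at 1.0); a
$+10^{-9}$ guard before the floor keeps nominal boundary values such as 0.6
in their mathematically intended bucket despite binary floating-point
representation.

The definitional search count is 100; the pipeline's default is 20
replicate parsimony searches per dataset, a deliberate desk-scale choice
(configurable via `difficulty_searches`) that is logged prominently in every
run. Plausibility of the search set is determined by evaluating one
representative per unique topology and AU-testing them jointly.

## Built-in inferrers

* **bionj** — Gascuel's variance-weighted neighbor joining on
  Jukes-Cantor distances. JC rather than GTR-ML distances is a deliberate
  simplicity choice for a baseline: closed form, no optimization, and exact
  on additive matrices. Pairwise deletion handles gaps; saturated pairs
  ($p \ge 3/4$) clamp to distance 10.
* **parsimony** — Fitch parsimony with random-order stepwise addition
  followed by first-improvement NNI sweeps on the parsimony score; branch
  lengths are per-edge change counts divided by alignment length. This is a
  distinct named inferrer, not a claim of equivalence to any specific tool's
  parsimony starting tree (tie-breaking differs).
* **nni-ml** — hill climbing over NNI rearrangements of the likelihood,
  starting from the parsimony tree: neighbors are screened at current branch
  lengths, the top three are re-optimized, and the best strict improvement
  (default 0.1 lnL units) is accepted. NNI rather than SPR keeps the
  searcher small and predictable; it is a reference point, not a competitor
  to production searchers.

External tools plug in through an argument-template registry; a registered
tool whose binary is absent yields a `skipped` cell, never a failure of the
run.

## Pipeline and reference trees

Per dataset the pipeline simulates the alignment, runs every inferrer,
evaluates all trees plus the reference under identical flags, AU-tests the
full set (reference included), computes difficulty, and emits one record per
tool. In `simulated-truth` mode the generating tree is the reference and is
excluded from best-known redefinition — truth is fixed by construction. In
`empirical-bestknown` mode the reference is the highest-likelihood tree over
replicate searches and tool trees, thorough-search trees winning exact ties.
The `gap-superimposed` mode simulates gaplessly and copies a gap mask taken
from an indel simulation, isolating the effect of gap placement from the
substitution signal. The relative log-likelihood difference is reported as
$\Delta \ln L / |\ln L_{ref}|$.

Runs are resumable: alignments, per-tool trees and difficulty values are
cached per dataset, so re-running an untouched output directory performs no
new inference and adding a tool recomputes only that tool's cells.

## Synthetic corpus and selection

`generate_synthetic_corpus()` emulates a database of dataset descriptors:
random binary trees by sequential leaf attachment (uniform edge choice,
exponential branch lengths), Dirichlet-style stationary frequencies
(Gamma(10) draws renormalized — realistic mild compositional skew),
log-uniform exchangeabilities in $[0.25, 4]$ relative to GT, log-uniform
Gamma shape in $[0.05, 5]$, and a gap-fraction target uniform in
$[0.05, 0.4]$. Default sizes are 10–20 taxa and 200–800 sites — single-gene
scale. The pattern count of each entry is measured on an actual gapless
simulation, so the patterns-to-taxa ratio used for representative selection
reflects each entry's real signal. Selection follows the two-stage design:
a strict cut at the interpolated 95th percentile of taxa and patterns, then
one random pick from each of $k$ contiguous rank buckets of the
patterns-to-taxa ratio (equal-count buckets; the earlier buckets absorb the
remainder).

## Problem sizes used by the checks

The package's own end-to-end check runs 20 synthetic datasets with 10–20
taxa and 150–400 sites through all three built-in inferrers with 20
difficulty searches and $B = 1000$, and asserts a positive Spearman
correlation between difficulty and RF distance for every inferrer, plus the
resume contracts. Oracle comparisons run exhaustively over all 5-leaf
topology pairs and seeded random pairs up to 12 leaves (distances), up to 5
taxa and 4 sites (likelihood against exhaustive state summation), and 20
self-recovery targets (calibration). These sizes are the package's chosen
desk scale: large enough to exercise easy and rugged regimes, small enough
to re-run routinely.

## Known limitations

* The normalized tree distance is implemented as
  $|S_1 \triangle S_2| / (|S_1| + |S_2|)$ — a symmetric-difference
  normalization that coincides with normalized RF on binary trees. Other
  definitions circulate under similar names; the operation is isolated so a
  different normalization is a one-line change.
* The quartet distance is exact brute force over $\binom{n}{4}$
  quadruples, capped by default at 200 leaves.
* The NNI-ML searcher is a baseline, not a state-of-the-art heuristic; on
  rugged datasets it inherits the usual local-optimum behavior (which is
  precisely what the difficulty score quantifies).
* Gap realism extends only to the three matched statistics; run-length
  spectra per taxon are not matched.
* Amino-acid models are out of scope; the alphabet is fixed to DNA.
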