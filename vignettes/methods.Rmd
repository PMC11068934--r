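---
title: "Consensus Bayesian networks and key driver analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus Bayesian networks and key driver analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netkda)
```

# The problem

Gene co-expression tells us which genes move together, but not which genes
drive the movement. `netkda` implements a pipeline built around a directed
answer to that question: learn a Bayesian network — a directed acyclic graph
(DAG) whose joint distribution factorizes over node-given-parents conditional
probabilities — from bulk expression data, then rank genes by how much of the
network sits downstream of them. Genes that regulate many more downstream
genes than expected by chance ("type 1 key drivers"), or whose downstream
neighborhood is enriched for trait-associated GWAS candidate genes ("type 2
key drivers"), are candidate regulators worth taking to the bench. The
motivating application is adipose tissue and body-fat distribution
(WHR~adjBMI~), with networks learned per sex, depot and cohort and key
drivers required to replicate across two independent cohorts, but nothing in
the machinery is tissue-specific.

# Model and procedure

## Preprocessing

Expression arrives as a genes × samples matrix on a TPM-like scale. Genes
with abundance below 0.1 in **more than** 80% of samples are removed (the
boundary case — low in exactly 80% — is retained), values are transformed to
`ln(x + 1)` (defined at zero, order-preserving), and each gene is discretized
into three ordered levels `low < medium < high` by one-dimensional 3-means on
its own values. In one dimension the k-means optimum is a contiguous
partition of the sorted values, so we compute the exact global optimum by
searching the two cut points that minimize the within-cluster sum of squares
(prefix-sum arithmetic, O(m²) over m distinct values). Unlike restart-based
k-means this is deterministic and invariant to sample order, which the rest
of the pipeline assumes. Degenerate genes follow fixed rules: constant genes
become all-`medium`; two-valued genes map to `low`/`high`.

Cohorts can be split by a marker gene (e.g. XIST to confirm sex assignments);
the default threshold is the midpoint of a 2-means split of the marker.

## Priors

Two sources of prior information restrict and bias the structure search:

* **Correlation candidates.** All pairwise Pearson correlations on the
  continuous data; pairs with p < 0.01 become mutual candidate parents.
  Only candidate pairs are considered as edges, which both regularizes the
  problem and keeps the search tractable.
* **eGenes.** Genes with cis-eQTL support are more plausible regulators
  (information flows from DNA outward), so each edge whose parent is an
  eGene earns an additive score bonus (`egene_bonus`, default 1 on the BIC
  scale). It is a soft preference, not a constraint.

## Scoring

A network's score is the sum over node families of

```
BIC(node | parents) = k · ln(n) − 2 · ln(L),
```

where `L` is the maximized multinomial likelihood of the node's three-level
values under each joint parent configuration, `k = 2 · 3^|parents|` free
parameters, and `n` the number of samples, minus the eGene bonus per
eGene-parented edge. We minimize this score: the penalty grows exponentially
in the number of parents, so an edge must buy enough likelihood to justify
its parameters. Parent configurations never observed contribute zero
likelihood terms and no pruned parameters. Conditional tables are full joint
tables over the parent set; no product-of-marginals factorization is
assumed, since `P(A | B, C) = P(A|B) · P(A|C)` holds only under special
independence structure.

## Search

Structure learning is greedy hill climbing over edge additions, deletions
and reversals, restricted to candidate pairs, keeping the graph acyclic and
in-degree at most `max_parents` (default 3, a tractability cap standing in
for a Markov-blanket candidate search). At each step the move with the
largest score decrease is applied; near-ties are broken in a random order
drawn from the run's seed, which is how independently seeded runs explore
different local optima. Single-parent family scores for all candidate pairs
are computed upfront as nine 3×3 contingency tables via indicator-matrix
products, and move deltas are maintained incrementally, so a 200-gene run
at 500 samples takes a few seconds.

## Consensus and cycles

The pipeline runs `n_seeds` independently seeded searches (desk default 25;
the production scale for this kind of analysis is 1,000) and retains edges
present in at least 30% of runs (inclusive threshold); the retained edge's
confidence is its occurrence frequency. Because the merge can create
directed cycles, cycles are then removed: while any cycle remains, the
minimum-confidence edge lying on a cycle (an edge inside a non-trivial
strongly connected component) is deleted, ties broken by lexicographically
smallest (parent, child). The removed-edge log is kept with the result.

## Topology diagnostics

Constructed networks are checked for the two signatures of biological
networks. *Scale-freeness*: the out-degree distribution over parents
(k ≥ 1) is fitted as `log P(k) ~ −a · log k` by ordinary least squares;
biological networks typically show `a` in 2–3. *Small-worldness*: the
average local clustering coefficient of the undirected projection (nodes
with fewer than two neighbors contribute 0) is compared against
size-matched uniform random directed graphs, alongside the mean directed
shortest-path length over reachable ordered pairs.

Two estimator caveats are deliberate. The line fit is exact on collinear
degree distributions but is biased low on heavy-tailed finite samples,
because singleton tail degrees flatten the slope; we therefore check the
2–3 band on configuration-model graphs with truncated power-law out-degrees
(`simulate_scale_free()`, exponent 2.5, maximum degree 12, 1,500 parents),
where the estimator is consistent, rather than on growth-model graphs whose
finite-size distribution is not a pure power law. Maximum-likelihood
power-law fitting and degree-preserving rewiring nulls are out of scope.

## Key driver analysis

Every gene is profiled for its number of downstream genes at exact
shortest-path distances 1–10 (`G_d`); the network mean `NM_d` and
population SD `NS_d` at each distance summarize the background. Per gene
and distance, `Score_d = (G_d − NM_d) / NS_d` (0 when `NS_d = 0`), and

```
GeneScore = 1·S₁ + 1·S₂ + 1·S₃ + 0.75·S₄ + 0.5·S₅ + 0.25·S₆
            + 0.125·S₇ + 0.0625·S₈ + 0.03125·S₉
```

so a gene one SD above the mean at every distance scores exactly 4.71875.
The weight vector covers distances 1–9; the distance-10 count is profiled
but unweighted, as the scoring formula is defined. The top 10% of genes by
GeneScore are type-1 key drivers, with all boundary ties included
(`⌈0.10 · N⌉` genes in the absence of ties).

Type-2 drivers come from set enrichment: each gene's downstream
neighborhood (within 4 edges) is tested for over-representation of GWAS
candidate genes by a one-sided Fisher exact test — computed as the exact
upper hypergeometric tail, which is identical for a fixed-margin 2×2
table — over the universe of network genes excluding the focal gene (a gene
cannot be its own downstream gene). Significance is nominal p < 0.05 by
default, configurable to Benjamini–Hochberg. A network's key drivers are
the union of both types; drivers replicated in a second cohort's network
are the intersection of the two union sets.

## Replication null

Whether two networks share more key drivers than chance is judged by
permutation: draw as many random genes from each network's connected genes
as it has key drivers, count the intersection, repeat 10,000 times, and
report the add-one empirical p-value `(1 + #{null ≥ observed}) / (1 +
replicates)` — never exactly zero. The sampling universe is the connected
genes (the genes eligible to be key drivers), not the full input gene list.

## Assay metrics

Two closed-form readouts from the cellular validation side are included.
Doubling time from two counts of an exponentially growing population:
`Td = (T2 − T1) · ln 2 / ln(N2 / N1)` (days). And the standard
mitochondrial stress-test phenotypes from a 12-timepoint, per-cell
normalized oxygen-consumption trace, with conditions A (basal, timepoints
1–3), B (oligomycin, 4–6), C (FCCP, 7–9), D (rotenone/antimycin A, 10–12)
averaged as technical replicates: non-mitochondrial respiration D, basal
A−D, ATP-linked A−B, proton leak B−D, maximal capacity C−D, reserve C−A.
The identity basal = ATP-linked + proton leak holds algebraically.

# The synthetic-data generator

Real cohort data of this kind are restricted-access, so the package ships a
generator that emulates the statistical structure the analysis assumes and
lets every stage be tested end to end.

* `simulate_dag()` samples a topological order, designates a few hub
  regulators among several parentless roots, and attaches children
  preferentially to hubs (hub weight 30:1), giving sparse DAGs with clear
  high-out-degree regulators. Defaults — 200 genes, 5 hubs, edge density
  0.02 (about one edge per gene) — mirror the sparsity of published adipose
  Bayesian networks (~1.1 edges per connected gene). GWAS labels are
  planted 5-fold enriched among descendants of half the hubs over a 5%
  background, so type-2 signal exists by construction; eGene labels cover
  the hubs plus a random tenth of genes.
* `simulate_expression()` draws linear-Gaussian structural equations along
  the topological order — each gene is `effect` times the mean of its
  parents plus Gaussian noise (effect 1, noise SD 0.5; roots are standard
  normal) — then exponentiates onto a non-negative TPM-like scale so that
  the standard log-and-discretize preprocessing applies.
* `make_replicates()` draws two cohorts from one truth with independent
  noise, optionally unbalanced, emulating cross-cohort replication and
  size-matched sub-sampling experiments.

What the generator does **not** emulate: negative-binomial count noise,
batch and library-size structure, sex-chromosome biology, or hidden
confounders. Passing the recovery tests therefore shows the machinery is
correct and well-calibrated under its own assumptions, not that real-tissue
networks are recovered at these rates.

# Numerical choices and degenerate inputs

* Consensus threshold is inclusive (≥ 30%); duplicate edges on input keep
  the maximum confidence.
* `NS_d = 0` gives `Score_d = 0`; population (not sample) SD is used — the
  difference is a factor `√(N/(N−1))` common to all genes and does not
  change rankings.
* Neighborhoods that are empty or cover the whole universe get enrichment
  p = 1.
* Hill climbing stops at a local optimum or after `max_moves` accepted
  moves; score improvements below 10⁻⁹ are treated as ties.
* Degree-exponent fitting requires at least two distinct positive
  out-degrees; all-equal degrees raise an error rather than a fake fit.
* Shrinking populations give a negative doubling time with a warning;
  `N2 = N1` is an error.

# Problem sizes used in the checks

The automated checks run at desk scale, chosen once: structure recovery on
a 20-node truth (500 samples, 25 seeds, threshold 0.30) with skeleton
recall ≥ 0.6 and false discovery ≤ 0.4; hub recovery (5 hubs in 200 genes)
on the true DAG over 20 simulations and end to end over 4 truths × 10
learning seeds with mean type-1 recall ≥ 0.8 and ≥ 0.6 respectively;
oracle equivalence of the graph queries and enrichment p-values against
brute-force enumeration on networks up to 60 nodes; and the permutation
null against its hypergeometric expectation at 10,000 replicates.

# Known limitations

The hill climber is a local search; consensus over seeds mitigates but does
not eliminate local optima, and edge orientation is only identifiable up to
the data's dependence structure plus priors. Discretization to three levels
costs power for weak effects. The in-degree cap (3) biases against
high-in-degree targets. The permutation null treats the two networks'
key-driver sets as exchangeable random draws, ignoring degree structure.
All of these mirror the trade-offs of the production-scale analysis this
package models.
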