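---
title: "Interdependent site clusters in protein alignments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interdependent site clusters in protein alignments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevclust)
```

coevclust discovers groups of mutually interdependent columns ("sites",
"attributes") in a protein-family multiple sequence alignment, the amino-acid
patterns those groups carry, and the way the groups nest into a hierarchical
cluster tree. This vignette is the package's own account of the underlying
statistics, the tunable parameters, the numerical choices, and what the
validation on synthetic alignments does and does not establish.

## The interdependency measure

Each retained alignment column $X_i$ is a categorical random variable over
the 20 amino acids plus the gap symbol. For a pair of columns the package
computes plug-in (maximum-likelihood) estimates of the joint entropy
$H(X_i, X_{i'})$ and the mutual information $I(X_i, X_{i'})$, and summarises
their interdependency by the *redundancy*

$$R_{ii'} = \frac{I(X_i, X_{i'})}{H(X_i, X_{i'})} \in [0, 1],$$

i.e. normalised mutual information. $R = 1$ when one column is a bijective
relabelling of the other (perfect dependence) and $R = 0$ when the empirical
joint distribution factorises exactly. The normalisation matters: raw mutual
information grows with the number of symbols a column uses, which would bias
any clustering toward high-diversity columns; the ratio is also base-free, so
it does not matter which logarithm is used.

Numerical choices:

* Entropies are computed in nats internally, because the dependency test
  below compares $2 n I$ with a chi-square quantile — the G-statistic
  asymptotics — and that identity requires natural logarithms.
* When both columns are constant, $H = 0$ and the ratio is undefined; the
  pair carries no interdependency signal and is reported as $R = 0$
  ("uninformative"). Constant columns are likewise excluded from testing
  (df = 0, "not testable").
* Frequencies are plug-in, with no pseudocounts: probabilities are estimated
  directly from the sample.
* The gap symbol participates as an ordinary 21st symbol. Retained columns
  are less than 20% gapped, and dropping gapped rows per pair would make the
  effective $n$ vary from pair to pair.

Two sites are called dependent when

$$R_{ii'} \ge \frac{\chi^2_{(G_i - 1)(G_{i'} - 1)}(1 - \alpha)}{2\,n\,H(X_i, X_{i'})},$$

equivalently $2 n I \ge \chi^2$, with $\alpha = 0.05$ by default. $G_i$ is by
default the number of *observed* distinct symbols at site $i$, not the fixed
21-letter alphabet: in sparse columns a fixed $(20)(20)$ degrees-of-freedom
count would be wildly conservative. Both conventions are implemented
(`df_alphabet = "observed"` / `"full"`), and the two routes to the decision
($R \cdot 2nH$ versus $2nI$) are verified to agree exactly in the test suite.

## SR, modes, and k-modes clustering

Within a candidate cluster, $SR(i)$ is the sum of $R_{ii'}$ from site $i$ to
every other member. The *mode* of a cluster is the member with maximal $SR$
(ties go to the lowest site label), and a cluster is scored by

$$SR(\mathit{mode}) = \frac{SR(\mathit{mode})}{N^*}, \qquad N^* = |\text{cluster}| - 1,$$

the mode's average redundancy to its cluster mates. $N^*$ is read as "the
number of pairs involving the mode", so a two-site cluster scores exactly its
$R$ — the natural calibration when ranking clusters of different orders. The
alternative reading (all $\binom{m}{2}$ pairs) is available via
`sr_mode_value(..., n_star = "all_pairs")`.

`run_kmodes()` partitions the $N$ sites into $k$ clusters:

1. draw $k$ distinct sites as candidate modes (seeded, so runs are
   reproducible);
2. assign every remaining site to the cluster whose mode it is most
   redundant with;
3. recompute each cluster's mode; repeat 2–3 until no site changes cluster,
   or `max_iter` (default 100) iterations.

Tie handling is deterministic: a site that ties between clusters keeps its
current cluster if it is among the best, otherwise joins the one with the
lowest mode label — this promotes convergence and removes order dependence.
The algorithm is a local optimiser: when all initial modes land inside one
planted block it can converge to a sub-optimal partition, so `sweep_k()`
accepts `restarts` and keeps, per $k$, the configuration with the largest
within-cluster redundancy objective
$\sum_c \sum_{i \in c} R_{i,\mathit{mode}(c)}$. The recovery experiments in
the test suite use 5 restarts; with strongly coupled planted blocks the best
configuration is then the same from every master seed.

`sweep_k()` runs $k$ from $N-1$ down to 2 by default. Nothing at a single
$k$ is hierarchical; the hierarchy appears when the sweep's configurations
are compared across $k$, which is what the cluster tree formalises.

## Patterns and adjusted residuals

A *compound event* assigns one amino acid to each site of a cluster. Its
significance is judged against the expectation under full independence of
the sites: with marginal frequencies $p_j$,

$$e_\lambda = n \prod_j p_j, \qquad
  \nu_\lambda = e_\lambda \prod_j (1 - p_j), \qquad
  \gamma_\lambda = \frac{o_\lambda - e_\lambda}{\sqrt{\nu_\lambda}}.$$

This variance is the Haberman standardised-residual form generalised to
order-$m$ events; for $m = 2$ it reduces exactly to the classical two-way
contingency-table adjusted residual, and the test suite checks that identity
to $10^{-9}$ on random pairs. Under independence $\gamma$ is asymptotically
standard normal, so the default cutoff 3.29 corresponds to a two-sided
confidence of 99.9% (2.58 for 99%); `confidence_to_cutoff()` converts any
level. The comparison is strict ($\gamma > $ cutoff).

Candidate events are only the symbol combinations actually observed in at
least one row — the $21^m$ lattice is never enumerated — and by default only
full-order events spanning all cluster sites are reported
(`span = "sub"` additionally enumerates every subset of two or more sites).
Gap-containing events are legal (gaps are column symbols after filtering)
and can be excluded with `allow_gaps = FALSE`.

**Validity caveat.** $\gamma$ is an asymptotic statistic. With a 20-letter
alphabet and small $n$, expected counts $e_\lambda$ are tiny and every
singleton observation produces an enormous $\gamma$: the statistic is then
strongly anti-conservative and the fixed cutoff does not control the error
rate. The classical rule of thumb is that expected cell counts should be at
least about 5, i.e. $n / |G|^m \gtrsim 5$. The package's null-calibration
simulation therefore uses a binary alphabet and order-2 clusters at
$n = 50$ — the regime where the approximation is honest — and confirms that
fewer than 5% of 200 null replicates yield any pattern call at 3.29. On real
alignments the sample sizes are typically in the hundreds to thousands of
unique sequences, but users screening small or highly diverse clusters
should treat large $\gamma$ values on near-singleton events with suspicion
(the `expected` column makes them easy to spot).

## The cluster tree

Across the sweep, identical site sets are deduplicated into tree nodes. A
cluster of order $\ge 2$ is linked to a parent by the nesting rule: in the
configuration at the next $k$ below the cluster's last appearance, the
cluster containing *strictly more than half* of its sites, provided that
cluster has strictly larger order (maximal overlap wins ties, then smaller
parent order, then lowest mode label). Clusters with no qualifying parent
stay unattached — they may be locally meaningful structure and are retained.
Singleton clusters are recorded as nodes but never start chains: branches
begin at the lowest-order (pairwise and upward) clusters, mirroring how the
tree is laid out from second-order clusters downward.

* A *branch* is the chain followed from each childless cluster of order
  $\ge 2$ through parent links; branches are numbered left-to-right by their
  root's minimum site label.
* A *node* in the narrow sense is a cluster where two or more branches
  converge; the set of branches reaching a common node is a *module*.
  Branch groups with no converging node but pairwise interlacing of at least
  `min_shared = 2` sites are *declared* modules — an approximation to
  judgement-based grouping, for which no sharp published criterion exists.
* A branch is *Type II* when at least `min_interlace = 1` of the sites in
  its exclusive clusters also occurs in another branch's exclusive clusters,
  else *Type I*. Interlacing is computed on exclusive (pre-convergence)
  clusters only: a shared tail after a merge is convergence, not
  interlacing, and must not flip both branches to Type II.
* The *representative* of a branch is its cluster with maximal
  $SR(\mathit{mode})$; a higher-order cluster within a relative 5% of the
  maximum is preferred (more sites, more informative), with remaining ties
  to larger order then lowest mode label. The tolerance is relative — e.g.
  0.245 is within 5% of 0.25, while 0.20 is not within 5% of 0.26.

## Preprocessing

`preprocess_msa()` applies, in order: optional removal of insert-state
columns (lowercase / `"."` in the Pfam Stockholm dialect — the default for
Stockholm input), removal of columns with gap fraction $\ge$ 20% (strict:
a column at exactly 20% is dropped), then collapsing of duplicate rows to
their first occurrence. Ambiguity codes (B, Z, X, U, O, J) map to the gap
symbol by default since the working alphabet is the 20 amino acids; how the
original analyses treated them is not documented anywhere we know of, so
this is a package choice and can be disabled. Fewer than five unique
sequences triggers a warning — below that, interdependency estimates are
meaningless. Site labels are reference numbering (e.g. offset so that 69
retained columns are reported as sites 6–74), carried through every
downstream report.

## The synthetic generator

`simulate_msa()` is first-class, tested code, and the package's validation
substrate. It plants:

* **blocks** — each block of sites shares a latent i.i.d. symbol stream;
  each member column copies the latent symbol with probability $\rho$ and
  otherwise draws uniform background noise. The copy model was chosen over
  pairwise-potential models because within-block mutual information is
  monotone in $\rho$ and the extremes are exact ($\rho = 1$ gives $R = 1$;
  $\rho = 0$ is the null);
* **hierarchy** — groups of blocks additionally copy a shared group-level
  stream with probability $\rho_2$, so blocks merge as $k$ decreases,
  giving ground-truth parent–child edges for the tree;
* **patterns** — chosen symbol tuples written jointly into a target fraction
  of rows (patterns on the same site set share one row partition, so their
  frequencies must sum below 1);
* **gaps** — per-cell gaps at `gap_rate`, capped per column strictly below
  20% by construction.

The background is uniform over a configurable alphabet (default all 20
residues) to keep marginal entropies high and degrees of freedom stable.

What the generator does *not* emulate: phylogenetic relatedness (rows are
exchangeable; real alignments carry tree-structured correlation that
inflates apparent covariation), alignment error, biased amino-acid
composition, and conservation gradients along the sequence. Passing the
planted-recovery tests therefore shows the estimator and optimiser are
correct under the stated model — not that every cluster found in a real
family is biologically meaningful.

## Validation problem sizes

The test suite runs entirely on synthetic data built at run time: oracle
equivalences on 100 random column pairs; exhaustive-search comparisons on
5-site matrices (all 15 bipartitions, all 6 pair merges); block recovery at
$n = 200$ rows, 12 sites, 3 blocks, $\rho = 0.8$, adjusted Rand index
$\ge 0.9$ against the planted partition; planted merge schedules of 4 blocks
recovered edge-for-edge; null calibration over 200 replicates at $n = 50$;
and byte-identical reproducibility of a full $k$-sweep pipeline on a
200-row, 70-site alignment. These sizes keep the whole suite under a minute
while leaving each statistic in the regime it needs (the calibration
argument above fixes its own sizes).

## Known limitations

* No correction for phylogenetic relatedness or sequence weighting, and no
  average-product correction; all are deliberate non-goals, matching the
  method being characterised.
* The fixed adjusted-residual cutoff performs no multiple-testing correction
  across candidate events beyond its 99.9% level.
* k-modes finds local optima; use `restarts` (and compare objectives) on
  weakly structured data. On such data different seeds may legitimately
  return different partitions — stability is a property of the data, not a
  guarantee of the algorithm.
* Declared (interlacing-based) modules approximate a judgement call; the
  `min_shared` threshold is a package choice with no external ground truth.
* Historical published cluster tables for specific families (ubiquitin,
  transthyretin) depend on the Pfam alignment versions used at the time and
  are treated as documentation examples, not regression targets.
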