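# coevclust

Discovering clusters of mutually interdependent sites in protein-family
multiple sequence alignments — and the amino-acid patterns and hierarchical
sub-domain structure they reveal.

## What it does, and for whom

Columns of a protein-family alignment do not vary independently: residues
that touch in the 3D structure, stabilise the same fold element, or share a
binding function co-vary across the family. For sequence analysts who want
to read that signal directly out of an alignment — without a solved
structure — `coevclust` implements a complete statistical pipeline:

1. **Interdependency redundancy.** Every pair of aligned sites is scored by
   normalised mutual information, *R* = *I*(*X<sub>i</sub>*, *X<sub>i'</sub>*) /
   *H*(*X<sub>i</sub>*, *X<sub>i'</sub>*) ∈ [0, 1] (1 = perfectly dependent,
   0 = exactly independent), with a chi-square test for pairwise dependence
   (*R* ≥ χ²<sub>(G<sub>i</sub>−1)(G<sub>i'</sub>−1)</sub> / 2*nH*).
2. **k-modes attribute clustering.** Sites are partitioned into *k* clusters
   by iterative mode selection and reassignment, maximising within-cluster
   redundancy; the *mode* is the site with the highest sum of redundancies
   *SR*(*i*) to its cluster mates, and clusters are ranked by
   *SR*(mode)/*N*\*. The clustering is swept from *k* = *N*−1 down to 2.
3. **Pattern discovery.** Within a cluster, each observed amino-acid
   combination λ is scored by its adjusted residual
   γ<sub>λ</sub> = (o<sub>λ</sub> − e<sub>λ</sub>)/√ν<sub>λ</sub> against
   the independence expectation; γ > 3.29 marks 99.9% confidence
   (2.58 for 99%).
4. **Cluster tree.** Clusters across the sweep are assembled into a nesting
   hierarchy with branches (Type I: self-contained; Type II: interlacing),
   convergence nodes, modules, and one representative cluster per branch —
   a map of candidate sub-domains.

A seeded synthetic-alignment generator with planted dependent blocks,
nesting hierarchies, patterns and gaps (`simulate_msa()`) backs every claim
with ground-truth tests. Results are tibbles or objects with broom-style
`tidy()`/`glance()` methods and `ggplot2::autoplot()` views.

## Worked example

Simulate a family of 200 sequences over 20 sites with three planted blocks
(sites 1–4, 5–8, 9–12; blocks 1 and 2 merge at a second level) and one
planted NK pattern, then run the analysis:

```r
library(coevclust)

sim <- simulate_msa(200, 20, blocks = list(1:4, 5:8, 9:12),
                    hierarchy = list(c(1, 2)), rho = 0.85, rho2 = 0.5,
                    patterns = list(list(sites = c(1, 2),
                                         symbols = c("N", "K"), freq = 0.35)),
                    seed = 42)
aln  <- preprocess_msa(sim$aln)     # <20%-gap columns, unique sequences
rmat <- redundancy_matrix(aln)
glance(rmat)
#> # A tibble: 1 × 5
#>   n_sites n_seqs mean_R max_R min_R
#>     <int>  <int>  <dbl> <dbl> <dbl>
#> 1      20    200  0.214 0.629 0.156
```

The strongest pairs are exactly the planted ones — sites 1–2 carry both the
block coupling and the planted pattern:

```r
head(dplyr::arrange(tidy(rmat), dplyr::desc(R)), 3)
#> # A tibble: 3 × 5
#>   site_i site_j     R     I     H
#>    <int>  <int> <dbl> <dbl> <dbl>
#> 1      1      2 0.629  1.88  2.99
#> 2      6      7 0.604  2.22  3.68
#> 3      3      4 0.603  2.22  3.69
```

Sweep *k*, inspect the planted *k* = 3 partition, and build the tree:

```r
sw <- sweep_k(rmat, seed = 42, restarts = 3)
sw$configs[["3"]]
#> <kmodes_config> k = 3, 4 iterations, converged; objective = 6.333
#>   [1] mode 2, SR(mode) = 0.391: 1 2 3 4 16
#>   [2] mode 6, SR(mode) = 0.363: 5 6 7 8 15 17 18 19
#>   [3] mode 9, SR(mode) = 0.372: 9 10 11 12 13 14 20

tree <- build_cluster_tree(sw)
glance(tree)
#> # A tibble: 1 × 6
#>   n_clusters n_edges n_branches n_type_ii n_modules n_unattached
#>        <int>   <int>      <int>     <int>     <int>        <int>
#> 1         58         19         21        21         1           12
```

Each planted block reappears (with a little noise) as a cluster whose
*SR*(mode) ranks it highly; the three blocks' branches carry the signal.
Finally, the planted pattern is recovered with a large adjusted residual:

```r
enumerate_patterns(aln, c(1, 2), cutoff = 3.29)[3, ]
#> # A tibble: 1 × 8
#>   sites symbols order observed expected residual variance adjusted_residual
#>   <chr> <chr>   <int>    <int>    <dbl>    <dbl>    <dbl>             <dbl>
#> 1 1,2   NK          2       71     30.4     40.6     11.3              12.1
```

71 of 200 rows carry NK jointly at sites 1–2 against an independence
expectation of 30.4 — γ ≈ 12, far beyond the 3.29 (99.9%) cutoff.

For file-based work, `run_pipeline(run_config(input = "family.fasta",
out_dir = "out", seed = 1))` executes preprocess → redundancy matrix →
k-sweep → tree → patterns and writes TSV/JSON/DOT artifacts; the same
pipeline is scriptable from a shell via the thin wrapper installed at
`cli/coevclust` (subcommands `run`, `simulate`, `preprocess`, `rmatrix`,
`cluster`, `tree`, `patterns`).

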