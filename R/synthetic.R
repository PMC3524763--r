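# Seeded synthetic alignments with planted structure.
#
# Dependence is planted by a latent-stream copy model: each block of sites
# shares a latent symbol stream, and each member site copies the latent
# symbol with probability rho (else draws i.i.d. background noise). Within a
# block, pairwise mutual information is monotone in rho and R -> 1 as
# rho -> 1, which makes planted partitions analytically easy to reason
# about (a pairwise-potential model would not have this property). A
# two-level hierarchy couples blocks through a shared group stream with
# probability rho2, so blocks merge as k decreases. Amino-acid patterns are
# planted by overwriting a target fraction of rows at chosen sites.

#' Generate a synthetic alignment with planted interdependent blocks
#'
#' @param n_rows Number of sequences.
#' @param n_sites Number of aligned sites; sites not covered by `blocks` are
#'   i.i.d. background noise.
#' @param blocks List of disjoint site-index vectors, each a planted block of
#'   mutually dependent sites.
#' @param rho Copy probability in `[0, 1]`, scalar or one per block: the
#'   probability a member site copies its block's latent symbol rather than
#'   drawing background noise. `rho = 1` makes block columns identical up to
#'   relabelling; `rho = 0` is the null.
#' @param hierarchy Optional list of integer vectors grouping block indices;
#'   blocks in a group copy a shared group-level stream with probability
#'   `rho2`, planting a second nesting level.
#' @param rho2 Group-level copy probability (scalar or one per group).
#' @param patterns List of planted compound events, each
#'   `list(sites =, symbols =, freq =)`: the given symbols are written jointly
#'   at the given sites in a `freq` fraction of rows. Patterns over the same
#'   site set share one row partition, so their frequencies must sum to < 1.
#' @param gap_rate Per-cell gap probability; must be `< 0.2` and achieved
#'   per-column gap fractions are capped below 0.2 by construction.
#' @param alphabet Background symbol set (default the 20 amino acids).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list with `aln` (an [msa]) and `truth`: the planted `partition`
#'   (integer block id per site, background sites as singletons), `blocks`,
#'   `n_blocks`, `patterns`, `hierarchy` and `seed`.
#' @export
simulate_msa <- function(n_rows, n_sites, blocks = list(), rho = 1,
                         hierarchy = list(), rho2 = 0.3,
                         patterns = list(), gap_rate = 0,
                         alphabet = AA_RESIDUES, seed = 1) {
  if (length(blocks) > 0) {
    all_sites <- unlist(blocks)
    if (anyDuplicated(all_sites)) abort("`blocks` must be disjoint.")
    if (any(all_sites < 1 | all_sites > n_sites)) {
      abort("Block sites must lie in 1..n_sites.")
    }
  }
  rho <- rep_len(rho, max(1, length(blocks)))
  if (any(rho < 0 | rho > 1)) abort("`rho` must lie in [0, 1].")
  if (gap_rate < 0 || gap_rate >= 0.2) {
    abort("`gap_rate` must lie in [0, 0.2); columns must stay <20% gapped.")
  }
  if (length(patterns) > 0) {
    keys <- vapply(patterns, function(p) set_key(p$sites), character(1))
    for (k in unique(keys)) {
      tot <- sum(vapply(patterns[keys == k], function(p) p$freq, numeric(1)))
      if (tot >= 1) {
        abort(paste0("Pattern frequencies on sites {", k,
                     "} sum to ", tot, " >= 1; infeasible."))
      }
    }
    for (p in patterns) {
      if (length(p$sites) != length(p$symbols)) {
        abort("Each pattern needs one symbol per site.")
      }
      if (p$freq <= 0 || p$freq >= 1) {
        abort("Pattern frequencies must lie in (0, 1).")
      }
    }
  }
  rho2 <- rep_len(rho2, max(1, length(hierarchy)))

  with_seed_local(seed, {
    mat <- matrix(sample(alphabet, n_rows * n_sites, replace = TRUE),
                  nrow = n_rows)
    group_stream <- lapply(seq_along(hierarchy), function(g) {
      sample(alphabet, n_rows, replace = TRUE)
    })
    block_group <- rep(NA_integer_, length(blocks))
    for (g in seq_along(hierarchy)) block_group[hierarchy[[g]]] <- g
    for (b in seq_along(blocks)) {
      latent <- sample(alphabet, n_rows, replace = TRUE)
      g <- block_group[b]
      if (!is.na(g)) {
        take <- runif(n_rows) < rho2[g]
        latent[take] <- group_stream[[g]][take]
      }
      for (s in blocks[[b]]) {
        copy <- runif(n_rows) < rho[b]
        mat[copy, s] <- latent[copy]
      }
    }
    if (length(patterns) > 0) {
      keys <- vapply(patterns, function(p) set_key(p$sites), character(1))
      for (k in unique(keys)) {
        grp <- patterns[keys == k]
        u <- runif(n_rows)
        lo <- 0
        for (p in grp) {
          hit <- u >= lo & u < lo + p$freq
          lo <- lo + p$freq
          mat[hit, p$sites] <- matrix(p$symbols, nrow = sum(hit),
                                      ncol = length(p$sites), byrow = TRUE)
        }
      }
    }
    if (gap_rate > 0) {
      cap <- ceiling(0.2 * n_rows) - 1L
      for (s in seq_len(n_sites)) {
        g_rows <- which(runif(n_rows) < gap_rate)
        if (length(g_rows) > cap) g_rows <- sample(g_rows, cap)
        mat[g_rows, s] <- GAP
      }
    }
    partition <- rep(NA_integer_, n_sites)
    for (b in seq_along(blocks)) partition[blocks[[b]]] <- b
    nb <- length(blocks)
    free <- which(is.na(partition))
    partition[free] <- nb + seq_along(free)
    rownames(mat) <- paste0("sim", seq_len(n_rows))
    list(aln = new_msa(mat, seq_len(n_sites), validate = FALSE),
         truth = list(partition = partition, blocks = blocks,
                      n_blocks = nb, patterns = patterns,
                      hierarchy = hierarchy, seed = seed))
  })
}

#' Planted nesting sweep from a simulation truth
#'
#' Converts the planted partition and merge schedule of a [simulate_msa()]
#' truth into explicit cluster configurations: one at the planted number of
#' clusters, and one per hierarchy level with each group's blocks merged.
#' Useful as a ground-truth sweep for [build_cluster_tree()].
#'
#' @param truth The `truth` component returned by [simulate_msa()].
#' @param rmat Optional [redundancy_matrix()] for mode/`SR(mode)` annotation.
#' @return A `kmodes_sweep` of planted configurations.
#' @export
truth_sweep <- function(truth, rmat = NULL) {
  part <- truth$partition
  base <- split(seq_along(part), part)
  configs <- list(as_kmodes_config(unname(base), k = length(base),
                                   rmat = rmat))
  if (length(truth$hierarchy) > 0) {
    grouped <- lapply(truth$hierarchy, function(g) sort(unlist(base[g])))
    rest <- base[setdiff(seq_along(base), unlist(truth$hierarchy))]
    merged <- c(grouped, unname(rest))
    configs <- c(configs, list(as_kmodes_config(merged, k = length(merged),
                                                rmat = rmat)))
  }
  as_kmodes_sweep(configs)
}
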