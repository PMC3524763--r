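# Hierarchical cluster tree over the k-sweep.
#
# Clusters found at different k nest: a cluster of few sites (low order) is
# usually contained in a larger cluster at a smaller k. Deduplicated clusters
# become tree nodes; a child of order m links to the cluster holding the
# majority of its sites in the configuration one k-step below its last
# occurrence, provided that cluster has strictly larger order. Chains from
# the lowest-order clusters are branches; branches converging on a shared
# node (or strongly interlacing) form modules.

#' Wrap an explicit partition as a k-modes configuration
#'
#' Useful for assembling cluster trees from partitions not produced by
#' [run_kmodes()] (e.g. planted hierarchies in simulations).
#'
#' @param clusters List of disjoint site-label vectors.
#' @param k Cluster count tag (defaults to `length(clusters)`).
#' @param rmat Optional [redundancy_matrix()]; when given, modes and
#'   `sr_mode` values are computed, otherwise the lowest label stands in as
#'   mode and `sr_mode` is 0.
#' @return A `kmodes_config`.
#' @export
as_kmodes_config <- function(clusters, k = length(clusters), rmat = NULL) {
  clusters <- lapply(clusters, sort)
  if (is.null(rmat)) {
    modes <- vapply(clusters, min, numeric(1))
    srm <- rep(0, length(clusters))
  } else {
    modes <- vapply(clusters, function(cl) compute_mode(rmat, cl),
                    numeric(1))
    srm <- vapply(clusters, function(cl) sr_mode_value(rmat, cl),
                  numeric(1))
  }
  ord <- order(modes)
  structure(list(k = k, clusters = clusters[ord], modes = modes[ord],
                 sr_mode = srm[ord], iterations = 0L, converged = TRUE,
                 seed = NULL, objective = NA_real_,
                 labels = sort(unlist(clusters))),
            class = "kmodes_config")
}

#' Bundle configurations into a sweep
#'
#' @param configs List of `kmodes_config`s (distinct `k` values).
#' @return A `kmodes_sweep`.
#' @export
as_kmodes_sweep <- function(configs) {
  ks <- vapply(configs, function(c) c$k, numeric(1))
  ord <- order(ks, decreasing = TRUE)
  configs <- configs[ord]
  names(configs) <- ks[ord]
  structure(list(configs = configs, k_values = ks[ord], seed = NULL,
                 restarts = NA_integer_, labels = configs[[1]]$labels),
            class = "kmodes_sweep")
}

set_key <- function(sites) paste(sort(sites), collapse = ",")

tree_nodes <- function(sweep) {
  rows <- purrr::map_dfr(sweep$configs, function(cfg) {
    tibble(k = cfg$k,
           sites = lapply(cfg$clusters, sort),
           order = lengths(cfg$clusters),
           mode = cfg$modes, sr_mode = cfg$sr_mode)
  })
  rows$key <- vapply(rows$sites, set_key, character(1))
  nodes <- rows |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(sites = .data$sites[1], order = .data$order[1],
                     mode = .data$mode[1], sr_mode = .data$sr_mode[1],
                     k_first = max(.data$k), k_last = min(.data$k),
                     k_values = list(sort(unique(.data$k))),
                     .groups = "drop") |>
    dplyr::arrange(.data$order,
                   vapply(.data$sites, min, numeric(1)))
  nodes$node <- seq_len(nrow(nodes))
  nodes
}

find_parent <- function(sites, cfg, node_lookup) {
  m <- length(sites)
  overlap <- vapply(cfg$clusters, function(cl) length(intersect(sites, cl)),
                    numeric(1))
  ord <- lengths(cfg$clusters)
  ok <- overlap > m / 2 & ord > m
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  cand <- cand[order(-overlap[cand], ord[cand], cfg$modes[cand])]
  best <- cand[1]
  list(parent_key = set_key(cfg$clusters[[best]]), overlap = overlap[best])
}

#' Build the cluster tree from a k-sweep
#'
#' Deduplicates identical site sets across the sweep into nodes, links each
#' order->=2 cluster to its nesting parent (the majority-containing,
#' strictly larger cluster in the configuration at the next lower k after the
#' cluster's last appearance), traces branches from the lowest-order
#' clusters, classifies them Type I/II by interlacing, groups converging or
#' strongly interlacing branches into modules, and selects a representative
#' cluster per branch by `SR(mode)`.
#'
#' @param sweep A `kmodes_sweep` (from [sweep_k()] or [as_kmodes_sweep()])
#'   over a contiguous k range.
#' @param min_interlace Minimum number of shared sites between two branches'
#'   exclusive clusters for Type II classification (default 1).
#' @param min_shared Minimum pairwise shared-site count for grouping
#'   non-converging branches into a declared module (default 2).
#' @param rep_tolerance Relative `SR(mode)` tolerance for preferring a
#'   higher-order representative (default 0.05).
#' @return A `cluster_tree` with tibbles `nodes`, `edges`, `branches`,
#'   `modules`, `representatives`.
#' @export
build_cluster_tree <- function(sweep, min_interlace = 1, min_shared = 2,
                               rep_tolerance = 0.05) {
  stopifnot(inherits(sweep, "kmodes_sweep"))
  if (length(sweep$configs) == 0) abort("Empty sweep.")
  nodes <- tree_nodes(sweep)
  key_to_id <- setNames(nodes$node, nodes$key)
  ks <- sort(sweep$k_values, decreasing = TRUE)

  edges <- purrr::map_dfr(seq_len(nrow(nodes)), function(i) {
    if (nodes$order[i] < 2) return(NULL)
    k_next <- ks[ks < nodes$k_last[i]][1]
    if (is.na(k_next)) return(NULL)
    hit <- find_parent(nodes$sites[[i]], sweep$configs[[as.character(k_next)]],
                       key_to_id)
    if (is.null(hit)) return(NULL)
    tibble(child = nodes$node[i], parent = unname(key_to_id[hit$parent_key]),
           overlap = hit$overlap)
  })
  if (nrow(edges) == 0) {
    edges <- tibble(child = integer(), parent = integer(),
                    overlap = integer())
  }

  parent_of <- setNames(rep(NA_integer_, nrow(nodes)), nodes$node)
  if (nrow(edges) > 0) parent_of[as.character(edges$child)] <- edges$parent

  roots <- nodes$node[nodes$order >= 2 &
                        !(nodes$node %in% edges$parent)]
  roots <- roots[order(vapply(nodes$sites[match(roots, nodes$node)], min,
                              numeric(1)))]
  branches <- lapply(roots, function(r) {
    chain <- r
    while (!is.na(parent_of[as.character(chain[length(chain)])])) {
      nxt <- parent_of[[as.character(chain[length(chain)])]]
      if (nxt %in% chain) break   # guard; edges increase order so no cycles
      chain <- c(chain, nxt)
    }
    chain
  })
  names(branches) <- seq_along(branches)

  tree <- structure(list(nodes = nodes, edges = edges, branches = branches,
                         min_interlace = min_interlace,
                         min_shared = min_shared,
                         rep_tolerance = rep_tolerance),
                    class = "cluster_tree")
  tree$branch_types <- classify_branches(tree, min_interlace)
  tree$modules <- detect_modules(tree, min_shared)
  tree$representatives <- select_representative(tree,
                                                tolerance = rep_tolerance)
  tree
}

branch_exclusive_sites <- function(tree) {
  counts <- table(unlist(tree$branches))
  lapply(tree$branches, function(chain) {
    own <- chain[counts[as.character(chain)] == 1]
    sort(unique(unlist(tree$nodes$sites[match(own, tree$nodes$node)])))
  })
}

#' Classify branches as Type I or Type II
#'
#' A branch is Type II when at least `min_interlace` of the sites in its
#' exclusive clusters (clusters not shared with another branch's chain) also
#' occur in another branch's exclusive clusters; otherwise Type I.
#' Convergence on a shared node is not interlacing.
#'
#' @param tree A [build_cluster_tree()] result.
#' @param min_interlace Shared-site threshold (default from the tree).
#' @return A tibble with `branch`, `root`, `n_clusters`, `type`.
#' @export
classify_branches <- function(tree, min_interlace = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  min_interlace <- min_interlace %||% tree$min_interlace
  own <- branch_exclusive_sites(tree)
  nb <- length(tree$branches)
  type <- rep("I", nb)
  if (nb > 1) {
    for (a in seq_len(nb - 1)) {
      for (b in (a + 1):nb) {
        if (length(intersect(own[[a]], own[[b]])) >= min_interlace) {
          type[a] <- type[b] <- "II"
        }
      }
    }
  }
  tibble(branch = seq_len(nb),
         root = vapply(tree$branches, `[`, numeric(1), 1),
         n_clusters = lengths(tree$branches),
         type = type)
}

#' Group branches into modules
#'
#' Branches whose chains converge on a common node form a module; groups of
#' branches with no converging node but pairwise interlacing of at least
#' `min_shared` sites are declared a module as well. Components containing a
#' single branch are not modules.
#'
#' @inheritParams classify_branches
#' @param min_shared Pairwise shared-site threshold for declared modules.
#' @return A tibble with `branch`, `module` (NA for branches in no module)
#'   and `kind` (`"converging"` or `"interlaced"`).
#' @export
detect_modules <- function(tree, min_shared = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  min_shared <- min_shared %||% tree$min_shared
  nb <- length(tree$branches)
  own <- branch_exclusive_sites(tree)
  converge <- matrix(FALSE, nb, nb)
  interlace <- matrix(FALSE, nb, nb)
  if (nb > 1) {
    for (a in seq_len(nb - 1)) {
      for (b in (a + 1):nb) {
        if (length(intersect(tree$branches[[a]], tree$branches[[b]])) > 0) {
          converge[a, b] <- converge[b, a] <- TRUE
        } else if (length(intersect(own[[a]], own[[b]])) >= min_shared) {
          interlace[a, b] <- interlace[b, a] <- TRUE
        }
      }
    }
  }
  adj <- converge | interlace
  comp <- seq_len(nb)   # union-find by repeated relabelling
  repeat {
    changed <- FALSE
    for (a in seq_len(nb)) {
      linked <- which(adj[a, ])
      if (length(linked) > 0) {
        target <- min(comp[c(a, linked)])
        if (any(comp[c(a, linked)] != target)) {
          comp[c(a, linked)] <- target
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  module_ids <- names(sizes)[sizes >= 2]
  module_num <- setNames(seq_along(module_ids), module_ids)
  kind <- vapply(seq_len(nb), function(a) {
    members <- which(comp == comp[a])
    if (length(members) < 2) return(NA_character_)
    if (any(converge[members, members])) "converging" else "interlaced"
  }, character(1))
  tibble(branch = seq_len(nb),
         module = unname(module_num[as.character(comp)]),
         kind = kind)
}

#' Select the representative cluster of each branch
#'
#' The cluster with the highest `SR(mode)` in the branch; when a
#' higher-order cluster's `SR(mode)` is within a relative `tolerance` of the
#' maximum, the higher-order cluster is preferred (more sites, more
#' informative). Remaining ties go to the larger order, then the lowest mode
#' label.
#'
#' @inheritParams classify_branches
#' @param tolerance Relative tolerance (default from the tree, 0.05).
#' @return A tibble with `branch`, `node`, `sites`, `order`, `mode`,
#'   `sr_mode`.
#' @export
select_representative <- function(tree, tolerance = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  tolerance <- tolerance %||% tree$rep_tolerance
  purrr::map_dfr(seq_along(tree$branches), function(b) {
    chain <- tree$branches[[b]]
    sub <- tree$nodes[match(chain, tree$nodes$node), ]
    best <- max(sub$sr_mode)
    cand <- sub[sub$sr_mode >= (1 - tolerance) * best, ]
    cand <- cand[order(-cand$order, cand$mode), ]
    tibble(branch = b, node = cand$node[1],
           sites = paste(cand$sites[[1]], collapse = ","),
           order = cand$order[1], mode = cand$mode[1],
           sr_mode = cand$sr_mode[1])
  })
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("<cluster_tree> ", nrow(x$nodes), " clusters, ", nrow(x$edges),
      " nesting edges, ", length(x$branches), " branches, ",
      max(c(0, x$modules$module), na.rm = TRUE), " modules\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_tree <- function(x, ...) {
  branch_of <- rep(NA_integer_, nrow(x$nodes))
  for (b in seq_along(x$branches)) {
    first_hit <- is.na(branch_of[x$branches[[b]]])
    branch_of[x$branches[[b]][first_hit]] <- b
  }
  tibble(node = x$nodes$node,
         sites = vapply(x$nodes$sites, paste, character(1), collapse = ","),
         order = x$nodes$order, mode = x$nodes$mode,
         sr_mode = x$nodes$sr_mode,
         k_first = x$nodes$k_first, k_last = x$nodes$k_last,
         parent = x$edges$parent[match(x$nodes$node, x$edges$child)],
         branch = branch_of,
         representative = x$nodes$node %in% x$representatives$node)
}

#' @exportS3Method generics::glance
glance.cluster_tree <- function(x, ...) {
  tibble(n_clusters = nrow(x$nodes), n_edges = nrow(x$edges),
         n_branches = length(x$branches),
         n_type_ii = sum(x$branch_types$type == "II"),
         n_modules = length(unique(stats::na.omit(x$modules$module))),
         n_unattached = sum(x$nodes$order >= 2 &
                              !(x$nodes$node %in% x$edges$child) &
                              !(x$nodes$node %in% x$edges$parent)))
}

#' Export a cluster tree as Graphviz DOT
#'
#' @param tree A `cluster_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_tree_dot <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  nodes <- tree$nodes
  lab <- vapply(seq_len(nrow(nodes)), function(i) {
    paste0("n", nodes$node[i], " [label=\"",
           paste(nodes$sites[[i]], collapse = " "),
           "\\norder ", nodes$order[i], ", SR(mode) ",
           signif(nodes$sr_mode[i], 3), "\"];")
  }, character(1))
  ed <- if (nrow(tree$edges) > 0) {
    paste0("n", tree$edges$child, " -> n", tree$edges$parent, ";")
  } else character(0)
  writeLines(c("digraph cluster_tree {", "  rankdir=TB;",
               paste0("  ", lab), paste0("  ", ed), "}"), path)
  invisible(path)
}
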