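# k-modes attribute clustering of aligned sites.
#
# Sites are partitioned into k clusters by iterating two steps: assign each
# site to the cluster whose mode it is most redundant with (highest R), then
# recompute each cluster's mode as the member with the highest within-cluster
# SR. Iteration stops when no site changes cluster. The mode plays the role
# the medoid plays in k-medoids, but the "distance" is interdependency, not
# similarity: dissimilar columns can be strongly interdependent.

with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, k, r) {
  as.integer((abs(seed) * 100003 + k * 1009 + r * 7919) %% 2147483629L)
}

#' Mode of a site cluster
#'
#' The cluster member with the highest sum of redundancies `SR(i)` to the
#' other members; ties are broken by the lowest site label.
#'
#' @param rmat A [redundancy_matrix()].
#' @param cluster Vector of site labels.
#' @return The mode's site label.
#' @export
compute_mode <- function(rmat, cluster) {
  stopifnot(inherits(rmat, "redundancy_matrix"))
  if (length(cluster) == 0) abort("`cluster` must be non-empty.")
  if (length(cluster) == 1) return(cluster)
  idx <- label_index(rmat, cluster)
  Rsub <- rmat$R[idx, idx, drop = FALSE]
  diag(Rsub) <- 0
  sr <- rowSums(Rsub)
  best <- sr >= max(sr) - 1e-12
  min(cluster[best])
}

#' SR(mode) of a cluster
#'
#' The mode's `SR` divided by the number of pairs involving the mode,
#' `N* = |cluster| - 1`, so a pair's `SR(mode)` equals its `R`. Singletons
#' score 0. Used to rank clusters by internal interdependency.
#'
#' @inheritParams compute_mode
#' @param n_star `"pairs_with_mode"` (default, divides by `|cluster| - 1`) or
#'   `"all_pairs"` (divides by `choose(|cluster|, 2)`).
#' @return Value in `[0, 1]`.
#' @export
sr_mode_value <- function(rmat, cluster,
                          n_star = c("pairs_with_mode", "all_pairs")) {
  n_star <- match.arg(n_star)
  m <- length(cluster)
  if (m < 2) return(0)
  mode <- compute_mode(rmat, cluster)
  denom <- if (n_star == "pairs_with_mode") m - 1 else choose(m, 2)
  sr_sum(rmat, mode, cluster) / denom
}

config_objective <- function(rmat, membership, modes) {
  total <- 0
  for (c in seq_along(modes)) {
    members <- which(membership == c)
    others <- setdiff(members, modes[c])
    if (length(others) > 0) {
      total <- total + sum(rmat$R[others, modes[c]])
    }
  }
  total
}

finalize_config <- function(rmat, membership, modes, k, iterations,
                            converged, seed) {
  labels <- rmat$labels
  ord <- order(labels[modes])
  clusters <- lapply(ord, function(c) sort(labels[membership == c]))
  mode_labels <- labels[modes][ord]
  srm <- vapply(clusters, function(cl) sr_mode_value(rmat, cl), numeric(1))
  structure(list(k = k, clusters = clusters, modes = mode_labels,
                 sr_mode = srm, iterations = iterations,
                 converged = converged, seed = seed,
                 objective = config_objective(rmat, membership, modes),
                 labels = labels),
            class = "kmodes_config")
}

#' Run the k-modes site-clustering algorithm
#'
#' Partitions the aligned sites into `k` clusters. Initialisation draws `k`
#' distinct sites as candidate modes; each remaining site is then assigned to
#' the cluster whose mode gives it the highest redundancy `R`, and modes are
#' recomputed as the member with maximal within-cluster `SR`. Assignment and
#' mode update alternate until no site changes cluster (or `max_iter`).
#' Assignment ties keep the current cluster when it is among the best,
#' otherwise take the lowest mode label.
#'
#' @param rmat A [redundancy_matrix()].
#' @param k Number of clusters, `2 <= k <= N` (with `k = N` every site is its
#'   own cluster).
#' @param seed Integer seed for the random initialisation; `NULL` uses the
#'   current RNG state.
#' @param max_iter Iteration cap (default 100); hitting it returns
#'   `converged = FALSE` with a warning.
#' @return A `kmodes_config`: clusters (site-label sets ordered by mode
#'   label), modes, per-cluster `sr_mode`, iteration count, convergence flag,
#'   seed and the within-cluster redundancy objective.
#' @export
run_kmodes <- function(rmat, k, seed = NULL, max_iter = 100) {
  stopifnot(inherits(rmat, "redundancy_matrix"))
  N <- length(rmat$labels)
  if (k < 2 || k > N) {
    abort(paste0("`k` must be between 2 and ", N, "."))
  }
  R <- rmat$R
  with_seed_local(seed, {
    modes <- sort(sample.int(N, k))
    membership <- rep(NA_integer_, N)
    membership[modes] <- seq_len(k)
    iterations <- 0L
    converged <- FALSE
    repeat {
      iterations <- iterations + 1L
      prev <- membership
      new_membership <- rep(NA_integer_, N)
      new_membership[modes] <- seq_len(k)
      free <- setdiff(seq_len(N), modes)
      if (length(free) > 0) {
        scores <- R[free, modes, drop = FALSE]
        for (a in seq_along(free)) {
          s <- scores[a, ]
          best <- which(s >= max(s) - 1e-12)
          cur <- prev[free[a]]
          if (!is.na(cur) && cur %in% best) {
            new_membership[free[a]] <- cur
          } else {
            new_membership[free[a]] <-
              best[which.min(rmat$labels[modes[best]])]
          }
        }
      }
      # unreachable in normal operation (every cluster keeps its mode), kept
      # as a guard: an emptied cluster is reseeded with the worst-fit site
      for (c in which(tabulate(new_membership, k) == 0)) {
        fit <- apply(R[, modes, drop = FALSE], 1, max)
        cand <- which.min(replace(fit, modes, Inf))
        new_membership[cand] <- c
        modes[c] <- cand
      }
      membership <- new_membership
      modes <- vapply(seq_len(k), function(c) {
        members <- which(membership == c)
        label_index(rmat, compute_mode(rmat, rmat$labels[members]))
      }, integer(1))
      # no site changed cluster => modes are a function of membership and are
      # stable too
      if (!anyNA(prev) && identical(prev, membership)) {
        converged <- TRUE
        break
      }
      if (iterations >= max_iter) break
    }
    if (!converged) {
      warn(paste0("k-modes did not converge within ", max_iter,
                  " iterations (k = ", k, ")."))
    }
    finalize_config(rmat, membership, modes, k, iterations, converged, seed)
  })
}

#' @export
print.kmodes_config <- function(x, ...) {
  cat("<kmodes_config> k = ", x$k, ", ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged",
      "; objective = ", signif(x$objective, 4), "\n", sep = "")
  for (c in seq_along(x$clusters)) {
    cat("  [", c, "] mode ", x$modes[c], ", SR(mode) = ",
        signif(x$sr_mode[c], 3), ": ",
        paste(x$clusters[[c]], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kmodes_config <- function(x, ...) {
  purrr::map_dfr(seq_along(x$clusters), function(c) {
    tibble(site = x$clusters[[c]], cluster = c, mode = x$modes[c],
           sr_mode = x$sr_mode[c], order = length(x$clusters[[c]]),
           is_mode = x$clusters[[c]] == x$modes[c])
  })
}

#' @exportS3Method generics::glance
glance.kmodes_config <- function(x, ...) {
  tibble(k = x$k, iterations = x$iterations, converged = x$converged,
         objective = x$objective,
         n_singletons = sum(lengths(x$clusters) == 1))
}

#' Partition vector of a clustering
#'
#' @param config A `kmodes_config`.
#' @return Integer cluster ids named by site label, in site-label order —
#'   convenient for comparing partitions (e.g. adjusted Rand index).
#' @export
site_partition <- function(config) {
  stopifnot(inherits(config, "kmodes_config"))
  out <- integer(length(config$labels))
  names(out) <- config$labels
  for (c in seq_along(config$clusters)) {
    out[as.character(config$clusters[[c]])] <- c
  }
  out[order(as.integer(names(out)))]
}

#' Sweep k from high to low
#'
#' Runs [run_kmodes()] for every `k` from `k_max` down to `k_min` (the full
#' sweep `N - 1 .. 2` by default), keeping for each `k` the best of `restarts`
#' seeded initialisations by the within-cluster redundancy objective. The
#' sweep exposes the nested cluster structure consumed by
#' [build_cluster_tree()].
#'
#' @param rmat A [redundancy_matrix()].
#' @param k_max,k_min Sweep bounds; defaults `N - 1` and 2.
#' @param seed Integer seed; per-(k, restart) seeds are derived from it, so
#'   the whole sweep is reproducible.
#' @param restarts Restarts per `k` (default 1).
#' @param max_iter Passed to [run_kmodes()].
#' @return A `kmodes_sweep`: list of `kmodes_config`s indexed by `k`.
#' @export
sweep_k <- function(rmat, k_max = NULL, k_min = 2, seed = 1, restarts = 1,
                    max_iter = 100) {
  stopifnot(inherits(rmat, "redundancy_matrix"))
  N <- length(rmat$labels)
  if (is.null(k_max)) k_max <- N - 1
  if (k_min < 2 || k_max > N - 1 || k_min > k_max) {
    abort("Require 2 <= k_min <= k_max <= N - 1.")
  }
  ks <- seq(k_max, k_min, by = -1)
  configs <- lapply(ks, function(k) {
    best <- NULL
    for (r in seq_len(restarts)) {
      cfg <- run_kmodes(rmat, k, seed = derive_seed(seed, k, r),
                        max_iter = max_iter)
      if (is.null(best) || cfg$objective > best$objective) best <- cfg
    }
    best
  })
  names(configs) <- ks
  structure(list(configs = configs, k_values = ks, seed = seed,
                 restarts = restarts, labels = rmat$labels),
            class = "kmodes_sweep")
}

#' @export
print.kmodes_sweep <- function(x, ...) {
  cat("<kmodes_sweep> k = ", max(x$k_values), " .. ", min(x$k_values),
      " over ", length(x$labels), " sites (seed ", x$seed, ", ",
      x$restarts, " restart(s))\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kmodes_sweep <- function(x, ...) {
  purrr::map_dfr(x$configs, function(cfg) {
    tibble(k = cfg$k, cluster = seq_along(cfg$clusters),
           mode = cfg$modes, sr_mode = cfg$sr_mode,
           order = lengths(cfg$clusters),
           sites = purrr::map_chr(cfg$clusters, paste, collapse = ","))
  })
}

#' @exportS3Method generics::glance
glance.kmodes_sweep <- function(x, ...) {
  purrr::map_dfr(x$configs, glance)
}
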