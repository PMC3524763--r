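# Independent brute-force oracles: explicit sums over contingency tables and
# exhaustive searches, deliberately written without reusing the package's
# computation paths.

oracle_joint_entropy <- function(x, y, base = exp(1)) {
  h <- 0
  n <- length(x)
  for (a in unique(x)) {
    for (b in unique(y)) {
      p <- sum(x == a & y == b) / n
      if (p > 0) h <- h - p * log(p, base = base)
    }
  }
  h
}

oracle_mutual_information <- function(x, y, base = exp(1)) {
  n <- length(x)
  mi <- 0
  for (a in unique(x)) {
    pa <- sum(x == a) / n
    for (b in unique(y)) {
      pb <- sum(y == b) / n
      pab <- sum(x == a & y == b) / n
      if (pab > 0) mi <- mi + pab * log(pab / (pa * pb), base = base)
    }
  }
  mi
}

oracle_redundancy <- function(x, y, base = exp(1)) {
  h <- oracle_joint_entropy(x, y, base)
  if (h == 0) 0 else oracle_mutual_information(x, y, base) / h
}

# Classical two-way contingency-table adjusted residual (Haberman):
# gamma = (o - e) / sqrt(e (1 - p_row)(1 - p_col)).
oracle_adjusted_residual_2way <- function(x, y, a, b) {
  n <- length(x)
  o <- sum(x == a & y == b)
  pr <- sum(x == a) / n
  pc <- sum(y == b) / n
  e <- n * pr * pc
  (o - e) / sqrt(e * (1 - pr) * (1 - pc))
}

random_column <- function(n, alphabet = c("A", "C", "D", "E")) {
  sample(alphabet, n, replace = TRUE)
}

# All ways to split `sites` into two non-empty groups.
all_two_partitions <- function(sites) {
  n <- length(sites)
  out <- list()
  for (code in 1:(2^(n - 1) - 1)) {
    mask <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    out[[length(out) + 1]] <- list(sites[mask], sites[!mask])
  }
  out
}

# Package-definition clustering objective, recomputed longhand.
oracle_partition_objective <- function(partition, R, labels) {
  total <- 0
  for (cl in partition) {
    idx <- match(cl, labels)
    if (length(idx) == 1) next
    sr <- sapply(idx, function(i) sum(R[i, setdiff(idx, i)]))
    mode_pos <- which(sr == max(sr))
    mode_pos <- mode_pos[which.min(labels[idx][mode_pos])]
    total <- total + sum(R[setdiff(idx, idx[mode_pos]), idx[mode_pos]])
  }
  total
}

# A redundancy_matrix carrying an arbitrary symmetric R (for clustering and
# tree tests that do not need I/H).
rmat_from_R <- function(R, labels = NULL, n = 100) {
  coevclust:::new_redundancy_matrix(R, n = n, labels = labels)
}

block_R_matrix <- function(blocks, within, between, labels = NULL) {
  sites <- unlist(blocks)
  N <- length(sites)
  R <- matrix(between, N, N)
  start <- 0
  for (b in blocks) {
    idx <- start + seq_along(b)
    R[idx, idx] <- within
    start <- start + length(b)
  }
  diag(R) <- 1
  rmat_from_R(R, labels = labels %||% sites)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
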