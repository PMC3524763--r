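# Pairwise interdependency between aligned sites.
#
# The interdependency redundancy between two columns is the mutual information
# normalised by the joint entropy, R = I/H, a base-free quantity in [0, 1]:
# 1 for perfectly dependent columns, 0 for an exactly factorising pair.
# Probabilities are plug-in relative frequencies; entropies are in nats so
# that 2*n*I follows the G-statistic chi-square asymptotics used by the
# dependency test.

entropy_from_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  p <- counts / n
  -sum(p * log(p))
}

check_pair <- function(col_i, col_j) {
  if (length(col_i) != length(col_j)) {
    abort("Columns must have the same length.")
  }
  if (length(col_i) < 1) abort("Columns must be non-empty.")
}

#' Joint entropy of two symbol columns (nats)
#'
#' Plug-in joint entropy `H = -sum p(x, y) log p(x, y)` over the observed
#' joint symbols of two aligned-site columns.
#'
#' @param col_i,col_j Equal-length vectors of categorical symbols.
#' @return Joint entropy in nats; 0 when only one joint symbol occurs.
#' @examples
#' joint_entropy(c("A", "A", "B", "B"), c("C", "C", "D", "D")) # log(2)
#' @export
joint_entropy <- function(col_i, col_j) {
  check_pair(col_i, col_j)
  entropy_from_counts(table(paste(col_i, col_j, sep = "\r")))
}

#' Mutual information of two symbol columns (nats)
#'
#' Plug-in mutual information `I = sum p(x,y) log[p(x,y) / (p(x) p(y))]`,
#' equal to `H_i + H_j - H_ij`.
#'
#' @inheritParams joint_entropy
#' @return Mutual information in nats (non-negative up to rounding).
#' @export
mutual_information <- function(col_i, col_j) {
  check_pair(col_i, col_j)
  hi <- entropy_from_counts(table(col_i))
  hj <- entropy_from_counts(table(col_j))
  hij <- joint_entropy(col_i, col_j)
  max(hi + hj - hij, 0)
}

#' Interdependency redundancy between two symbol columns
#'
#' Normalised mutual information `R = I / H` where `H` is the joint entropy.
#' `R = 1` for perfectly dependent columns (one is a bijective relabelling of
#' the other) and `R = 0` for an exactly factorising pair. When both columns
#' are constant (`H = 0`) the pair carries no interdependency signal and
#' `R = 0` is returned.
#'
#' @inheritParams joint_entropy
#' @return Redundancy in `[0, 1]`.
#' @examples
#' redundancy(c("A", "A", "B", "B"), c("C", "C", "D", "D")) # 1
#' redundancy(c("A", "A", "B", "B"), c("C", "D", "C", "D")) # 0
#' @export
redundancy <- function(col_i, col_j) {
  h <- joint_entropy(col_i, col_j)
  if (h <= 0) return(0)
  min(max(mutual_information(col_i, col_j) / h, 0), 1)
}

# ---- full matrix -----------------------------------------------------------

# Encode columns as integers over their observed symbols; joint tables are
# then tabulate() calls rather than string tables, which matters for the
# N(N-1)/2 sweep.
encode_columns <- function(mat) {
  lapply(seq_len(ncol(mat)), function(j) {
    f <- factor(mat[, j])
    list(code = as.integer(f), g = nlevels(f))
  })
}

#' Pairwise redundancy matrix over all aligned sites
#'
#' Computes, for every pair of columns, the joint entropy, mutual information
#' and redundancy `R = I/H`. The diagonal of the `H` slot holds the marginal
#' entropies; the diagonal of `R` is 1 for variable columns and 0 for constant
#' ("uninformative") ones.
#'
#' @param aln An [msa] with at least 2 columns.
#' @return An object of class `redundancy_matrix`: a list with symmetric
#'   matrices `R`, `I`, `H` (dimnames = site labels), the sequence count `n`,
#'   site `labels`, and `G`, the per-site count of distinct observed symbols
#'   (gap included when present).
#' @export
redundancy_matrix <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  mat <- aln$mat
  N <- ncol(mat)
  n <- nrow(mat)
  if (N < 2) abort("Need at least 2 aligned sites.")
  if (length(unique(apply(mat, 1, paste, collapse = ""))) < 5) {
    warn("Fewer than 5 unique sequences; interdependency estimates are unreliable.")
  }
  enc <- encode_columns(mat)
  Hm <- matrix(0, N, N)
  Im <- matrix(0, N, N)
  marg <- vapply(enc, function(e) entropy_from_counts(tabulate(e$code, e$g)),
                 numeric(1))
  diag(Hm) <- marg
  for (i in seq_len(N - 1)) {
    ei <- enc[[i]]
    for (j in (i + 1):N) {
      ej <- enc[[j]]
      joint <- tabulate(ei$code + ei$g * (ej$code - 1L), ei$g * ej$g)
      hij <- entropy_from_counts(joint)
      Hm[i, j] <- Hm[j, i] <- hij
      Im[i, j] <- Im[j, i] <- max(marg[i] + marg[j] - hij, 0)
    }
  }
  Rm <- matrix(0, N, N)
  pos <- Hm > 0
  Rm[pos] <- pmin(pmax(Im[pos] / Hm[pos], 0), 1)
  diag(Rm) <- ifelse(marg > 0, 1, 0)
  labels <- aln$site_labels
  dn <- list(labels, labels)
  dimnames(Rm) <- dimnames(Im) <- dimnames(Hm) <- dn
  structure(list(R = Rm, I = Im, H = Hm, n = n, labels = labels,
                 G = vapply(enc, function(e) e$g, integer(1))),
            class = "redundancy_matrix")
}

# Bare constructor used by tests and simulations when only an R matrix is
# available (I, H left NULL).
new_redundancy_matrix <- function(R, n = NA_integer_, labels = NULL,
                                  I = NULL, H = NULL, G = NULL) {
  if (is.null(labels)) labels <- seq_len(ncol(R))
  dimnames(R) <- list(labels, labels)
  structure(list(R = R, I = I, H = H, n = n, labels = labels, G = G),
            class = "redundancy_matrix")
}

#' @export
print.redundancy_matrix <- function(x, ...) {
  cat("<redundancy_matrix> ", length(x$labels), " sites, n = ", x$n,
      "; mean off-diagonal R = ",
      signif(mean(x$R[upper.tri(x$R)]), 3), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.redundancy_matrix <- function(x, ...) {
  N <- length(x$labels)
  ut <- which(upper.tri(x$R), arr.ind = TRUE)
  tibble(site_i = x$labels[ut[, 1]], site_j = x$labels[ut[, 2]],
         R = x$R[ut],
         I = if (is.null(x$I)) NA_real_ else x$I[ut],
         H = if (is.null(x$H)) NA_real_ else x$H[ut])
}

#' @exportS3Method generics::glance
glance.redundancy_matrix <- function(x, ...) {
  off <- x$R[upper.tri(x$R)]
  tibble(n_sites = length(x$labels), n_seqs = x$n,
         mean_R = mean(off), max_R = max(off), min_R = min(off))
}

label_index <- function(rmat, sites) {
  idx <- match(sites, rmat$labels)
  if (anyNA(idx)) {
    abort(paste0("Unknown site label(s): ",
                 paste(sites[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Chi-square interdependency test for site pairs
#'
#' Tests each pair of sites for dependence: the pair is called dependent when
#' `R >= qchisq(1 - alpha, df) / (2 n H)` with
#' `df = (G_i - 1)(G_j - 1)`, equivalent to comparing the G-statistic `2 n I`
#' with the chi-square quantile. By default `G_i` is the number of distinct
#' symbols observed at site `i`; `df_alphabet = "full"` uses the fixed
#' 21-letter alphabet (20 amino acids + gap) instead. Pairs involving a
#' constant column (`df = 0`) are reported as not testable.
#'
#' @param rmat A [redundancy_matrix()] with `I` and `H` slots.
#' @param alpha Significance level (default 0.05).
#' @param pairs Optional two-column matrix/data frame of site labels to test;
#'   default all pairs.
#' @param df_alphabet `"observed"` (default) or `"full"`.
#' @return A tibble with one row per pair: site labels, `R`, `I`, `H`, `df`,
#'   `threshold` (on the R scale), `statistic` (`2 n I`), `testable`, and the
#'   `dependent` decision.
#' @export
dependency_test <- function(rmat, alpha = 0.05, pairs = NULL,
                            df_alphabet = c("observed", "full")) {
  stopifnot(inherits(rmat, "redundancy_matrix"))
  df_alphabet <- match.arg(df_alphabet)
  if (is.null(rmat$H) || is.null(rmat$I)) {
    abort("`rmat` must carry I and H (use redundancy_matrix()).")
  }
  if (is.null(pairs)) {
    ut <- which(upper.tri(rmat$R), arr.ind = TRUE)
    pairs <- cbind(rmat$labels[ut[, 1]], rmat$labels[ut[, 2]])
  }
  pairs <- as.matrix(pairs)
  i <- label_index(rmat, pairs[, 1])
  j <- label_index(rmat, pairs[, 2])
  g <- if (df_alphabet == "observed") rmat$G else
    rep(length(AA_RESIDUES) + 1L, length(rmat$labels))
  df <- (g[i] - 1) * (g[j] - 1)
  h <- rmat$H[cbind(i, j)]
  r <- rmat$R[cbind(i, j)]
  testable <- df >= 1 & h > 0
  q <- ifelse(testable, qchisq(1 - alpha, pmax(df, 1)), NA_real_)
  threshold <- q / (2 * rmat$n * h)
  tibble(site_i = pairs[, 1], site_j = pairs[, 2],
         R = r, I = rmat$I[cbind(i, j)], H = h, df = df,
         statistic = 2 * rmat$n * rmat$I[cbind(i, j)],
         threshold = threshold, testable = testable,
         dependent = testable & r >= threshold)
}

#' Sum of redundancies of one site against a site set
#'
#' `SR(i)` for site `i` within a cluster: the sum of `R(i, i')` over every
#' other member `i'` of `site_set`. A singleton set gives 0.
#'
#' @param rmat A [redundancy_matrix()].
#' @param site A site label.
#' @param site_set Vector of site labels (may include `site`).
#' @return The SR value.
#' @export
sr_sum <- function(rmat, site, site_set) {
  stopifnot(inherits(rmat, "redundancy_matrix"))
  i <- label_index(rmat, site)
  others <- setdiff(site_set, site)
  if (length(others) == 0) return(0)
  sum(rmat$R[i, label_index(rmat, others)])
}
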