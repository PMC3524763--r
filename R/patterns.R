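# Pattern discovery within a site cluster.
#
# A compound event is a joint assignment of amino acids to the sites of a
# cluster; it is a pattern when its occurrence deviates significantly from
# the expectation under full independence of the sites. Significance is
# judged by the adjusted residual
#   gamma = (o - e) / sqrt(v),   e = n * prod(p_j),
#   v = e * prod(1 - p_j),
# the Haberman standardised-residual form, which for a two-site event reduces
# exactly to the classical two-way contingency-table adjusted residual.
# Under independence gamma is asymptotically standard normal, so fixed
# cutoffs correspond to two-sided confidence levels (2.58 ~ 99%,
# 3.29 ~ 99.9%).

#' Adjusted-residual cutoff for a confidence level
#'
#' Two-sided standard-normal critical value: 0.99 gives 2.58, 0.999 gives
#' 3.29 (to 2 decimal places).
#'
#' @param confidence Confidence level in (0, 1).
#' @return The cutoff value.
#' @examples
#' confidence_to_cutoff(0.999) # 3.29...
#' @export
confidence_to_cutoff <- function(confidence) {
  if (!is.numeric(confidence) || any(confidence <= 0) ||
      any(confidence >= 1)) {
    abort("`confidence` must lie strictly between 0 and 1.")
  }
  qnorm(1 - (1 - confidence) / 2)
}

marginal_freqs <- function(aln, sites) {
  idx <- match(sites, aln$site_labels)
  if (anyNA(idx)) {
    abort(paste0("Unknown site label(s): ",
                 paste(sites[is.na(idx)], collapse = ", ")))
  }
  lapply(idx, function(j) {
    tab <- table(aln$mat[, j])
    setNames(as.numeric(tab) / nrow(aln$mat), names(tab))
  })
}

pattern_row <- function(sites, symbols, o, p, n) {
  e <- n * prod(p)
  v <- e * prod(1 - p)
  m <- length(sites)
  tibble(sites = paste(sites, collapse = ","),
         symbols = paste(symbols, collapse = ""),
         order = m,
         observed = o, expected = e, residual = o - e,
         variance = v,
         adjusted_residual = if (v > 0) (o - e) / sqrt(v) else NA_real_)
}

#' Adjusted residual of a compound event
#'
#' Counts the occurrences of the event (the given amino acids jointly at the
#' given sites) across the alignment rows, compares with the expected count
#' under independence of the sites, and standardises the difference.
#'
#' @param aln An [msa].
#' @param sites Site labels the event spans (>= 1).
#' @param symbols Character vector of symbols, one per site.
#' @return A one-row tibble: `sites`, `symbols`, `order`, `observed`,
#'   `expected`, `residual`, `variance`, `adjusted_residual`.
#' @examples
#' aln <- msa(rep(c("NK", "NK", "NK", "NK", "NE", "KN", "KK", "NK", "NK",
#'                  "NK"), 1))
#' adjusted_residual(aln, c(1, 2), c("N", "K"))
#' @export
adjusted_residual <- function(aln, sites, symbols) {
  stopifnot(inherits(aln, "msa"))
  if (length(sites) != length(symbols)) {
    abort("`sites` and `symbols` must have the same length.")
  }
  pm <- marginal_freqs(aln, sites)
  p <- vapply(seq_along(sites), function(j) {
    pj <- pm[[j]][symbols[j]]
    if (is.na(pj) || pj == 0) {
      abort(paste0("Symbol '", symbols[j], "' is never observed at site ",
                   sites[j], "."))
    }
    unname(pj)
  }, numeric(1))
  idx <- match(sites, aln$site_labels)
  hit <- rep(TRUE, nrow(aln$mat))
  for (j in seq_along(idx)) hit <- hit & aln$mat[, idx[j]] == symbols[j]
  pattern_row(sites, symbols, sum(hit), p, nrow(aln$mat))
}

enumerate_on_sites <- function(aln, sites, allow_gaps) {
  idx <- match(sites, aln$site_labels)
  sub <- aln$mat[, idx, drop = FALSE]
  n <- nrow(sub)
  m <- length(sites)
  key <- apply(sub, 1, paste, collapse = "")
  counts <- table(key)
  first <- !duplicated(key)
  uniq <- sub[first, , drop = FALSE]
  o <- as.integer(counts[key[first]])
  if (!allow_gaps) {
    keep <- rowSums(uniq == GAP) == 0
    uniq <- uniq[keep, , drop = FALSE]
    o <- o[keep]
  }
  if (nrow(uniq) == 0) return(empty_pattern_tbl())
  pm <- marginal_freqs(aln, sites)
  P <- vapply(seq_len(m), function(j) unname(pm[[j]][uniq[, j]]),
              numeric(nrow(uniq)))
  P <- matrix(P, nrow = nrow(uniq), ncol = m)
  e <- n * apply(P, 1, prod)
  v <- e * apply(1 - P, 1, prod)
  tibble(sites = paste(sites, collapse = ","),
         symbols = apply(uniq, 1, paste, collapse = ""),
         order = m, observed = o, expected = e, residual = o - e,
         variance = v,
         adjusted_residual = ifelse(v > 0, (o - e) / sqrt(v), NA_real_))
}

empty_pattern_tbl <- function() {
  tibble(sites = character(), symbols = character(), order = integer(),
         observed = integer(), expected = numeric(), residual = numeric(),
         variance = numeric(), adjusted_residual = numeric())
}

#' Enumerate significant patterns within a site cluster
#'
#' Candidate events are the joint symbol combinations actually observed in at
#' least one alignment row over the cluster's sites (the full `|G|^m` lattice
#' is never enumerated). Events whose adjusted residual strictly exceeds
#' `cutoff` are returned, sorted by decreasing adjusted residual.
#'
#' @param aln An [msa].
#' @param cluster Site labels of the cluster (>= 2 sites).
#' @param cutoff Adjusted-residual threshold; default 3.29 (99.9% two-sided
#'   confidence). Overridden by `confidence` when given.
#' @param confidence Optional confidence level; converted with
#'   [confidence_to_cutoff()].
#' @param span `"full"` (default): events span all cluster sites, as in the
#'   reported cluster patterns; `"sub"`: additionally enumerate every site
#'   subset of size >= 2.
#' @param allow_gaps Keep events containing the gap symbol (default TRUE;
#'   gaps are ordinary symbols in the <20%-gapped retained columns).
#' @return A tibble of patterns (possibly empty), one row per significant
#'   event, with the columns of [adjusted_residual()].
#' @export
enumerate_patterns <- function(aln, cluster, cutoff = 3.29,
                               confidence = NULL,
                               span = c("full", "sub"),
                               allow_gaps = TRUE) {
  stopifnot(inherits(aln, "msa"))
  span <- match.arg(span)
  if (length(cluster) < 2) abort("`cluster` must span at least 2 sites.")
  if (!is.null(confidence)) cutoff <- confidence_to_cutoff(confidence)
  site_sets <- list(cluster)
  if (span == "sub" && length(cluster) > 2) {
    site_sets <- unlist(lapply(seq(2, length(cluster)), function(m) {
      utils::combn(cluster, m, simplify = FALSE)
    }), recursive = FALSE)
  }
  out <- purrr::map_dfr(site_sets, enumerate_on_sites, aln = aln,
                        allow_gaps = allow_gaps)
  if (nrow(out) == 0) return(out)
  out <- dplyr::filter(out, !is.na(.data$adjusted_residual),
                       .data$adjusted_residual > cutoff)
  dplyr::arrange(out, dplyr::desc(.data$adjusted_residual))
}
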