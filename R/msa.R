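# Alignment container and preprocessing.
#
# An `msa` is an M x N character matrix of single upper-case symbols over the
# 20 amino acids plus the gap symbol "-", together with per-column reference
# site labels (1-based, strictly increasing). Columns are "aligned sites" /
# "attributes"; rows are sequences.

AA_RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_AMBIGUOUS <- c("B", "Z", "X", "U", "O", "J")
GAP <- "-"

new_msa <- function(mat, site_labels = NULL, validate = TRUE) {
  if (!is.matrix(mat) || !is.character(mat)) {
    abort("`mat` must be a character matrix of single symbols.")
  }
  if (is.null(site_labels)) site_labels <- seq_len(ncol(mat))
  site_labels <- as.integer(site_labels)
  if (validate) {
    if (length(site_labels) != ncol(mat)) {
      abort("`site_labels` must have one label per alignment column.")
    }
    if (ncol(mat) > 1 && any(diff(site_labels) <= 0)) {
      abort("`site_labels` must be strictly increasing.")
    }
    bad <- setdiff(unique(as.vector(mat)), c(AA_RESIDUES, GAP))
    if (length(bad) > 0) {
      abort(paste0("Alignment contains symbols outside the amino-acid ",
                   "alphabet plus gap: ", paste(bad, collapse = ", ")))
    }
  }
  structure(list(mat = mat, site_labels = site_labels,
                 alphabet = c(AA_RESIDUES, GAP)),
            class = "msa")
}

#' Construct an alignment from aligned sequence strings
#'
#' @param sequences Character vector of equal-length aligned sequences
#'   (upper-case amino acids and `"-"` gaps).
#' @param ids Optional sequence identifiers (defaults to `seq1`, `seq2`, ...).
#' @param site_labels Optional integer reference labels for the columns,
#'   strictly increasing; defaults to `1:N`.
#' @return An object of class `msa`.
#' @examples
#' aln <- msa(c("ACDE", "ACDF", "GCDE"))
#' n_sites(aln)
#' @export
msa <- function(sequences, ids = NULL, site_labels = NULL) {
  if (length(sequences) == 0) abort("`sequences` must be non-empty.")
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1) {
    off <- ids[which(widths != widths[1])[1]]
    abort(paste0("Sequences have unequal lengths; first offending record: ",
                 off))
  }
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  rownames(mat) <- ids
  new_msa(mat, site_labels)
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", nrow(x$mat), " sequences x ", ncol(x$mat), " sites; labels ",
      x$site_labels[1], "..", x$site_labels[length(x$site_labels)], "\n",
      sep = "")
  invisible(x)
}

#' @export
as.matrix.msa <- function(x, ...) x$mat

#' Number of aligned sites (columns)
#' @param aln An `msa`.
#' @return Integer count.
#' @export
n_sites <- function(aln) ncol(aln$mat)

#' Number of sequences (rows)
#' @param aln An `msa`.
#' @return Integer count.
#' @export
n_seqs <- function(aln) nrow(aln$mat)

#' @exportS3Method generics::glance
glance.msa <- function(x, ...) {
  tibble(n_seqs = nrow(x$mat), n_sites = ncol(x$mat),
         gap_fraction = mean(x$mat == GAP),
         n_unique_seqs = length(unique(apply(x$mat, 1, paste, collapse = ""))))
}

# ---- reading / writing -----------------------------------------------------

# Scan raw Stockholm text for insert-state columns (lowercase residues or "."
# gaps). Biostrings' parser normalises case, so the mask is recovered from the
# sequence lines directly; on any inconsistency the mask is dropped with a
# warning rather than trusted.
stockholm_insert_mask <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seq_lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "//") &
                       nzchar(trimws(lines))]
  parts <- strsplit(trimws(seq_lines), "\\s+")
  ok <- lengths(parts) == 2
  if (!any(ok)) return(NULL)
  ids <- vapply(parts[ok], `[[`, character(1), 1)
  chunks <- vapply(parts[ok], `[[`, character(1), 2)
  seqs <- vapply(split(chunks, factor(ids, levels = unique(ids))),
                 paste, character(1), collapse = "")
  if (length(unique(nchar(seqs))) != 1) return(NULL)
  cm <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  apply(cm, 2, function(col) any(col == "." | col %in% letters))
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Stockholm (Pfam dialect) file into an [msa].
#' Symbols are upper-cased and both gap characters (`"-"`, `"."`) are
#' normalised to `"-"`. Ambiguity codes (B, Z, X, U, O, J) are mapped to the
#' gap symbol unless `keep_ambiguous = TRUE`, in which case reading fails on
#' them (the working alphabet is the 20 amino acids).
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @param drop_insert_columns Drop Pfam insert-state columns (lowercase
#'   residues / `"."` gaps) before anything else. Default: `TRUE` for
#'   Stockholm input, `FALSE` for FASTA.
#' @param map_ambiguous_to_gap Map ambiguity codes to the gap symbol
#'   (default `TRUE`); if `FALSE` their presence is an error.
#' @return An [msa] with `site_labels = 1:N`.
#' @export
read_msa <- function(path,
                     format = c("fasta", "stockholm"),
                     drop_insert_columns = NULL,
                     map_ambiguous_to_gap = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("Alignment file not found: ", path))
  if (is.null(drop_insert_columns)) {
    drop_insert_columns <- format == "stockholm"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0) abort(paste0("No sequences in file: ", path))
    widths <- Biostrings::width(set)
    if (length(unique(widths)) != 1) {
      off <- names(set)[which(widths != widths[1])[1]]
      abort(paste0("Ragged alignment: record '", off,
                   "' has length ", widths[names(set) == off][1],
                   " but expected ", widths[1], "."))
    }
    mat <- do.call(rbind, strsplit(as.character(set), "", fixed = TRUE))
    rownames(mat) <- names(set)
    insert_mask <- apply(mat, 2, function(col) {
      any(col == "." | col %in% letters)
    })
  } else {
    ma <- tryCatch(
      Biostrings::readAAMultipleAlignment(path, format = "stockholm"),
      error = function(e) {
        abort(paste0("Failed to parse Stockholm file ", path, ": ",
                     conditionMessage(e)))
      })
    seqs <- as.character(Biostrings::unmasked(ma))
    if (length(seqs) == 0) abort(paste0("No sequences in file: ", path))
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- names(seqs)
    insert_mask <- stockholm_insert_mask(path)
    if (drop_insert_columns && is.null(insert_mask)) {
      warn("Could not recover insert-state columns from the Stockholm text; no columns dropped.")
    }
  }
  if (drop_insert_columns && !is.null(insert_mask) && any(insert_mask)) {
    mat <- mat[, !insert_mask, drop = FALSE]
  }
  mat[] <- toupper(mat)
  mat[mat == "."] <- GAP
  amb <- mat %in% AA_AMBIGUOUS
  if (any(amb)) {
    if (map_ambiguous_to_gap) {
      mat[amb] <- GAP
    } else {
      abort(paste0("Ambiguity codes present (",
                   paste(unique(mat[amb]), collapse = ", "),
                   ") and `map_ambiguous_to_gap = FALSE`."))
    }
  }
  bad <- setdiff(unique(as.vector(mat)), c(AA_RESIDUES, GAP))
  if (length(bad) > 0) {
    abort(paste0("Unknown residue characters in ", path, ": ",
                 paste(bad, collapse = ", ")))
  }
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  rownames(mat) <- ids
  new_msa(mat, seq_len(ncol(mat)))
}

#' Write an alignment to aligned FASTA
#'
#' @param aln An [msa].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- rownames(aln$mat)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---- preprocessing ---------------------------------------------------------

#' Remove heavily gapped columns
#'
#' Retains exactly the columns whose gap fraction is strictly below
#' `max_gap_fraction` (a column at the threshold is removed). Site labels of
#' retained columns are preserved in order.
#'
#' @param aln An [msa].
#' @param max_gap_fraction Columns with gap fraction `>=` this value are
#'   dropped; default 0.20.
#' @return A filtered [msa]; the per-column decision is recorded in the
#'   `"preprocess"` attribute.
#' @export
filter_gapped_columns <- function(aln, max_gap_fraction = 0.20) {
  stopifnot(inherits(aln, "msa"))
  if (max_gap_fraction < 0 || max_gap_fraction > 1) {
    abort("`max_gap_fraction` must be in [0, 1].")
  }
  gap_frac <- colMeans(aln$mat == GAP)
  keep <- gap_frac < max_gap_fraction
  if (!any(keep)) {
    abort(paste0("All columns have gap fraction >= ", max_gap_fraction,
                 "; raise `max_gap_fraction`."))
  }
  out <- new_msa(aln$mat[, keep, drop = FALSE], aln$site_labels[keep])
  attr(out, "preprocess") <- list(
    columns_in = ncol(aln$mat), columns_out = sum(keep),
    max_gap_fraction = max_gap_fraction,
    column_gap_fraction = setNames(gap_frac, aln$site_labels))
  out
}

#' Collapse duplicate sequences
#'
#' Rows whose full symbol string (over the retained columns) is identical are
#' collapsed to their first occurrence; row order is otherwise preserved.
#'
#' @param aln An [msa].
#' @return A deduplicated [msa]; the number of removed rows is recorded in the
#'   `"preprocess"` attribute.
#' @export
deduplicate_sequences <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  keys <- apply(aln$mat, 1, paste, collapse = "")
  keep <- !duplicated(keys)
  out <- new_msa(aln$mat[keep, , drop = FALSE], aln$site_labels)
  attr(out, "preprocess") <- list(rows_in = nrow(aln$mat),
                                  rows_out = sum(keep),
                                  rows_removed = sum(!keep))
  out
}

#' Relabel alignment sites with reference numbering
#'
#' @param aln An [msa].
#' @param labels Either a single integer offset added to positions `1:N`
#'   (e.g. `5` to label 69 columns as reference sites 6..74), or an explicit
#'   strictly increasing integer vector of length `N`.
#' @return The relabelled [msa].
#' @export
relabel_sites <- function(aln, labels) {
  stopifnot(inherits(aln, "msa"))
  n <- ncol(aln$mat)
  if (length(labels) == 1) {
    labels <- seq_len(n) + as.integer(labels)
  }
  if (length(labels) != n) {
    abort(paste0("`labels` has length ", length(labels),
                 " but the alignment has ", n, " sites."))
  }
  new_msa(aln$mat, labels)
}

#' Preprocess an alignment: drop gapped columns, then deduplicate
#'
#' Applies [filter_gapped_columns()] and then (optionally)
#' [deduplicate_sequences()], in that order, and records a machine-readable
#' report.
#'
#' @param aln An [msa].
#' @param max_gap_fraction Passed to [filter_gapped_columns()].
#' @param dedup Collapse duplicate rows after column filtering (default TRUE).
#' @return A preprocessed [msa] whose `"preprocess"` attribute holds the
#'   report; see [preprocess_report()].
#' @export
preprocess_msa <- function(aln, max_gap_fraction = 0.20, dedup = TRUE) {
  stopifnot(inherits(aln, "msa"))
  filtered <- filter_gapped_columns(aln, max_gap_fraction)
  rep_cols <- attr(filtered, "preprocess")
  out <- filtered
  rep_rows <- list(rows_in = nrow(aln$mat), rows_out = nrow(aln$mat),
                   rows_removed = 0L)
  if (dedup) {
    out <- deduplicate_sequences(filtered)
    rep_rows <- attr(out, "preprocess")
  }
  if (nrow(out$mat) < 5) {
    warn(paste0("Only ", nrow(out$mat), " unique sequences remain; ",
                "interdependency estimates need at least 5."))
  }
  attr(out, "preprocess") <- c(rep_rows, rep_cols)
  out
}

#' Preprocessing report as a list (JSON-ready)
#'
#' @param aln An [msa] returned by [preprocess_msa()].
#' @return A list with rows in/out, columns in/out and per-column gap
#'   fractions, suitable for `jsonlite::write_json()`.
#' @export
preprocess_report <- function(aln) {
  rep <- attr(aln, "preprocess")
  if (is.null(rep)) abort("`aln` carries no preprocessing report.")
  rep$column_gap_fraction <- as.list(rep$column_gap_fraction)
  rep
}
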