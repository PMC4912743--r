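# Alignment -> statistical free energy conversion.
#
# For each non-gap position j of the query sequence, the column's amino-acid
# counts c_i (query included) are pseudocounted and converted to
#   ddG_i,j = -log10( (c_i + pc) / (c_wt + pc) )
# so the wild type (query) amino acid sits at exactly 0 and disfavored amino
# acids are positive. Non-canonical letters (B, Z, X, U, O) and gaps (-, .)
# are excluded from the counts and tallied per column.

#' Convert a gapped protein alignment to a statistical free-energy table
#'
#' @param alignment A FASTA file path, a named character vector of aligned
#'   sequences, or a [Biostrings::AAStringSet].
#' @param query_id Name of the query/reference record; residue numbers are
#'   1-based ungapped positions of this sequence (plus `offset`).
#' @param pseudocount Positive pseudocount added to every amino-acid count in
#'   every column (default 1, add-one/Laplace).
#' @param offset Integer added to the residue numbers to map them onto an
#'   author/PDB numbering scheme.
#' @return A [pref_table()] with `metric = "ddg"`, one row per non-gap query
#'   position, with `k*` computed from the converted free energies and a
#'   `low_coverage` flag for columns where every non-query row is a gap.
#' @export
#' @examples
#' aln <- c(q = "MKV", s1 = "MRV", s2 = "M-V")
#' alignment_to_ddg(aln, "q")
alignment_to_ddg <- function(alignment, query_id, pseudocount = 1,
                             offset = 0L) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  seqs <- .as_aligned_chars(alignment)
  if (!(query_id %in% names(seqs)))
    stop("query_id '", query_id, "' not found in the alignment")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequences have unequal aligned lengths")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  aa <- aa_codes()
  qrow <- m[query_id, ]
  keep <- qrow %in% aa
  pos <- cumsum(keep)  # ungapped query coordinate
  idx <- which(keep)
  n_sites <- length(idx)
  prefs <- matrix(NA_real_, n_sites, 20L, dimnames = list(NULL, aa))
  excluded <- integer(n_sites)
  lowcov <- logical(n_sites)
  nonquery <- setdiff(rownames(m), query_id)
  for (s in seq_len(n_sites)) {
    col <- m[, idx[s]]
    counts <- table(factor(col[col %in% aa], levels = aa))
    excluded[s] <- sum(!(col %in% aa))
    lowcov[s] <- length(nonquery) == 0L ||
      all(!(m[nonquery, idx[s]] %in% aa))
    wt <- qrow[idx[s]]
    prefs[s, ] <- -log10((as.numeric(counts) + pseudocount) /
                           (counts[[wt]] + pseudocount))
  }
  tab <- pref_table(wt = qrow[idx], residue = pos[idx] + as.integer(offset),
                    prefs = prefs, metric = "ddg",
                    low_coverage = lowcov,
                    source = sprintf("alignment (%d sequences, pseudocount %g)",
                                     nrow(m), pseudocount))
  tab$n_excluded <- excluded
  add_kstar(tab)
}

# normalize the accepted alignment inputs to a named character vector
.as_aligned_chars <- function(alignment) {
  if (inherits(alignment, "AAStringSet")) {
    out <- as.character(alignment)
  } else if (is.character(alignment) && length(alignment) == 1L &&
             file.exists(alignment)) {
    out <- as.character(Biostrings::readAAStringSet(alignment))
  } else if (is.character(alignment)) {
    out <- alignment
  } else stop("alignment must be a FASTA path, character vector or AAStringSet")
  if (is.null(names(out)) || any(!nzchar(names(out))))
    stop("aligned sequences must be named")
  # FASTA headers may carry descriptions; keep the first token as the id
  names(out) <- vapply(strsplit(names(out), "\\s+"), `[[`, "", 1L)
  out
}

#' Per-column amino-acid counts of an alignment
#'
#' Tallies, for every alignment column, the counts of the 20 canonical amino
#' acids, gaps (`-`, `.`) and other excluded letters across all records.
#'
#' @inheritParams alignment_to_ddg
#' @return A list with `counts` (columns x 20 matrix), `gaps`, `excluded`
#'   (integer vectors) and `n_sequences`; for every column
#'   `rowSums(counts) + gaps + excluded == n_sequences`.
#' @export
alignment_profile <- function(alignment) {
  seqs <- .as_aligned_chars(alignment)
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment: sequences have unequal aligned lengths")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  aa <- aa_codes()
  L <- ncol(m)
  counts <- matrix(0L, L, 20L, dimnames = list(NULL, aa))
  gaps <- integer(L); excl <- integer(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    counts[j, ] <- as.integer(table(factor(col[col %in% aa], levels = aa)))
    gaps[j] <- sum(col %in% c("-", "."))
    excl[j] <- nrow(m) - sum(counts[j, ]) - gaps[j]
  }
  list(counts = counts, gaps = gaps, excluded = excl,
       n_sequences = nrow(m))
}
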