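#' The 20 canonical amino acids
#'
#' One-letter codes of the canonical amino acids in the package's column
#' order (alphabetical by one-letter code). All 20-valued vectors in
#' \pkg{prefscan} — descriptor scales, preference rows — follow this order
#' unless a file header says otherwise.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_codes()
aa_codes <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# order a named 20-vector into canonical column order, checking completeness
.aa_order <- function(x, what = "values") {
  aa <- aa_codes()
  if (is.null(names(x))) {
    if (length(x) != 20L)
      stop(what, " must have 20 entries, got ", length(x))
    names(x) <- aa
    return(x)
  }
  missing <- setdiff(aa, names(x))
  if (length(missing))
    stop(what, " missing amino acid(s): ", paste(missing, collapse = ", "))
  x[aa]
}
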