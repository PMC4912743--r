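# Preference tables: one row per site, 20 amino-acid preference values.
#
# metric = "preference": any metric increasing with the probability of
#   observing the amino acid (deep-sequencing enrichment scores, frequencies).
# metric = "ddg": statistical free energies, ddG = -log10(P_i/P_wt); 0 for
#   the wild type, positive for disfavored residues (lower = more preferred).

#' Construct a preference table
#'
#' @param wt Character vector of wild-type amino acids (1-letter codes).
#' @param residue Integer residue numbers (unique; need not be contiguous).
#' @param prefs Numeric matrix, one row per site, 20 columns in [aa_codes()]
#'   order (or named by amino acid).
#' @param metric `"preference"` (higher = more preferred) or `"ddg"`
#'   (statistical free energy, wild type exactly 0, lower = more preferred).
#' @param kstar Optional numeric vector of tolerance-to-substitution values
#'   in `[1, 20]`; `NA` entries are computed on demand by the screen.
#' @param extra Optional numeric vector of user data carried along.
#' @param low_coverage Optional logical vector flagging sites with no
#'   observations beyond the query sequence (alignment inputs).
#' @param source Free-text provenance of the table.
#' @return A data frame of class `pref_table` with columns `wt`, `residue`,
#'   the 20 amino acids, and optionally `kstar`, `kstar_source`, `extra`,
#'   `low_coverage`; the metric is stored in `attr(, "metric")`.
#' @export
pref_table <- function(wt, residue, prefs, metric = c("preference", "ddg"),
                       kstar = NULL, extra = NULL, low_coverage = NULL,
                       source = "constructed") {
  metric <- match.arg(metric)
  aa <- aa_codes()
  prefs <- as.matrix(prefs)
  if (ncol(prefs) != 20L)
    stop("prefs must have 20 columns, got ", ncol(prefs))
  if (!is.null(colnames(prefs))) {
    missing <- setdiff(aa, colnames(prefs))
    if (length(missing))
      stop("prefs missing amino acid column(s): ",
           paste(missing, collapse = ", "))
    prefs <- prefs[, aa, drop = FALSE]
  } else colnames(prefs) <- aa
  n <- nrow(prefs)
  wt <- toupper(as.character(wt))
  residue <- as.integer(residue)
  if (length(wt) != n || length(residue) != n)
    stop("wt, residue and prefs disagree in length")
  bad <- !(wt %in% aa)
  if (any(bad))
    stop("unknown wild-type amino acid code(s): ",
         paste(unique(wt[bad]), collapse = ", "))
  if (anyDuplicated(residue))
    stop("duplicate residue number(s): ",
         paste(unique(residue[duplicated(residue)]), collapse = ", "))
  if (any(!is.finite(prefs)))
    stop("non-finite preference value(s) at row(s) ",
         paste(which(rowSums(!is.finite(prefs)) > 0), collapse = ", "))
  if (metric == "ddg") {
    wt_vals <- prefs[cbind(seq_len(n), match(wt, aa))]
    if (any(abs(wt_vals) > 1e-6))
      stop("ddg metric requires the wild-type entry to be 0; violated at residue(s) ",
           paste(residue[abs(wt_vals) > 1e-6], collapse = ", "))
  }
  out <- data.frame(wt = wt, residue = residue, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(prefs))
  if (!is.null(kstar)) {
    kstar <- as.numeric(kstar)
    chk <- kstar[!is.na(kstar)]
    if (any(chk < 1 - 1e-9 | chk > 20 + 1e-9))
      stop("kstar values must lie in [1, 20]")
    out$kstar <- kstar
    out$kstar_source <- ifelse(is.na(kstar), NA_character_, "user-provided")
  }
  if (!is.null(extra)) out$extra <- as.numeric(extra)
  if (!is.null(low_coverage)) out$low_coverage <- as.logical(low_coverage)
  rownames(out) <- NULL
  structure(out, metric = metric, source = source,
            class = c("pref_table", "data.frame"))
}

#' @export
print.pref_table <- function(x, ...) {
  cat("Preference table:", nrow(x), "sites, metric =",
      attr(x, "metric"), "\n")
  cat("Source:", attr(x, "source"), "\n")
  print(utils::head(as.data.frame(x), 6L), digits = 4)
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more sites\n")
  invisible(x)
}

# preference row of one site as a named 20-vector
site_prefs <- function(table, i) {
  unlist(table[i, aa_codes()])
}

#' Read a tab-delimited preference table
#'
#' The expected dialect is one row per residue with 22, 23 or 24 tab-delimited
#' fields: wild-type amino acid (1-letter), residue number, preferences for
#' all 20 amino acids, then optionally a tolerance-to-substitution value
#' (`k*`, taken as-is and never recomputed) and optionally one extra numeric
#' column. An optional header row names the amino-acid column order; without
#' a header the 20 preference columns are taken alphabetical by 1-letter code
#' (see [aa_codes()]).
#'
#' @param file Path to the table, or a character vector of lines.
#' @param metric Interpretation of the preference values; see [pref_table()].
#' @return A [pref_table()].
#' @export
read_preference_table <- function(file, metric = c("preference", "ddg")) {
  metric <- match.arg(metric)
  lines <- if (length(file) == 1L && file.exists(file))
    readLines(file) else as.character(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty preference table")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  aa_order <- aa_codes()
  first <- toupper(trimws(fields[[1L]]))
  header <- length(first) >= 22L && all(first[3:22] %in% aa_codes()) &&
    !anyDuplicated(first[3:22])
  if (header) {
    aa_order <- first[3:22]
    fields <- fields[-1L]
    if (!length(fields)) stop("preference table has a header but no data rows")
  }
  n <- length(fields)
  wt <- character(n); residue <- integer(n)
  prefs <- matrix(NA_real_, n, 20L, dimnames = list(NULL, aa_order))
  kstar <- rep(NA_real_, n); extra <- rep(NA_real_, n)
  any_k <- FALSE; any_e <- FALSE
  for (i in seq_len(n)) {
    f <- trimws(fields[[i]])
    if (!(length(f) %in% 22:24))
      stop("row ", i, ": expected 22, 23 or 24 tab-delimited fields, got ",
           length(f))
    if (!(toupper(f[1L]) %in% aa_codes()))
      stop("row ", i, ": unknown amino acid code '", f[1L], "'")
    wt[i] <- toupper(f[1L])
    residue[i] <- suppressWarnings(as.integer(f[2L]))
    if (is.na(residue[i]))
      stop("row ", i, ": residue number '", f[2L], "' is not an integer")
    p <- suppressWarnings(as.numeric(f[3:22]))
    if (any(is.na(p)))
      stop("row ", i, ": non-numeric preference value(s)")
    prefs[i, ] <- p
    if (length(f) >= 23L) {
      kstar[i] <- suppressWarnings(as.numeric(f[23L])); any_k <- TRUE
      if (is.na(kstar[i])) stop("row ", i, ": non-numeric k* value")
    }
    if (length(f) == 24L) {
      extra[i] <- suppressWarnings(as.numeric(f[24L])); any_e <- TRUE
    }
  }
  if (anyDuplicated(residue))
    stop("duplicate residue number(s): ",
         paste(unique(residue[duplicated(residue)]), collapse = ", "))
  pref_table(wt, residue, prefs[, aa_codes(), drop = FALSE], metric = metric,
             kstar = if (any_k) kstar else NULL,
             extra = if (any_e) extra else NULL,
             source = if (length(file) == 1L && file.exists(file))
               file else "text input")
}

#' Write a preference table in the tab-delimited dialect
#'
#' Writes a header row plus one 22/23/24-field row per site — wild-type amino
#' acid, residue number, the 20 preferences in [aa_codes()] order, `k*` when
#' present, and the extra column when present — loadable back by
#' [read_preference_table()].
#'
#' @param table A [pref_table()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_preference_table <- function(table, file) {
  stopifnot(inherits(table, "pref_table"))
  aa <- aa_codes()
  cols <- c("wt", "residue", aa)
  if ("kstar" %in% names(table)) cols <- c(cols, "kstar")
  if ("extra" %in% names(table)) cols <- c(cols, "extra")
  out <- as.data.frame(table)[, cols, drop = FALSE]
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

#' Tolerance to substitution (effective number of amino acids)
#'
#' Summarizes one site's 20 preferences as the effective number of amino
#' acids tolerated, `k* = 2^H` where `H` is the Shannon entropy (base 2) of
#' the site's amino-acid frequencies. `k*` ranges from 1 (only one amino acid
#' tolerated) to 20 (all amino acids equally tolerated).
#'
#' For `metric = "ddg"` the frequencies are recovered from the statistical
#' free energies as `P_i = 10^(-ddG_i)` (so `P_wt = 1`) and then normalized;
#' for `metric = "preference"` the given non-negative preferences are
#' normalized directly.
#'
#' @param prefs Numeric vector of 20 preference values (named by amino acid
#'   or in [aa_codes()] order).
#' @param metric See [pref_table()].
#' @return A single number in `[1, 20]`.
#' @export
#' @examples
#' compute_kstar(rep(0.05, 20))           # uniform -> 20
#' compute_kstar(c(1, rep(0, 19)))        # one amino acid -> 1
#' compute_kstar(rep(0, 20), metric = "ddg")  # flat ddG -> 20
compute_kstar <- function(prefs, metric = c("preference", "ddg")) {
  metric <- match.arg(metric)
  prefs <- .aa_order(unlist(prefs), "preferences")
  if (any(!is.finite(prefs))) stop("non-finite preference value(s)")
  p <- if (metric == "ddg") 10^(-prefs) else {
    if (any(prefs < 0))
      stop("negative preference value(s) under metric = 'preference'")
    prefs
  }
  tot <- sum(p)
  if (tot <= 0) stop("all preferences are zero; frequencies undefined")
  f <- p / tot
  nz <- f > 0
  h <- -sum(f[nz] * log2(f[nz]))
  2^h
}

# fill missing kstar values from the preferences
add_kstar <- function(table) {
  metric <- attr(table, "metric")
  if (!("kstar" %in% names(table))) {
    table$kstar <- NA_real_
    table$kstar_source <- NA_character_
  }
  todo <- is.na(table$kstar)
  for (i in which(todo)) {
    table$kstar[i] <- compute_kstar(site_prefs(table, i), metric)
    table$kstar_source[i] <- "computed"
  }
  table
}
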