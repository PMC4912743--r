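# Sequence- and structure-mapping outputs of a screen.

#' Per-residue sequence map of a screen
#'
#' One row per residue, ordered by residue number: residue number, wild-type
#' amino acid, `k*`, site class, best descriptor (`"-"` for unexplained
#' sites), trend, adjusted p-value and slope.
#'
#' @param object A `pref_screen` from [preference_screen()].
#' @return A data frame.
#' @export
sequence_map <- function(object) {
  stopifnot(inherits(object, "pref_screen"))
  cl <- object$classes[order(object$classes$residue), , drop = FALSE]
  b <- object$best
  j <- match(cl$residue, b$residue)
  out <- data.frame(
    residue = cl$residue, wt = cl$wt, kstar = cl$kstar, class = cl$class,
    descriptor = ifelse(is.na(j), "-", b$descriptor_id[j]),
    trend = ifelse(is.na(j), "-", b$trend[j]),
    p_adj = ifelse(is.na(j), NA_real_, b$p_adj[j]),
    slope = ifelse(is.na(j), NA_real_, b$slope[j]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' PyMOL / VMD selection strings for screened residues
#'
#' Builds prebuilt atom-selection text for external structure viewers,
#' listing the residues whose best fit matches the requested descriptor
#' and/or trend (all explained residues when no filter is given).
#'
#' @param object A `pref_screen`.
#' @param chain Chain identifier in the structure.
#' @param dialect `"pymol"` (`select <name>, chain <C> and resi n1+n2+...`)
#'   or `"vmd"` (`chain <C> and resid n1 n2 ...`).
#' @param descriptor Optional descriptor id filter.
#' @param trend Optional `"positive"`/`"negative"` filter.
#' @return A single selection line; residues sorted ascending. When no
#'   residue matches, the comment line `"# empty selection"`.
#' @export
#' @examples
#' gen <- gen_planted_table(3, "hydrophobicity", -1, 0.02, seed = 4)
#' sc <- preference_screen(gen$table)
#' structure_selections(sc, chain = "A", dialect = "pymol",
#'                      descriptor = "hydrophobicity", trend = "negative")
structure_selections <- function(object, chain, dialect = c("pymol", "vmd"),
                                 descriptor = NULL, trend = NULL) {
  stopifnot(inherits(object, "pref_screen"))
  dialect <- match.arg(dialect)
  b <- object$best
  keep <- rep(TRUE, nrow(b))
  if (!is.null(descriptor)) keep <- keep & b$descriptor_id == descriptor
  if (!is.null(trend)) keep <- keep & b$trend == trend
  resi <- sort(b$residue[keep])
  if (!length(resi)) return("# empty selection")
  name <- paste(c(if (!is.null(descriptor)) descriptor else "best_fit",
                  if (!is.null(trend)) substr(trend, 1, 3)),
                collapse = "_")
  if (dialect == "pymol")
    sprintf("select %s, chain %s and resi %s", name, chain,
            paste(resi, collapse = "+"))
  else
    sprintf("chain %s and resid %s", chain, paste(resi, collapse = " "))
}

#' Write per-residue values into the B-factor column of a PDB file
#'
#' Headless stand-in for structure coloring: the B-factor field (columns
#' 61-66) of every `ATOM`/`HETATM` record of the given chain is replaced by
#' the value mapped to its residue number (e.g. `k*` or the best-fit adjusted
#' p-value); residues without a mapped value get `default`. Everything
#' outside the B-factor field is preserved byte for byte.
#'
#' @param pdb Path to a PDB file or a character vector of its lines.
#' @param chain Chain identifier (column 22).
#' @param values Named numeric vector, names = residue numbers.
#' @param default Value written for unmapped residues of the chain.
#' @return Character vector of rewritten PDB lines.
#' @export
bfactor_annotate <- function(pdb, chain, values, default = 0) {
  lines <- if (length(pdb) == 1L && file.exists(pdb)) readLines(pdb)
           else as.character(pdb)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom))
    stop("input does not parse as PDB: no ATOM/HETATM records found")
  if (is.null(names(values)))
    stop("values must be named by residue number")
  idx <- which(is_atom)
  ch <- substr(lines[idx], 22, 22)
  resno <- trimws(substr(lines[idx], 23, 26))
  on_chain <- ch == chain
  if (!any(on_chain))
    stop("chain '", chain, "' not found in the structure")
  if (!any(resno[on_chain] %in% names(values)))
    stop("no residue number of chain ", chain, " matches the mapped values; ",
         "consider a numbering offset")
  for (k in which(on_chain)) {
    v <- values[resno[k]]
    if (is.na(v)) v <- default
    line <- lines[idx[k]]
    if (nchar(line) < 66) line <- formatC(line, width = -66)
    substr(line, 61, 66) <- sprintf("%6.2f", v)
    lines[idx[k]] <- line
  }
  lines
}

#' Export a screen's tables to files
#'
#' Writes the all-fits table, the best-fits table, the class/descriptor
#' summary and the per-residue sequence map, as TSV and/or JSON with
#' identical content.
#'
#' @param object A `pref_screen`.
#' @param dir Output directory (created if needed).
#' @param format Subset of `c("tsv", "json")`.
#' @return Invisibly, the paths written.
#' @export
export_report <- function(object, dir, format = c("tsv", "json")) {
  stopifnot(inherits(object, "pref_screen"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sm <- summary(object)
  parts <- list(all_fits = object$fits, best_fits = object$best,
                summary_classes = sm$classes,
                summary_descriptors = sm$descriptors,
                sequence_map = sequence_map(object))
  paths <- character()
  for (nm in names(parts)) {
    if ("tsv" %in% format) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(parts[[nm]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
      paths <- c(paths, p)
    }
    if ("json" %in% format) {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(parts[[nm]], p, dataframe = "rows", digits = NA,
                           na = "null")
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
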