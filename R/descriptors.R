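# Amino-acid descriptor catalog.
#
# Sets:
#   1  eight basic physicochemical scales
#   2  two metabolic scales
#   3  sixteen composites of Set 1 scales (ratio "/", product "x", sum "+")
#   4  four discrete side-chain composition counts
#
# The numeric values are standard published scales; each table carries a
# provenance string, and aa_catalog(file=) accepts a full user override so any
# exact scale can be substituted.

# Set 1 scales, canonical amino-acid order (A C D E F G H I K L M N P Q R S T V W Y)
.set1_values <- function() {
  v <- rbind(
    volume = c(88.6, 108.5, 111.1, 138.4, 189.9, 60.1, 153.2, 166.7, 168.6,
               166.7, 162.9, 114.1, 112.7, 143.8, 173.4, 89.0, 116.1, 140.0,
               227.8, 193.6),
    # aqueous solubility, g per 100 g water at 25 C; stored as log10
    log_solubility = log10(c(16.65, 28.0, 0.778, 0.864, 2.965, 24.99, 4.19,
                             4.117, 73.9, 2.426, 3.381, 3.53, 162.3, 2.5,
                             18.2, 5.023, 13.2, 8.85, 1.136, 0.0453)),
    hydrophobicity = c(0.31, 1.54, -0.77, -0.64, 1.79, 0.00, 0.13, 1.80,
                       -0.99, 1.70, 1.23, -0.60, 0.72, -0.22, -1.01, -0.04,
                       0.26, 1.22, 2.25, 0.96),
    isoelectric_point = c(6.00, 5.07, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02,
                          9.74, 5.98, 5.74, 5.41, 6.30, 5.65, 10.76, 5.68,
                          5.60, 5.96, 5.89, 5.66),
    p_helix = c(1.42, 0.70, 1.01, 1.51, 1.13, 0.57, 1.00, 1.08, 1.16, 1.21,
                1.45, 0.67, 0.57, 1.11, 0.98, 0.77, 0.83, 1.06, 1.08, 0.69),
    steric_hindrance = c(0.52, 0.62, 0.76, 0.68, 0.70, 0.00, 0.70, 1.02,
                         0.68, 0.98, 0.78, 0.76, 0.36, 0.68, 0.68, 0.53,
                         0.96, 1.02, 0.70, 0.70),
    p_sheet = c(0.83, 1.19, 0.54, 0.37, 1.38, 0.75, 0.87, 1.60, 0.74, 1.30,
                1.05, 0.89, 0.55, 1.10, 0.93, 0.75, 1.19, 1.70, 1.37, 1.47),
    flexibility = c(0.357, 0.346, 0.511, 0.497, 0.314, 0.544, 0.323, 0.462,
                    0.466, 0.365, 0.295, 0.463, 0.509, 0.507, 0.529, 0.507,
                    0.444, 0.386, 0.305, 0.420)
  )
  colnames(v) <- aa_codes()
  v
}

.set1_info <- function() {
  data.frame(
    descriptor_id = c("volume", "log_solubility", "hydrophobicity",
                      "isoelectric_point", "p_helix", "steric_hindrance",
                      "p_sheet", "flexibility"),
    display_name = c("Volume", "Log(solubility)", "Hydrophobicity",
                     "Isoelectric point", "P(helix)", "Steric hindrance",
                     "P(sheet)", "Flexibility"),
    set_id = 1L,
    provenance = c(
      "Residue volume (A^3), Zamyatnin (1972)",
      "log10 aqueous solubility (g/100 g water, 25 C), CRC-style compilation; freely soluble Cys/Lys/Arg assigned measured literature values",
      "Side-chain hydrophobicity (octanol/water pi), Fauchere & Pliska (1983)",
      "Isoelectric point of the free amino acid, standard biochemical tables",
      "Alpha-helix propensity P(alpha), Chou & Fasman (1978)",
      "Side-chain steric parameter, Charton (1981)",
      "Beta-sheet propensity P(beta), Chou & Fasman (1978)",
      "Average flexibility index, Bhaskaran & Ponnuswamy (1988)"),
    stringsAsFactors = FALSE
  )
}

.set2_values <- function() {
  v <- rbind(
    decay_time = c(1200, 1200, 3, 30, 3, 1200, 3, 30, 3, 3,
                   1200, 3, 1200, 10, 2, 1200, 1200, 1200, 3, 10),
    synthesis_cost = c(11.7, 24.7, 12.7, 15.3, 52.0, 11.7, 38.3, 32.3, 30.3,
                       27.3, 34.3, 14.7, 20.3, 16.3, 27.3, 11.7, 18.7, 23.3,
                       74.3, 50.0)
  )
  colnames(v) <- aa_codes()
  v
}

.set2_info <- function() {
  data.frame(
    descriptor_id = c("decay_time", "synthesis_cost"),
    display_name = c("In vivo decay time", "Cost for synthesis"),
    set_id = 2L,
    provenance = c(
      "In vivo half-life conferred by the N-terminal residue in yeast (minutes), N-end rule, Bachmair et al. (1986)",
      "Biosynthetic cost in high-energy phosphate bonds, Akashi & Gojobori (2002)"),
    stringsAsFactors = FALSE
  )
}

# Set 4: discrete side-chain composition counts (backbone excluded, His neutral).
# H-bond donors+acceptors: each side-chain O/N/S counted once as acceptor plus
# once more per attached polar hydrogen site (thiol and thioether included).
.set4_values <- function() {
  v <- rbind(
    n_oxygen   = c(0, 0, 2, 2, 0, 0, 0, 0, 0, 0, 0, 1, 0, 1, 0, 1, 1, 0, 0, 1),
    n_nitrogen = c(0, 0, 0, 0, 0, 0, 2, 0, 1, 0, 0, 1, 0, 1, 3, 0, 0, 0, 1, 0),
    n_sulfur   = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    n_hbond    = c(0, 2, 2, 2, 0, 0, 2, 0, 2, 0, 1, 2, 0, 2, 4, 2, 2, 0, 1, 2)
  )
  colnames(v) <- aa_codes()
  v
}

.set4_info <- function() {
  data.frame(
    descriptor_id = c("n_oxygen", "n_nitrogen", "n_sulfur", "n_hbond"),
    display_name = c("Number of Oxygen atoms in side chain",
                     "Number of Nitrogen atoms in side chain",
                     "Number of Sulfur atoms in side chain",
                     "Number of H-bond donors and acceptors in side chain"),
    set_id = 4L,
    provenance = rep("Counted from side-chain chemical structure (backbone excluded; His neutral)", 4L),
    stringsAsFactors = FALSE
  )
}

# (display name, operator, parents) definition of the 16 Set 3 composites
.set3_spec <- function() {
  list(
    list(id = "volume_per_p_helix",   name = "Volume/P(helix)",              op = "/", a = "volume", b = "p_helix"),
    list(id = "volume_per_p_sheet",   name = "Volume/P(sheet)",              op = "/", a = "volume", b = "p_sheet"),
    list(id = "volume_per_logsol",    name = "Volume/log(solubility)",       op = "/", a = "volume", b = "log_solubility"),
    list(id = "logsol_x_flexibility", name = "Log(solubility) x Flexibility", op = "*", a = "log_solubility", b = "flexibility"),
    list(id = "steric_x_flexibility", name = "Steric hindrance x Flexibility", op = "*", a = "steric_hindrance", b = "flexibility"),
    list(id = "p_helix_plus_p_sheet", name = "P(helix) + P(sheet)",          op = "+", a = "p_helix", b = "p_sheet"),
    list(id = "logsol_x_hydrophobicity", name = "log(solubility) x Hydrophobicity", op = "*", a = "log_solubility", b = "hydrophobicity"),
    list(id = "hydro_x_flexibility",  name = "Hydrophobicity x Flexibility", op = "*", a = "hydrophobicity", b = "flexibility"),
    list(id = "volume_per_helix_sheet", name = "Volume/(P(helix) + P(sheet))", op = "/", a = "volume", b = "p_helix_plus_p_sheet"),
    list(id = "steric_per_p_helix",   name = "Steric hindrance/P(helix)",    op = "/", a = "steric_hindrance", b = "p_helix"),
    list(id = "iep_per_p_sheet",      name = "Isoelectric point/P(sheet)",   op = "/", a = "isoelectric_point", b = "p_sheet"),
    list(id = "volume_x_iep",         name = "Volume x Isoelectric Point",   op = "*", a = "volume", b = "isoelectric_point"),
    list(id = "iep_per_p_helix",      name = "Isoelectric point/P(helix)",   op = "/", a = "isoelectric_point", b = "p_helix"),
    list(id = "p_helix_per_p_sheet",  name = "P(helix)/P(sheet)",            op = "/", a = "p_helix", b = "p_sheet"),
    list(id = "steric_per_p_sheet",   name = "Steric hindrance/P(sheet)",    op = "/", a = "steric_hindrance", b = "p_sheet"),
    list(id = "p_helix_x_flexibility", name = "P(helix) x Flexibility",      op = "*", a = "p_helix", b = "flexibility")
  )
}

#' Derive the Set 3 composite descriptors from the Set 1 scales
#'
#' The composite set extends the eight basic physicochemical scales with 16
#' precomputed amino-acid-wise combinations — ratios ("/"), products ("x") and
#' one sum ("+") — such as `Volume/P(helix)`. Parents may themselves be a
#' combination (`Volume/(P(helix) + P(sheet))`).
#'
#' @param set1 Numeric matrix of the 8 Set 1 scales (rows named by
#'   `descriptor_id`, 20 columns in [aa_codes()] order), e.g. the Set 1 block
#'   of [aa_catalog()].
#' @return A list with `values` (16 x 20 numeric matrix) and `info`
#'   (data frame with `descriptor_id`, `display_name`, `set_id`,
#'   `provenance`).
#' @export
#' @examples
#' cat <- aa_catalog()
#' comp <- derive_composites(cat$values[cat$info$set_id == 1, ])
#' comp$info$display_name
derive_composites <- function(set1) {
  need <- .set1_info()$descriptor_id
  missing <- setdiff(need, rownames(set1))
  if (length(missing))
    stop("missing parent scale(s): ", paste(missing, collapse = ", "))
  spec <- .set3_spec()
  pool <- set1
  out <- matrix(NA_real_, nrow = length(spec), ncol = 20L,
                dimnames = list(vapply(spec, `[[`, "", "id"), colnames(set1)))
  for (k in seq_along(spec)) {
    s <- spec[[k]]
    a <- pool[s$a, ]
    b <- pool[s$b, ]
    if (s$op == "/" && any(b == 0))
      stop("composite '", s$name, "': denominator scale '", s$b,
           "' is zero for amino acid(s) ",
           paste(colnames(set1)[b == 0], collapse = ", "))
    val <- switch(s$op, "/" = a / b, "*" = a * b, "+" = a + b)
    out[k, ] <- val
    pool <- rbind(pool, val)
    rownames(pool)[nrow(pool)] <- s$id
  }
  info <- data.frame(
    descriptor_id = vapply(spec, `[[`, "", "id"),
    display_name = vapply(spec, `[[`, "", "name"),
    set_id = 3L,
    provenance = "Composite of built-in Set 1 scales",
    stringsAsFactors = FALSE
  )
  list(values = out, info = info)
}

.validate_catalog <- function(values, info) {
  aa <- aa_codes()
  if (!identical(colnames(values), aa))
    stop("catalog value columns must be the 20 canonical amino acids in order")
  if (anyDuplicated(info$descriptor_id))
    stop("duplicate descriptor name(s): ",
         paste(unique(info$descriptor_id[duplicated(info$descriptor_id)]),
               collapse = ", "))
  for (i in seq_len(nrow(values))) {
    v <- values[i, ]
    id <- info$descriptor_id[i]
    if (any(!is.finite(v)))
      stop("descriptor '", id, "' has non-finite values")
    if (length(unique(v)) == 1L)
      stop("descriptor '", id, "' is constant; a constant scale cannot be fit")
    if (info$set_id[i] == 4L && any(v < 0 | v != round(v)))
      stop("descriptor '", id, "' (Set 4) must contain non-negative integers")
  }
  if (!all(info$set_id %in% 1:4))
    stop("set_id must be in 1..4")
  invisible(TRUE)
}

#' The amino-acid descriptor catalog
#'
#' Builds the built-in catalog of 30 amino-acid descriptor scales — Set 1
#' (8 physicochemical), Set 2 (2 metabolic), Set 3 (16 composites derived from
#' Set 1 by [derive_composites()]) and Set 4 (4 discrete side-chain
#' composition counts) — or reads a full replacement catalog from a
#' tab-delimited file.
#'
#' The custom file must have a header row `descriptor  set  A  C  D ... Y`
#' (the 20 one-letter codes in any order), then one row per descriptor:
#' name, set id in 1..4, and 20 numeric values.
#'
#' @param file Optional path to a custom descriptor table; when given it
#'   replaces the built-in catalog entirely.
#' @return An object of class `aa_catalog`: a list with `info` (data frame:
#'   `descriptor_id`, `display_name`, `set_id`, `provenance`) and `values`
#'   (numeric matrix, one row per descriptor, 20 columns in [aa_codes()]
#'   order). Rows are ordered Set 1 to Set 4.
#' @export
#' @examples
#' cat <- aa_catalog()
#' table(cat$info$set_id)
#' cat$values["volume", c("G", "W")]
aa_catalog <- function(file = NULL) {
  if (!is.null(file)) return(.read_custom_catalog(file))
  s1v <- .set1_values(); s1i <- .set1_info()
  s2v <- .set2_values(); s2i <- .set2_info()
  s3 <- derive_composites(s1v)
  s4v <- .set4_values(); s4i <- .set4_info()
  values <- rbind(s1v, s2v, s3$values, s4v)
  info <- rbind(s1i, s2i, s3$info, s4i)
  rownames(values) <- info$descriptor_id
  rownames(info) <- NULL
  .validate_catalog(values, info)
  structure(list(info = info, values = values), class = "aa_catalog")
}

.read_custom_catalog <- function(file) {
  raw <- utils::read.delim(file, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing <- setdiff(aa_codes(), colnames(raw))
  if (length(missing))
    stop("custom descriptor file missing amino acid column(s): ",
         paste(missing, collapse = ", "))
  if (ncol(raw) < 22L)
    stop("custom descriptor file must have name, set and 20 amino-acid columns")
  ids <- as.character(raw[[1L]])
  sets <- suppressWarnings(as.integer(raw[[2L]]))
  if (anyDuplicated(ids))
    stop("duplicate descriptor name(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  values <- matrix(NA_real_, nrow = nrow(raw), ncol = 20L,
                   dimnames = list(ids, aa_codes()))
  for (i in seq_len(nrow(raw))) {
    v <- suppressWarnings(as.numeric(unlist(raw[i, aa_codes()])))
    if (any(is.na(v)))
      stop("descriptor '", ids[i], "': non-numeric value(s) in row ", i)
    values[i, ] <- v
  }
  if (any(is.na(sets)))
    stop("non-integer set id for descriptor(s): ",
         paste(ids[is.na(sets)], collapse = ", "))
  info <- data.frame(descriptor_id = ids, display_name = ids,
                     set_id = sets, provenance = paste("user file:", file),
                     stringsAsFactors = FALSE)
  o <- order(info$set_id, seq_len(nrow(info)))
  info <- info[o, , drop = FALSE]; values <- values[o, , drop = FALSE]
  rownames(info) <- NULL
  .validate_catalog(values, info)
  structure(list(info = info, values = values), class = "aa_catalog")
}

#' @export
print.aa_catalog <- function(x, ...) {
  n <- table(factor(x$info$set_id, levels = 1:4))
  cat("Amino-acid descriptor catalog:", nrow(x$info), "descriptors",
      sprintf("(Set 1: %d, Set 2: %d, Set 3: %d, Set 4: %d)\n",
              n[1], n[2], n[3], n[4]))
  invisible(x)
}

# rows of the catalog restricted to the selected sets, scan order preserved
catalog_subset <- function(catalog, sets) {
  stopifnot(inherits(catalog, "aa_catalog"), all(sets %in% 1:4))
  keep <- catalog$info$set_id %in% sets
  structure(list(info = catalog$info[keep, , drop = FALSE],
                 values = catalog$values[keep, , drop = FALSE]),
            class = "aa_catalog")
}
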