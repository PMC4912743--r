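# Synthetic preference tables and alignments with planted ground truth.
#
# The generators emulate the three site archetypes the screen must tell
# apart: sites shaped by a descriptor (response = slope * d + Gaussian
# noise), unconstrained sites (i.i.d. Gaussian responses), and conserved
# sites (one amino acid tolerated, k* = 1). Responses are re-encoded in the
# requested metric: "ddg" negates and shifts so the wild type sits at 0;
# "preference" min-shifts to non-negative values. Both encodings are affine
# in the response, so fits (r, p) are unchanged by the encoding. All
# generators take an explicit seed and touch no global random state beyond
# set.seed.

# encode a response vector (higher = more favored) into the given metric;
# the wild type is the most favored amino acid
.encode_site <- function(response, metric) {
  wt <- names(response)[which.max(response)]
  prefs <- if (metric == "ddg") response[wt] - response
           else response - min(response)
  list(wt = wt, prefs = prefs)
}

#' Generate a table of sites planted on one descriptor
#'
#' Each site's response is `slope * d + eps`, `eps ~ N(0, noise_sd)`, with
#' `d` the chosen descriptor scale, then re-encoded into the requested
#' metric. With `noise_sd = 0` every site fits the planted descriptor with
#' `|r| = 1`.
#'
#' @param n_sites Number of sites.
#' @param descriptor_id A descriptor id of `catalog`.
#' @param slope Nonzero true slope on the response scale.
#' @param noise_sd Standard deviation of the Gaussian noise (>= 0).
#' @param seed Integer seed; runs are reproducible per seed.
#' @param metric Output metric, see [pref_table()].
#' @param catalog An [aa_catalog()].
#' @return A list with `table` (a [pref_table()]) and `truth` (data frame of
#'   per-site class, descriptor, slope, noise sd and seed).
#' @export
gen_planted_table <- function(n_sites, descriptor_id, slope, noise_sd,
                              seed, metric = c("preference", "ddg"),
                              catalog = aa_catalog()) {
  metric <- match.arg(metric)
  stopifnot(n_sites >= 1, slope != 0, noise_sd >= 0)
  if (!(descriptor_id %in% rownames(catalog$values)))
    stop("unknown descriptor_id '", descriptor_id, "'")
  d <- catalog$values[descriptor_id, ]
  set.seed(seed)
  wt <- character(n_sites)
  prefs <- matrix(NA_real_, n_sites, 20L, dimnames = list(NULL, aa_codes()))
  for (i in seq_len(n_sites)) {
    resp <- slope * d + stats::rnorm(20L, 0, noise_sd)
    enc <- .encode_site(resp, metric)
    wt[i] <- enc$wt; prefs[i, ] <- enc$prefs
  }
  truth <- data.frame(residue = seq_len(n_sites), class = "planted",
                      descriptor_id = descriptor_id, slope = slope,
                      noise_sd = noise_sd, seed = seed,
                      stringsAsFactors = FALSE)
  list(table = pref_table(wt, seq_len(n_sites), prefs, metric,
                          source = "synthetic: planted"),
       truth = truth)
}

#' Generate a table of null (unconstrained) sites
#'
#' Responses are i.i.d. Gaussian with no descriptor dependence — the null
#' model for family-wise type-I error control.
#'
#' @inheritParams gen_planted_table
#' @return A [pref_table()].
#' @export
gen_null_table <- function(n_sites, noise_sd = 1, seed,
                           metric = c("preference", "ddg")) {
  metric <- match.arg(metric)
  stopifnot(n_sites >= 1, noise_sd > 0)
  set.seed(seed)
  aa <- aa_codes()
  wt <- character(n_sites)
  prefs <- matrix(NA_real_, n_sites, 20L, dimnames = list(NULL, aa))
  for (i in seq_len(n_sites)) {
    resp <- stats::setNames(stats::rnorm(20L, 0, noise_sd), aa)
    enc <- .encode_site(resp, metric)
    wt[i] <- enc$wt; prefs[i, ] <- enc$prefs
  }
  pref_table(wt, seq_len(n_sites), prefs, metric,
             source = "synthetic: null")
}

#' Generate a table of conserved sites
#'
#' Each site tolerates a single amino acid (preference 1, all others 0, or
#' the `ddg` equivalent with strongly positive free energies), so
#' `k* = 1 < 4` and the site is degenerate for regression.
#'
#' @inheritParams gen_planted_table
#' @return A [pref_table()].
#' @export
gen_conserved_table <- function(n_sites, seed,
                                metric = c("preference", "ddg")) {
  metric <- match.arg(metric)
  stopifnot(n_sites >= 1)
  set.seed(seed)
  aa <- aa_codes()
  wt <- sample(aa, n_sites, replace = TRUE)
  prefs <- matrix(if (metric == "ddg") 12 else 0, n_sites, 20L,
                  dimnames = list(NULL, aa))
  for (i in seq_len(n_sites))
    prefs[i, wt[i]] <- if (metric == "ddg") 0 else 1
  pref_table(wt, seq_len(n_sites), prefs, metric,
             source = "synthetic: conserved")
}

#' Generate a mixed benchmark table with ground truth
#'
#' A mixture of planted, null and conserved sites in the given proportions,
#' with the planted sites distributed round-robin across the chosen
#' descriptors with random slope signs. The planted noise is
#' `noise_rel * |slope| * sd(d)`, i.e. relative to the planted signal's
#' spread.
#'
#' @param n_sites Total number of sites.
#' @param fractions Named numeric vector of mixture proportions for
#'   `planted`, `null`, `conserved` (summing to 1).
#' @param descriptor_ids Descriptors to plant on (default: the Set 1 ids).
#' @param slope Magnitude of the planted slope (sign randomized per site).
#' @param noise_rel Planted noise sd relative to `|slope| * sd(d)`.
#' @inheritParams gen_planted_table
#' @return A list with `table` and `truth` (class, descriptor, slope,
#'   noise sd per site).
#' @export
gen_mixture_table <- function(n_sites = 500,
                              fractions = c(planted = 0.6, null = 0.3,
                                            conserved = 0.1),
                              descriptor_ids = NULL, slope = 1,
                              noise_rel = 0.1, seed = 1,
                              metric = c("preference", "ddg"),
                              catalog = aa_catalog()) {
  metric <- match.arg(metric)
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  if (is.null(descriptor_ids))
    descriptor_ids <-
      catalog$info$descriptor_id[catalog$info$set_id == 1L]
  set.seed(seed)
  aa <- aa_codes()
  n_planted <- round(n_sites * fractions[["planted"]])
  n_conserved <- round(n_sites * fractions[["conserved"]])
  n_null <- n_sites - n_planted - n_conserved
  cls <- sample(rep(c("planted", "null", "conserved"),
                    c(n_planted, n_null, n_conserved)))
  wt <- character(n_sites)
  prefs <- matrix(NA_real_, n_sites, 20L, dimnames = list(NULL, aa))
  truth <- data.frame(residue = seq_len(n_sites), class = cls,
                      descriptor_id = NA_character_, slope = NA_real_,
                      noise_sd = NA_real_, seed = seed,
                      stringsAsFactors = FALSE)
  pl <- which(cls == "planted")
  picks <- rep_len(descriptor_ids, length(pl))
  for (k in seq_along(pl)) {
    i <- pl[k]
    d <- catalog$values[picks[k], ]
    sl <- slope * sample(c(-1, 1), 1L)
    nsd <- noise_rel * abs(sl) * stats::sd(d)
    resp <- sl * d + stats::rnorm(20L, 0, nsd)
    enc <- .encode_site(resp, metric)
    wt[i] <- enc$wt; prefs[i, ] <- enc$prefs
    truth$descriptor_id[i] <- picks[k]
    truth$slope[i] <- sl
    truth$noise_sd[i] <- nsd
  }
  for (i in which(cls == "null")) {
    resp <- stats::setNames(stats::rnorm(20L), aa)
    enc <- .encode_site(resp, metric)
    wt[i] <- enc$wt; prefs[i, ] <- enc$prefs
  }
  for (i in which(cls == "conserved")) {
    w <- sample(aa, 1L)
    prefs[i, ] <- if (metric == "ddg") 12 else 0
    prefs[i, w] <- if (metric == "ddg") 0 else 1
    wt[i] <- w
  }
  list(table = pref_table(wt, seq_len(n_sites), prefs, metric,
                          source = "synthetic: mixture"),
       truth = truth)
}

#' Generate a gapped alignment from per-column amino-acid profiles
#'
#' Samples each column of each non-query record multinomially from the
#' column's profile (optionally replacing a fraction with gaps); the first
#' record is the ungapped query, carrying the modal amino acid of every
#' column.
#'
#' @param n_sequences Total number of records, query included.
#' @param column_profiles Numeric matrix, one row per column, 20 columns in
#'   [aa_codes()] order (rows are normalized internally).
#' @param seed Integer seed.
#' @param gap_fraction Per-column probability of a gap in non-query rows.
#' @param query_id Name of the query record.
#' @return Named character vector of aligned sequences, query first.
#' @export
gen_alignment <- function(n_sequences, column_profiles, seed,
                          gap_fraction = 0, query_id = "query") {
  stopifnot(n_sequences >= 2, gap_fraction >= 0, gap_fraction < 1)
  p <- as.matrix(column_profiles)
  if (ncol(p) != 20L) stop("column_profiles must have 20 columns")
  colnames(p) <- aa_codes()
  set.seed(seed)
  L <- nrow(p)
  aa <- aa_codes()
  query <- aa[apply(p, 1L, which.max)]
  body <- matrix("", n_sequences - 1L, L)
  for (j in seq_len(L)) {
    prob <- p[j, ] / sum(p[j, ])
    col <- sample(aa, n_sequences - 1L, replace = TRUE, prob = prob)
    if (gap_fraction > 0) {
      g <- stats::runif(n_sequences - 1L) < gap_fraction
      col[g] <- "-"
    }
    body[, j] <- col
  }
  out <- c(paste(query, collapse = ""),
           apply(body, 1L, paste, collapse = ""))
  names(out) <- c(query_id, paste0("seq", seq_len(n_sequences - 1L)))
  out
}

#' Write aligned sequences to a FASTA file
#'
#' @param sequences Named character vector (e.g. from [gen_alignment()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(sequences, file) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sequences), file)
  invisible(file)
}
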