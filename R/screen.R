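#' Screen a preference table for descriptor-shaped sites
#'
#' The central fit of \pkg{prefscan}: every site of a preference table is
#' screened against the selected descriptor sets ([screen_site()]), missing
#' tolerance values `k*` are filled in ([compute_kstar()]), and each site is
#' classified as
#' \describe{
#'   \item{`explained`}{at least one descriptor fit passes the
#'     Bonferroni-adjusted cutoff; the best one is reported,}
#'   \item{`unexplained_low_tolerance`}{no fit and `k* < k_low` (near-conserved,
#'     active-site-like),}
#'   \item{`unexplained_high_tolerance`}{no fit and `k* > k_high` (almost
#'     anything goes),}
#'   \item{`unexplained_mid`}{no fit, intermediate tolerance.}
#' }
#' The result is deterministic given the table, catalog and configuration.
#'
#' @param table A [pref_table()] (from [read_preference_table()],
#'   [alignment_to_ddg()] or a generator).
#' @param catalog An [aa_catalog()]; the built-in catalog by default.
#' @param config A [screen_config()]; individual settings can also be passed
#'   through `...` (e.g. `alpha`, `sets`, `quadratic`).
#' @param ... Arguments forwarded to [screen_config()] when `config` is not
#'   supplied.
#' @return An object of class `pref_screen` with components `table` (with
#'   `k*` filled), `fits` (all retained fits, all sites), `best` (best fit
#'   per explained site), `classes` (per-site classification), `catalog`,
#'   `config` and `call`. Methods: `print`, `summary`, `coef`, `plot`,
#'   `predict`, `fitted`, `residuals`.
#' @export
#' @examples
#' gen <- gen_planted_table(5, "hydrophobicity", slope = 1,
#'                          noise_sd = 0.05, seed = 1)
#' fit <- preference_screen(gen$table, sets = 1)
#' summary(fit)
preference_screen <- function(table, catalog = aa_catalog(),
                              config = NULL, ...) {
  stopifnot(inherits(table, "pref_table"), nrow(table) > 0)
  if (is.null(config)) config <- screen_config(...)
  stopifnot(inherits(config, "screen_config"))
  metric <- attr(table, "metric")
  table <- add_kstar(table)

  fits <- list(); best <- list(); models <- list()
  for (i in seq_len(nrow(table))) {
    res <- screen_site(site_prefs(table, i), catalog, config, metric)
    if (nrow(res$retained)) {
      res$retained <- cbind(residue = table$residue[i], res$retained)
      fits[[length(fits) + 1L]] <- res$retained
    }
    if (!is.null(res$best)) {
      b <- cbind(residue = table$residue[i], res$best)
      best[[length(best) + 1L]] <- b
    }
  }
  fits <- if (length(fits)) do.call(rbind, fits) else
    cbind(residue = integer(), .empty_fits())
  best <- if (length(best)) do.call(rbind, best) else
    cbind(residue = integer(), .empty_fits())
  rownames(fits) <- rownames(best) <- NULL

  explained <- table$residue %in% best$residue
  classes <- ifelse(explained, "explained",
             ifelse(table$kstar < config$k_low, "unexplained_low_tolerance",
             ifelse(table$kstar > config$k_high, "unexplained_high_tolerance",
                    "unexplained_mid")))
  classes <- data.frame(residue = table$residue, wt = table$wt,
                        kstar = table$kstar, class = classes,
                        stringsAsFactors = FALSE)
  structure(list(table = table, fits = fits, best = best, classes = classes,
                 catalog = catalog, config = config, metric = metric,
                 call = match.call()),
            class = "pref_screen")
}

#' @export
print.pref_screen <- function(x, ...) {
  n <- nrow(x$table)
  ne <- sum(x$classes$class == "explained")
  cat("Per-site descriptor screen (prefscan)\n")
  cat(sprintf("  %d sites, metric = %s, sets {%s}, alpha = %g%s\n",
              n, x$metric, paste(x$config$sets, collapse = ","),
              x$config$alpha,
              if (x$config$quadratic) ", quadratic" else ""))
  cat(sprintf("  explained: %d sites (%.1f%%); retained fits: %d\n",
              ne, 100 * ne / n, nrow(x$fits)))
  invisible(x)
}

#' Summarize a screen by descriptor and site class
#'
#' Produces the two standard summary tables: how often each descriptor was
#' picked as a site's best fit (split by trend sign, as counts and as
#' percentages of explained and of all sites), and the four-way partition of
#' sites into explained / unexplained of very low tolerance (`k* < k_low`) /
#' unexplained of very high tolerance (`k* > k_high`) / unexplained of
#' intermediate tolerance. Class percentages are over all sites with data;
#' the per-descriptor "share of explained" column is labelled as such.
#'
#' @param object A `pref_screen`.
#' @param grouped Collapse descriptors by set (default `FALSE`).
#' @param ... Unused.
#' @return A list of class `summary.pref_screen` with `classes` (class,
#'   count, percent) and `descriptors` (descriptor, trend counts,
#'   percentages).
#' @export
summary.pref_screen <- function(object, grouped = FALSE, ...) {
  n <- nrow(object$table)
  cls <- c("explained", "unexplained_low_tolerance",
           "unexplained_high_tolerance", "unexplained_mid")
  counts <- vapply(cls, function(k) sum(object$classes$class == k), 0L)
  class_tab <- data.frame(class = cls, count = unname(counts),
                          percent = unname(100 * counts / n),
                          stringsAsFactors = FALSE)
  b <- object$best
  key <- if (grouped) paste0("set_", b$set_id) else b$descriptor_id
  n_exp <- counts[["explained"]]
  if (nrow(b)) {
    ids <- unique(key)
    desc_tab <- data.frame(
      descriptor = ids,
      n_positive = vapply(ids, function(k) sum(key == k & b$trend == "positive"), 0L),
      n_negative = vapply(ids, function(k) sum(key == k & b$trend == "negative"), 0L),
      stringsAsFactors = FALSE)
    desc_tab$n_best <- desc_tab$n_positive + desc_tab$n_negative
    desc_tab$pct_of_explained <- if (n_exp > 0) 100 * desc_tab$n_best / n_exp else 0
    desc_tab$pct_of_all <- 100 * desc_tab$n_best / n
    desc_tab <- desc_tab[order(-desc_tab$n_best), , drop = FALSE]
    rownames(desc_tab) <- NULL
  } else {
    desc_tab <- data.frame(descriptor = character(), n_positive = integer(),
                           n_negative = integer(), n_best = integer(),
                           pct_of_explained = numeric(), pct_of_all = numeric(),
                           stringsAsFactors = FALSE)
  }
  structure(list(n_sites = n, classes = class_tab, descriptors = desc_tab,
                 grouped = grouped, config = object$config),
            class = "summary.pref_screen")
}

#' @export
print.summary.pref_screen <- function(x, ...) {
  cat(sprintf("Summary over %d sites\n\nSite classes (%% of all sites):\n",
              x$n_sites))
  tab <- x$classes
  tab$percent <- sprintf("%.1f%%", tab$percent)
  print(tab, row.names = FALSE)
  cat("\nBest-fit descriptor frequencies:\n")
  if (nrow(x$descriptors)) {
    tab <- x$descriptors
    tab$pct_of_explained <- sprintf("%.1f%%", tab$pct_of_explained)
    tab$pct_of_all <- sprintf("%.1f%%", tab$pct_of_all)
    print(tab, row.names = FALSE)
  } else cat("  (no explained sites)\n")
  invisible(x)
}

#' @export
coef.pref_screen <- function(object, ...) {
  b <- object$best
  m <- as.matrix(b[, c("intercept", "slope", "quad")])
  rownames(m) <- b$residue
  m
}

# best-fit model of one residue, rebuilt from the stored coefficients
.best_fit_of <- function(object, residue) {
  b <- object$best[object$best$residue == residue, , drop = FALSE]
  if (!nrow(b)) return(NULL)
  d <- object$catalog$values[b$descriptor_id, ]
  fv <- b$intercept + b$slope * d +
    (if (!is.na(b$quad)) b$quad * d^2 else 0)
  i <- match(residue, object$table$residue)
  y <- response_values(site_prefs(object$table, i), object$metric)
  list(row = b, descriptor = d, fitted = fv, response = y)
}

#' @export
predict.pref_screen <- function(object, residue, ...) {
  f <- .best_fit_of(object, residue)
  if (is.null(f)) stop("residue ", residue, " has no best fit")
  f$fitted
}

#' @export
fitted.pref_screen <- function(object, ...) {
  res <- lapply(object$best$residue, function(r) .best_fit_of(object, r)$fitted)
  names(res) <- object$best$residue
  res
}

#' @export
residuals.pref_screen <- function(object, ...) {
  res <- lapply(object$best$residue, function(r) {
    f <- .best_fit_of(object, r); f$response - f$fitted
  })
  names(res) <- object$best$residue
  res
}

#' Plot one site's preferences against its best-fit descriptor
#'
#' Scatter of the site's response values (higher = more favored; statistical
#' free energies are negated) against the best-fit descriptor scale, with
#' points labelled by amino acid and the fitted line or curve overlaid.
#'
#' @param x A `pref_screen`.
#' @param residue Residue number to plot (defaults to the explained site with
#'   the smallest adjusted p-value).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pref_screen <- function(x, residue = NULL, ...) {
  if (!nrow(x$best)) stop("no explained sites to plot")
  if (is.null(residue))
    residue <- x$best$residue[which.min(x$best$p_adj)]
  f <- .best_fit_of(x, residue)
  if (is.null(f)) stop("residue ", residue, " has no best fit")
  info <- x$catalog$info
  dn <- info$display_name[match(f$row$descriptor_id, info$descriptor_id)]
  graphics::plot(f$descriptor, f$response, type = "n",
                 xlab = dn,
                 ylab = if (x$metric == "ddg") "-ddG (favorability)"
                        else "preference",
                 main = sprintf("residue %d (%s trend, p_adj = %.2g)",
                                residue, f$row$trend, f$row$p_adj), ...)
  graphics::text(f$descriptor, f$response, labels = names(f$response))
  o <- order(f$descriptor)
  graphics::lines(f$descriptor[o], f$fitted[o], col = "red3")
  invisible(f)
}
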