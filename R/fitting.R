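# Per-site regression screening.
#
# For one site, the 20 amino-acid responses (higher = more favored) are
# regressed on each descriptor scale in catalog order (Set 1 -> Set 4).
# Fits passing the Bonferroni-adjusted p cutoff (and optional r/RMSE limits)
# are retained; the best fit per site is selected by seeding with the first
# retained fit and replacing it only when a later fit lowers the RMSE
# significantly by a variance-ratio F test. The Set 1 -> 4 scan order plus
# incumbent-wins tie-breaking ensures composite and discrete descriptors are
# only picked when they are statistically better than the simple scales.

#' Response values of one site (higher = more favored)
#'
#' Puts a site's preferences on the scale used for fitting and plotting:
#' statistical free energies are negated (so more favored amino acids get
#' higher values), preference-type metrics are used unchanged.
#'
#' @param prefs Numeric vector of 20 preferences (named or in [aa_codes()]
#'   order).
#' @param metric See [pref_table()].
#' @return Named numeric vector of 20 response values.
#' @export
response_values <- function(prefs, metric = c("preference", "ddg")) {
  metric <- match.arg(metric)
  prefs <- .aa_order(unlist(prefs), "preferences")
  if (metric == "ddg") -prefs else prefs
}

#' Least-squares fit of one site's responses on one descriptor
#'
#' Ordinary least squares of the 20 response values on the descriptor scale
#' (plus its square for `order = 2`). The reported p-value is that of the
#' overall regression F test, which for `order = 1` equals the two-sided
#' t test on the slope (and the closed-form Pearson correlation test).
#'
#' @param response Named numeric vector of 20 responses (see
#'   [response_values()]).
#' @param descriptor Numeric vector of 20 descriptor values.
#' @param order 1 (linear) or 2 (quadratic).
#' @return A list of class `site_fit_model`: `order`, `coefficients`
#'   (intercept, slope, optionally quadratic), `r` (Pearson correlation of
#'   response with fitted values), `rmse`, `p_raw`, `n_points`, `fitted`,
#'   `trend` (`"positive"`/`"negative"`). A constant response yields a
#'   degenerate model with `p_raw = 1`.
#' @export
fit_descriptor <- function(response, descriptor, order = 1L) {
  stopifnot(order %in% 1:2)
  y <- as.numeric(response); d <- as.numeric(descriptor)
  if (length(y) != length(d))
    stop("response and descriptor lengths differ")
  n <- length(y)
  if (length(unique(d)) == 1L) stop("descriptor is constant")
  if (length(unique(y)) == 1L) {
    return(structure(list(order = as.integer(order),
                          coefficients = c(intercept = y[1], slope = 0,
                                           quad = if (order == 2L) 0),
                          r = 0, rmse = 0, p_raw = 1, n_points = n,
                          fitted = rep(y[1], n), trend = "positive",
                          degenerate = TRUE),
                     class = "site_fit_model"))
  }
  fit <- if (order == 1L) stats::lm(y ~ d) else stats::lm(y ~ d + I(d^2))
  fv <- stats::fitted(fit)
  res <- stats::residuals(fit)
  rmse <- sqrt(mean(res^2))
  # a noise-free site fits exactly; summary.lm warns about it but the
  # degenerate p (~0) is the intended answer
  fstat <- suppressWarnings(summary(fit)$fstatistic)
  p_raw <- if (is.null(fstat)) 1 else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  r <- if (stats::sd(fv) == 0) 0 else stats::cor(y, fv)
  cf <- stats::coef(fit)
  trend <- if (order == 1L) {
    if (cf[2L] >= 0) "positive" else "negative"
  } else {
    # curved but near-monotone: classify by the correlation of the fitted
    # curve with the descriptor values
    ct <- stats::cor(fv, d)
    if (is.na(ct) || ct >= 0) "positive" else "negative"
  }
  names(cf) <- c("intercept", "slope", if (order == 2L) "quad")
  structure(list(order = as.integer(order), coefficients = cf,
                 r = unname(r), rmse = rmse, p_raw = unname(p_raw),
                 n_points = n, fitted = unname(fv), trend = trend,
                 degenerate = FALSE),
            class = "site_fit_model")
}

#' Bonferroni adjustment
#'
#' Family-wise error control across the descriptors screened at one site:
#' the raw p-value is multiplied by the number of tests and capped at 1.
#'
#' @param p_raw Raw p-value(s).
#' @param n_tests Number of tests in the family (descriptors screened,
#'   doubled when both linear and quadratic models are screened).
#' @return Adjusted p-value(s), `min(1, n_tests * p_raw)`.
#' @export
bonferroni <- function(p_raw, n_tests) {
  stopifnot(n_tests >= 1)
  pmin(1, n_tests * p_raw)
}

#' Best-fit replacement rule
#'
#' An incumbent best fit is replaced by a challenger (both already passing
#' the adjusted p cutoff) only if the challenger lowers the RMSE and the
#' improvement is significant by a variance-ratio F test:
#' `F = (rmse_inc / rmse_chal)^2` must exceed the upper `f_alpha` critical
#' value of the F distribution with `(n - q_inc, n - q_chal)` degrees of
#' freedom, `q` being the number of fitted coefficients.
#'
#' @param incumbent,challenger `site_fit_model` objects on the same site.
#' @param f_alpha Significance level of the replacement test.
#' @return `TRUE` if the challenger should replace the incumbent.
#' @export
replace_if_better <- function(incumbent, challenger, f_alpha = 0.05) {
  n <- incumbent$n_points
  if (challenger$rmse >= incumbent$rmse) return(FALSE)
  if (challenger$rmse == 0) return(TRUE)
  f <- (incumbent$rmse / challenger$rmse)^2
  df1 <- n - length(incumbent$coefficients)
  df2 <- n - length(challenger$coefficients)
  stats::pf(f, df1, df2, lower.tail = FALSE) < f_alpha
}

# nested comparison of the quadratic vs linear fit on the same descriptor:
# extra-sum-of-squares F test
.quad_improves <- function(lin, quad, f_alpha) {
  n <- lin$n_points
  rss1 <- n * lin$rmse^2
  rss2 <- n * quad$rmse^2
  if (rss2 >= rss1) return(FALSE)
  if (rss2 == 0) return(TRUE)
  f <- (rss1 - rss2) / (rss2 / (n - 3))
  stats::pf(f, 1, n - 3, lower.tail = FALSE) < f_alpha
}

#' Screening configuration
#'
#' @param alpha Family-wise p-value cutoff for retaining a fit (default
#'   0.05).
#' @param sets Descriptor sets to screen, a subset of 1:4 (default 1).
#' @param quadratic Also screen quadratic fits (default `FALSE`; doubles the
#'   Bonferroni divisor).
#' @param f_alpha Significance level of the best-fit replacement F test.
#' @param r_min Optional minimum correlation `r` of retained fits.
#' @param rmse_max Optional maximum RMSE of retained fits.
#' @param k_low,k_high Tolerance thresholds flagging unexplained sites of
#'   very low (`k* < k_low`) or very high (`k* > k_high`) tolerance to
#'   substitution (defaults 4 and 16).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.05, sets = 1L, quadratic = FALSE,
                          f_alpha = 0.05, r_min = NULL, rmse_max = NULL,
                          k_low = 4, k_high = 16) {
  stopifnot(alpha > 0, alpha <= 1, f_alpha > 0, f_alpha <= 1,
            all(sets %in% 1:4), k_low < k_high)
  structure(list(alpha = alpha, sets = sort(unique(as.integer(sets))),
                 quadratic = isTRUE(quadratic), f_alpha = f_alpha,
                 r_min = r_min, rmse_max = rmse_max,
                 k_low = k_low, k_high = k_high),
            class = "screen_config")
}

.passes_limits <- function(model, config) {
  if (!is.null(config$r_min) && model$r < config$r_min) return(FALSE)
  if (!is.null(config$rmse_max) && model$rmse > config$rmse_max) return(FALSE)
  TRUE
}

#' Screen one site against a descriptor catalog
#'
#' Fits the site's responses against every descriptor of the selected sets in
#' catalog order, retains fits whose Bonferroni-adjusted p-value passes the
#' cutoff (and the optional r/RMSE limits), and selects the best fit by the
#' [replace_if_better()] rule. Sites whose response takes fewer than 3
#' distinct values are degenerate for regression and return no fits.
#'
#' @param prefs Numeric vector of the site's 20 preferences.
#' @param catalog An [aa_catalog()] (already restricted, or restricted here
#'   via `config$sets`).
#' @param config A [screen_config()].
#' @param metric See [pref_table()].
#' @return A list with `retained` (data frame of all significant fits, one
#'   row each: descriptor_id, set_id, order, intercept, slope, quad, r,
#'   rmse, p_raw, p_adj, trend) and `best` (single-row data frame or `NULL`),
#'   plus `models` (the `site_fit_model` objects of the retained fits).
#' @export
screen_site <- function(prefs, catalog, config = screen_config(),
                        metric = c("preference", "ddg")) {
  metric <- match.arg(metric)
  sub <- catalog_subset(catalog, config$sets)
  y <- response_values(prefs, metric)
  n_desc <- nrow(sub$info)
  n_tests <- n_desc * (if (config$quadratic) 2L else 1L)
  empty <- list(retained = .empty_fits(), best = NULL, models = list())
  if (length(unique(round(y, 12))) < 3L) return(empty)

  rows <- list(); models <- list()
  best_row <- NULL; best_model <- NULL
  for (k in seq_len(n_desc)) {
    d <- sub$values[k, ]
    lin <- fit_descriptor(y, d, 1L)
    cand <- list(model = lin,
                 p_adj = bonferroni(lin$p_raw, n_tests))
    quad <- NULL
    if (config$quadratic) {
      quad <- fit_descriptor(y, d, 2L)
      quad_adj <- bonferroni(quad$p_raw, n_tests)
      lin_ok <- cand$p_adj <= config$alpha && .passes_limits(lin, config)
      quad_ok <- quad_adj <= config$alpha && .passes_limits(quad, config)
      if (quad_ok && (!lin_ok || .quad_improves(lin, quad, config$f_alpha)))
        cand <- list(model = quad, p_adj = quad_adj)
    }
    for (mm in c(list(list(model = lin, p_adj = bonferroni(lin$p_raw, n_tests))),
                 if (!is.null(quad))
                   list(list(model = quad, p_adj = bonferroni(quad$p_raw, n_tests))))) {
      if (mm$p_adj <= config$alpha && !mm$model$degenerate &&
          .passes_limits(mm$model, config)) {
        rows[[length(rows) + 1L]] <-
          .fit_row(sub$info$descriptor_id[k], sub$info$set_id[k], mm$model, mm$p_adj)
        models[[length(models) + 1L]] <- mm$model
      }
    }
    # candidate for best fit
    if (cand$p_adj <= config$alpha && !cand$model$degenerate &&
        .passes_limits(cand$model, config)) {
      if (is.null(best_model)) {
        best_model <- cand$model
        best_row <- .fit_row(sub$info$descriptor_id[k], sub$info$set_id[k],
                             cand$model, cand$p_adj)
      } else if (replace_if_better(best_model, cand$model, config$f_alpha)) {
        best_model <- cand$model
        best_row <- .fit_row(sub$info$descriptor_id[k], sub$info$set_id[k],
                             cand$model, cand$p_adj)
      }
    }
  }
  retained <- if (length(rows)) do.call(rbind, rows) else .empty_fits()
  list(retained = retained, best = best_row, models = models)
}

.fit_row <- function(id, set_id, model, p_adj) {
  cf <- model$coefficients
  data.frame(descriptor_id = id, set_id = set_id, order = model$order,
             intercept = unname(cf["intercept"]),
             slope = unname(cf["slope"]),
             quad = if (model$order == 2L) unname(cf["quad"]) else NA_real_,
             r = model$r, rmse = model$rmse, p_raw = model$p_raw,
             p_adj = p_adj, trend = model$trend,
             stringsAsFactors = FALSE)
}

.empty_fits <- function() {
  data.frame(descriptor_id = character(), set_id = integer(),
             order = integer(), intercept = numeric(), slope = numeric(),
             quad = numeric(), r = numeric(), rmse = numeric(),
             p_raw = numeric(), p_adj = numeric(), trend = character(),
             stringsAsFactors = FALSE)
}
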