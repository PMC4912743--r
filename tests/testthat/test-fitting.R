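test_that("responses are oriented so that higher means more favored", {
  ddg <- setNames(c(0, 1, -2, rep(0.5, 17)), aa_codes())
  resp <- response_values(ddg, "ddg")
  expect_equal(unname(resp[1:3]), c(0, -1, 2))
  pref <- setNames(runif(20), aa_codes())
  expect_equal(response_values(pref, "preference"), pref)
})

test_that("a perfect linear dependence is recovered exactly", {
  d <- aa_catalog()$values["volume", ]
  fit <- fit_descriptor(2 * d + 1, d, 1L)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-9)
  expect_lt(fit$p_raw, 1e-12)
  expect_equal(fit$trend, "positive")
  fit_neg <- fit_descriptor(-0.5 * d, d, 1L)
  expect_equal(fit_neg$trend, "negative")
})

test_that("constant responses yield a degenerate, never-significant model", {
  d <- aa_catalog()$values["volume", ]
  fit <- fit_descriptor(rep(3, 20), d, 1L)
  expect_true(fit$degenerate)
  expect_equal(fit$p_raw, 1)
  expect_equal(unname(fit$coefficients["slope"]), 0)
})

test_that("regression p-values agree with a permutation oracle", {
  d <- aa_catalog()$values["hydrophobicity", ]
  set.seed(314)
  y <- d + rnorm(20, 0, 0.5 * sd(d))
  fit <- fit_descriptor(y, d, 1L)
  B <- 1e5L
  r_obs <- abs(cor(y, d))
  perms <- vapply(seq_len(B), function(i) sample(y), numeric(20))
  r_perm <- abs(as.vector(cor(d, perms)))
  p_perm <- mean(r_perm >= r_obs - 1e-12)
  tol <- 3 * sqrt(max(fit$p_raw, 1 / B) / B)
  expect_lt(abs(p_perm - fit$p_raw), tol + 1e-12)
})

test_that("order-1 p-values equal the closed-form correlation test", {
  cat <- aa_catalog()
  set.seed(99)
  for (i in 1:20) {
    d <- cat$values[sample(nrow(cat$values), 1), ]
    y <- rnorm(20)
    fit <- fit_descriptor(y, d, 1L)
    r <- cor(y, d)
    tstat <- r * sqrt(18 / (1 - r^2))
    p_closed <- 2 * pt(-abs(tstat), df = 18)
    expect_equal(fit$p_raw, p_closed, tolerance = 1e-10)
    expect_equal(fit$r, abs(r), tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.001, 8), 0.008)
  expect_equal(bonferroni(0.2, 10), 1.0)
  expect_equal(bonferroni(0.37, 1), 0.37)
})

test_that("the replacement F test follows the variance-ratio rule", {
  d1 <- aa_catalog()$values["volume", ]
  set.seed(7)
  y <- d1 + rnorm(20, 0, 0.3 * sd(d1))
  inc <- fit_descriptor(y, d1, 1L)
  # equal RMSE: F = 1, incumbent kept
  expect_false(replace_if_better(inc, inc))
  # challenger with half the RMSE on 20 points: F = 4 on (18, 18) df
  chal <- inc
  chal$rmse <- inc$rmse / 2
  expect_equal((inc$rmse / chal$rmse)^2, 4)
  expect_identical(replace_if_better(inc, chal, 0.05),
                   pf(4, 18, 18, lower.tail = FALSE) < 0.05)
  expect_true(replace_if_better(inc, chal, 0.05))
  # a challenger whose RMSE ratio sits below the critical value is rejected
  crit <- qf(0.95, 18, 18)
  chal$rmse <- inc$rmse / sqrt(crit * 0.99)
  expect_false(replace_if_better(inc, chal, 0.05))
  chal$rmse <- inc$rmse / sqrt(crit * 1.01)
  expect_true(replace_if_better(inc, chal, 0.05))
  # larger RMSE never replaces
  chal$rmse <- inc$rmse * 1.5
  expect_false(replace_if_better(inc, chal))
})

test_that("fits are affine-invariant in the descriptor", {
  d <- aa_catalog()$values["flexibility", ]
  set.seed(12)
  y <- 3 * d + rnorm(20, 0, 0.2 * sd(d))
  f0 <- fit_descriptor(y, d, 1L)
  f1 <- fit_descriptor(y, 5 * d + 2, 1L)
  expect_equal(f1$r, f0$r, tolerance = 1e-12)
  expect_equal(f1$rmse, f0$rmse, tolerance = 1e-12)
  expect_equal(f1$p_raw, f0$p_raw, tolerance = 1e-12)
  expect_equal(f1$trend, f0$trend)
  f2 <- fit_descriptor(y, -2 * d, 1L)
  expect_equal(f2$p_raw, f0$p_raw, tolerance = 1e-12)
  expect_equal(f2$trend, "negative")
})

test_that("quadratic fits never have larger RMSE than the nested linear fit", {
  cat <- aa_catalog()
  set.seed(77)
  for (i in 1:10) {
    d <- cat$values[sample(8, 1), ]
    y <- rnorm(20)
    lin <- fit_descriptor(y, d, 1L)
    quad <- fit_descriptor(y, d, 2L)
    expect_lte(quad$rmse, lin$rmse + 1e-12)
  }
})

test_that("a planted descriptor is picked as best with the planted trend", {
  cat <- aa_catalog()
  d <- cat$values["volume", ]
  set.seed(8)
  y <- -1.5 * d + rnorm(20, 0, 0.05 * sd(d))
  prefs <- y - min(y)  # preference encoding
  names(prefs) <- aa_codes()
  res <- screen_site(prefs, cat, screen_config(sets = 1), "preference")
  expect_equal(res$best$descriptor_id, "volume")
  expect_equal(res$best$trend, "negative")
  expect_gte(nrow(res$retained), 1L)
})

test_that("best-fit selection matches an exhaustive brute-force scan", {
  cat5 <- toy_catalog()
  cfg <- screen_config(alpha = 0.2, sets = 1)  # toy ids are all Set 1
  set.seed(2024)
  n_checked <- 0L
  for (rep in 1:40) {
    # half the sites lean on a random toy descriptor, half are noise
    y <- if (rep %% 2 == 0) rnorm(20) else {
      d <- cat5$values[sample(5, 1), ]
      sign(rnorm(1)) * d / sd(d) + rnorm(20, 0, runif(1, 0.2, 1))
    }
    names(y) <- aa_codes()
    prefs <- y - min(y)
    got <- screen_site(prefs, cat5, cfg, "preference")

    # independent brute force: closed-form p, explicit scan with F CDF
    p_raw <- r_all <- rmse_all <- numeric(5)
    for (k in 1:5) {
      d <- cat5$values[k, ]
      r <- cor(y, d)
      tstat <- r * sqrt(18 / (1 - r^2))
      p_raw[k] <- 2 * pt(-abs(tstat), 18)
      fitv <- fitted(lm(y ~ d))
      rmse_all[k] <- sqrt(mean((y - fitv)^2))
      r_all[k] <- abs(r)
    }
    p_adj <- pmin(1, 5 * p_raw)
    pass <- which(p_adj <= cfg$alpha)
    best <- if (length(pass)) {
      b <- pass[1]
      for (k in setdiff(pass, b)) {
        f <- (rmse_all[b] / rmse_all[k])^2
        if (rmse_all[k] < rmse_all[b] &&
            pf(f, 18, 18, lower.tail = FALSE) < cfg$f_alpha) b <- k
      }
      cat5$info$descriptor_id[b]
    } else NULL
    if (is.null(best)) {
      expect_null(got$best)
    } else {
      n_checked <- n_checked + 1L
      expect_equal(got$best$descriptor_id, best)
      expect_equal(sort(got$retained$descriptor_id),
                   sort(cat5$info$descriptor_id[pass]))
    }
  }
  expect_gte(n_checked, 10L)  # the comparison actually exercised real fits
})

test_that("retained fits shrink monotonically as alpha decreases", {
  gen <- gen_planted_table(10, "hydrophobicity", 1, 0.6, seed = 31)
  cat <- aa_catalog()
  loose <- preference_screen(gen$table, cat, alpha = 0.2, sets = 1)
  strict <- preference_screen(gen$table, cat, alpha = 0.01, sets = 1)
  expect_true(all(strict$fits$p_adj >= strict$fits$p_raw))
  key <- function(f) paste(f$residue, f$descriptor_id, f$order)
  expect_true(all(key(strict$fits) %in% key(loose$fits)))
})

test_that("the screen is deterministic and skips degenerate sites", {
  gen <- gen_mixture_table(30, seed = 5)
  s1 <- preference_screen(gen$table, sets = 1)
  s2 <- preference_screen(gen$table, sets = 1)
  expect_identical(s1$fits, s2$fits)
  expect_identical(s1$best, s2$best)
  expect_identical(s1$classes, s2$classes)
  # conserved (two-valued) sites are never fitted
  cons <- gen$truth$residue[gen$truth$class == "conserved"]
  expect_false(any(s1$best$residue %in% cons))
})

test_that("quadratic screening doubles the Bonferroni family", {
  gen <- gen_planted_table(5, "p_sheet", 1, 0.3, seed = 13)
  lin <- preference_screen(gen$table, sets = 1, quadratic = FALSE)
  quad <- preference_screen(gen$table, sets = 1, quadratic = TRUE)
  # the same linear fit carries a doubled adjusted p under quadratic screening
  l1 <- lin$fits[lin$fits$order == 1, ]
  q1 <- quad$fits[quad$fits$order == 1, ]
  shared <- merge(l1, q1, by = c("residue", "descriptor_id"))
  expect_gt(nrow(shared), 0)
  expect_equal(shared$p_adj.y, pmin(1, 2 * shared$p_adj.x), tolerance = 1e-12)
})
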