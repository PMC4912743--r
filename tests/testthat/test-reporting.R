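# one small mixed screen reused across the reporting tests
gen <- gen_mixture_table(40, seed = 17)
sc <- preference_screen(gen$table, sets = 1)

test_that("site classes partition all sites exactly once", {
  cl <- sc$classes
  expect_setequal(cl$residue, sc$table$residue)
  expect_true(all(cl$class %in% c("explained", "unexplained_low_tolerance",
                                  "unexplained_high_tolerance",
                                  "unexplained_mid")))
  # explained iff a best fit exists; extremes split by k* thresholds
  expect_setequal(cl$residue[cl$class == "explained"], sc$best$residue)
  nofit <- cl[cl$class != "explained", ]
  expect_true(all(nofit$kstar[nofit$class == "unexplained_low_tolerance"] < 4))
  expect_true(all(nofit$kstar[nofit$class == "unexplained_high_tolerance"] > 16))
  mid <- nofit$kstar[nofit$class == "unexplained_mid"]
  expect_true(all(mid >= 4 & mid <= 16))
})

test_that("summary percentages recompute exactly from the per-site lists", {
  sm <- summary(sc)
  expect_equal(sum(sm$classes$count), nrow(sc$table))
  expect_equal(sum(sm$classes$percent), 100, tolerance = 1e-9)
  n_exp <- sm$classes$count[sm$classes$class == "explained"]
  expect_equal(sum(sm$descriptors$n_best), n_exp)
  expect_equal(sm$descriptors$n_best,
               sm$descriptors$n_positive + sm$descriptors$n_negative)
  expect_equal(sm$descriptors$pct_of_explained,
               100 * sm$descriptors$n_best / n_exp, tolerance = 1e-12)
  # grouped summary collapses by set but keeps the same totals
  smg <- summary(sc, grouped = TRUE)
  expect_equal(sum(smg$descriptors$n_best), n_exp)
  expect_true(all(grepl("^set_", smg$descriptors$descriptor)))
})

test_that("an empty screen summarizes to zero counts", {
  nul <- gen_null_table(5, 1, seed = 2)
  sc0 <- preference_screen(nul, sets = 1, alpha = 1e-6)
  sm <- summary(sc0)
  expect_equal(sm$classes$count[sm$classes$class == "explained"], 0L)
  expect_equal(nrow(sm$descriptors), 0L)
})

test_that("the sequence map has one ordered row per residue and round-trips", {
  m <- sequence_map(sc)
  expect_equal(m$residue, sort(sc$table$residue))
  expect_true(all(m$descriptor[m$class != "explained"] == "-"))
  expect_true(all(m$descriptor[m$class == "explained"] != "-"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(m, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$residue, m$residue)
  expect_equal(back$descriptor, m$descriptor)
  expect_equal(back$kstar, m$kstar, tolerance = 1e-9)
})

test_that("selection strings contain exactly the filtered residues", {
  b <- sc$best
  top <- names(sort(table(b$descriptor_id), decreasing = TRUE))[1]
  expected <- sort(b$residue[b$descriptor_id == top])
  pml <- structure_selections(sc, chain = "A", dialect = "pymol",
                              descriptor = top)
  expect_match(pml, sprintf("^select %s, chain A and resi ", top))
  expect_equal(as.integer(strsplit(sub(".*resi ", "", pml), "\\+")[[1]]),
               expected)
  vmd <- structure_selections(sc, chain = "B", dialect = "vmd",
                              descriptor = top)
  expect_equal(vmd, sprintf("chain B and resid %s",
                            paste(expected, collapse = " ")))
  empty <- structure_selections(sc, chain = "A", dialect = "pymol",
                                descriptor = "no_such_descriptor")
  expect_equal(empty, "# empty selection")
})

test_that("selection string format matches the viewer dialects", {
  fake <- sc
  fake$best <- sc$best[1:2, ]
  fake$best$residue <- c(34L, 12L)
  fake$best$descriptor_id <- "hydrophobicity"
  fake$best$trend <- "negative"
  expect_equal(structure_selections(fake, "A", "pymol", "hydrophobicity",
                                    "negative"),
               "select hydrophobicity_neg, chain A and resi 12+34")
  expect_equal(structure_selections(fake, "A", "vmd", "hydrophobicity",
                                    "negative"),
               "chain A and resid 12 34")
})

test_that("B-factor annotation rewrites only the B-factor field", {
  pdb <- make_pdb_lines(c(12L, 13L, 14L), chain = "A")
  out <- bfactor_annotate(pdb, "A", c("12" = 7.5, "14" = 1.25), default = -1)
  atom <- grepl("^ATOM", out)
  expect_equal(sum(atom), 6L)
  b <- as.numeric(substr(out[atom], 61, 66))
  expect_equal(b, c(7.5, 7.5, -1, -1, 1.25, 1.25))
  # everything outside columns 61-66 is byte-identical
  strip <- function(x) paste0(substr(x, 1, 60), substr(x, 67, nchar(x)))
  expect_identical(strip(out[atom]), strip(pdb[grepl("^ATOM", pdb)]))
  expect_identical(out[!atom], pdb[!grepl("^ATOM", pdb)])
})

test_that("B-factor annotation is cross-checked by an independent PDB reader", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bfactor_annotate(make_pdb_lines(5:7), "A",
                              c("5" = 3.5, "6" = 18, "7" = 0.25)), f)
  pdb <- bio3d::read.pdb(f)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  expect_equal(ca$b[match(5:7, ca$resno)], c(3.5, 18, 0.25))
})

test_that("B-factor annotation rejects unusable inputs", {
  expect_error(bfactor_annotate(c("not", "a pdb"), "A", c("1" = 1)),
               "ATOM/HETATM")
  pdb <- make_pdb_lines(1:3)
  expect_error(bfactor_annotate(pdb, "A", c("99" = 1)), "offset")
  expect_error(bfactor_annotate(pdb, "Z", c("1" = 1)), "chain")
})

test_that("exported reports round-trip in both formats", {
  dir <- withr::local_tempdir()
  paths <- export_report(sc, dir)
  expect_true(all(file.exists(file.path(
    dir, c("all_fits.tsv", "best_fits.tsv", "sequence_map.json")))))
  best_tsv <- read.delim(file.path(dir, "best_fits.tsv"),
                         stringsAsFactors = FALSE)
  expect_equal(best_tsv$residue, sc$best$residue)
  expect_equal(best_tsv$p_adj, sc$best$p_adj, tolerance = 1e-9)
  best_json <- jsonlite::read_json(file.path(dir, "best_fits.json"),
                                   simplifyVector = TRUE)
  expect_equal(best_json$residue, sc$best$residue)
  expect_equal(best_json$descriptor_id, sc$best$descriptor_id)
  expect_equal(best_json$rmse, sc$best$rmse, tolerance = 1e-12)
})

test_that("model methods expose the best fits", {
  cf <- coef(sc)
  expect_equal(nrow(cf), nrow(sc$best))
  r1 <- sc$best$residue[1]
  pv <- predict(sc, r1)
  expect_length(pv, 20L)
  res <- residuals(sc)[[as.character(r1)]]
  expect_equal(sqrt(mean(res^2)), sc$best$rmse[1], tolerance = 1e-9)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(sc, residue = r1); grDevices::dev.off()
  expect_true(file.exists(f))
})
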