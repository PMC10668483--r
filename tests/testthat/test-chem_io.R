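# Reaction/EC parsing, dataset loading, folds and fixtures.

test_that("reaction SMILES splits into reactants, agents, products", {
  rx <- parse_reaction_smiles("CCO.O>>CC=O")
  expect_length(rx$reactants, 2)
  expect_length(rx$agents, 0)
  expect_length(rx$products, 1)

  rx <- parse_reaction_smiles("CCO>O>CC=O")
  expect_length(rx$reactants, 1)
  expect_length(rx$agents, 1)
  expect_length(rx$products, 1)

  expect_error(parse_reaction_smiles("CCO>>"), "no product")
  expect_error(parse_reaction_smiles("CCO>CC=O"), "exactly 3")
  expect_error(parse_reaction_smiles("CCQ>>C"), "unexpected atom token")
})

test_that("EC labels parse, truncate and round-trip", {
  ec <- parse_ec("3.4.13")
  expect_equal(c(ec$x, ec$y, ec$z), c(3L, 4L, 13L))
  expect_true(is.na(ec$sn))
  expect_identical(truncate_ec("2.4.1.17", 1), "2")
  expect_identical(truncate_ec(ec, 3), "3.4.13")
  expect_error(parse_ec("3..13"), "malformed")
  expect_error(parse_ec("8.1"), "1..7")
  expect_error(parse_ec("a.b"), "malformed")

  # render(parse(s)) == s at every level, incl. the 99 sub-subclass
  for (s in c("1", "2.4", "2.4.99", "3.4.13.9", "6.1.1.10")) {
    expect_identical(truncate_ec(parse_ec(s)), s)
  }
})

test_that("dataset loader filters class 7, strips embedded EC, reports rejects", {
  rhea <- tempfile(fileext = ".csv")
  writeLines(c("rxn_smiles,ec",
               "CCO>>CC=O,1.1.1",
               "CC>>CCO,7.1.1",
               "OCC>>OC=C,2.4.1"), rhea)
  recs <- load_reaction_dataset(rhea, "rhea_csv")
  expect_length(recs, 2)
  expect_equal(attr(recs, "n_class7"), 1L)
  expect_false(any(vapply(recs, function(r) r$ec$x, 0L) == 7L))

  ecreact <- tempfile(fileext = ".csv")
  writeLines(c("rxn_smiles,ec,source",
               "CC|2.4.1>>CCO,,brenda",
               "CCO>>CC=O,1.1.1,rhea"), ecreact)
  recs <- load_reaction_dataset(ecreact, "ecreact_csv")
  expect_identical(recs[[1]]$reaction_smiles, "CC>>CCO")
  expect_identical(truncate_ec(recs[[1]]$ec), "2.4.1")
  expect_identical(recs[[1]]$source, "brenda")

  dirty <- tempfile(fileext = ".csv")
  writeLines(c("rxn_smiles,ec",
               "CCO>>CC=O,1.1.1",
               "not_a_smiles($)>>C,2.1.1"), dirty)
  expect_warning(recs <- load_reaction_dataset(dirty, "rhea_csv"), "skipped")
  expect_length(recs, 1)
  expect_equal(nrow(attr(recs, "rejects")), 1L)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("smiles,ec", "CCO>>CC=O,1.1.1"), bad)
  expect_error(load_reaction_dataset(bad, "rhea_csv"), "missing column")

  only7 <- tempfile(fileext = ".csv")
  writeLines(c("rxn_smiles,ec", "CC>>CCO,7.1.1"), only7)
  expect_error(load_reaction_dataset(only7, "rhea_csv"), "no usable records")
})

test_that("cross-validation folds are stratified, disjoint and deterministic", {
  recs8 <- c(lapply(1:4, function(i) reaction_record("CCO>>CC=O", "1.1.1")),
             lapply(1:4, function(i) reaction_record("CC>>CCO", "2.1.1")))
  folds <- make_cv_folds(recs8, k = 4, level = 1, seed = 9)
  for (f in folds) {
    labs <- fixture_labels(recs8[f$test], 1)
    expect_equal(sort(labs), c("1", "2"))  # one per class per test fold
  }
  expect_identical(folds, make_cv_folds(recs8, k = 4, level = 1, seed = 9))
  expect_false(identical(folds, make_cv_folds(recs8, k = 4, level = 1, seed = 10)))

  w <- fixture_world()
  folds <- make_cv_folds(w$records, k = 4, level = 1, seed = 7)
  tests <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(tests), seq_along(w$records))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_length(intersect(tests[[i]], tests[[j]]), 0)
  }
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0)
    expect_setequal(c(f$train, f$validation, f$test), seq_along(w$records))
    expect_gte(length(f$validation), 1)
  }
  expect_error(make_cv_folds(w$records, k = 31, level = 1, seed = 1), "exceeds")
  expect_error(make_cv_folds(w$records, k = 1, level = 1, seed = 1), ">= 2")
})

test_that("fixture corpus has the stated shape and is reproducible", {
  cfg <- fixture_config(n_classes = 3, n_per_class = 10, seed = 7)
  recs <- generate_fixture_corpus(cfg)
  expect_length(recs, 30)
  labs <- fixture_labels(recs, 3)
  expect_equal(as.vector(table(labs)), rep(10L, 3))
  expect_setequal(unique(labs), c("1.1.1", "2.1.1", "3.1.1"))

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_reaction_csv(recs, f1)
  write_reaction_csv(generate_fixture_corpus(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("fixture config rejects a diagnostic that occurs in a scaffold", {
  # methanol shares its methyl environment with the alcohol scaffolds
  bad <- fixture_config(n_classes = 2, diagnostics = c("CO", "Br"))
  expect_error(generate_fixture_corpus(bad), "shares fragment")
  clash <- fixture_config(n_classes = 2, diagnostics = c("Br", "Br"))
  expect_error(generate_fixture_corpus(clash), "share fragments")
})

test_that("every fixture record carries its class's diagnostic bits", {
  w <- fixture_world()
  for (i in seq_along(w$records)) {
    ci <- as.integer(substr(w$y1[i], 1, 1))
    expect_true(all(w$corpus$matrix[i, w$diag[[ci]]$bits + 1L] == 1L),
                label = sprintf("record %d carries class-%d bits", i, ci))
    other <- setdiff(seq_along(w$diag), ci)
    for (o in other) {
      expect_true(all(w$corpus$matrix[i, w$diag[[o]]$bits + 1L] == 0L))
    }
  }
})
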