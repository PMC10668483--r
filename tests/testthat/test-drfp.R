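# Mapped differential reaction fingerprint.

test_that("shingle extraction matches the stated environments", {
  # dimethyl ether: radius-0 environments C and O; radius 1 adds CO and COC
  occ <- extract_shingles(parse_smiles("COC"),
                          fp_params(radius = 1, include_hydrogens = FALSE))
  smis <- unique(vapply(occ, `[[`, "", "smiles"))
  expect_true(all(c("C", "O") %in% smis))
  occ_h <- extract_shingles(parse_smiles("COC"), fp_params(radius = 1))
  expect_true("[H]C([H])([H])OC([H])([H])[H]" %in%
                vapply(occ_h, `[[`, "", "smiles"))

  # a single-atom molecule has exactly its radius-0 environment at any radius
  occ <- extract_shingles(parse_smiles("O"), fp_params(radius = 2))
  expect_length(occ, 1)
  expect_identical(occ[[1]]$smiles, "[H]O[H]")
})

test_that("shingle inventory equals a brute-force enumeration oracle", {
  mols <- c("CCO", "CC(C)O", "OCC=O", "C(N)C", "OC1CC1", "N#CC")
  for (smi in mols) {
    for (radius in 0:2) {
      for (eh in c(TRUE, FALSE)) {
        mine <- sort(unique(vapply(
          extract_shingles(parse_smiles(smi),
                           fp_params(radius = radius, include_hydrogens = eh)),
          `[[`, "", "smiles")))
        expect_identical(mine, oracle_shingles(parse_smiles(smi), radius, eh),
                         label = sprintf("%s r=%d h=%s", smi, radius, eh))
      }
    }
  }
})

test_that("identity reactions encode to the zero vector", {
  fp <- encode_reaction("CCO>>CCO", test_fp_params())
  expect_equal(sum(fp$bits), 0)
  expect_length(fp$on_bits, 0)
  expect_length(fp$bit_to_fragments, 0)
})

test_that("encoding is symmetric in reaction direction", {
  pairs <- list(c("CCO.O>>CC=O", "CC=O>>CCO.O"),
                c("CC(=O)OC>>CO.CC(O)=O", "CO.CC(O)=O>>CC(=O)OC"))
  for (p in pairs) {
    f1 <- encode_reaction(p[1], test_fp_params())
    f2 <- encode_reaction(p[2], test_fp_params())
    expect_identical(f1$bits, f2$bits)
    expect_identical(f1$bit_to_fragments, f2$bit_to_fragments)
  }
})

test_that("encoding is invariant to atom numbering and molecule order", {
  set.seed(31)
  for (rep in 1:100) {
    n_r <- sample(1:2, 1); n_p <- sample(1:2, 1)
    rmols <- lapply(seq_len(n_r), function(i) random_mol(sample(3:7, 1)))
    pmols <- lapply(seq_len(n_p), function(i) random_mol(sample(3:7, 1)))
    smi1 <- paste0(paste(vapply(rmols, canonical_smiles, ""), collapse = "."),
                   ">>",
                   paste(vapply(pmols, canonical_smiles, ""), collapse = "."))
    smi2 <- paste0(paste(rev(vapply(rmols, random_writing, "")), collapse = "."),
                   ">>",
                   paste(rev(vapply(pmols, random_writing, "")), collapse = "."))
    pp <- fp_params(dim = 512)
    f1 <- encode_reaction(smi1, pp)
    f2 <- encode_reaction(smi2, pp)
    expect_identical(f1$bits, f2$bits, label = sprintf("%s vs %s", smi1, smi2))
    # map consistency: popcount == number of mapped bits
    expect_equal(sum(f1$bits), length(f1$bit_to_fragments))
    # fold correctness: every stored fragment folds to its bit
    for (b in names(f1$bit_to_fragments)) {
      expect_true(all(fold_hash(hash32(f1$bit_to_fragments[[b]]), pp$dim) ==
                        as.integer(b)))
    }
  }
})

test_that("on-bit count matches the brute-force oracle", {
  pp <- test_fp_params()
  for (smi in c("CC(=O)OC.O>>CO.CC(O)=O", "CCO.O>>CC=O", "OCC(N)C>>OCC(N)C=O")) {
    fp <- encode_reaction(smi, pp)
    expect_identical(fp$on_bits, oracle_on_bits(smi, pp), label = smi)
  }
})

test_that("corpus encoding stacks rows and accumulates the global map", {
  w <- fixture_world()
  expect_equal(dim(w$corpus$matrix), c(30L, w$params$dim))
  expect_true(all(rowSums(w$corpus$matrix) > 0))

  # single record
  co1 <- encode_corpus(w$records[1], w$params)
  expect_equal(dim(co1$matrix), c(1L, w$params$dim))

  # global map is the union of the per-reaction maps
  expected <- list()
  for (fp in w$corpus$fingerprints) {
    for (b in names(fp$bit_to_fragments)) {
      expected[[b]] <- union(expected[[b]], fp$bit_to_fragments[[b]])
    }
  }
  expect_setequal(names(w$corpus$global_bit_to_fragments), names(expected))
  for (b in names(expected)) {
    expect_setequal(w$corpus$global_bit_to_fragments[[b]], expected[[b]])
  }
  # corpus-wide fragment count equals the union of per-reaction fragment sets
  per_rxn <- unique(unlist(lapply(w$corpus$fingerprints,
                                  function(fp) names(fp$fragment_to_occurrences))))
  expect_equal(length(unique(unlist(w$corpus$global_bit_to_fragments))),
               length(per_rxn))
})

test_that("corpus encoding survives bad records with a rejects report", {
  recs <- c(fixture_world()$records[1:2],
            list(reaction_record("CC(Q)>>C", "1.1.1")))
  expect_warning(co <- encode_corpus(recs, test_fp_params()), "rejected")
  expect_equal(nrow(co$matrix), 2L)
  expect_equal(co$rejects$index, 3L)
})

test_that("nearest-neighbour search is exact Jaccard with stable ties", {
  w <- fixture_world()
  # distinct reactions: a self-identical query row ranks first at 1.0
  distinct <- list(reaction_record("CCO>>CC=O", "1.1.1"),
                   reaction_record("CC(=O)OC.O>>CO.CC(O)=O", "3.1.1"),
                   reaction_record("OCC(N)C>>OCC(N)C=O", "1.1.1"))
  cod <- encode_corpus(distinct, w$params)
  nn <- nearest_neighbors(cod, cod$fingerprints[[2]], k = 3)
  expect_equal(nn$record[1], 2L)
  expect_equal(nn$similarity[1], 1.0)
  # duplicate rows at similarity 1.0 resolve by record id
  nn <- nearest_neighbors(w$corpus, w$corpus$fingerprints[[5]], k = 3)
  expect_equal(nn$similarity[1], 1.0)
  expect_equal(nn$record[1], 1L)

  zero <- encode_reaction("CCO>>CCO", w$params)
  nn0 <- nearest_neighbors(w$corpus, zero, k = 30)
  expect_true(all(nn0$similarity == 0))
  expect_equal(nn0$record, seq_len(30))  # ties broken by record id

  # brute-force pairwise ordering oracle on 10 rows
  q <- w$corpus$fingerprints[[8]]
  brute <- vapply(seq_len(10), function(i) {
    a <- which(w$corpus$matrix[i, ] == 1); b <- q$on_bits + 1L
    u <- length(union(a, b))
    if (u == 0) 0 else length(intersect(a, b)) / u
  }, 0)
  sub <- w$corpus
  sub$matrix <- sub$matrix[1:10, , drop = FALSE]
  sub$fingerprints <- sub$fingerprints[1:10]
  nn <- nearest_neighbors(sub, q, k = 10)
  expect_equal(nn$record, order(-brute, seq_len(10)))
  expect_equal(nn$similarity, brute[order(-brute, seq_len(10))])

  expect_error(nearest_neighbors(sub, rep(0L, 7), k = 1), "dimension")
})
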