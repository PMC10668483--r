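# DeepLIFT Rescale attribution and fragment/atom aggregation.

test_that("identical input and reference yield exactly zero contributions", {
  m <- rand_relu_net(6, 4, 3, seed = 2)
  x <- rep(c(1, 0), 3)
  expect_identical(deeplift_rescale(m, x, x, 1), rep(0, 6))
  expect_identical(deepshap_contributions(m, x, matrix(x, 1), 2)$feature_contributions,
                   rep(0, 6))
})

test_that("a linear-regime model reduces to the closed-form weight chain", {
  m <- rand_relu_net(5, 3, 2, seed = 4)
  m$b1[] <- 100  # hidden pre-activations always positive on bounded inputs
  x <- c(1, 0, 1, 1, 0); ref <- c(0, 1, 0, 0, 0)
  combined <- m$W1 %*% m$W2  # effective linear map
  expect_equal(deeplift_rescale(m, x, ref, 2), combined[, 2] * (x - ref),
               tolerance = 1e-12)
})

test_that("completeness holds on random ReLU nets and the trained model", {
  set.seed(6)
  for (i in 1:50) {
    d <- sample(3:10, 1); h <- sample(2:8, 1); C <- sample(2:4, 1)
    m <- rand_relu_net(d, h, C, seed = i)
    x <- stats::rnorm(d); ref <- stats::rnorm(d)
    ci <- sample(C, 1)
    contrib <- deeplift_rescale(m, x, ref, ci)
    delta <- mlp_scores(m, x)[1, ci] - mlp_scores(m, ref)[1, ci]
    expect_lt(abs(sum(contrib) - delta), 1e-5)
    # probability output: sums to the probability difference instead
    cp <- deeplift_rescale(m, x, ref, ci, output = "probability")
    p <- function(v) { s <- mlp_scores(m, v)[1, ]; e <- exp(s - max(s)); e / sum(e) }
    expect_lt(abs(sum(cp) - (p(x)[ci] - p(ref)[ci])), 1e-5)
  }
  w <- fixture_world()
  x <- w$corpus$matrix[4, ]
  core <- deepshap_contributions(w$model, x, w$background, 1)
  expect_lt(abs(sum(core$feature_contributions) -
                  (core$output_value - core$expected_value)), 1e-5)
})

test_that("DeepSHAP averages single-reference DeepLIFT over the background", {
  m <- rand_relu_net(6, 5, 3, seed = 9)
  set.seed(10)
  x <- stats::rnorm(6)
  B <- matrix(stats::rnorm(4 * 6), 4, 6)
  ds <- deepshap_contributions(m, x, B, 3)
  singles <- vapply(1:4, function(i) deeplift_rescale(m, x, B[i, ], 3),
                    numeric(6))
  expect_equal(ds$feature_contributions, rowMeans(singles), tolerance = 1e-12)
  expect_equal(ds$expected_value, mean(mlp_scores(m, B)[, 3]))
  # background of size one degenerates to the single reference
  ds1 <- deepshap_contributions(m, x, B[1, , drop = FALSE], 3)
  expect_equal(ds1$feature_contributions, deeplift_rescale(m, x, B[1, ], 3))
})

test_that("attributions split into present and absent fragments", {
  w <- fixture_world()
  fp <- w$corpus$fingerprints[[25]]  # class 3
  core <- deepshap_contributions(w$model, fp$bits, w$background, 3)
  sp <- split_fragment_contributions(core$feature_contributions, fp,
                                     corpus = w$corpus)
  expect_true(all(sp$present$bit %in% fp$on_bits))
  expect_true(all(fp$bits[sp$absent$bit + 1L] == 0))
  # fixture fragments never collide at dim 2048: one SMILES per present bit
  expect_true(all(sp$present$collisions == 1))
  # absent candidates come from the corpus-wide map
  has_cand <- lengths(sp$absent$candidates) > 0
  for (i in which(has_cand)) {
    expect_setequal(sp$absent$candidates[[i]],
                    w$corpus$global_bit_to_fragments[[as.character(sp$absent$bit[i])]])
  }
  # zero contributions leave nothing above any positive threshold
  sp0 <- split_fragment_contributions(numeric(w$params$dim), fp,
                                      threshold = 0)
  expect_equal(nrow(sp0$absent), 0)
})

test_that("atom aggregation follows the per-fragment sum rule", {
  # hand-built fingerprint: f1 covers atoms {1,2} (w 0.2), f2 covers {2,3} (w -0.1)
  fp <- structure(list(
    bits = c(1L, 1L, rep(0L, 6)), on_bits = c(0L, 1L),
    bit_to_fragments = list(`0` = "f1", `1` = "f2"),
    fragment_to_occurrences = list(
      f1 = list(list(smiles = "f1", molecule_index = 1L, side = "reactant",
                     atom_indices = c(1L, 2L))),
      f2 = list(list(smiles = "f2", molecule_index = 1L, side = "reactant",
                     atom_indices = c(2L, 3L)))),
    molecules = data.frame(molecule_index = 1L, side = "reactant", n_atoms = 4L),
    params = fp_params(dim = 8), reaction_smiles = "synthetic"),
    class = "ecx_fp")
  present <- data.frame(smiles = c("f1", "f2"), bit = c(0L, 1L),
                        weight = c(0.2, -0.1), collisions = 1L)
  aw <- atom_contributions(present, fp)
  expect_equal(aw$weight[match(1:3, aw$atom)], c(0.2, 0.1, -0.1))
  expect_false(4L %in% aw$atom)  # uncovered atom weighs 0 (absent row)

  # single fragment
  aw1 <- atom_contributions(present[1, ], fp)
  expect_equal(aw1$weight, rep(0.2, 2))
  expect_equal(aw1$atom, c(1L, 2L))

  # no present fragments
  aw0 <- atom_contributions(present[0, ], fp)
  expect_equal(nrow(aw0), 0)

  # out-of-range occurrence is an integrity error
  bad <- fp
  bad$fragment_to_occurrences$f1[[1]]$atom_indices <- c(1L, 9L)
  expect_error(atom_contributions(present, bad), "out-of-range")

  # randomized configurations against a brute-force double loop
  set.seed(12)
  for (rep in 1:20) {
    nfrag <- sample(2:6, 1); natom <- sample(4:9, 1)
    frs <- paste0("g", seq_len(nfrag))
    sets <- lapply(seq_len(nfrag), function(i) sort(sample(natom, sample(1:3, 1))))
    wts <- round(stats::rnorm(nfrag), 3)
    fpr <- structure(list(
      bits = NULL, on_bits = seq_len(nfrag) - 1L,
      bit_to_fragments = stats::setNames(as.list(frs), seq_len(nfrag) - 1L),
      fragment_to_occurrences = stats::setNames(lapply(seq_len(nfrag), function(i) {
        list(list(smiles = frs[i], molecule_index = 1L, side = "product",
                  atom_indices = sets[[i]]))
      }), frs),
      molecules = data.frame(molecule_index = 1L, side = "product",
                             n_atoms = natom),
      params = fp_params(dim = 64), reaction_smiles = "synthetic"),
      class = "ecx_fp")
    pres <- data.frame(smiles = frs, bit = seq_len(nfrag) - 1L, weight = wts,
                       collisions = 1L)
    aw <- atom_contributions(pres, fpr)
    brute <- numeric(natom)
    for (i in seq_len(nfrag)) for (a in sets[[i]]) brute[a] <- brute[a] + wts[i]
    got <- numeric(natom)
    got[aw$atom] <- aw$weight
    expect_equal(got, brute)
    # total identity: sum_a w_a == sum_f w_f * |atoms(f)|
    expect_equal(sum(got), sum(wts * lengths(sets)))
  }
})

test_that("attribution is label-sensitive and faithful on the fixture model", {
  w <- fixture_world()
  fp <- w$corpus$fingerprints[[2]]  # class 1
  c1 <- deepshap_contributions(w$model, fp$bits, w$background, 1)$feature_contributions
  c2 <- deepshap_contributions(w$model, fp$bits, w$background, 2)$feature_contributions
  dbit <- w$diag[[1]]$bits + 1L
  # the diagnostic bits push towards class 1 and against class 2
  expect_true(all(c1[dbit] > 0))
  expect_true(all(c2[dbit] < 0))

  # zeroing the most positive present bit lowers the explained class's score
  sp <- split_fragment_contributions(c1, fp)
  top_bit <- sp$present$bit[which.max(sp$present$weight)]
  x2 <- fp$bits; x2[top_bit + 1L] <- 0L
  expect_lt(mlp_scores(w$model, x2)[1, 1], mlp_scores(w$model, fp$bits)[1, 1])
})

test_that("explanations serialise to the documented JSON contract", {
  w <- fixture_world()
  ex <- explain_reaction(w$model, w$records[[17]], w$background,
                         corpus = w$corpus, top = 2)
  js <- explanation_to_json(ex)
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_identical(parsed$reaction_smiles, w$records[[17]]$reaction_smiles)
  expect_length(parsed$explanations, 2)
  e1 <- parsed$explanations[[1]]
  expect_true(all(c("label", "rank", "probability", "expected_value",
                    "present", "absent", "atoms") %in% names(e1)))
  expect_identical(e1$label, "2")
})
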