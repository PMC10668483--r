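# Shared fixtures and independent oracles.
#
# The fixture world (corpus, trained model, background) is built once per
# test run and memoised; everything is scaled down from the paper-scale
# defaults (dim 2048 instead of 10240, hidden 64 instead of 1664, batch 2
# instead of 256) so the whole suite stays CPU-cheap while exercising the
# same code paths.

.test_cache <- new.env(parent = emptyenv())

test_fp_params <- function(dim = 2048L) fp_params(dim = dim)

test_train_config <- function(seed = 11L) {
  train_config(hidden_size = 64L, batch_size = 2L, seed = seed)
}

# fixture corpus + encoded matrix + a model trained on all 30 reactions
fixture_world <- function() {
  if (!is.null(.test_cache$world)) return(.test_cache$world)
  pp <- test_fp_params()
  recs <- generate_fixture_corpus(fixture_config(seed = 42L), pp)
  corpus <- encode_corpus(recs, pp)
  y1 <- vapply(recs, function(r) truncate_ec(r$ec, 1), "")
  y3 <- vapply(recs, function(r) truncate_ec(r$ec, 3), "")
  model <- train_mlp(corpus$matrix, y1, config = test_train_config(), fp_params = pp)
  model3 <- train_mlp(corpus$matrix, y3, config = test_train_config(), fp_params = pp)
  bg <- background_set(corpus, 100L, seed = 3L)
  .test_cache$world <- list(params = pp, records = recs, corpus = corpus,
                            y1 = y1, y3 = y3, model = model, model3 = model3,
                            background = bg,
                            diag = diagnostic_bits(fixture_config(seed = 42L), pp))
  .test_cache$world
}

# random small ReLU net with the ec_model layout
rand_relu_net <- function(d, h, C, seed) {
  set.seed(seed)
  structure(list(layer_dims = c(d, h, C),
                 W1 = matrix(stats::rnorm(d * h), d, h), b1 = stats::rnorm(h),
                 W2 = matrix(stats::rnorm(h * C), h, C), b2 = stats::rnorm(C),
                 activation = "relu", vocab = as.character(seq_len(C)),
                 fp_params = NULL, config = NULL,
                 history = data.frame()),
            class = "ec_model")
}

# random acyclic molecule with valence-respecting single bonds
random_mol <- function(n_heavy = 6L) {
  budget <- c(C = 4L, N = 3L, O = 2L)
  elems <- sample(names(budget), n_heavy, replace = TRUE, prob = c(0.6, 0.2, 0.2))
  left <- budget[elems]
  atoms <- data.frame(element = elems, aromatic = FALSE, charge = 0L,
                      nH = 0L, isotope = 0L, bracket = FALSE,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0))
  for (i in seq_len(n_heavy)[-1]) {
    parents <- which(seq_len(n_heavy) < i & left > 0)
    if (length(parents) == 0) parents <- 1L  # force connectivity; H count clamps
    p <- if (length(parents) == 1) parents else sample(parents, 1)
    bonds <- rbind(bonds, data.frame(a1 = p, a2 = i, order = 1))
    left[p] <- left[p] - 1L
    left[i] <- left[i] - 1L
  }
  mol <- ecxplain:::.new_mol(atoms, bonds)
  for (a in seq_len(n_heavy)) {
    ords <- bonds$order[bonds$a1 == a | bonds$a2 == a]
    mol$atoms$nH[a] <- ecxplain:::.implicit_h(elems[a], FALSE, ords)
  }
  mol
}

# a SMILES of mol written under a random atom ordering
random_writing <- function(mol) {
  ecxplain:::write_smiles(mol, ranks = sample(nrow(mol$atoms)))
}

# independent brute-force circular-environment enumerator: igraph distances
# + its own induced-subgraph builder (shares only the canonical writer)
oracle_shingles <- function(mol, radius, explicit_h) {
  n <- nrow(mol$atoms)
  g <- igraph::make_graph(t(cbind(mol$bonds$a1, mol$bonds$a2)), n = n,
                          directed = FALSE)
  D <- igraph::distances(g)
  out <- character(0)
  for (a in seq_len(n)) {
    for (r in 0:radius) {
      keep <- which(is.finite(D[a, ]) & D[a, ] <= r)
      sel <- mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep
      sub <- ecxplain:::.new_mol(
        mol$atoms[keep, , drop = FALSE],
        data.frame(a1 = match(mol$bonds$a1[sel], keep),
                   a2 = match(mol$bonds$a2[sel], keep),
                   order = mol$bonds$order[sel]))
      out <- c(out, canonical_smiles(sub, explicit_h = explicit_h))
    }
  }
  sort(unique(out))
}

# oracle on-bit count for a reaction SMILES: brute-force shingles of each
# side, symmetric difference, hash and fold
oracle_on_bits <- function(reaction_smiles, params) {
  rx <- parse_reaction_smiles(reaction_smiles)
  side_set <- function(mols) {
    sort(unique(unlist(lapply(mols, oracle_shingles, radius = params$radius,
                              explicit_h = params$include_hydrogens))))
  }
  l <- side_set(c(rx$reactants, rx$agents))
  r <- side_set(rx$products)
  sd <- union(setdiff(l, r), setdiff(r, l))
  if (length(sd) == 0) return(integer(0))
  sort(unique(fold_hash(hash32(sd), params$dim)))
}

fixture_labels <- function(records, level) {
  vapply(records, function(r) truncate_ec(r$ec, level), "")
}
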