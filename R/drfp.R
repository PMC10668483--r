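# Fragment-mapped differential reaction fingerprint.
#
# The reaction is encoded as the symmetric difference between the circular
# substructure (shingle) SMILES sets of the reactant and product sides, each
# surviving fragment hashed (CRC-32) and folded (mod dim) into a binary
# vector. Unlike a plain fingerprint, the encoding keeps, per bit, the
# fragment SMILES it represents and, per fragment, every occurrence (parent
# molecule + atom indices), which is what lets attributions flow back from
# input features to atoms.

#' Fingerprint parameters
#'
#' Defaults are the explainability-oriented settings: 10,240 bits (to keep
#' folding collisions rare) and radius 2, explicit hydrogens in fragment
#' SMILES, one non-rooted canonical SMILES per fragment.
#'
#' @param dim folded fingerprint length.
#' @param radius maximum circular-substructure radius in bonds.
#' @param include_hydrogens spell out hydrogens in fragment SMILES.
#' @param root_central_atom emit one SMILES rooted at each occurrence's
#'   central atom instead of a single canonical SMILES per fragment
#'   (the legacy, collision-heavier behaviour).
#' @param include_rings also emit whole-ring shingles from a fundamental
#'   cycle basis (off by default; approximation of the upstream ring
#'   inventory, see the methods vignette).
#' @return a `fp_params` list.
#' @export
fp_params <- function(dim = 10240L, radius = 2L, include_hydrogens = TRUE,
                      root_central_atom = FALSE, include_rings = FALSE) {
  stopifnot(dim >= 1, radius >= 0)
  structure(list(dim = as.integer(dim), radius = as.integer(radius),
                 include_hydrogens = isTRUE(include_hydrogens),
                 root_central_atom = isTRUE(root_central_atom),
                 include_rings = isTRUE(include_rings)),
            class = "fp_params")
}

# breadth-first bond-distance vector from atom a (own implementation; tests
# cross-check against igraph::distances)
.bfs_dist <- function(adj, n, a) {
  d <- rep(NA_integer_, n)
  d[a] <- 0L
  frontier <- a
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; nxt <- c(nxt, w) }
    }
    frontier <- nxt
  }
  d
}

.submol <- function(mol, atom_ids) {
  keep <- sort(atom_ids)
  map <- match(seq_len(nrow(mol$atoms)), keep)
  bsel <- mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep
  bonds <- mol$bonds[bsel, , drop = FALSE]
  bonds$a1 <- map[bonds$a1]
  bonds$a2 <- map[bonds$a2]
  .new_mol(mol$atoms[keep, , drop = FALSE], bonds)
}

# fundamental cycle basis rings (flagged shingle variant)
.ring_atom_sets <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- nrow(mol$bonds)
  if (nb < n) return(list())
  g <- igraph::make_graph(t(cbind(mol$bonds$a1, mol$bonds$a2)), n = n, directed = FALSE)
  out <- list()
  for (b in seq_len(nb)) {
    g2 <- igraph::delete_edges(g, b)
    sp <- suppressWarnings(igraph::shortest_paths(g2, mol$bonds$a1[b], mol$bonds$a2[b])$vpath[[1]])
    if (length(sp) > 0) {
      ring <- sort(as.integer(sp))
      key <- paste(ring, collapse = ",")
      out[[key]] <- ring
    }
  }
  unname(out)
}

#' Extract circular substructures of a molecule
#'
#' For every atom, the environment at each radius `0..params$radius` (the
#' induced subgraph on atoms within that bond distance) is serialised as one
#' canonical fragment SMILES. Environments that stop growing are emitted
#' once.
#'
#' @param mol an `ecx_mol`.
#' @param params [fp_params()].
#' @return a list of occurrences, each `list(smiles, atom_indices, radius,
#'   center)`; `atom_indices` index into `mol$atoms`.
#' @export
extract_shingles <- function(mol, params = fp_params()) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
    adj[[a1]] <- c(adj[[a1]], a2)
    adj[[a2]] <- c(adj[[a2]], a1)
  }
  occ <- list()
  seen <- character(0)
  add_occ <- function(ids, frag_mol, center) {
    root <- if (params$root_central_atom && !is.null(center)) match(center, sort(ids)) else NULL
    if (params$include_hydrogens) {
      m <- add_explicit_hydrogens(frag_mol)
      smi <- write_smiles(m, canonical_ranks(m), root = root)
    } else {
      m <- .strip_h_info(frag_mol)
      smi <- write_smiles(m, canonical_ranks(m), root = root, h_agnostic = TRUE)
    }
    key <- paste0(smi, "|", paste(sort(ids), collapse = ","))
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    occ[[length(occ) + 1L]] <<- list(smiles = smi, atom_indices = sort(ids),
                                     radius = NA_integer_, center = center)
  }
  for (a in seq_len(n)) {
    d <- .bfs_dist(adj, n, a)
    prev_size <- 0L
    for (r in 0:params$radius) {
      ids <- which(!is.na(d) & d <= r)
      if (r > 0L && length(ids) == prev_size) break
      prev_size <- length(ids)
      add_occ(ids, .submol(mol, ids), a)
    }
  }
  if (params$include_rings) {
    for (ring in .ring_atom_sets(mol)) add_occ(ring, .submol(mol, ring), NULL)
  }
  occ
}

.zero_fp <- function(params, molecules, reaction_smiles) {
  structure(list(
    bits = integer(params$dim), on_bits = integer(0),
    bit_to_fragments = list(), fragment_to_occurrences = list(),
    molecules = molecules, params = params, reaction_smiles = reaction_smiles
  ), class = "ecx_fp")
}

#' Encode a reaction as a mapped differential fingerprint
#'
#' Shingle SMILES sets are built for the reactant side (agents merged in) and
#' the product side; the symmetric difference is hashed with [hash32()] and
#' folded modulo `params$dim`. The result keeps the bit→fragment and
#' fragment→atom maps needed for explanation.
#'
#' @param reaction a reaction SMILES string, a `reaction_record`, or a parsed
#'   `ecx_reaction`.
#' @param params [fp_params()].
#' @return an `ecx_fp` with fields `bits` (0/1 integer vector), `on_bits`
#'   (0-based indices), `bit_to_fragments` (named by bit index),
#'   `fragment_to_occurrences`, `molecules` (per-molecule table) and `params`.
#' @export
encode_reaction <- function(reaction, params = fp_params()) {
  rx <- if (inherits(reaction, "ecx_reaction")) reaction else
    if (inherits(reaction, "reaction_record")) parse_reaction_smiles(reaction$reaction_smiles) else
      parse_reaction_smiles(reaction)
  mols <- c(rx$reactants, rx$agents, rx$products)
  sides <- c(rep("reactant", length(rx$reactants) + length(rx$agents)),
             rep("product", length(rx$products)))
  molecules <- data.frame(
    molecule_index = seq_along(mols), side = sides,
    n_atoms = vapply(mols, function(m) nrow(m$atoms), 0L),
    stringsAsFactors = FALSE)

  occs <- list(); occ_side <- character(0)
  for (mi in seq_along(mols)) {
    so <- extract_shingles(mols[[mi]], params)
    for (o in so) {
      o$molecule_index <- mi
      o$side <- sides[mi]
      occs[[length(occs) + 1L]] <- o
      occ_side <- c(occ_side, sides[mi])
    }
  }
  smi_all <- vapply(occs, `[[`, "", "smiles")
  left <- unique(smi_all[occ_side == "reactant"])
  right <- unique(smi_all[occ_side == "product"])
  sd <- union(setdiff(left, right), setdiff(right, left))
  if (length(sd) == 0) return(.zero_fp(params, molecules, rx$smiles))

  bit <- fold_hash(hash32(sd), params$dim)
  bit_to_fragments <- split(sd, bit)   # names are 0-based bit indices
  frag_occ <- split(occs[smi_all %in% sd], smi_all[smi_all %in% sd])
  bits <- integer(params$dim)
  bits[unique(bit) + 1L] <- 1L
  structure(list(
    bits = bits, on_bits = sort(unique(bit)),
    bit_to_fragments = bit_to_fragments,
    fragment_to_occurrences = frag_occ,
    molecules = molecules, params = params, reaction_smiles = rx$smiles
  ), class = "ecx_fp")
}

#' @export
print.ecx_fp <- function(x, ...) {
  cat(sprintf("<reaction fingerprint: dim %d, %d bits on, %d fragments>\n",
              x$params$dim, length(x$on_bits), length(x$fragment_to_occurrences)))
  invisible(x)
}

#' Encode a corpus of reaction records
#'
#' @param records list of `reaction_record`s (see [load_reaction_dataset()]
#'   or [generate_fixture_corpus()]).
#' @param params [fp_params()].
#' @return an `ecx_corpus`: binary `matrix` (reactions x dim), per-reaction
#'   `fingerprints`, the corpus-wide `global_bit_to_fragments` map, `records`,
#'   and a `rejects` data frame for records that failed to encode.
#' @export
encode_corpus <- function(records, params = fp_params()) {
  if (length(records) == 0) stop_input("encode_corpus() needs at least one record")
  fps <- vector("list", length(records))
  ok <- logical(length(records))
  rej <- list()
  for (i in seq_along(records)) {
    fp <- tryCatch(encode_reaction(records[[i]], params), error = function(e) e)
    if (inherits(fp, "error")) {
      rej[[length(rej) + 1L]] <- data.frame(index = i, reason = conditionMessage(fp))
      warning(sprintf("record %d rejected: %s", i, conditionMessage(fp)), call. = FALSE)
    } else {
      fps[[i]] <- fp
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) stop_input("no record could be encoded")
  fps <- fps[ok]
  mat <- do.call(rbind, lapply(fps, `[[`, "bits"))
  global <- list()
  for (fp in fps) {
    for (b in names(fp$bit_to_fragments)) {
      global[[b]] <- union(global[[b]], fp$bit_to_fragments[[b]])
    }
  }
  structure(list(
    matrix = mat, fingerprints = fps,
    global_bit_to_fragments = global,
    records = records[ok], params = params,
    rejects = if (length(rej)) do.call(rbind, rej) else
      data.frame(index = integer(0), reason = character(0))
  ), class = "ecx_corpus")
}

#' @export
print.ecx_corpus <- function(x, ...) {
  cat(sprintf("<reaction corpus: %d reactions, dim %d, %d distinct fragments>\n",
              nrow(x$matrix), x$params$dim,
              length(unique(unlist(x$global_bit_to_fragments, use.names = FALSE)))))
  invisible(x)
}

#' Exact nearest-neighbour search over a fingerprint corpus
#'
#' Jaccard (Tanimoto) similarity over on-bit sets, descending; ties broken by
#' record index. The 0/0 case (both query and row empty) is defined as 0.
#'
#' @param index an `ecx_corpus`.
#' @param query an `ecx_fp` or a 0/1 vector of matching length.
#' @param k number of neighbours.
#' @return data frame with `record`, `similarity`.
#' @export
nearest_neighbors <- function(index, query, k = 10L) {
  stopifnot(inherits(index, "ecx_corpus"), k >= 1)
  q <- if (inherits(query, "ecx_fp")) query$bits else as.integer(query)
  if (length(q) != ncol(index$matrix)) {
    stop_input("query fingerprint dimension does not match the index")
  }
  inter <- drop(index$matrix %*% q)
  uni <- rowSums(index$matrix) + sum(q) - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  ord <- order(-sim, seq_along(sim))
  top <- ord[seq_len(min(k, length(ord)))]
  data.frame(record = top, similarity = sim[top])
}
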