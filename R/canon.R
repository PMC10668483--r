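# Canonical SMILES writing.
#
# Canonical atom ranks come from the BLISS canonical form (igraph). Bond
# orders are encoded by subdividing every bond with a coloured auxiliary
# vertex, since BLISS colours vertices only. Two atom orderings of the same
# molecule therefore always serialise to the same string, which is what makes
# "one SMILES per fragment" (and hence stable fingerprint bits) possible.

.atom_color_code <- function(atoms) {
  idx <- match(atoms$element, .ELEMENTS)
  if (anyNA(idx)) stop_input("atom with element outside the supported table")
  (((atoms$isotope * 100L + idx) * 2L + as.integer(atoms$aromatic)) * 40L +
     (atoms$charge + 16L)) * 10L + pmin(atoms$nH, 9L)
}

# canonical rank (1 = first emitted) of every atom
canonical_ranks <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 1) return(1L)
  nb <- nrow(mol$bonds)
  # subdivided graph: atoms 1..n, bond-vertices n+1..n+nb
  edges <- rbind(
    cbind(mol$bonds$a1, n + seq_len(nb)),
    cbind(mol$bonds$a2, n + seq_len(nb))
  )
  g <- igraph::make_graph(t(edges), n = n + nb, directed = FALSE)
  colors <- c(.atom_color_code(mol$atoms),
              100000000L + as.integer(mol$bonds$order * 10))
  lab <- igraph::canonical_permutation(g, colors = colors)$labeling
  rank(lab[seq_len(n)])
}

.bond_symbol <- function(order, arom1, arom2) {
  if (order == 1) return("")
  if (order == 2) return("=")
  if (order == 3) return("#")
  if (order == 4) return("$")
  if (order == 1.5) return(if (arom1 && arom2) "" else ":")
  stop_input("unsupported bond order ", order)
}

.atom_token <- function(mol, a, orders_at, h_agnostic = FALSE) {
  at <- mol$atoms[a, ]
  elem <- at$element
  sym <- if (at$aromatic) tolower(elem) else elem
  bare_ok <- at$charge == 0L && at$isotope == 0L && elem != "H" &&
    (elem %in% .ORGANIC_SUBSET || elem == "*") &&
    ((h_agnostic && at$nH == 0L) ||
       at$nH == .implicit_h(elem, at$aromatic, orders_at))
  if (bare_ok) return(sym)
  h <- if (at$nH == 0L) "" else if (at$nH == 1L) "H" else paste0("H", at$nH)
  chg <- if (at$charge == 0L) "" else if (at$charge == 1L) "+" else
    if (at$charge == -1L) "-" else sprintf("%+d", at$charge)
  iso <- if (at$isotope == 0L) "" else as.character(at$isotope)
  paste0("[", iso, sym, h, chg, "]")
}

# serialise a molecule following the given atom ranks; `root` optionally
# forces the start atom of its component (used by the rooted-SMILES flag).
write_smiles <- function(mol, ranks = NULL, root = NULL, h_agnostic = FALSE) {
  n <- nrow(mol$atoms)
  if (is.null(ranks)) ranks <- canonical_ranks(mol)
  stopifnot(length(ranks) == n)
  bonds <- mol$bonds
  nb <- nrow(bonds)
  adj <- vector("list", n)
  if (nb) {
    for (b in seq_len(nb)) {
      adj[[bonds$a1[b]]] <- rbind(adj[[bonds$a1[b]]], c(bonds$a2[b], b))
      adj[[bonds$a2[b]]] <- rbind(adj[[bonds$a2[b]]], c(bonds$a1[b], b))
    }
    for (a in seq_len(n)) {
      if (!is.null(adj[[a]])) adj[[a]] <- adj[[a]][order(ranks[adj[[a]][, 1]]), , drop = FALSE]
    }
  }
  visited <- rep(FALSE, n)
  edge_used <- rep(FALSE, nb)
  tree_children <- vector("list", n)   # per atom: matrix (child, bond)
  ring_digit <- rep(NA_integer_, nb)
  n_rings <- 0L

  classify <- function(a) {
    visited[a] <<- TRUE
    nbrs <- adj[[a]]
    if (is.null(nbrs)) return(invisible())
    for (r in seq_len(nrow(nbrs))) {
      nb_a <- nbrs[r, 1]; bid <- nbrs[r, 2]
      if (edge_used[bid]) next
      edge_used[bid] <<- TRUE
      if (!visited[nb_a]) {
        tree_children[[a]] <<- rbind(tree_children[[a]], c(nb_a, bid))
        classify(nb_a)
      } else {
        n_rings <<- n_rings + 1L
        if (n_rings > 99L) stop_input("more than 99 ring closures")
        ring_digit[bid] <<- n_rings
      }
    }
  }

  digit_tok <- function(d) if (d < 10L) as.character(d) else paste0("%", sprintf("%02d", d))

  emit <- function(a) {
    ords <- if (is.null(adj[[a]])) numeric(0) else bonds$order[adj[[a]][, 2]]
    out <- .atom_token(mol, a, ords, h_agnostic = h_agnostic)
    # ring-closure digits on this atom, in digit order
    if (nb) {
      inc <- which((bonds$a1 == a | bonds$a2 == a) & !is.na(ring_digit))
      if (length(inc)) {
        inc <- inc[order(ring_digit[inc])]
        for (bid in inc) {
          other <- if (bonds$a1[bid] == a) bonds$a2[bid] else bonds$a1[bid]
          sym <- .bond_symbol(bonds$order[bid], mol$atoms$aromatic[a], mol$atoms$aromatic[other])
          out <- paste0(out, sym, digit_tok(ring_digit[bid]))
        }
      }
    }
    ch <- tree_children[[a]]
    if (!is.null(ch)) {
      for (r in seq_len(nrow(ch))) {
        c_a <- ch[r, 1]; bid <- ch[r, 2]
        sym <- .bond_symbol(bonds$order[bid], mol$atoms$aromatic[a], mol$atoms$aromatic[c_a])
        sub <- paste0(sym, emit(c_a))
        out <- paste0(out, if (r < nrow(ch)) paste0("(", sub, ")") else sub)
      }
    }
    out
  }

  comps <- character(0)
  repeat {
    todo <- which(!visited)
    if (!length(todo)) break
    start <- if (!is.null(root) && !visited[root]) root else todo[which.min(ranks[todo])]
    classify(start)
    comps <- c(comps, emit(start))
  }
  paste(comps, collapse = ".")
}

#' Canonical SMILES of a molecular graph
#'
#' One unique string per molecule regardless of input atom order, via the
#' BLISS canonical form. With `explicit_h = TRUE`, implicit hydrogens are
#' materialised as `[H]` atoms (so dimethyl ether serialises with its six
#' hydrogens spelled out rather than as `COC`); otherwise hydrogen counts are
#' dropped from neutral organic-subset atoms (skeleton SMILES, the usual
#' fragment convention), while bracket atoms such as `[NH4+]` keep theirs.
#'
#' @param mol an `ecx_mol`.
#' @param explicit_h materialise hydrogens as explicit `[H]` atoms.
#' @return a single SMILES string.
#' @export
canonical_smiles <- function(mol, explicit_h = FALSE) {
  if (explicit_h) {
    m <- add_explicit_hydrogens(mol)
    return(write_smiles(m, canonical_ranks(m)))
  }
  m <- .strip_h_info(mol)
  write_smiles(m, canonical_ranks(m), h_agnostic = TRUE)
}

# drop hydrogen counts from atoms that will print bare, so the canonical
# colours match exactly the information the serialisation keeps; aromatic
# heteroatoms keep their hydrogens (the [nH] convention), aromatic carbons
# and aliphatic organic-subset atoms do not
.strip_h_info <- function(mol) {
  eligible <- mol$atoms$charge == 0L & mol$atoms$isotope == 0L &
    mol$atoms$element %in% .ORGANIC_SUBSET &
    (!mol$atoms$aromatic | mol$atoms$element == "C")
  mol$atoms$nH[eligible] <- 0L
  mol
}
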