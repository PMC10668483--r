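# Minimal SMILES molecular-graph toolkit.
#
# No cheminformatics toolkit ships with this R environment, and the mapped
# fingerprint needs full control over fragment extraction and atom provenance,
# so the package carries its own small SMILES layer. It supports the organic
# subset, bracket atoms (isotope, charge, explicit H count), aromatic
# lowercase atoms, branches, ring closures (incl. %nn) and bond symbols.
# Stereo tokens (@, @@, /, \) are accepted and dropped from the graph; the
# verbatim input string is what reaction records store, so stereochemistry is
# preserved at the record level even though fragments are achiral.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s", "se", "as")

# fixed element table; index feeds the canonical-colour code, so order is part
# of the on-disk fingerprint definition and must not change.
.ELEMENTS <- c(
  "*", "H", "B", "C", "N", "O", "F", "Na", "Mg", "Si", "P", "S", "Cl", "K",
  "Ca", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "As", "Se", "Br", "Mo", "I", "W",
  "Li", "Al", "Cr", "V", "Ti", "Sn", "Sb", "Te", "Ba", "Hg", "Pb", "Bi"
)

.VALENCE <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

.BOND_ORDER <- c("-" = 1, "=" = 2, "#" = 3, "$" = 4, ":" = 1.5, "/" = 1, "\\" = 1)

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("ecx_input_error", "error")))
}

.new_mol <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "ecx_mol")
}

#' @export
print.ecx_mol <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms, %d bonds>\n", nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

# implicit hydrogen count a SMILES reader assigns to a bare organic-subset
# atom given the orders of its explicit bonds (aromatic bonds count 1, with
# one valence consumed by the aromatic system).
.implicit_h <- function(element, aromatic, orders) {
  v <- .VALENCE[[element]]
  if (is.null(v)) return(0L)
  if (aromatic) {
    s <- sum(ifelse(orders > 1 & orders < 2, 1, orders))
    return(max(0L, as.integer(min(v) - s - 1L)))
  }
  s <- sum(orders)
  for (vv in v) if (vv + 1e-9 >= s) return(as.integer(round(vv - s)))
  0L
}

.BRACKET_RE <- paste0(
  "^\\[([0-9]+)?",                                  # isotope
  "([A-Z][a-z]?|[a-z]{1,2}|\\*)",                   # element (lowercase = aromatic)
  "(@@|@(?:TH[12]|AL[12])?)?",                      # chirality (dropped)
  "(H[0-9]*)?",                                     # explicit hydrogen count
  "(\\+{1,3}|-{1,3}|[+-][0-9]+)?",                  # charge
  "(:[0-9]+)?\\]"                                   # atom map (dropped)
)

.parse_charge <- function(tok) {
  if (is.na(tok) || !nzchar(tok)) return(0L)
  if (grepl("^[+-][0-9]+$", tok)) {
    sgn <- if (substr(tok, 1, 1) == "+") 1L else -1L
    return(sgn * as.integer(substring(tok, 2)))
  }
  if (grepl("^\\++$", tok)) return(nchar(tok))
  -nchar(tok)
}

#' Parse a molecule SMILES string
#'
#' Builds the molecular graph used by fingerprinting and depiction. Implicit
#' hydrogen counts are computed from standard valences for bare
#' organic-subset atoms; bracket atoms carry the hydrogen count they declare.
#'
#' @param s a single SMILES string for one molecule (no `.` components).
#' @return an `ecx_mol`: a list with `atoms` (element, aromatic, charge, nH,
#'   isotope, bracket) and `bonds` (a1, a2, order; aromatic bonds have order
#'   1.5) data frames.
#' @export
parse_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s)) {
    stop_input("parse_smiles() expects one non-empty SMILES string")
  }
  bad <- function(what, at) {
    stop_input(sprintf("invalid SMILES '%s': %s at position %d", s, what, at))
  }
  n <- nchar(s)
  element <- character(); aromatic <- logical(); charge <- integer()
  nH <- integer(); isotope <- integer(); bracket <- logical()
  b_a1 <- integer(); b_a2 <- integer(); b_ord <- numeric()
  stack <- integer(0)
  prev <- 0L
  pend <- NA_real_
  rings <- list()
  i <- 1L

  new_atom <- function(elem, arom, chg, h, iso, brk, pos) {
    if (!arom && !(elem %in% .ELEMENTS)) bad(sprintf("unsupported element '%s'", elem), pos)
    if (arom && !(elem %in% .AROMATIC_OK)) bad(sprintf("'%s' cannot be aromatic", elem), pos)
    element[length(element) + 1L] <<- if (arom) {
      paste0(toupper(substr(elem, 1, 1)), substring(elem, 2))
    } else elem
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    nH[length(nH) + 1L] <<- h
    isotope[length(isotope) + 1L] <<- iso
    bracket[length(bracket) + 1L] <<- brk
    a <- length(element)
    if (prev > 0L) {
      b_a1[length(b_a1) + 1L] <<- prev
      b_a2[length(b_a2) + 1L] <<- a
      b_ord[length(b_ord) + 1L] <<- pend  # NA resolved later
    }
    prev <<- a
    pend <<- NA_real_
    invisible(a)
  }

  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      m <- regexec(.BRACKET_RE, substring(s, i))[[1]]
      if (m[1] == -1) bad("malformed bracket atom", i)
      g <- regmatches(substring(s, i), regexec(.BRACKET_RE, substring(s, i)))[[1]]
      iso <- if (nzchar(g[2])) as.integer(g[2]) else 0L
      elem <- g[3]
      arom <- elem == tolower(elem) && elem != "*"
      htok <- g[5]
      h <- if (!nzchar(htok)) 0L else if (htok == "H") 1L else as.integer(substring(htok, 2))
      chg <- .parse_charge(g[6])
      new_atom(elem, arom, chg, h, iso, TRUE, i)
      i <- i + attr(m, "match.length")[1]
    } else if (ch %in% c("(", ")")) {
      if (ch == "(") {
        if (prev == 0L) bad("branch before any atom", i)
        stack <- c(stack, prev)
      } else {
        if (length(stack) == 0) bad("unmatched ')'", i)
        prev <- stack[length(stack)]
        stack <- stack[-length(stack)]
      }
      i <- i + 1L
    } else if (ch %in% names(.BOND_ORDER)) {
      pend <- .BOND_ORDER[[ch]]
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (prev == 0L) bad("ring closure before any atom", i)
      if (ch == "%") {
        lab <- substr(s, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", lab)) bad("malformed %nn ring closure", i)
        i <- i + 3L
      } else {
        lab <- ch
        i <- i + 1L
      }
      if (is.null(rings[[lab]])) {
        rings[[lab]] <- list(atom = prev, order = pend)
      } else {
        op <- rings[[lab]]
        ord <- if (!is.na(pend)) pend else op$order
        if (!is.na(pend) && !is.na(op$order) && pend != op$order) {
          bad(sprintf("conflicting bond orders on ring closure %s", lab), i)
        }
        if (is.na(ord)) ord <- if (aromatic[op$atom] && aromatic[prev]) 1.5 else 1
        if (op$atom == prev) bad("ring closure to self", i)
        b_a1 <- c(b_a1, op$atom); b_a2 <- c(b_a2, prev); b_ord <- c(b_ord, ord)
        rings[[lab]] <- NULL
      }
      pend <- NA_real_
    } else if (ch == "*") {
      new_atom("*", FALSE, 0L, 0L, 0L, FALSE, i)
      i <- i + 1L
    } else if (grepl("[A-Z]", ch)) {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        new_atom(two, FALSE, 0L, 0L, 0L, FALSE, i)
        i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        new_atom(ch, FALSE, 0L, 0L, 0L, FALSE, i)
        i <- i + 1L
      } else bad(sprintf("unexpected atom token '%s' (use brackets)", ch), i)
    } else if (grepl("[a-z]", ch)) {
      if (!(ch %in% c("b", "c", "n", "o", "p", "s"))) bad(sprintf("unexpected token '%s'", ch), i)
      new_atom(ch, TRUE, 0L, 0L, 0L, FALSE, i)
      i <- i + 1L
    } else if (ch == ".") {
      bad("'.' component separator inside a single molecule", i)
    } else {
      bad(sprintf("unexpected character '%s'", ch), i)
    }
  }
  if (length(element) == 0) stop_input(sprintf("invalid SMILES '%s': no atoms", s))
  if (length(stack) != 0) stop_input(sprintf("invalid SMILES '%s': unclosed branch", s))
  if (length(rings) != 0) {
    stop_input(sprintf("invalid SMILES '%s': unmatched ring closure(s) %s",
                       s, paste(names(rings), collapse = ", ")))
  }
  # resolve default bond orders
  if (length(b_ord)) {
    na <- is.na(b_ord)
    b_ord[na] <- ifelse(aromatic[b_a1[na]] & aromatic[b_a2[na]], 1.5, 1)
  }
  atoms <- data.frame(element = element, aromatic = aromatic, charge = charge,
                      nH = nH, isotope = isotope, bracket = bracket,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = b_ord)
  # implicit hydrogens for bare atoms
  for (a in which(!atoms$bracket)) {
    ords <- bonds$order[bonds$a1 == a | bonds$a2 == a]
    atoms$nH[a] <- .implicit_h(atoms$element[a], atoms$aromatic[a], ords)
  }
  .new_mol(atoms, bonds)
}

# append nH explicit hydrogen atoms to every heavy atom (used when fragments
# are serialised with include_hydrogens)
add_explicit_hydrogens <- function(mol) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  heavy <- which(atoms$nH > 0L)
  for (a in heavy) {
    for (k in seq_len(atoms$nH[a])) {
      atoms <- rbind(atoms, data.frame(
        element = "H", aromatic = FALSE, charge = 0L, nH = 0L,
        isotope = 0L, bracket = TRUE, stringsAsFactors = FALSE))
      bonds <- rbind(bonds, data.frame(a1 = a, a2 = nrow(atoms), order = 1))
    }
  }
  atoms$nH[heavy] <- 0L
  .new_mol(atoms, bonds)
}
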