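# Reaction and EC-label I/O, dataset dialects, CV folds, fixture corpus.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# expand one master seed into named sub-seeds (all < 2^31)
derive_seeds <- function(master, what) {
  with_seed(master, function() {
    s <- sample.int(.Machine$integer.max - 1L, length(what))
    names(s) <- what
    s
  })
}

#' Parse a reaction SMILES
#'
#' Splits `reactants>agents>products` and parses every molecule. The agents
#' field may be empty; downstream encoding merges agents into the reactant
#' side (the differential fingerprint is defined on two sides).
#'
#' @param s a daylight reaction SMILES string.
#' @return an `ecx_reaction`: lists `reactants`, `agents`, `products` of
#'   `ecx_mol`, plus the verbatim input in `smiles`.
#' @export
parse_reaction_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s)) {
    stop_input("parse_reaction_smiles() expects one string")
  }
  parts <- strsplit(paste0(s, "\x01"), ">", fixed = TRUE)[[1]]
  parts[length(parts)] <- sub("\x01$", "", parts[length(parts)])
  if (length(parts) != 3) {
    stop_input(sprintf("reaction SMILES '%s' must have exactly 3 '>'-separated parts, got %d",
                       s, length(parts)))
  }
  if (!nzchar(parts[1])) stop_input(sprintf("reaction '%s' has no reactants", s))
  if (!nzchar(parts[3])) stop_input(sprintf("reaction '%s' has no product", s))
  parse_side <- function(p) {
    if (!nzchar(p)) return(list())
    lapply(strsplit(p, ".", fixed = TRUE)[[1]], parse_smiles)
  }
  structure(list(reactants = parse_side(parts[1]),
                 agents = parse_side(parts[2]),
                 products = parse_side(parts[3]),
                 smiles = s),
            class = "ecx_reaction")
}

#' Parse an EC number
#'
#' EC numbers are hierarchical `x.y.z.sn` labels: class, subclass,
#' sub-subclass, serial number, filled left to right (1 to 4 levels).
#'
#' @param s an EC string such as `"3.4.13"`.
#' @return an `ec_label` with integer fields `x`, `y`, `z`, `sn` (NA when
#'   absent).
#' @export
parse_ec <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s)) {
    stop_input("parse_ec() expects one non-empty string")
  }
  fields <- strsplit(s, ".", fixed = TRUE)[[1]]
  if (length(fields) < 1 || length(fields) > 4 || any(!grepl("^[0-9]+$", fields))) {
    stop_input(sprintf("malformed EC number '%s'", s))
  }
  v <- as.integer(fields)
  if (v[1] < 1 || v[1] > 7) stop_input(sprintf("EC class must be 1..7, got '%s'", s))
  structure(list(x = v[1],
                 y = if (length(v) >= 2) v[2] else NA_integer_,
                 z = if (length(v) >= 3) v[3] else NA_integer_,
                 sn = if (length(v) >= 4) v[4] else NA_integer_),
            class = "ec_label")
}

#' Render an EC label, optionally truncated
#'
#' @param ec an `ec_label` or EC string.
#' @param level 1 (class) to 4 (serial number); `NULL` renders all populated
#'   levels.
#' @return the `x`, `x.y`, ... prefix string.
#' @export
truncate_ec <- function(ec, level = NULL) {
  if (is.character(ec)) ec <- parse_ec(ec)
  stopifnot(inherits(ec, "ec_label"))
  v <- c(ec$x, ec$y, ec$z, ec$sn)
  avail <- which(!is.na(v))
  depth <- if (is.null(level)) max(avail) else level
  if (depth < 1 || depth > 4) stop_input("EC level must be in 1..4")
  if (depth > max(avail)) depth <- max(avail)
  paste(v[seq_len(depth)], collapse = ".")
}

#' @export
format.ec_label <- function(x, ...) truncate_ec(x)

#' @export
print.ec_label <- function(x, ...) {
  cat("<EC ", truncate_ec(x), ">\n", sep = "")
  invisible(x)
}

#' Construct a reaction record
#'
#' @param reaction_smiles verbatim reaction SMILES (stereochemistry kept).
#' @param ec an `ec_label` or EC string.
#' @param source data-source tag (`"rhea"`, `"ecreact"`, `"fixture"`).
#' @return a `reaction_record`.
#' @export
reaction_record <- function(reaction_smiles, ec, source = "rhea") {
  if (is.character(ec)) ec <- parse_ec(ec)
  structure(list(reaction_smiles = reaction_smiles, ec = ec, source = source),
            class = "reaction_record")
}

# EC token embedded in the SMILES via '|' (public ECREACT layout)
.strip_embedded_ec <- function(smiles) {
  m <- regmatches(smiles, regexec("\\|([0-9]+(?:\\.[0-9]+){0,3})", smiles))[[1]]
  ec <- if (length(m) >= 2) m[2] else NA_character_
  list(smiles = gsub("\\|[0-9]+(?:\\.[0-9]+){0,3}", "", smiles), ec = ec)
}

#' Load a reaction dataset CSV
#'
#' Two dialects are supported: `rhea_csv` (columns `rxn_smiles`, `ec`) and
#' `ecreact_csv` (`rxn_smiles`, `ec`, optional `source`; an EC token embedded
#' after `|` inside `rxn_smiles` is tolerated and stripped). Translocases
#' (EC class 7) carry no chemical transformation and are removed. Rows whose
#' SMILES or EC fail to parse are skipped with a warning and reported in the
#' `rejects` attribute.
#'
#' @param path CSV file path.
#' @param dialect `"rhea_csv"` or `"ecreact_csv"`.
#' @return list of `reaction_record`s with attributes `rejects` (data frame)
#'   and `n_class7` (count of filtered translocase rows).
#' @export
load_reaction_dataset <- function(path, dialect = c("rhea_csv", "ecreact_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("dataset file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rxn_smiles", "ec")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_input(sprintf("dataset '%s' is missing column(s): %s",
                       path, paste(missing_cols, collapse = ", ")))
  }
  src_col <- if (dialect == "ecreact_csv" && "source" %in% names(df)) df$source else
    rep(if (dialect == "rhea_csv") "rhea" else "ecreact", nrow(df))
  records <- list()
  rej <- list()
  n7 <- 0L
  for (i in seq_len(nrow(df))) {
    smi <- df$rxn_smiles[i]
    ec_str <- as.character(df$ec[i])
    if (dialect == "ecreact_csv" && grepl("|", smi, fixed = TRUE)) {
      st <- .strip_embedded_ec(smi)
      smi <- st$smiles
      if (is.na(ec_str) || !nzchar(ec_str)) ec_str <- st$ec
    }
    res <- tryCatch({
      ec <- parse_ec(ec_str)
      parse_reaction_smiles(smi)  # validation only; records keep the string
      reaction_record(smi, ec, src_col[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rej[[length(rej) + 1L]] <- data.frame(row = i, reason = conditionMessage(res))
      warning(sprintf("row %d skipped: %s", i, conditionMessage(res)), call. = FALSE)
    } else if (res$ec$x == 7L) {
      n7 <- n7 + 1L
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  if (length(records) == 0) stop_input("no usable records in ", path)
  attr(records, "rejects") <- if (length(rej)) do.call(rbind, rej) else
    data.frame(row = integer(0), reason = character(0))
  attr(records, "n_class7") <- n7
  records
}

#' Write reaction records as a rhea_csv-layout CSV
#'
#' @param records list of `reaction_record`s.
#' @param path output path.
#' @export
write_reaction_csv <- function(records, path) {
  df <- data.frame(
    rxn_smiles = vapply(records, `[[`, "", "reaction_smiles"),
    ec = vapply(records, function(r) truncate_ec(r$ec), ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified cross-validation folds
#'
#' Partitions records into `k` test folds stratified by the level-truncated
#' EC label (labels with fewer than `k` members are placed randomly). Within
#' each training portion, 10% is held out (stratified) as a validation set
#' for early stopping.
#'
#' @param records list of `reaction_record`s.
#' @param k number of folds (>= 2).
#' @param level EC truncation level (1, 2 or 3).
#' @param seed RNG seed; identical inputs and seed give identical folds.
#' @param val_fraction validation share of each training portion.
#' @return list of `k` elements, each `list(train, validation, test)` of
#'   record indices.
#' @export
make_cv_folds <- function(records, k = 4L, level = 1L, seed = 1L,
                          val_fraction = 0.1) {
  n <- length(records)
  if (k < 2) stop_input("k must be >= 2")
  if (k > n) stop_input("k exceeds the number of records")
  labels <- vapply(records, function(r) truncate_ec(r$ec, level), "")
  with_seed(seed, function() {
    fold_of <- integer(n)
    for (L in unique(labels)) {
      idx <- which(labels == L)
      if (length(idx) >= k) {
        fold_of[sample(idx)] <- rep_len(seq_len(k), length(idx))
      } else {
        fold_of[idx] <- sample.int(k, length(idx), replace = TRUE)
      }
    }
    lapply(seq_len(k), function(f) {
      test <- which(fold_of == f)
      pool <- which(fold_of != f)
      val <- integer(0)
      for (L in unique(labels[pool])) {
        idx <- pool[labels[pool] == L]
        nv <- floor(length(idx) * val_fraction)
        if (nv > 0) val <- c(val, sample(idx, nv))
      }
      if (length(val) == 0 && length(pool) > 1) val <- sample(pool, 1L)
      list(train = sort(setdiff(pool, val)), validation = sort(val),
           test = sort(test))
    })
  })
}

#' Fixture-corpus configuration
#'
#' Each pseudo-class is defined by a diagnostic product molecule whose
#' fragments are absent from every scaffold (and from the other classes), so
#' the class signal is a known set of fingerprint bits. Defaults give the
#' 3-class x 10-reaction corpus used throughout the test suite: carbon/oxygen
#' scaffolds and chemically disjoint diagnostics HBr, HI and H2S.
#'
#' @param n_classes number of pseudo-classes (1..6 with default templates).
#' @param n_per_class reactions per class.
#' @param seed RNG seed.
#' @param diagnostics one diagnostic molecule SMILES per class.
#' @param scaffolds scaffold pool shared by all classes.
#' @return a `fixture_config`.
#' @export
fixture_config <- function(n_classes = 3L, n_per_class = 10L, seed = 42L,
                           diagnostics = NULL, scaffolds = NULL) {
  default_diag <- c("Br", "I", "S", "P", "C#N", "Cl")
  if (is.null(diagnostics)) {
    if (n_classes > length(default_diag)) {
      stop_input("default templates support up to ", length(default_diag), " classes")
    }
    diagnostics <- default_diag[seq_len(n_classes)]
  }
  if (length(diagnostics) != n_classes) stop_input("need one diagnostic per class")
  if (is.null(scaffolds)) {
    scaffolds <- c("CCO", "CCCO", "CCCCO", "CC(C)O", "CC(C)CO", "CCC(C)O",
                   "CC(C)(C)O", "CCCCCO", "CCC(C)CO", "OC1CCCC1", "CC(O)CC",
                   "OCC1CCC1")
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed),
                 diagnostics = diagnostics, scaffolds = scaffolds),
            class = "fixture_config")
}

# shingle-SMILES set of one molecule SMILES
.shingle_set <- function(smiles, params) {
  unique(vapply(extract_shingles(parse_smiles(smiles), params), `[[`, "", "smiles"))
}

#' Generate a synthetic fixture corpus
#'
#' Emits `n_classes * n_per_class` template reactions
#' `scaffold >> scaffold . diagnostic`, labelled with pseudo-EC `c.1.1`.
#' Every record's product side contains the class diagnostic molecule and the
#' reactant side does not, so the diagnostic fragments are guaranteed to land
#' in the fingerprint's symmetric difference. Because the scaffold appears on
#' both sides it cancels out of the difference: each class is encoded by
#' exactly its diagnostic bits, which makes the corpus linearly separable by
#' construction (the property the explainability tests rely on), while the
#' drawn scaffolds still vary between records for depiction purposes.
#'
#' @param config a [fixture_config()].
#' @param params fingerprint parameters used to validate that diagnostics
#'   share no fragment with any scaffold.
#' @return list of `reaction_record`s.
#' @export
generate_fixture_corpus <- function(config = fixture_config(),
                                    params = fp_params()) {
  stopifnot(inherits(config, "fixture_config"))
  scaff_sets <- lapply(config$scaffolds, .shingle_set, params = params)
  for (ci in seq_len(config$n_classes)) {
    dset <- .shingle_set(config$diagnostics[ci], params)
    for (si in seq_along(config$scaffolds)) {
      hit <- intersect(dset, scaff_sets[[si]])
      if (length(hit)) {
        stop_input(sprintf(
          "fixture config error: diagnostic '%s' shares fragment(s) %s with scaffold '%s'",
          config$diagnostics[ci], paste(hit, collapse = ", "), config$scaffolds[si]))
      }
    }
    for (cj in seq_len(config$n_classes)) {
      if (ci != cj && length(intersect(dset, .shingle_set(config$diagnostics[cj], params)))) {
        stop_input("fixture config error: diagnostics of classes ", ci, " and ",
                   cj, " share fragments")
      }
    }
  }
  with_seed(config$seed, function() {
    records <- list()
    for (ci in seq_len(config$n_classes)) {
      for (r in seq_len(config$n_per_class)) {
        sc <- sample(config$scaffolds, 1L)
        smi <- paste0(sc, ">>", sc, ".", config$diagnostics[ci])
        records[[length(records) + 1L]] <-
          reaction_record(smi, paste0(ci, ".1.1"), "fixture")
      }
    }
    records
  })
}

#' Fingerprint bits carried by each fixture class's diagnostic molecule
#'
#' @param config a [fixture_config()].
#' @param params [fp_params()].
#' @return list (one per class) of `list(bits, fragments)`.
#' @export
diagnostic_bits <- function(config = fixture_config(), params = fp_params()) {
  lapply(seq_len(config$n_classes), function(ci) {
    frs <- .shingle_set(config$diagnostics[ci], params)
    list(bits = sort(unique(fold_hash(hash32(frs), params$dim))), fragments = frs)
  })
}
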