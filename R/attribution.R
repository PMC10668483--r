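# DeepLIFT (Rescale rule) attributions for the two-linear-layer ReLU MLP,
# averaged over a background sample (DeepSHAP style), then mapped back to
# present fragments, absent fragments and atoms.
#
# For this architecture the backpropagated multipliers have a closed form:
# linear layers contribute their weight matrices, and the hidden ReLU
# contributes m_h = (relu(z_h) - relu(z_ref_h)) / (z_h - z_ref_h), with the
# gradient (the 0/1 ReLU derivative) as fallback when |z - z_ref| < 1e-7.
# Completeness — contributions summing exactly to score(x) - score(ref) —
# holds by construction and is asserted property-style in the tests.

.relu_multipliers <- function(z, zr) {
  dz <- z - zr
  m <- ifelse(abs(dz) < 1e-7, as.numeric(z > 0), (pmax(z, 0) - pmax(zr, 0)) / dz)
  m
}

#' DeepLIFT Rescale contributions against a single reference
#'
#' Explains the pre-softmax score of one class by default; `output =
#' "probability"` applies one extra Rescale step through the softmax of that
#' class, making contributions sum to the probability difference instead.
#'
#' @param model an `ec_model` (ReLU hidden activation required).
#' @param x input fingerprint vector.
#' @param reference reference fingerprint vector of the same length.
#' @param class_index explained output index (position in `model$vocab`).
#' @param output `"score"` (pre-softmax, default) or `"probability"`.
#' @return numeric vector of per-input contributions; their sum equals
#'   `output(x) - output(reference)` up to floating-point error.
#' @export
deeplift_rescale <- function(model, x, reference, class_index,
                             output = c("score", "probability")) {
  output <- match.arg(output)
  if (!identical(model$activation, "relu")) {
    stop_input("unsupported hidden activation '", model$activation,
               "': the Rescale rule is implemented for ReLU")
  }
  d <- model$layer_dims[1]
  if (length(x) != d || length(reference) != d) {
    stop_input("input/reference length must equal the model input dim ", d)
  }
  z <- drop(crossprod(model$W1, x)) + model$b1
  zr <- drop(crossprod(model$W1, reference)) + model$b1
  m <- .relu_multipliers(z, zr)
  w2c <- model$W2[, class_index]
  contrib <- (x - reference) * drop(model$W1 %*% (m * w2c))
  if (output == "probability") {
    s <- drop(crossprod(model$W2, pmax(z, 0))) + model$b2
    sr <- drop(crossprod(model$W2, pmax(zr, 0))) + model$b2
    p <- exp(s - max(s)); p <- p / sum(p)
    pr <- exp(sr - max(sr)); pr <- pr / sum(pr)
    ds <- s[class_index] - sr[class_index]
    mout <- if (abs(ds) < 1e-7) p[class_index] * (1 - p[class_index]) else
      (p[class_index] - pr[class_index]) / ds
    contrib <- contrib * mout
  }
  contrib
}

#' Background reference set for DeepSHAP averaging
#'
#' Samples rows uniformly without replacement from a training fingerprint
#' matrix (100 reactions by default).
#'
#' @param X training fingerprint matrix or `ecx_corpus`.
#' @param n background size (capped at the number of rows).
#' @param seed sampling seed.
#' @return matrix of reference fingerprints with attribute `indices`.
#' @export
background_set <- function(X, n = 100L, seed = 1L) {
  if (inherits(X, "ecx_corpus")) X <- X$matrix
  X <- as.matrix(X)
  n <- min(n, nrow(X))
  if (n < 1) stop_input("background set needs at least one sample")
  idx <- with_seed(seed, function() sort(sample.int(nrow(X), n)))
  structure(X[idx, , drop = FALSE], indices = idx)
}

#' DeepSHAP feature contributions (Rescale averaged over a background)
#'
#' @param model an `ec_model`.
#' @param x input fingerprint vector or `ecx_fp`.
#' @param background reference matrix from [background_set()].
#' @param class_index explained output index.
#' @param output `"score"` or `"probability"`.
#' @return list with `feature_contributions` (length dim; mean over
#'   references), `expected_value` (mean class output over the background)
#'   and `output_value` (class output at `x`).
#' @export
deepshap_contributions <- function(model, x, background, class_index,
                                   output = c("score", "probability")) {
  output <- match.arg(output)
  if (inherits(x, "ecx_fp")) x <- x$bits
  B <- as.matrix(background)
  if (nrow(B) < 1) stop_input("background must be non-empty")
  d <- model$layer_dims[1]
  if (length(x) != d || ncol(B) != d) stop_input("dimension mismatch")
  z <- drop(crossprod(model$W1, x)) + model$b1
  Zr <- sweep(B %*% model$W1, 2, model$b1, `+`)            # n x h
  M <- .relu_multipliers(matrix(z, nrow(Zr), ncol(Zr), byrow = TRUE), Zr)  # n x h
  w2c <- model$W2[, class_index]
  Tm <- (M * matrix(w2c, nrow(M), ncol(M), byrow = TRUE)) %*% t(model$W1)  # n x d
  D <- matrix(x, nrow(B), d, byrow = TRUE) - B
  contrib_per_ref <- D * Tm
  s_x <- drop(crossprod(model$W2, pmax(z, 0))) + model$b2
  S_r <- sweep(pmax(Zr, 0) %*% model$W2, 2, model$b2, `+`) # n x C
  if (output == "probability") {
    p_x <- { e <- exp(s_x - max(s_x)); e / sum(e) }
    P_r <- .softmax_rows(S_r)
    ds <- s_x[class_index] - S_r[, class_index]
    mout <- ifelse(abs(ds) < 1e-7, p_x[class_index] * (1 - p_x[class_index]),
                   (p_x[class_index] - P_r[, class_index]) / ds)
    contrib_per_ref <- contrib_per_ref * mout
    expected <- mean(P_r[, class_index])
    outv <- p_x[class_index]
  } else {
    expected <- mean(S_r[, class_index])
    outv <- s_x[class_index]
  }
  list(feature_contributions = colMeans(contrib_per_ref),
       expected_value = expected, output_value = outv)
}

#' Split feature contributions into present and absent fragments
#'
#' Present fragments are the reaction's own fragments (bits with v = 1),
#' each carrying the bit's contribution w_f; a bit mapping to more than one
#' of the reaction's fragments is flagged as a collision and every colliding
#' SMILES is reported. Absent fragments are off-bits with |w_f| above
#' `threshold`, annotated with the corpus-wide candidate fragments for that
#' bit when a corpus index is available.
#'
#' @param contribs feature-contribution vector (length dim).
#' @param fp the reaction's `ecx_fp`.
#' @param corpus optional `ecx_corpus` supplying candidates for absent bits.
#' @param top_k_absent report at most this many absent bits (by |w_f|).
#' @param threshold minimum |w_f| for an absent bit to be reported.
#' @return list `present` (data frame: smiles, bit, weight, collisions) and
#'   `absent` (data frame: bit, weight, list-column candidates).
#' @export
split_fragment_contributions <- function(contribs, fp, corpus = NULL,
                                         top_k_absent = 10L, threshold = 0) {
  stopifnot(inherits(fp, "ecx_fp"))
  if (length(contribs) != fp$params$dim) stop_input("contribs length must equal dim")
  pres <- list()
  for (b in names(fp$bit_to_fragments)) {
    frs <- fp$bit_to_fragments[[b]]
    bit <- as.integer(b)
    pres[[length(pres) + 1L]] <- data.frame(
      smiles = frs, bit = bit, weight = contribs[bit + 1L],
      collisions = length(frs), stringsAsFactors = FALSE)
  }
  present <- if (length(pres)) do.call(rbind, pres) else
    data.frame(smiles = character(0), bit = integer(0), weight = numeric(0),
               collisions = integer(0))
  off <- setdiff(seq_along(contribs) - 1L, fp$on_bits)
  w <- contribs[off + 1L]
  keep <- abs(w) > threshold
  off <- off[keep]; w <- w[keep]
  ord <- order(-abs(w), off)
  take <- ord[seq_len(min(top_k_absent, length(ord)))]
  absent <- data.frame(bit = off[take], weight = w[take])
  absent$candidates <- if (is.null(corpus)) {
    replicate(nrow(absent), character(0), simplify = FALSE)
  } else {
    lapply(absent$bit, function(b) {
      cand <- corpus$global_bit_to_fragments[[as.character(b)]]
      if (is.null(cand)) character(0) else sort(cand)
    })
  }
  list(present = present, absent = absent)
}

#' Aggregate present-fragment contributions to atoms
#'
#' Implements the atom weighting w_a = sum of w_f over present fragments
#' whose occurrences cover atom a. When a bit carries several colliding
#' present fragments, its single w_f is attributed once over the union of
#' their atom sets (collisions are flagged, not resolved).
#'
#' @param present the `present` data frame from
#'   [split_fragment_contributions()].
#' @param fp the reaction's `ecx_fp`.
#' @return data frame `molecule`, `atom`, `weight` (atoms covered by no
#'   fragment are absent, i.e. weigh 0).
#' @export
atom_contributions <- function(present, fp) {
  stopifnot(inherits(fp, "ecx_fp"))
  acc <- new.env(parent = emptyenv())
  for (b in unique(present$bit)) {
    rows <- present[present$bit == b, ]
    w <- rows$weight[1]
    keys <- character(0)
    for (smi in rows$smiles) {
      for (occ in fp$fragment_to_occurrences[[smi]]) {
        n_at <- fp$molecules$n_atoms[occ$molecule_index]
        if (any(occ$atom_indices < 1 | occ$atom_indices > n_at)) {
          stop("occurrence of '", smi, "' references an out-of-range atom index",
               call. = FALSE)
        }
        keys <- union(keys, paste(occ$molecule_index, occ$atom_indices))
      }
    }
    for (k in keys) {
      acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + w
    }
  }
  keys <- ls(acc)
  if (!length(keys)) {
    return(data.frame(molecule = integer(0), atom = integer(0), weight = numeric(0)))
  }
  parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  out <- data.frame(molecule = as.integer(parts[, 1]), atom = as.integer(parts[, 2]),
                    weight = vapply(keys, function(k) acc[[k]], 0))
  out <- out[order(out$molecule, out$atom), ]
  rownames(out) <- NULL
  out
}

#' Explain a reaction's classification
#'
#' End-to-end explanation: encodes the reaction, ranks the model's
#' predictions, and for each of the `top` classes computes DeepSHAP feature
#' contributions, the present/absent fragment split and the per-atom weights.
#'
#' @param model an `ec_model`.
#' @param reaction reaction SMILES string or `reaction_record`.
#' @param background reference matrix from [background_set()].
#' @param corpus optional `ecx_corpus` for absent-fragment candidates.
#' @param top number of top-ranked classes to explain.
#' @param output `"score"` or `"probability"` (what the contributions sum to).
#' @param params fingerprint parameters; defaults to those stored in the
#'   model bundle.
#' @return an `ecx_explanation`: `reaction_smiles`, `fingerprint`, and one
#'   entry per explained class with label, rank, probability, expected value,
#'   contributions, present/absent tables and atom weights.
#' @export
explain_reaction <- function(model, reaction, background, corpus = NULL,
                             top = 3L, output = c("score", "probability"),
                             params = NULL) {
  output <- match.arg(output)
  if (is.null(params)) params <- model$fp_params
  if (is.null(params)) params <- fp_params()
  if (params$dim != model$layer_dims[1]) {
    stop_input("fingerprint dim does not match the model input layer")
  }
  fp <- encode_reaction(reaction, params)
  pr <- predict(model, fp$bits, top_k = min(top, length(model$vocab)))
  expl <- lapply(seq_len(nrow(pr)), function(r) {
    ci <- match(pr$label[r], model$vocab)
    core <- deepshap_contributions(model, fp$bits, background, ci, output = output)
    sp <- split_fragment_contributions(core$feature_contributions, fp, corpus)
    atoms <- atom_contributions(sp$present, fp)
    list(label = pr$label[r], rank = r, probability = pr$probability[r],
         expected_value = core$expected_value, output_value = core$output_value,
         feature_contributions = core$feature_contributions,
         present = sp$present, absent = sp$absent, atoms = atoms)
  })
  structure(list(reaction_smiles = fp$reaction_smiles, fingerprint = fp,
                 output = output, explanations = expl),
            class = "ecx_explanation")
}

#' @export
print.ecx_explanation <- function(x, ...) {
  cat(sprintf("<explanation of '%s': %d class(es)>\n", x$reaction_smiles,
              length(x$explanations)))
  for (e in x$explanations) {
    cat(sprintf("  #%d %s (p = %.3f), %d present / %d absent fragments\n",
                e$rank, e$label, e$probability, nrow(e$present), nrow(e$absent)))
  }
  invisible(x)
}

#' Serialise an explanation to JSON
#'
#' @param explanation an `ecx_explanation`.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @param run_config optional provenance list embedded verbatim.
#' @return the JSON string, invisibly when written to a file.
#' @export
explanation_to_json <- function(explanation, path = NULL, run_config = NULL) {
  stopifnot(inherits(explanation, "ecx_explanation"))
  obj <- list(
    reaction_smiles = explanation$reaction_smiles,
    output = explanation$output,
    explanations = lapply(explanation$explanations, function(e) {
      list(label = e$label, rank = e$rank, probability = e$probability,
           expected_value = e$expected_value,
           present = lapply(seq_len(nrow(e$present)), function(i) list(
             smiles = e$present$smiles[i], bit = e$present$bit[i],
             weight = e$present$weight[i], collisions = e$present$collisions[i])),
           absent = lapply(seq_len(nrow(e$absent)), function(i) list(
             bit = e$absent$bit[i], weight = e$absent$weight[i],
             candidates = as.list(e$absent$candidates[[i]]))),
           atoms = lapply(seq_len(nrow(e$atoms)), function(i) list(
             molecule = e$atoms$molecule[i], atom = e$atoms$atom[i],
             weight = e$atoms$weight[i])))
    }))
  if (!is.null(run_config)) obj$run_config <- run_config
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
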