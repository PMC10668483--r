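# Reaction depiction with a Gaussian attribution heat-map underlay.
#
# Atom weights are normalised to [-1, 1] across the whole reaction, summed as
# isotropic Gaussians centred on the atoms' 2D coordinates (the exponent uses
# the sum of squared coordinate differences), rasterised on a diverging
# colormap (negative -> magenta, positive -> green, zero -> transparent), and
# the molecule drawing is composited on top. Layouts come from a
# force-directed embedding (Kamada-Kawai seeded from a circle), so they are
# deterministic but not chemistry-aware like a dedicated depiction engine.

#' Rendering parameters
#'
#' @param sigma Gaussian width in drawing units; default 0.3 x median bond
#'   length (resolved at render time so blobs stay atom-sized at any scale).
#' @param ppu raster pixels per drawing unit for the background layer.
#' @param padding extent padding around the drawing, in drawing units.
#' @param max_alpha opacity of a |weight| = 1 blob centre.
#' @return a `render_params` list.
#' @export
render_params <- function(sigma = NULL, ppu = 20L, padding = 1,
                          max_alpha = 0.85) {
  if (!is.null(sigma) && sigma <= 0) stop_input("sigma must be > 0")
  stopifnot(ppu >= 1, padding >= 0)
  structure(list(sigma = sigma, ppu = as.integer(ppu), padding = padding,
                 max_alpha = max_alpha), class = "render_params")
}

.layout_one <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 1) return(matrix(0, 1, 2))
  g <- igraph::make_graph(t(cbind(mol$bonds$a1, mol$bonds$a2)), n = n,
                          directed = FALSE)
  start <- igraph::layout_in_circle(g)
  xy <- igraph::layout_with_kk(g, coords = start, dim = 2)
  if (nrow(mol$bonds) > 0) {
    bl <- sqrt(rowSums((xy[mol$bonds$a1, , drop = FALSE] -
                          xy[mol$bonds$a2, , drop = FALSE])^2))
    med <- stats::median(bl)
    if (med > 0) xy <- xy / med
  }
  sweep(xy, 2, colMeans(xy))
}

#' Lay out a reaction for drawing
#'
#' Reactant-side molecules (agents included), an arrow gap, then products,
#' left to right with non-overlapping bounding boxes. Coordinates are in
#' drawing units with median bond length 1; repeated calls give identical
#' coordinates.
#'
#' @param reaction reaction SMILES string, `reaction_record` or
#'   `ecx_reaction`.
#' @return an `ecx_layout`: per-molecule coordinates/bonds/atom info and
#'   boxes, the arrow segment, and the overall extent.
#' @export
layout_reaction <- function(reaction) {
  rx <- if (inherits(reaction, "ecx_reaction")) reaction else
    if (inherits(reaction, "reaction_record")) parse_reaction_smiles(reaction$reaction_smiles) else
      parse_reaction_smiles(reaction)
  mols <- c(rx$reactants, rx$agents, rx$products)
  sides <- c(rep("reactant", length(rx$reactants) + length(rx$agents)),
             rep("product", length(rx$products)))
  gap <- 1.2; arrow_len <- 2.2
  cursor <- 0
  out <- vector("list", length(mols))
  arrow <- NULL
  for (i in seq_along(mols)) {
    if (i > 1) {
      if (sides[i] == "product" && sides[i - 1] == "reactant") {
        arrow <- c(cursor + 0.4, cursor + arrow_len - 0.4, 0)
        cursor <- cursor + arrow_len
      } else cursor <- cursor + gap
    }
    xy <- .layout_one(mols[[i]])
    xy[, 1] <- xy[, 1] - min(xy[, 1]) + cursor
    box <- c(xmin = min(xy[, 1]), xmax = max(xy[, 1]),
             ymin = min(xy[, 2]), ymax = max(xy[, 2]))
    cursor <- box["xmax"]
    out[[i]] <- list(molecule_index = i, side = sides[i], coords = xy,
                     bonds = mols[[i]]$bonds, atoms = mols[[i]]$atoms, box = box)
  }
  allxy <- do.call(rbind, lapply(out, `[[`, "coords"))
  bl <- unlist(lapply(out, function(m) {
    if (nrow(m$bonds) == 0) return(numeric(0))
    sqrt(rowSums((m$coords[m$bonds$a1, , drop = FALSE] -
                    m$coords[m$bonds$a2, , drop = FALSE])^2))
  }))
  structure(list(molecules = out, arrow = arrow,
                 median_bond = if (length(bl)) stats::median(bl) else 1,
                 extent = c(xmin = min(allxy[, 1]), xmax = max(allxy[, 1]),
                            ymin = min(allxy[, 2], -0.5), ymax = max(allxy[, 2], 0.5))),
            class = "ecx_layout")
}

#' Normalise atom weights across a whole reaction
#'
#' Divides every weight by the maximum |weight| over all atoms of all
#' molecules, mapping into `[-1, 1]` with signs preserved; an all-zero vector
#' is returned unchanged. Idempotent.
#'
#' @param w numeric vector (or the `weight` column of an atom table).
#' @return normalised numeric vector.
#' @export
normalize_atom_weights <- function(w) {
  if (length(w) == 0) return(w)
  m <- max(abs(w))
  if (m == 0) return(w)
  w / m
}

#' Gaussian field over a pixel grid
#'
#' `G(x, y) = sum_j w_j exp(-((x - x_j)^2 + (y - y_j)^2) / (2 sigma^2))`.
#'
#' @param coords n x 2 matrix of atom coordinates.
#' @param weights length-n weights.
#' @param xs,ys grid coordinates (vectors).
#' @param sigma Gaussian width (> 0).
#' @return length(ys) x length(xs) matrix of G values.
#' @export
gaussian_field <- function(coords, weights, xs, ys, sigma) {
  if (sigma <= 0) stop_input("sigma must be > 0")
  stopifnot(nrow(coords) == length(weights))
  G <- matrix(0, length(ys), length(xs))
  for (j in seq_along(weights)) {
    if (weights[j] == 0) next
    gx <- exp(-(xs - coords[j, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ys - coords[j, 2])^2 / (2 * sigma^2))
    G <- G + weights[j] * outer(gy, gx)
  }
  G
}

#' Attribution heat-map grid for a laid-out reaction
#'
#' @param layout an `ecx_layout`.
#' @param atom_weights data frame `molecule`, `atom`, `weight` (as produced
#'   by [atom_contributions()]); weights are normalised here.
#' @param params [render_params()].
#' @return an `ecx_heatmap`: `values` (rows top-to-bottom), `extent`,
#'   `sigma`, `ppu`, and the normalised weights used.
#' @export
heatmap_grid <- function(layout, atom_weights, params = render_params()) {
  stopifnot(inherits(layout, "ecx_layout"))
  sigma <- if (is.null(params$sigma)) 0.3 * layout$median_bond else params$sigma
  if (sigma <= 0) stop_input("sigma must be > 0")
  ext <- layout$extent + c(-1, 1, -1, 1) * params$padding
  xs <- seq(ext[1], ext[2], by = 1 / params$ppu)
  ys <- seq(ext[4], ext[3], by = -1 / params$ppu)  # top row first
  w <- normalize_atom_weights(atom_weights$weight)
  coords <- matrix(0, nrow(atom_weights), 2)
  for (i in seq_len(nrow(atom_weights))) {
    m <- layout$molecules[[atom_weights$molecule[i]]]
    if (atom_weights$atom[i] > nrow(m$coords)) {
      stop_input("atom weight references an atom outside its molecule")
    }
    coords[i, ] <- m$coords[atom_weights$atom[i], ]
  }
  structure(list(values = gaussian_field(coords, w, xs, ys, sigma),
                 extent = ext, sigma = sigma, ppu = params$ppu,
                 weights = w),
            class = "ecx_heatmap")
}

# diverging colormap: magenta (negative) .. transparent (0) .. green (positive)
.heat_raster <- function(values, max_alpha) {
  v <- pmax(pmin(values, 1), -1)
  pos <- v > 0
  r <- ifelse(pos, 0.10, 0.85)
  g <- ifelse(pos, 0.65, 0.10)
  b <- ifelse(pos, 0.25, 0.75)
  a <- abs(v) * max_alpha
  arr <- array(0, dim = c(nrow(v), ncol(v), 4))
  arr[, , 1] <- r; arr[, , 2] <- g; arr[, , 3] <- b; arr[, , 4] <- a
  arr
}

.ATOM_COLORS <- c(O = "#c0392b", N = "#2e5bba", S = "#b8860b", P = "#cc7722",
                  F = "#2e8b57", Cl = "#2e8b57", Br = "#8b4513", I = "#6a0dad")

.draw_reaction <- function(layout, heat = NULL, params = render_params()) {
  ext <- layout$extent + c(-1, 1, -1, 1) * params$padding
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot(NA, xlim = ext[1:2], ylim = ext[3:4], asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  if (!is.null(heat) && any(heat$values != 0)) {
    graphics::rasterImage(.heat_raster(heat$values, params$max_alpha),
                          heat$extent[1], heat$extent[3],
                          heat$extent[2], heat$extent[4], interpolate = FALSE)
  }
  for (m in layout$molecules) {
    labelled <- m$atoms$element != "C" | m$atoms$charge != 0 |
      nrow(m$coords) == 1
    if (nrow(m$bonds)) {
      for (bi in seq_len(nrow(m$bonds))) {
        p1 <- m$coords[m$bonds$a1[bi], ]; p2 <- m$coords[m$bonds$a2[bi], ]
        # shorten towards labelled atoms so text stays readable
        shrink <- function(p, q, lab) if (lab) p + 0.22 * (q - p) else p
        a <- shrink(p1, p2, labelled[m$bonds$a1[bi]])
        b <- shrink(p2, p1, labelled[m$bonds$a2[bi]])
        ord <- m$bonds$order[bi]
        d <- b - a
        nrm <- c(-d[2], d[1]) / max(sqrt(sum(d^2)), 1e-9) * 0.07
        offs <- if (ord == 2) list(-nrm / 2, nrm / 2) else
          if (ord == 3) list(-nrm, c(0, 0), nrm) else list(c(0, 0))
        for (o in offs) {
          graphics::segments(a[1] + o[1], a[2] + o[2], b[1] + o[1], b[2] + o[2],
                             lwd = 2, lty = if (ord == 1.5) 1 else 1)
        }
      }
    }
    for (ai in which(labelled)) {
      el <- m$atoms$element[ai]
      h <- m$atoms$nH[ai]
      lab <- paste0(el, if (h == 1) "H" else if (h > 1) paste0("H", h) else "",
                    if (m$atoms$charge[ai] > 0) "+" else
                      if (m$atoms$charge[ai] < 0) "-" else "")
      col <- if (el %in% names(.ATOM_COLORS)) .ATOM_COLORS[[el]] else "black"
      graphics::text(m$coords[ai, 1], m$coords[ai, 2], lab, col = col, cex = 0.9)
    }
  }
  # plus signs between same-side molecules
  mols <- layout$molecules
  if (length(mols) > 1) {
    for (i in 2:length(mols)) {
      if (mols[[i]]$side == mols[[i - 1]]$side) {
        graphics::text((mols[[i - 1]]$box["xmax"] + mols[[i]]$box["xmin"]) / 2, 0,
                       "+", cex = 1.2)
      }
    }
  }
  if (!is.null(layout$arrow)) {
    graphics::arrows(layout$arrow[1], layout$arrow[3], layout$arrow[2],
                     layout$arrow[3], length = 0.08, lwd = 2)
  }
  invisible(NULL)
}

.render_png <- function(layout, heat, params, file) {
  ext <- layout$extent + c(-1, 1, -1, 1) * params$padding
  wpx <- max(64L, as.integer(round((ext[2] - ext[1]) * params$ppu * 2)))
  hpx <- max(64L, as.integer(round((ext[4] - ext[3]) * params$ppu * 2)))
  grDevices::png(file, width = wpx, height = hpx, type = "cairo")
  on.exit(grDevices::dev.off())
  .draw_reaction(layout, heat, params)
  invisible(file)
}

#' Render a reaction depiction (with optional attribution heat-map) to PNG
#'
#' With an explanation, the per-atom weights of the class at `class_rank` are
#' normalised, rasterised as a diverging Gaussian heat-map (nearest-neighbour
#' scaled, never interpolated) and composited beneath the molecule drawing.
#' Output is byte-deterministic for identical inputs. A zero-weight (or
#' missing) explanation yields the plain depiction.
#'
#' @param reaction reaction SMILES string or `reaction_record`.
#' @param file output PNG path.
#' @param explanation optional `ecx_explanation` for this reaction.
#' @param class_rank which explained class to visualise.
#' @param params [render_params()].
#' @return the raw PNG bytes, invisibly.
#' @export
render_explanation <- function(reaction, file, explanation = NULL,
                               class_rank = 1L, params = render_params()) {
  smi <- if (inherits(reaction, "reaction_record")) reaction$reaction_smiles else
    if (inherits(reaction, "ecx_reaction")) reaction$smiles else reaction
  layout <- layout_reaction(smi)
  heat <- NULL
  if (!is.null(explanation)) {
    stopifnot(inherits(explanation, "ecx_explanation"))
    if (!identical(explanation$reaction_smiles, smi)) {
      stop_input("explanation does not reference this reaction")
    }
    e <- explanation$explanations[[class_rank]]
    if (nrow(e$atoms) > 0) heat <- heatmap_grid(layout, e$atoms, params)
  }
  .render_png(layout, heat, params, file)
  invisible(readBin(file, "raw", file.info(file)$size))
}

#' Tabulate the strongest absent-fragment contributions
#'
#' @param absent the `absent` data frame of one explanation entry.
#' @param top_k rows to keep, ranked by |weight| descending (ties broken by
#'   bit index ascending). Bits whose corpus map holds several colliding
#'   candidates list all of them.
#' @return the ordered, truncated data frame.
#' @export
absent_fragment_report <- function(absent, top_k = 10L) {
  if (nrow(absent) == 0) return(absent)
  ord <- order(-abs(absent$weight), absent$bit)
  out <- absent[ord[seq_len(min(top_k, nrow(absent)))], ]
  rownames(out) <- NULL
  out
}
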