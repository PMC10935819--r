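#' Molecule depiction rasterization
#'
#' Molecules are laid out in 2D with OpenBabel and rasterized in-package:
#' bonds are drawn as thick black segments (double/triple bonds as parallel
#' strokes), heteroatoms as filled discs, on a white background. Drawing
#' in-package gives a pixel-exact ink mask — the ground truth the
#' segmentation model trains against — with controlled line thickness.
#'
#' @name depiction
NULL

INK_CUTOFF <- 128  # grey level separating ink from background

# Stamp a thick line segment (value 0) onto a 0-255 canvas.
# p0/p1 are continuous (row, col) coordinates; t is the stroke thickness.
draw_thick_segment <- function(canvas, p0, p1, t) {
  H <- nrow(canvas); W <- ncol(canvas)
  half <- t / 2
  rr <- max(1L, floor(min(p0[1], p1[1]) - half - 1)):min(H, ceiling(max(p0[1], p1[1]) + half + 1))
  cc <- max(1L, floor(min(p0[2], p1[2]) - half - 1)):min(W, ceiling(max(p0[2], p1[2]) + half + 1))
  if (length(rr) == 0 || length(cc) == 0) return(canvas)
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  vr <- p1[1] - p0[1]; vc <- p1[2] - p0[2]
  L2 <- vr^2 + vc^2
  if (L2 == 0) {
    d2 <- (R - p0[1])^2 + (C - p0[2])^2
  } else {
    tt <- clamp(((R - p0[1]) * vr + (C - p0[2]) * vc) / L2, 0, 1)
    d2 <- (R - (p0[1] + tt * vr))^2 + (C - (p0[2] + tt * vc))^2
  }
  sub <- canvas[rr, cc, drop = FALSE]
  sub[d2 <= half^2] <- 0
  canvas[rr, cc] <- sub
  canvas
}

# Stamp a filled disc (value 0).
draw_disc <- function(canvas, center, radius) {
  draw_thick_segment(canvas, center, center, 2 * radius)
}

# Rasterize one laid-out fragment (atoms/bonds tables from OpenBabel).
render_fragment <- function(frag, thickness, bond_px) {
  at <- frag$atoms; bd <- frag$bonds
  if (nrow(bd) > 0) {
    bl <- sqrt((at$x[bd$i] - at$x[bd$j])^2 + (at$y[bd$i] - at$y[bd$j])^2)
    unit <- stats::median(bl[bl > 0])
    if (!is.finite(unit) || unit == 0) unit <- 1
  } else unit <- 1
  scale <- bond_px / unit
  margin <- thickness + 6
  pc <- (at$x - min(at$x)) * scale + margin + 1           # col
  pr <- (max(at$y) - at$y) * scale + margin + 1           # row (y flipped)
  H <- ceiling(max(pr)) + margin; W <- ceiling(max(pc)) + margin
  canvas <- matrix(255, H, W)
  off <- max(2, round(0.13 * bond_px))  # parallel-stroke offset
  for (b in seq_len(nrow(bd))) {
    p0 <- c(pr[bd$i[b]], pc[bd$i[b]])
    p1 <- c(pr[bd$j[b]], pc[bd$j[b]])
    v <- p1 - p0; L <- sqrt(sum(v^2))
    n <- if (L > 0) c(-v[2], v[1]) / L else c(0, 1)
    ord <- bd$order[b]
    # main stroke always runs atom-to-atom so the skeleton stays connected;
    # higher orders add shortened parallel strokes, as in printed depictions
    canvas <- draw_thick_segment(canvas, p0, p1, thickness)
    if (!is.na(ord) && ord >= 2) {
      q0 <- p0 + 0.15 * v; q1 <- p1 - 0.15 * v
      canvas <- draw_thick_segment(canvas, q0 + n * off, q1 + n * off, thickness)
      if (ord >= 3)
        canvas <- draw_thick_segment(canvas, q0 - n * off, q1 - n * off, thickness)
    }
  }
  het <- which(!(at$symbol %in% c("C", "H")))
  rad <- max(2, round(0.14 * bond_px)) + (thickness - 1) / 2
  if (nrow(bd) == 0) het <- seq_len(nrow(at))  # lone atoms still draw
  for (a in het) canvas <- draw_disc(canvas, c(pr[a], pc[a]), rad)
  canvas
}

# Shrink a canvas so neither side exceeds max_px, re-quantizing ink.
cap_canvas <- function(canvas, max_px) {
  f <- max(dim(canvas)) / max_px
  if (f <= 1) return(canvas)
  out <- resize_image(canvas, max(1, round(nrow(canvas) / f)),
                      max(1, round(ncol(canvas) / f)), "bilinear")
  quantize_canvas(out)
}

# Push near-background greys to pure white; ink stays < INK_CUTOFF.
quantize_canvas <- function(canvas) {
  canvas[canvas >= INK_CUTOFF] <- 255
  canvas
}

# Trim a canvas to the tight bounding box of its ink, so a depiction's
# extent (and hence its recorded placement bbox) is the ink bbox.
trim_canvas <- function(canvas) {
  ink <- canvas < INK_CUTOFF
  rr <- which(rowSums(ink) > 0); cc <- which(colSums(ink) > 0)
  if (length(rr) == 0) return(canvas)
  canvas[min(rr):max(rr), min(cc):max(cc), drop = FALSE]
}

#' Render a molecule record to a bitmap with its ink mask
#'
#' Single-fragment records are rasterized directly; multi-fragment
#' (cluster) records render each fragment and arrange them on a grid with
#' small spacing, emulating the tightly packed multi-molecule figures of
#' patents. Oversized depictions are scaled down to `max_px`.
#'
#' @param mol one library record (single-row data.frame or list with
#'   `id` and `smiles`)
#' @param thickness bond stroke thickness in pixels
#' @param cfg a [synthesis_config()] (bond length, spacing, caps)
#' @param max_px maximum canvas side; defaults from `cfg`
#' @return object of class `chemseg_depiction`: `bitmap` (0-255 matrix,
#'   white background), `ink_mask` (= bitmap below the ink cut-off),
#'   `angle` (0), `line_thickness`, `id`
#' @export
render_depiction <- function(mol, thickness = 2L, cfg = synthesis_config(),
                             max_px = NULL) {
  if (is.data.frame(mol)) mol <- as.list(mol[1, ])
  frags <- strsplit(mol$smiles, ".", fixed = TRUE)[[1]]
  multi <- length(frags) > 1L
  if (is.null(max_px))
    max_px <- if (multi) min(cfg$page_size) - 96L else cfg$max_single_px
  key <- paste(mol$smiles, thickness, max_px, sep = "|")
  if (is.null(the$depict_cache)) the$depict_cache <- new.env(parent = emptyenv())
  hit <- the$depict_cache[[key]]
  if (!is.null(hit)) { hit$id <- mol$id; return(hit) }
  bond_px <- if (multi) cfg$cluster_bond_px else cfg$bond_px
  canvases <- lapply(frags, function(s) {
    frag <- tryCatch(fragment_coords(s),
                     error = function(e) stop("depiction failed for molecule '",
                                              mol$id, "': ", conditionMessage(e)))
    render_fragment(frag, thickness, bond_px)
  })
  canvas <- if (multi) arrange_grid(canvases, cfg$cluster_spacing_px)$canvas
            else canvases[[1]]
  canvas <- trim_canvas(cap_canvas(canvas, max_px))
  dep <- structure(list(bitmap = canvas,
                        ink_mask = (canvas < INK_CUTOFF) * 1,
                        angle = 0,
                        line_thickness = thickness,
                        id = mol$id),
                   class = "chemseg_depiction")
  the$depict_cache[[key]] <- dep
  dep
}

# Tile fragment canvases on a near-square grid with fixed spacing.
# Returns the combined canvas and each fragment's tight ink bbox
# (0-based half-open) within it.
arrange_grid <- function(canvases, spacing) {
  n <- length(canvases)
  ncols <- ceiling(sqrt(n)); nrows <- ceiling(n / ncols)
  hs <- vapply(canvases, nrow, 0L); ws <- vapply(canvases, ncol, 0L)
  ch <- max(hs); cw <- max(ws)
  H <- nrows * ch + (nrows - 1) * spacing
  W <- ncols * cw + (ncols - 1) * spacing
  out <- matrix(255, H, W)
  boxes <- vector("list", n)
  for (k in seq_len(n)) {
    r <- (k - 1) %/% ncols; c <- (k - 1) %% ncols
    r0 <- r * (ch + spacing) + (ch - hs[k]) %/% 2
    c0 <- c * (cw + spacing) + (cw - ws[k]) %/% 2
    out[(r0 + 1):(r0 + hs[k]), (c0 + 1):(c0 + ws[k])] <-
      pmin(out[(r0 + 1):(r0 + hs[k]), (c0 + 1):(c0 + ws[k])], canvases[[k]])
    boxes[[k]] <- c(r0, c0, r0 + hs[k], c0 + ws[k])
  }
  list(canvas = out, boxes = boxes)
}

# Cluster depiction with per-fragment bookkeeping: each fragment is
# rendered and rotated individually (same angle), trimmed, and tiled;
# fragment bboxes are returned for per-fragment ground truth.
render_cluster_asset <- function(rec, thickness, angle, cfg) {
  frags <- strsplit(rec$smiles, ".", fixed = TRUE)[[1]]
  frag_max <- max(64L, (min(cfg$page_size) - 96L -
                        2L * cfg$cluster_spacing_px) %/% 3L)
  fcfg <- cfg
  fcfg$bond_px <- cfg$cluster_bond_px
  deps <- lapply(seq_along(frags), function(k) {
    d <- render_depiction(list(id = paste0(rec$id, "_f", k), smiles = frags[k]),
                          thickness, fcfg, max_px = frag_max)
    rotate_depiction(d, angle)
  })
  g <- arrange_grid(lapply(deps, `[[`, "bitmap"), cfg$cluster_spacing_px)
  list(kind = "cluster", id = rec$id, bitmap = g$canvas,
       ink_mask = (g$canvas < INK_CUTOFF) * 1,
       frag_boxes = g$boxes, angle = angle, thickness = thickness)
}

#' Rotate a depiction
#'
#' Rotates the bitmap by `angle` degrees (white fill, bilinear
#' interpolation, output sized to the rotated bounding box), re-quantizes
#' near-background greys to white, and re-derives the ink mask as
#' `bitmap < 128` so the ink/bitmap correspondence stays exact.
#'
#' @param dep a `chemseg_depiction`
#' @param angle rotation in degrees, must lie in `[0, 30]`
#' @return rotated `chemseg_depiction` with `angle` recorded
#' @export
rotate_depiction <- function(dep, angle) {
  if (!is.numeric(angle) || length(angle) != 1 || angle < 0 || angle > 30)
    stop("angle must lie in [0, 30] degrees")
  if (angle == 0) return(dep)
  b <- rotate_bilinear(dep$bitmap, angle, fill = 255)
  b <- trim_canvas(repair_ink_breaks(quantize_canvas(b)))
  structure(list(bitmap = b, ink_mask = (b < INK_CUTOFF) * 1,
                 angle = dep$angle + angle,
                 line_thickness = dep$line_thickness, id = dep$id),
            class = "chemseg_depiction")
}

# Repair 1-2 px aliasing breaks that rotation resampling can cut into
# thin strokes: candidate gap pixels come from a 3x3 morphological
# closing of the ink, but only pixels that actually reconnect two
# distinct ink components are drawn (dark), so the ink count barely moves.
repair_ink_breaks <- function(b) {
  ink <- (b < INK_CUTOFF) * 1
  if (sum(ink) == 0) return(b)
  lab <- label_components(ink, 8L)
  if (max(lab) <= 1) return(b)
  closed <- EBImage::closing(ink, EBImage::makeBrush(3, "box"))
  added <- which(closed > 0 & ink == 0, arr.ind = TRUE)
  if (nrow(added) == 0) return(b)
  H <- nrow(b); W <- ncol(b)
  labsets <- lapply(seq_len(nrow(added)), function(k) {
    r <- added[k, 1]; c <- added[k, 2]
    nb <- lab[max(1, r - 1):min(H, r + 1), max(1, c - 1):min(W, c + 1)]
    setdiff(unique(as.vector(nb)), 0L)
  })
  keep <- vapply(labsets, function(s) length(s) >= 2, TRUE)
  touch <- which(lengths(labsets) > 0)
  if (length(touch) > 1) {
    for (a in seq_along(touch)[-length(touch)]) {
      i <- touch[a]
      for (j in touch[(a + 1):length(touch)]) {
        if (abs(added[i, 1] - added[j, 1]) <= 1 &&
            abs(added[i, 2] - added[j, 2]) <= 1 &&
            length(unique(c(labsets[[i]], labsets[[j]]))) >= 2)
          keep[c(i, j)] <- TRUE
      }
    }
  }
  if (any(keep)) b[added[keep, , drop = FALSE]] <- 64
  b
}

# Rotate a matrix by `angle` degrees about its centre; output covers the
# rotated bounding box. Inverse mapping with bilinear sampling.
rotate_bilinear <- function(m, angle, fill = 255) {
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  Hn <- ceiling(abs(ct) * H + abs(st) * W)
  Wn <- ceiling(abs(ct) * W + abs(st) * H)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  crn <- (Hn + 1) / 2; ccn <- (Wn + 1) / 2
  ro <- matrix(seq_len(Hn) - crn, Hn, Wn)
  co <- matrix(seq_len(Wn) - ccn, Hn, Wn, byrow = TRUE)
  ri <- ct * ro - st * co + cr
  ci <- st * ro + ct * co + cc
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  pick <- function(rr, cc2) {
    ok <- rr >= 1 & rr <= H & cc2 >= 1 & cc2 <= W
    v <- matrix(fill, Hn, Wn)
    v[ok] <- m[cbind(rr[ok], cc2[ok])]
    v
  }
  v00 <- pick(r0, c0); v01 <- pick(r0, c0 + 1)
  v10 <- pick(r0 + 1, c0); v11 <- pick(r0 + 1, c0 + 1)
  v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
}
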