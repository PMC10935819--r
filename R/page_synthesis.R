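#' Synthesis configuration
#'
#' Study conditions for the synthetic page/mask generator: drug-like
#' single molecules carry 15-28 heavy atoms, multi-molecule cluster
#' records 250-300 total atoms (hydrogens included), 1-6 molecules are
#' placed per page with rotations drawn uniformly from 0-30 degrees and
#' variable bond stroke thickness, on 512 x 512 (or larger) pages with
#' optional table grid lines and non-molecular negative figures.
#'
#' @param n_pages number of page/mask pairs to generate
#' @param min_heavy,max_heavy heavy-atom band for single molecules
#' @param min_cluster_atoms,max_cluster_atoms total-atom band (H included)
#'   for cluster records
#' @param max_mols_per_page maximum molecules per page (single route)
#' @param max_rotation_deg maximum depiction rotation
#' @param thickness_range integer range of bond stroke thickness (pixels)
#' @param grid_prob probability a placed molecule gets a table grid box
#' @param negative_prob probability a page receives negative figures
#' @param cluster_prob probability a page takes the multi-molecule
#'   cluster route instead of the single-molecule route
#' @param page_size page dimensions `c(H, W)`, each at least 512
#' @param seed dataset RNG seed
#' @param bond_px rendered bond length (pixels) for single molecules
#' @param cluster_bond_px bond length inside cluster fragments
#' @param cluster_spacing_px spacing between cluster fragments
#' @param max_single_px cap on a single depiction's side
#' @param base_text_prob probability a base page carries paragraph text
#' @param placement_margin minimum white margin kept around each placed
#'   asset (also the pairwise separation buffer)
#' @param grid_pad padding between a molecule's bbox and its grid box
#' @return object of class `chemseg_synthesis_config`
#' @export
synthesis_config <- function(n_pages = 10L,
                             min_heavy = 15L, max_heavy = 28L,
                             min_cluster_atoms = 250L, max_cluster_atoms = 300L,
                             max_mols_per_page = 6L,
                             max_rotation_deg = 30,
                             thickness_range = c(2L, 4L),
                             grid_prob = 0.3,
                             negative_prob = 0.5,
                             cluster_prob = 0.2,
                             page_size = c(512L, 512L),
                             seed = 1L,
                             bond_px = 20L,
                             cluster_bond_px = 16L,
                             cluster_spacing_px = 12L,
                             max_single_px = 200L,
                             base_text_prob = 0.7,
                             placement_margin = 16L,
                             grid_pad = 10L) {
  stopifnot(n_pages >= 0, min_heavy >= 1, max_heavy >= min_heavy,
            min_cluster_atoms >= 1, max_cluster_atoms >= min_cluster_atoms,
            max_mols_per_page >= 1, max_rotation_deg >= 0,
            length(thickness_range) == 2, thickness_range[1] >= 1,
            thickness_range[2] >= thickness_range[1],
            grid_prob >= 0, grid_prob <= 1, negative_prob >= 0,
            negative_prob <= 1, cluster_prob >= 0, cluster_prob <= 1,
            length(page_size) == 2, all(page_size >= 512))
  structure(as.list(environment()), class = "chemseg_synthesis_config")
}

# ---- base pages and negative assets -------------------------------------

# Rows of dark dashes emulating printed words.
draw_dash_rows <- function(page, r0, r1, c0, c1, line_h = 6L, gap = 8L) {
  r <- r0
  while (r + line_h <= r1) {
    cpos <- c0
    while (cpos < c1 - 8) {
      w <- sample(8:34, 1)
      w <- min(w, c1 - cpos)
      page[r:(r + line_h - 1L), cpos:(cpos + w - 1L)] <- 40
      cpos <- cpos + w + sample(5:12, 1)
    }
    r <- r + line_h + gap
  }
  page
}

#' Synthesize a molecule-free base page
#'
#' Emulates a document page: white background with optional paragraph-text
#' bands (dash rendering) near the top and bottom, leaving interior white
#' space for figure placement. A user directory of real molecule-free page
#' scans can be supplied to [generate_dataset()] instead.
#'
#' @param cfg a [synthesis_config()]
#' @return grayscale page matrix (0-255)
#' @export
synth_base_page <- function(cfg = synthesis_config()) {
  H <- cfg$page_size[1]; W <- cfg$page_size[2]
  page <- matrix(255, H, W)
  if (stats::runif(1) < cfg$base_text_prob) {
    m <- 28L
    top_h <- sample(50:120, 1)
    page <- draw_dash_rows(page, m, m + top_h, m, W - m)
    if (stats::runif(1) < 0.7) {
      bot_h <- sample(30:80, 1)
      page <- draw_dash_rows(page, H - m - bot_h, H - m, m, W - m)
    }
  }
  page
}

#' Synthesize a non-molecular negative figure
#'
#' Stand-ins for the scraped non-molecule figures used as negative
#' samples: bar charts, line charts, blot-like blobs, and text boxes.
#'
#' @param kind one of "barchart", "linechart", "blob", "textbox";
#'   default: sampled
#' @return grayscale bitmap (0-255)
#' @export
synth_negative <- function(kind = NULL) {
  kinds <- c("barchart", "linechart", "blob", "textbox")
  if (is.null(kind)) kind <- sample(kinds, 1)
  kind <- match.arg(kind, kinds)
  H <- sample(60:130, 1); W <- sample(70:140, 1)
  b <- matrix(255, H, W)
  if (kind == "barchart") {
    b[, 1:2] <- 0; b[(H - 1):H, ] <- 0
    nb <- sample(4:7, 1)
    bw <- max(3L, (W - 10L) %/% (2L * nb))
    for (k in seq_len(nb)) {
      x0 <- 5L + (k - 1L) * 2L * bw
      if (x0 + bw > W) break
      hk <- sample(seq(5L, H - 8L), 1)
      b[(H - 2L - hk):(H - 2L), x0:(x0 + bw - 1L)] <- 70
    }
  } else if (kind == "linechart") {
    b[, 1:2] <- 0; b[(H - 1):H, ] <- 0
    xs <- round(seq(4, W - 4, length.out = 8))
    ys <- sample(seq(4L, H - 6L), 8, replace = TRUE)
    for (k in 1:7)
      b <- draw_thick_segment(b, c(ys[k], xs[k]), c(ys[k + 1], xs[k + 1]), 2)
  } else if (kind == "blob") {
    for (k in seq_len(sample(2:4, 1))) {
      cy <- stats::runif(1, H * 0.2, H * 0.8); cx <- stats::runif(1, W * 0.2, W * 0.8)
      a <- stats::runif(1, W * 0.1, W * 0.3); bb <- stats::runif(1, H * 0.08, H * 0.2)
      R <- matrix(seq_len(H), H, W); C <- matrix(seq_len(W), H, W, byrow = TRUE)
      inside <- ((R - cy) / bb)^2 + ((C - cx) / a)^2 <= 1
      b[inside] <- pmin(b[inside], sample(50:120, 1))
    }
  } else {
    b <- draw_dash_rows(b, 4L, H - 4L, 4L, W - 4L, line_h = 5L, gap = 6L)
  }
  b
}

# ---- composition --------------------------------------------------------

boxes_intersect <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

empty_placements <- function() {
  data.frame(asset_id = character(), kind = character(),
             row0 = integer(), col0 = integer(),
             row1 = integer(), col1 = integer(),
             angle = numeric(), thickness = integer(),
             has_grid = logical(), stringsAsFactors = FALSE)
}

#' Compose a page from placed assets
#'
#' Places molecule depictions and negative figures at random
#' non-overlapping positions on a molecule-free base page. Placement is
#' accepted only where the page is white under the asset's padded
#' bounding box, so assets never overlap each other or the page text;
#' overlap is tested on axis-aligned (padded) bounding boxes. Molecule
#' ink enters the ground-truth mask; grid boxes (drawn with probability
#' `grid_prob` around a molecule) and negatives appear on the page only.
#'
#' @param base_page grayscale molecule-free page (0-255)
#' @param assets list of assets: each a list with `kind`
#'   ("molecule"/"negative"), `id`, and `bitmap` (negatives) or a
#'   `chemseg_depiction` in `dep` (molecules)
#' @param cfg a [synthesis_config()]
#' @param strict if TRUE, failure to place an asset after bounded retries
#'   is an error naming the asset; if FALSE the asset is skipped
#' @param retries placement attempts per asset
#' @return list of class `chemseg_page_pair`: `page`, `mask`,
#'   `placements` (data.frame with 0-based half-open bboxes)
#' @export
compose_page <- function(base_page, assets, cfg = synthesis_config(),
                         strict = TRUE, retries = 250L) {
  H <- nrow(base_page); W <- ncol(base_page)
  page <- base_page
  mask <- matrix(0, H, W)
  placements <- empty_placements()
  pad <- cfg$placement_margin
  occupied <- list()
  for (asset in assets) {
    bm <- if (asset$kind == "molecule") asset$dep$bitmap else asset$bitmap
    ink <- switch(asset$kind, molecule = asset$dep$ink_mask,
                  cluster = asset$ink_mask, NULL)
    h <- nrow(bm); w <- ncol(bm)
    if (h + 2 * pad >= H || w + 2 * pad >= W) {
      if (strict) stop("asset '", asset$id, "' does not fit on the page")
      next
    }
    placed <- FALSE
    for (try in seq_len(retries)) {
      r0 <- sample.int(H - h - 2L * pad, 1L) + pad - 1L  # 0-based
      c0 <- sample.int(W - w - 2L * pad, 1L) + pad - 1L
      padded <- c(r0 - pad, c0 - pad, r0 + h + pad, c0 + w + pad)
      if (any(vapply(occupied, boxes_intersect, TRUE, a = padded))) next
      reg <- page[(padded[1] + 1L):padded[3], (padded[2] + 1L):padded[4]]
      if (min(reg) < 250) next  # must sit on white background
      rows <- (r0 + 1L):(r0 + h); cols <- (c0 + 1L):(c0 + w)
      page[rows, cols] <- pmin(page[rows, cols], bm)
      has_grid <- FALSE
      if (!is.null(ink)) {
        mask[rows, cols][ink == 1] <- 1
        if (stats::runif(1) < cfg$grid_prob) {
          g <- draw_grid_box(page, c(r0, c0, r0 + h, c0 + w), cfg)
          page <- g$page
          if (!is.null(g$bbox)) {
            has_grid <- TRUE
            placements <- rbind(placements, data.frame(
              asset_id = paste0(asset$id, "_grid"), kind = "gridline",
              row0 = g$bbox[1], col0 = g$bbox[2],
              row1 = g$bbox[3], col1 = g$bbox[4],
              angle = 0, thickness = g$thickness, has_grid = FALSE,
              stringsAsFactors = FALSE))
          }
        }
      }
      if (asset$kind == "cluster") {
        # one ground-truth molecule placement per fragment
        for (k in seq_along(asset$frag_boxes)) {
          fb <- asset$frag_boxes[[k]]
          placements <- rbind(placements, data.frame(
            asset_id = paste0(asset$id, "_f", k), kind = "molecule",
            row0 = r0 + fb[1], col0 = c0 + fb[2],
            row1 = r0 + fb[3], col1 = c0 + fb[4],
            angle = asset$angle, thickness = asset$thickness,
            has_grid = has_grid, stringsAsFactors = FALSE))
        }
      } else {
        placements <- rbind(placements, data.frame(
          asset_id = asset$id, kind = asset$kind,
          row0 = r0, col0 = c0, row1 = r0 + h, col1 = c0 + w,
          angle = if (asset$kind == "molecule") asset$dep$angle else 0,
          thickness = if (asset$kind == "molecule") asset$dep$line_thickness else 0L,
          has_grid = has_grid, stringsAsFactors = FALSE))
      }
      occupied[[length(occupied) + 1L]] <- padded
      placed <- TRUE
      break
    }
    if (!placed && strict)
      stop("could not place asset '", asset$id, "' after ", retries, " attempts")
  }
  structure(list(page = page, mask = mask, placements = placements),
            class = "chemseg_page_pair")
}

# Rectangle outline around a molecule's padded bbox (table grid emulation).
draw_grid_box <- function(page, bbox, cfg) {
  H <- nrow(page); W <- ncol(page)
  t <- sample(1:2, 1)
  g0 <- bbox[1:2] - cfg$grid_pad
  g1 <- bbox[3:4] + cfg$grid_pad
  if (g0[1] < 1 || g0[2] < 1 || g1[1] > H - 1 || g1[2] > W - 1)
    return(list(page = page, bbox = NULL, thickness = t))
  rows <- (g0[1] + 1L):g1[1]; cols <- (g0[2] + 1L):g1[2]
  page[g0[1] + seq_len(t), cols] <- 0
  page[g1[1] - seq_len(t) + 1L, cols] <- 0
  page[rows, g0[2] + seq_len(t)] <- 0
  page[rows, g1[2] - seq_len(t) + 1L] <- 0
  list(page = page, bbox = c(g0, g1), thickness = t)
}

#' Generate one synthetic page/mask pair
#'
#' Single-molecule route: 1 to `max_mols_per_page` drug-like molecules
#' (15-28 heavy atoms), each with random stroke thickness and rotation.
#' Cluster route (probability `cluster_prob`): one multi-molecule record
#' with 250-300 total atoms. Negative figures are added with probability
#' `negative_prob`. At least one molecule is always placed.
#'
#' @param library a [molecule_library()]
#' @param cfg a [synthesis_config()]
#' @return `chemseg_page_pair`
#' @export
generate_page_pair <- function(library, cfg = synthesis_config()) {
  for (attempt in 1:8) {
    base <- synth_base_page(cfg)
    assets <- list()
    cluster <- stats::runif(1) < cfg$cluster_prob &&
      any(library$total_atoms >= cfg$min_cluster_atoms &
          library$total_atoms <= cfg$max_cluster_atoms)
    if (cluster) {
      rec <- select_cluster_record(library, cfg)
      thick <- sample(seq(cfg$thickness_range[1], cfg$thickness_range[2]), 1)
      assets[[1L]] <- render_cluster_asset(
        as.list(rec[1, ]), thick,
        stats::runif(1, 0, cfg$max_rotation_deg), cfg)
    } else {
      recs <- select_single_molecules(library, cfg,
                sample.int(cfg$max_mols_per_page, 1L))
      for (k in seq_len(nrow(recs))) {
        thick <- sample(seq(cfg$thickness_range[1], cfg$thickness_range[2]), 1)
        dep <- render_depiction(recs[k, ], thick, cfg)
        dep <- rotate_depiction(dep, stats::runif(1, 0, cfg$max_rotation_deg))
        assets[[length(assets) + 1L]] <-
          list(kind = "molecule", id = recs$id[k], dep = dep)
      }
    }
    if (stats::runif(1) < cfg$negative_prob) {
      for (k in seq_len(sample(1:2, 1)))
        assets[[length(assets) + 1L]] <-
          list(kind = "negative", id = paste0("neg", k),
               bitmap = synth_negative())
    }
    pair <- compose_page(base, assets, cfg, strict = FALSE)
    if (sum(pair$placements$kind == "molecule") >= 1L) return(pair)
  }
  stop("failed to compose a page with at least one molecule")
}

#' Generate a synthetic dataset on disk
#'
#' Writes `pages/NNNN.png` and `masks/NNNN.png` (8-bit, masks 0/255) plus
#' a `manifest.jsonl` with one record per page carrying the seed and the
#' placement table (0-based half-open bboxes). The same `(cfg, seed)`
#' yields a bit-identical dataset.
#'
#' @param cfg a [synthesis_config()]
#' @param out_dir output directory (created)
#' @param library optional [molecule_library()]; default: packaged fixtures
#' @return invisibly, the manifest as a data.frame (one row per placement,
#'   with a `page` column)
#' @export
generate_dataset <- function(cfg = synthesis_config(), out_dir,
                             library = NULL) {
  if (is.null(library)) library <- molecule_library()
  dir.create(file.path(out_dir, "pages"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.jsonl")
  con <- file(manifest_path, open = "wt")
  on.exit(close(con))
  rows <- list()
  local_seed(cfg$seed, {
    for (i in seq_len(cfg$n_pages)) {
      name <- sprintf("%04d", i - 1L)
      pair <- generate_page_pair(library, cfg)
      write_page_png(pair$page, file.path(out_dir, "pages", paste0(name, ".png")))
      write_mask_png(pair$mask, file.path(out_dir, "masks", paste0(name, ".png")))
      writeLines(jsonlite::toJSON(
        list(page = name, seed = cfg$seed, placements = pair$placements),
        dataframe = "rows", auto_unbox = TRUE, digits = NA), con)
      if (nrow(pair$placements)) {
        pl <- pair$placements; pl$page <- name
        rows[[length(rows) + 1L]] <- pl
      }
    }
  })
  invisible(if (length(rows)) do.call(rbind, rows) else {
    m <- empty_placements(); m$page <- character(); m
  })
}

#' Read a dataset manifest written by [generate_dataset()]
#'
#' @param dir dataset directory
#' @return data.frame of placements with a `page` column
#' @export
read_dataset_manifest <- function(dir) {
  lines <- readLines(file.path(dir, "manifest.jsonl"))
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    if (length(rec$placements) == 0 || nrow(rec$placements) == 0) return(NULL)
    pl <- rec$placements; pl$page <- rec$page; pl
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows)) do.call(rbind, rows) else {
    m <- empty_placements(); m$page <- character(); m
  }
}
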