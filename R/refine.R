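#' Refinement configuration
#'
#' Parameters of the pixel-level mask refinement stage.
#'
#' @param min_region_px pixel-count threshold below which a connected
#'   component is discarded as a non-structure, anchored at a 512 x 512
#'   page; at other sizes it scales with the area ratio
#' @param ref_side side length anchoring `min_region_px` (512)
#' @param dilation_kernel_frac side of the square dilation kernel as a
#'   fraction of `max(H, W)` (minimum side 3; even sides are bumped to the
#'   next odd value so the structuring element is centred)
#' @param prob_threshold probability cut for binarizing model masks
#' @param connectivity 4 or 8, used for flood fill / components
#' @param hough_min_len_frac minimum detected line length as a fraction of
#'   the page dimension parallel to the line
#' @param hough_max_gap maximum pixel gap bridged within one detected line
#' @param hough_angle_tol angular tolerance (degrees) around 0 / 90
#' @param crop_pad padding in page pixels added around region crops
#' @param gap_bridge_px extra dilation (pixels) applied to the ink map for
#'   component *connectivity only* during [update_mask()]; the output is
#'   always intersected back to true ink pixels. 0 disables bridging.
#' @return object of class `chemseg_refine_config`
#' @export
refine_config <- function(min_region_px = 400L,
                          ref_side = 512L,
                          dilation_kernel_frac = 0.01,
                          prob_threshold = 0.5,
                          connectivity = 8L,
                          hough_min_len_frac = 0.5,
                          hough_max_gap = 3L,
                          hough_angle_tol = 2,
                          crop_pad = 4L,
                          gap_bridge_px = 0L) {
  stopifnot(min_region_px > 0, prob_threshold > 0, prob_threshold < 1,
            connectivity %in% c(4L, 8L), dilation_kernel_frac > 0,
            hough_min_len_frac > 0, hough_max_gap >= 0, hough_angle_tol >= 0,
            crop_pad >= 0, gap_bridge_px >= 0)
  structure(list(min_region_px = as.integer(min_region_px),
                 ref_side = as.integer(ref_side),
                 dilation_kernel_frac = dilation_kernel_frac,
                 prob_threshold = prob_threshold,
                 connectivity = as.integer(connectivity),
                 hough_min_len_frac = hough_min_len_frac,
                 hough_max_gap = as.integer(hough_max_gap),
                 hough_angle_tol = hough_angle_tol,
                 crop_pad = as.integer(crop_pad),
                 gap_bridge_px = as.integer(gap_bridge_px)),
            class = "chemseg_refine_config")
}

#' Binarize a grayscale page by its mean intensity
#'
#' A pixel is ink (1) iff its intensity is strictly below the page mean.
#' The data-dependent threshold suppresses non-white backgrounds and
#' low-quality-scan artifacts. A constant page yields an all-zero map.
#'
#' @param gray_page numeric matrix, values in 0-255 (or any single scale)
#' @return binary ink map
#' @export
binarize_image <- function(gray_page) {
  if (!is.matrix(gray_page)) stop("gray_page must be a single-channel matrix")
  (gray_page < mean(gray_page)) * 1
}

#' Remove long straight horizontal/vertical lines
#'
#' Restricted Hough transform over angles within `hough_angle_tol` degrees
#' of 0 (horizontal) and 90 (vertical). Votes are accumulated per quantized
#' line; along each candidate line, maximal runs of foreground pixels with
#' internal gaps of at most `hough_max_gap` and extent of at least
#' `hough_min_len_frac` times the parallel page dimension are erased.
#' Short co-linear strokes (bonds, text) never reach the length cut and are
#' untouched, as are diagonal lines.
#'
#' @param mask binary matrix (an ink map or a predicted mask)
#' @param cfg a [refine_config()]
#' @return binary matrix with detected line pixels set to 0
#' @export
remove_straight_lines <- function(mask, cfg = refine_config()) {
  assert_binary_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  px <- which(mask == 1, arr.ind = TRUE)
  if (nrow(px) == 0L) return(mask)
  out <- mask
  thetas <- seq(-cfg$hough_angle_tol, cfg$hough_angle_tol, by = 0.5)
  out <- erase_runs(out, px, thetas, horizontal = TRUE, cfg = cfg)
  px <- which(out == 1, arr.ind = TRUE)
  if (nrow(px)) out <- erase_runs(out, px, thetas, horizontal = FALSE, cfg = cfg)
  out
}

# Erase qualifying runs along near-horizontal (or, transposed, near-vertical)
# lines. `px` is the (row, col) index of foreground pixels.
erase_runs <- function(mask, px, thetas, horizontal, cfg) {
  H <- nrow(mask); W <- ncol(mask)
  r <- px[, 1]; c <- px[, 2]
  if (!horizontal) { tmp <- r; r <- c; c <- tmp; dim_par <- H } else dim_par <- W
  min_len <- floor(cfg$hough_min_len_frac * dim_par)
  if (min_len < 2) min_len <- 2
  kill <- rep(FALSE, length(r))
  for (th in thetas) {
    t <- tan(th * pi / 180)
    rho <- round(r - c * t)
    cnt <- table(rho)
    cand <- as.integer(names(cnt)[cnt >= min_len])
    for (q in cand) {
      sel <- which(rho == q)
      cs <- sort(c[sel])
      # split into runs with gaps <= max_gap
      brk <- c(0L, which(diff(cs) > cfg$hough_max_gap + 1L), length(cs))
      for (b in seq_len(length(brk) - 1L)) {
        run <- cs[(brk[b] + 1L):brk[b + 1L]]
        if ((max(run) - min(run) + 1L) >= min_len) {
          on_run <- sel[c[sel] >= min(run) & c[sel] <= max(run)]
          kill[on_run] <- TRUE
        }
      }
    }
  }
  if (any(kill)) {
    rr <- px[kill, 1]; cc <- px[kill, 2]
    mask[cbind(rr, cc)] <- 0
  }
  mask
}

#' Dilate a binary mask with a scaled square structuring element
#'
#' The kernel is a square whose side is
#' `max(3, round(dilation_kernel_frac * max(H, W)))` (5 at 512), bumped to
#' the next odd integer so the element is centred. Closes gaps between atom
#' symbols and adjacent bond strokes before flood-fill updating.
#'
#' @param mask binary matrix
#' @param cfg a [refine_config()]
#' @param side optional explicit kernel side, overriding the scaling law
#' @return dilated binary mask (always a superset of the input)
#' @export
dilate_mask <- function(mask, cfg = refine_config(), side = NULL) {
  assert_binary_mask(mask)
  if (is.null(side))
    side <- max(3L, as.integer(round(cfg$dilation_kernel_frac * max(dim(mask)))))
  if (side %% 2L == 0L) side <- side + 1L
  if (sum(mask) == 0) return(mask)
  out <- EBImage::dilate(mask, EBImage::makeBrush(side, shape = "box"))
  matrix(as.numeric(out > 0), nrow(mask), ncol(mask))
}

#' Binarize a per-pixel probability map
#'
#' Keeps pixels with probability greater than or equal to the threshold.
#'
#' @param prob_map numeric matrix with values in `[0, 1]`
#' @param cfg a [refine_config()]
#' @return binary mask
#' @export
threshold_prob_mask <- function(prob_map, cfg = refine_config()) {
  if (!is.matrix(prob_map)) stop("prob_map must be a matrix")
  if (length(prob_map) && (min(prob_map) < 0 || max(prob_map) > 1))
    stop("prob_map values must lie in [0, 1]")
  (prob_map >= cfg$prob_threshold) * 1
}

#' Flood-fill mask update: addition and deletion against the ink map
#'
#' Starting from every seed-mask pixel, neighbouring ink pixels are
#' collected until no adjacent ink remains, i.e. the output is the union of
#' all ink connected components (under `cfg$connectivity`) that intersect
#' the seed mask. Seed pixels not supported by ink are deleted. The
#' operation is idempotent. With `cfg$gap_bridge_px > 0`, connectivity is
#' evaluated on an ink map dilated by that many pixels (closing
#' symbol/bond gaps) but the output is still restricted to true ink pixels.
#'
#' @param ink binary ink map of the page (from [binarize_image()])
#' @param seed_mask binary seed mask (typically the thresholded, dilated
#'   model prediction)
#' @param cfg a [refine_config()]
#' @return updated binary mask
#' @export
update_mask <- function(ink, seed_mask, cfg = refine_config()) {
  assert_binary_mask(ink, "ink"); assert_binary_mask(seed_mask, "seed_mask")
  if (!all(dim(ink) == dim(seed_mask)))
    stop("ink and seed_mask must have the same shape")
  conn_map <- ink
  if (cfg$gap_bridge_px > 0L)
    conn_map <- dilate_mask(ink, cfg, side = 2L * cfg$gap_bridge_px + 1L)
  lab <- label_components(conn_map, cfg$connectivity)
  touched <- unique(lab[seed_mask == 1 & lab > 0L])
  if (length(touched) == 0L) return(matrix(0, nrow(ink), ncol(ink)))
  (matrix(lab %in% touched, nrow(ink), ncol(ink)) & ink == 1) * 1
}

#' Remove connected components too small to be structures
#'
#' Components with fewer than `round(min_region_px * H * W / ref_side^2)`
#' pixels are removed (400 at 512 x 512; the cut scales with page area).
#' Components at exactly the threshold are retained.
#'
#' @param mask binary matrix
#' @param cfg a [refine_config()]
#' @return filtered binary mask
#' @export
filter_small_regions <- function(mask, cfg = refine_config()) {
  assert_binary_mask(mask)
  thr <- small_region_threshold(dim(mask), cfg)
  lab <- label_components(mask, cfg$connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= thr)
  (matrix(lab %in% keep, nrow(mask), ncol(mask)) & mask == 1) * 1
}

#' @rdname filter_small_regions
#' @param dims mask dimensions `c(H, W)`
#' @export
small_region_threshold <- function(dims, cfg = refine_config()) {
  max(1L, as.integer(round(cfg$min_region_px * prod(dims) / cfg$ref_side^2)))
}

#' Crop structure regions out of the original page
#'
#' Each region's bounding box is scaled from mask resolution to page
#' resolution (when the mask was computed at a different size), padded by
#' `cfg$crop_pad` and clipped to the page; the crop keeps the source pixels
#' (colour preserved), so the output stays consistent with the input
#' document.
#'
#' @param original_page matrix (grayscale) or H x W x 3 array, 0-255
#' @param regions list of regions from [extract_regions()]
#' @param cfg a [refine_config()]
#' @param mask_dim dimensions `c(H, W)` the mask/regions were computed at;
#'   defaults to the page dimensions (no scaling)
#' @return list with one element per region: `image` (the crop) and `bbox`
#'   (padded, clipped, at page resolution, 0-based half-open)
#' @export
crop_structures <- function(original_page, regions, cfg = refine_config(),
                            mask_dim = NULL) {
  pd <- dim(original_page)[1:2]
  if (is.null(mask_dim)) mask_dim <- pd
  sr <- pd[1] / mask_dim[1]; sc <- pd[2] / mask_dim[2]
  lapply(regions, function(reg) {
    b <- reg$bbox
    r0 <- max(0L, as.integer(floor(b[1] * sr)) - cfg$crop_pad)
    c0 <- max(0L, as.integer(floor(b[2] * sc)) - cfg$crop_pad)
    r1 <- min(pd[1], as.integer(ceiling(b[3] * sr)) + cfg$crop_pad)
    c1 <- min(pd[2], as.integer(ceiling(b[4] * sc)) + cfg$crop_pad)
    img <- if (length(dim(original_page)) == 3L)
      original_page[(r0 + 1L):r1, (c0 + 1L):c1, , drop = FALSE]
    else
      original_page[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE]
    list(image = img, bbox = c(r0, c0, r1, c1))
  })
}

#' Full mask refinement: from probability map to structure regions
#'
#' Fixed order: threshold the probability map; remove table lines from the
#' seed; dilate the seed; binarize the page and remove table lines from the
#' ink; flood-fill update (addition/deletion) of the seed against the ink;
#' small-region filtering; region extraction.
#'
#' @param gray_page grayscale page matrix (0-255), same size as `prob_map`
#' @param prob_map per-pixel structure probability map
#' @param cfg a [refine_config()]
#' @return list with `mask` (refined binary mask), `regions`, and `ink`
#' @export
refine_mask <- function(gray_page, prob_map, cfg = refine_config()) {
  if (!all(dim(gray_page) == dim(prob_map)))
    stop("gray_page and prob_map must have the same shape")
  seed <- threshold_prob_mask(prob_map, cfg)
  seed <- remove_straight_lines(seed, cfg)
  seed <- dilate_mask(seed, cfg)
  ink <- binarize_image(gray_page)
  ink <- remove_straight_lines(ink, cfg)
  mask <- update_mask(ink, seed, cfg)
  mask <- filter_small_regions(mask, cfg)
  list(mask = mask, regions = extract_regions(mask, cfg), ink = ink)
}
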