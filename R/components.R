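#' Label connected components of a binary mask
#'
#' @param mask binary matrix (1 = foreground)
#' @param connectivity 4 or 8 (default 8: bond strokes are often diagonal)
#' @return integer matrix of labels (0 = background)
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_binary_mask(mask)
  storage.mode(mask) <- "integer"
  cpp_label_components(mask, as.integer(connectivity))
}

#' Extract connected regions from a binary mask
#'
#' Regions are maximal connected components under the configured
#' connectivity, pairwise disjoint, and returned sorted by bounding-box
#' (row0, col0). Bounding boxes are 0-based half-open
#' `(row0, col0, row1, col1)`.
#'
#' @param mask binary matrix
#' @param cfg a [refine_config()] (used for `connectivity`)
#' @return list of regions; each has `pixels` (n x 2 matrix of 0-based
#'   row/col), `bbox`, and `pixel_count`
#' @export
extract_regions <- function(mask, cfg = refine_config()) {
  lab <- label_components(mask, cfg$connectivity)
  n <- max(lab)
  if (n == 0L) return(list())
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[idx]
  regions <- lapply(seq_len(n), function(k) {
    px <- idx[labs == k, , drop = FALSE] - 1L  # 0-based
    bbox <- c(min(px[, 1]), min(px[, 2]), max(px[, 1]) + 1L, max(px[, 2]) + 1L)
    structure(list(pixels = unname(px), bbox = unname(bbox),
                   pixel_count = nrow(px)),
              class = "chemseg_region")
  })
  ord <- order(vapply(regions, function(r) r$bbox[1], 0),
               vapply(regions, function(r) r$bbox[2], 0))
  regions[ord]
}

#' @export
print.chemseg_region <- function(x, ...) {
  cat(sprintf("<region> bbox=(%d,%d,%d,%d) pixels=%d\n",
              x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4], x$pixel_count))
  invisible(x)
}
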