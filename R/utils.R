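#' @useDynLib chemseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm
#' @importFrom utils head tail
NULL

the <- new.env(parent = emptyenv())

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library/test code does not disturb
#' the caller's RNG stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Convert an image array to a grayscale matrix
#'
#' Colour arrays (H x W x 3 or H x W x 4) are reduced by the Rec. 601
#' luminance weights; matrices pass through. Values keep their input scale.
#'
#' @param img numeric matrix or 3-d array
#' @return numeric matrix (H x W)
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) return(img[, , 1L])
    return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  }
  stop("img must be a matrix or an H x W x C array")
}

#' Resize an image matrix
#'
#' Wraps `EBImage::resize`. `method = "nearest"` preserves binary values;
#' `"bilinear"` interpolates.
#'
#' @param img numeric matrix
#' @param h,w target dimensions (rows, cols)
#' @param method "bilinear" or "nearest"
#' @return numeric matrix h x w
#' @export
resize_image <- function(img, h, w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (nrow(img) == h && ncol(img) == w) return(img)
  filt <- if (method == "bilinear") "bilinear" else "none"
  out <- EBImage::resize(img, w = h, h = w, filter = filt)
  matrix(as.numeric(out), nrow = h, ncol = w)
}

#' Block-occupancy downsampling of a binary mask
#'
#' Reduces a binary mask to `out_h x out_w` where an output cell is 1 iff
#' any covered input pixel is 1. Used to build training targets at the
#' decoder output stride, where plain subsampling would drop thin strokes.
#'
#' @param mask binary matrix
#' @param out_h,out_w output dimensions
#' @return binary matrix out_h x out_w
#' @export
block_occupancy <- function(mask, out_h, out_w) {
  H <- nrow(mask); W <- ncol(mask)
  gr <- floor((seq_len(H) - 1L) * out_h / H)
  gc <- floor((seq_len(W) - 1L) * out_w / W)
  grp <- outer(gr, gc, function(r, c) r * out_w + c)
  s <- rowsum(as.numeric(mask), group = as.vector(grp))
  out <- matrix(0, out_h, out_w)
  ids <- as.integer(rownames(s))
  out[cbind(ids %/% out_w + 1L, ids %% out_w + 1L)] <- as.numeric(s[, 1] > 0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
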