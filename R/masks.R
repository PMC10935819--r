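#' Binary masks
#'
#' Throughout the package a binary mask is a plain numeric matrix of 0/1
#' with polarity 1 = structure/ink, 0 = background, indexed (row, col),
#' 0-based half-open bounding boxes.
#'
#' @param m numeric matrix
#' @param name argument name used in error messages
#' @return the validated matrix (invisibly its input)
#' @keywords internal
assert_binary_mask <- function(m, name = "mask") {
  if (!is.matrix(m)) stop(name, " must be a matrix")
  if (length(m) && !all(m == 0 | m == 1))
    stop(name, " must contain only 0/1 values")
  invisible(m)
}

#' Read a binary mask from an 8-bit PNG (0/255)
#'
#' @param path PNG file
#' @return binary matrix (1 where the PNG is >= 128)
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  m <- as_gray(m)
  (m >= 0.5) * 1
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask binary matrix
#' @param path output file
#' @export
write_mask_png <- function(mask, path) {
  assert_binary_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Write a grayscale or colour page image (0-255 scale) as PNG
#'
#' @param img matrix or H x W x 3 array with values in 0-255
#' @param path output file
#' @export
write_page_png <- function(img, path) {
  png::writePNG(clamp(img / 255, 0, 1), path)
  invisible(path)
}

#' Read a page image as a 0-255 array
#'
#' Grayscale files give a matrix; colour files an H x W x 3 array.
#' @param path PNG file
#' @return numeric matrix or array, 0-255
#' @export
read_page_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L && dim(m)[3] == 4L) m <- m[, , 1:3, drop = FALSE]
  if (length(dim(m)) == 3L && dim(m)[3] == 1L) m <- m[, , 1L]
  m * 255
}
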