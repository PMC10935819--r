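#' Heuristic structure/non-structure scoring of a segment crop
#'
#' Stand-in for a learned false-positive filter. The score combines two
#' closed-form features of the crop:
#' ink density `d` (fraction of pixels below the crop's mean intensity —
#' the classic "feature density" of rule-based structure finders) and the
#' aspect ratio `a = H/W`. Chemical structure depictions occupy a
#' characteristic low-density band (line drawings), so
#' \deqn{score = exp(-(d - 0.12)^2 / (2 \cdot 0.12^2)) \cdot
#'       exp(-max(0, |log a| - log 3))}
#' with `score = 0` when the crop carries no ink at all. Solid regions
#' (`d` near 1) and extreme aspect ratios score low. Deterministic.
#'
#' @param crop_image grayscale matrix or colour array (0-255)
#' @param threshold decision threshold on the score
#' @return `FilterVerdict`: list with `is_structure`, `score` in `[0,1]`,
#'   `method = "heuristic"`
#' @export
score_segment_heuristic <- function(crop_image, threshold = 0.5) {
  g <- as_gray(crop_image)
  if (length(g) == 0) stop("zero-area crop")
  d <- mean(binarize_image(g))
  score <- if (d == 0) 0 else {
    a <- nrow(g) / ncol(g)
    s_d <- exp(-(d - 0.12)^2 / (2 * 0.12^2))
    s_a <- exp(-max(0, abs(log(a)) - log(3)))
    s_d * s_a
  }
  list(is_structure = score >= threshold, score = score, method = "heuristic")
}

#' Learned filter scaffold (tiny ViT classifier)
#'
#' Pluggable alternative to the heuristic: the crop is resized to the
#' model input size, encoded with the same adapter-ViT scaffold as the
#' segmentation encoder, mean-pooled and mapped to a probability. Useful
#' once trained on labelled crops; an untrained instance is near-chance
#' and the heuristic remains the shipped default.
#'
#' @param model a [build_model()] result used as feature encoder
#' @param w,b optional classifier weights (`neck_dim` vector, scalar)
#' @return a scorer `function(crop_image, threshold)` returning a
#'   `FilterVerdict` with `method = "learned"`
#' @export
make_learned_scorer <- function(model, w = NULL, b = 0) {
  if (is.null(w)) w <- rep(1 / model$cfg$neck_dim, model$cfg$neck_dim)
  function(crop_image, threshold = 0.5) {
    g <- as_gray(crop_image)
    if (length(g) == 0) stop("zero-area crop")
    x <- resize_image(g, model$cfg$image_size, model$cfg$image_size)
    emb <- encode_image(x, model)
    score <- sigmoid(sum(colMeans(emb$grid) * w) + b)
    list(is_structure = score >= threshold, score = score, method = "learned")
  }
}

#' Partition segments into kept structures and rejected non-molecules
#'
#' Applies a scorer to every segment; segments scoring below the
#' threshold are rejected with label `"non-molecule"`. The input order is
#' preserved and kept + rejected always partition the input.
#'
#' @param segments list of crops (each a list with `image`, or a bare
#'   image matrix/array)
#' @param scorer scoring function, default [score_segment_heuristic()]
#' @param threshold decision threshold in `[0, 1]`
#' @return list with `kept` and `rejected`; each element carries its
#'   original `index`, the `verdict`, and (rejected only) `label`
#' @export
filter_segments <- function(segments, scorer = score_segment_heuristic,
                            threshold = 0.5) {
  kept <- list(); rejected <- list()
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    img <- if (is.list(seg) && !is.null(seg$image)) seg$image else seg
    v <- scorer(img, threshold)
    item <- list(index = i, segment = seg, verdict = v)
    if (v$is_structure) kept[[length(kept) + 1L]] <- item
    else {
      item$label <- "non-molecule"
      rejected[[length(rejected) + 1L]] <- item
    }
  }
  list(kept = kept, rejected = rejected)
}
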