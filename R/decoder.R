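#' Encode prompts (dense mask, points, boxes)
#'
#' Dense prompts: a prior mask is pooled to the embedding grid and mapped
#' per-cell through a learned linear embedding; without a prior mask a
#' learned "no-mask" embedding is broadcast over the grid. Sparse prompts:
#' points and box corners are encoded with random Fourier positional
#' features combined with learned per-type embeddings. Free-text prompts
#' are not supported.
#'
#' @param model a [build_model()] result
#' @param points optional n x 2 matrix of (row, col) image coordinates
#' @param boxes optional n x 4 matrix of (row0, col0, row1, col1) boxes
#' @param prior_mask optional binary mask at image resolution
#' @param text unsupported; any value raises an error
#' @return list with `dense` (tokens x neck_dim matrix) and `sparse`
#'   (k x neck_dim matrix, possibly 0-row)
#' @export
encode_prompts <- function(model, points = NULL, boxes = NULL,
                           prior_mask = NULL, text = NULL) {
  if (!is.null(text))
    stop("free-text prompts are unsupported (no text encoder is bundled)")
  cfg <- model$cfg; pr <- model$prompt
  S <- cfg$image_size %/% cfg$patch_size
  TT <- S * S; C <- cfg$neck_dim
  if (is.null(prior_mask)) {
    dense <- matrix(pr$no_mask, TT, C, byrow = TRUE)
  } else {
    if (!all(dim(prior_mask) == cfg$image_size))
      stop("prior_mask must match the model image size")
    m <- block_occupancy(prior_mask, S, S)
    mv <- as.vector(t(m))  # row-major token order
    dense <- outer(mv, pr$mask_w) + matrix(pr$mask_b, TT, C, byrow = TRUE)
  }
  sparse <- matrix(0, 0, C)
  pe <- function(rc) {
    xy <- c(rc[2], rc[1]) / cfg$image_size
    if (any(xy < 0) || any(xy > 1))
      stop("prompt coordinates out of image bounds")
    ang <- 2 * pi * (xy %*% pr$fourier)
    c(sin(ang), cos(ang))
  }
  if (!is.null(points)) {
    points <- rbind(points)
    for (i in seq_len(nrow(points)))
      sparse <- rbind(sparse, pe(points[i, ]) + pr$point_embed)
  }
  if (!is.null(boxes)) {
    boxes <- rbind(boxes)
    for (i in seq_len(nrow(boxes))) {
      sparse <- rbind(sparse, pe(boxes[i, 1:2]) + pr$box_embed[1, ])
      sparse <- rbind(sparse, pe(boxes[i, 3:4]) + pr$box_embed[2, ])
    }
  }
  list(dense = dense, sparse = sparse)
}

# Index map for a k2/s2 transposed convolution: token t of an S x S
# row-major grid feeds output tokens idx[t, 1:4] of the 2S x 2S grid,
# children ordered (0,0), (0,1), (1,0), (1,1) in (row, col) offsets.
upsample_index <- function(S) {
  t <- seq_len(S * S)
  r <- (t - 1) %/% S; c <- (t - 1) %% S
  idx <- matrix(0L, S * S, 4L)
  k <- 0L
  for (dr in 0:1) for (dc in 0:1) {
    k <- k + 1L
    idx[, k] <- (2L * r + dr) * 2L * S + (2L * c + dc) + 1L
  }
  idx
}

# Transposed conv k2/s2 as a per-token linear map to 2x2 output blocks.
upsample_fwd <- function(X, W, b, S) {
  d <- ncol(W) %/% 4L
  Y <- lin(X, W, b)
  idx <- upsample_index(S)
  out <- matrix(0, 4L * nrow(X), d)
  for (k in 1:4) out[idx[, k], ] <- Y[, ((k - 1L) * d + 1L):(k * d)]
  list(Y = out, X = X, idx = idx)
}

upsample_bwd <- function(dOut, cache, W) {
  d <- ncol(dOut)
  dY <- matrix(0, nrow(cache$X), 4L * d)
  for (k in 1:4) dY[, ((k - 1L) * d + 1L):(k * d)] <- dOut[cache$idx[, k], ]
  list(dX = dY %*% t(W), gW = crossprod(cache$X, dY), gb = colSums(dY))
}

decoder_fwd <- function(model, emb, prompts) {
  dec <- model$decoder; S <- emb$S
  Z <- emb$grid + prompts$dense
  g_in <- dec$out_token + colMeans(Z)
  if (nrow(prompts$sparse) > 0) g_in <- g_in + colMeans(prompts$sparse)
  g <- matrix(g_in, 1)
  pre_h <- lin(g, dec$hyper_Wh, dec$hyper_bh)
  h <- pmax(pre_h, 0)
  w_dyn <- lin(h, dec$hyper_Ww, dec$hyper_bw)
  u1 <- upsample_fwd(Z, dec$up1_W, dec$up1_b, S)
  A1 <- gelu(u1$Y)
  u2 <- upsample_fwd(A1, dec$up2_W, dec$up2_b, 2L * S)
  A2 <- gelu(u2$Y)
  logits <- as.vector(A2 %*% t(w_dyn)) + dec$b0
  pre_q <- lin(g, dec$iou_Wq, dec$iou_bq)
  hq <- pmax(pre_q, 0)
  iou <- sigmoid(sum(hq * dec$iou_w) + dec$iou_b)
  list(prob = sigmoid(logits), logits = logits, iou = iou,
       Z = Z, g = g, pre_h = pre_h, h = h, w_dyn = w_dyn,
       u1 = u1, A1 = A1, u2 = u2, A2 = A2)
}

# Backward from d(logits); returns dZ and decoder/prompt parameter grads.
decoder_bwd <- function(model, cache, dlogits) {
  dec <- model$decoder
  dl <- matrix(dlogits, ncol = 1)
  dA2 <- dl %*% cache$w_dyn
  gw_dyn <- crossprod(dl, cache$A2)          # 1 x d2
  gb0 <- sum(dlogits)
  dU2 <- dA2 * gelu_grad(cache$u2$Y)
  b2 <- upsample_bwd(dU2, cache$u2, dec$up2_W)
  dU1 <- b2$dX * gelu_grad(cache$u1$Y)
  b1 <- upsample_bwd(dU1, cache$u1, dec$up1_W)
  dh <- gw_dyn %*% t(dec$hyper_Ww)
  gWw <- crossprod(cache$h, gw_dyn)
  gbw <- as.vector(gw_dyn)
  dpre_h <- dh * (cache$pre_h > 0)
  gWh <- crossprod(cache$g, dpre_h)
  gbh <- as.vector(dpre_h)
  dg <- as.vector(dpre_h %*% t(dec$hyper_Wh))
  TT <- nrow(cache$Z)
  dZ <- b1$dX + matrix(dg / TT, TT, length(dg), byrow = TRUE)
  list(dZ = dZ,
       decoder = list(out_token = dg,
                      up1_W = b1$gW, up1_b = b1$gb,
                      up2_W = b2$gW, up2_b = b2$gb,
                      hyper_Wh = gWh, hyper_bh = gbh,
                      hyper_Ww = gWw, hyper_bw = gbw, b0 = gb0),
       prompt = list(no_mask = colSums(dZ)))
}

#' Decode a mask prediction from an image embedding and prompts
#'
#' Element-wise sum of the dense prompt embedding and the image embedding;
#' a learned output token (pooled with the embedding and any sparse
#' prompts) passes through an MLP to a dynamic per-pixel linear
#' classifier; the embedding is upsampled 4x by two transposed
#' convolutions; sigmoid outputs give per-pixel structure probabilities
#' and a predicted-IoU scalar.
#'
#' @param img_emb output of [encode_image()]
#' @param prompts output of [encode_prompts()]
#' @param model a [build_model()] result
#' @return list with `prob_map` (a `4*S` x `4*S` matrix of values in
#'   `[0, 1]`) and `iou_estimate` (scalar in `[0, 1]`)
#' @export
decode_mask <- function(img_emb, prompts, model) {
  if (!all(dim(prompts$dense) == dim(img_emb$grid)))
    stop("prompt dense embedding shape does not match the image embedding")
  out <- decoder_fwd(model, img_emb, prompts)
  side <- 4L * img_emb$S
  list(prob_map = matrix(out$prob, side, side, byrow = TRUE),
       iou_estimate = out$iou)
}

#' Predict a structure probability map for a page of any size
#'
#' The page is converted to grayscale, resized to the model input size,
#' passed through the encoder and no-prompt decoder, and the probability
#' map is resized back to the page resolution.
#'
#' @param image page matrix or H x W x 3 array (0-255), or a PNG path
#' @param model a `chemseg_model` or a checkpoint from [train_adapters()]
#' @return probability matrix at the input page resolution
#' @export
predict_page_mask <- function(image, model) {
  if (is.character(image)) image <- read_page_png(image)
  if (inherits(model, "chemseg_checkpoint")) model <- model$model
  g <- as_gray(image)
  cfg <- model$cfg
  x <- resize_image(g, cfg$image_size, cfg$image_size, "bilinear")
  emb <- encode_image(x, model)
  pred <- decode_mask(emb, encode_prompts(model), model)
  clamp(resize_image(pred$prob_map, nrow(g), ncol(g), "bilinear"), 0, 1)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding the full parameter
#' set with its embedded [encoder_config()] (and, after training, the
#' training history).
#'
#' @param ckpt a `chemseg_model` or `chemseg_checkpoint`
#' @param path file path
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
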