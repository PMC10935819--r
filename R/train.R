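#' Adapter training (frozen backbone)
#'
#' Trains only the adapters, the mask decoder, and the dense prompt
#' embedding with SGD + momentum on a per-pixel binary cross-entropy loss
#' over sigmoid outputs; every backbone parameter (patch embedding,
#' positional embedding, attention, MLP, layer norms, neck) is frozen.
#' Training targets are ground-truth masks occupancy-pooled to the
#' decoder output resolution.
#'
#' @name training
NULL

# Paths (list-index chains) of every trainable parameter.
trainable_paths <- function(model) {
  paths <- list()
  for (bn in names(model$adapters))
    for (an in c("a1", "a2"))
      for (pn in c("Wd", "bd", "Wu", "bu"))
        paths[[length(paths) + 1L]] <- c("adapters", bn, an, pn)
  for (pn in c("out_token", "up1_W", "up1_b", "up2_W", "up2_b",
               "hyper_Wh", "hyper_bh", "hyper_Ww", "hyper_bw", "b0"))
    paths[[length(paths) + 1L]] <- c("decoder", pn)
  paths[[length(paths) + 1L]] <- c("prompt", "no_mask")
  paths
}

path_key <- function(p) paste(p, collapse = "/")

# Forward + backward for one image; returns loss and grads keyed by path.
grad_one <- function(model, image, target_vec) {
  enc <- encoder_fwd(model, image, cache = TRUE)
  prompts <- encode_prompts(model)
  dc <- decoder_fwd(model, enc, prompts)
  p <- clamp(dc$prob, 1e-7, 1 - 1e-7)
  y <- target_vec
  loss <- -sum(y * log(p) + (1 - y) * log(1 - p))
  dlogits <- dc$prob - y
  db <- decoder_bwd(model, dc, dlogits)
  ag <- encoder_bwd(db$dZ, enc, model)
  g <- list()
  for (bn in names(ag))
    for (an in c("a1", "a2")) {
      gg <- ag[[bn]][[an]]
      g[[path_key(c("adapters", bn, an, "Wd"))]] <- gg$gWd
      g[[path_key(c("adapters", bn, an, "bd"))]] <- gg$gbd
      g[[path_key(c("adapters", bn, an, "Wu"))]] <- gg$gWu
      g[[path_key(c("adapters", bn, an, "bu"))]] <- gg$gbu
    }
  for (pn in names(db$decoder))
    g[[path_key(c("decoder", pn))]] <- db$decoder[[pn]]
  g[[path_key(c("prompt", "no_mask"))]] <- db$prompt$no_mask
  list(loss = loss, grads = g, prob = dc$prob)
}

# Resize a page and pool its mask to the decoder output grid (row-major
# vector), the representation the loss is computed in.
prepare_pair <- function(pair, cfg) {
  g <- as_gray(pair$page)
  img <- resize_image(g, cfg$image_size, cfg$image_size, "bilinear")
  out <- 4L * (cfg$image_size %/% cfg$patch_size)
  tgt <- block_occupancy(pair$mask, out, out)
  list(image = img, target = as.vector(t(tgt)), target_mat = tgt)
}

#' Train adapters, decoder, and prompt embedding on page/mask pairs
#'
#' @param pairs list of pairs, each a list with `page` (grayscale matrix,
#'   0-255) and `mask` (binary matrix); any resolution
#' @param model a [build_model()] result (or a previous checkpoint)
#' @param tcfg a [train_config()]
#' @return object of class `chemseg_checkpoint`: the trained `model`,
#'   per-step `history` (loss), and `tcfg`
#' @export
train_adapters <- function(pairs, model, tcfg = train_config()) {
  if (inherits(model, "chemseg_checkpoint")) model <- model$model
  if (length(pairs) == 0) stop("empty training dataset")
  steps <- tcfg$steps
  if (is.null(steps)) {
    if (is.null(tcfg$epochs)) stop("train_config needs steps or epochs")
    steps <- tcfg$epochs * ceiling(length(pairs) / tcfg$batch_size)
  }
  prep <- lapply(pairs, prepare_pair, cfg = model$cfg)
  paths <- trainable_paths(model)
  keys <- vapply(paths, path_key, "")
  vel <- lapply(paths, function(p) {
    v <- model[[p]]; v[] <- 0; v
  })
  names(vel) <- keys
  history <- numeric(steps)
  local_seed(tcfg$seed, {
    for (step in seq_len(steps)) {
      idx <- sample.int(length(prep), tcfg$batch_size,
                        replace = length(prep) < tcfg$batch_size)
      acc <- NULL; loss <- 0
      for (i in idx) {
        gi <- grad_one(model, prep[[i]]$image, prep[[i]]$target)
        loss <- loss + gi$loss
        acc <- if (is.null(acc)) gi$grads
               else mapply(`+`, acc, gi$grads, SIMPLIFY = FALSE)
      }
      loss <- loss / length(idx)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at step ", step)
      history[step] <- loss
      gnorm <- sqrt(sum(vapply(acc, function(x)
        sum((x / length(idx))^2), 0)))
      scale <- if (gnorm > tcfg$clip_norm) tcfg$clip_norm / gnorm else 1
      for (k in seq_along(paths)) {
        gk <- acc[[keys[k]]] / length(idx) * scale
        vel[[keys[k]]] <- tcfg$momentum * vel[[keys[k]]] -
          tcfg$learning_rate * gk
        model[[paths[[k]]]] <- model[[paths[[k]]]] + vel[[keys[k]]]
      }
    }
  })
  structure(list(model = model, history = history, tcfg = tcfg),
            class = "chemseg_checkpoint")
}

#' Mean training IoU of a model over page/mask pairs
#'
#' Predictions are thresholded at 0.5 and compared with the
#' occupancy-pooled targets at the decoder output resolution.
#'
#' @param model `chemseg_model` or checkpoint
#' @param pairs as in [train_adapters()]
#' @return mean intersection-over-union
#' @export
mean_train_iou <- function(model, pairs) {
  if (inherits(model, "chemseg_checkpoint")) model <- model$model
  ious <- vapply(pairs, function(pair) {
    pp <- prepare_pair(pair, model$cfg)
    enc <- encoder_fwd(model, pp$image)
    dc <- decoder_fwd(model, enc, encode_prompts(model))
    pred <- dc$prob >= 0.5
    y <- pp$target > 0
    u <- sum(pred | y)
    if (u == 0) 1 else sum(pred & y) / u
  }, 0)
  mean(ious)
}

#' Checksum of the frozen backbone parameters
#'
#' Training must leave the backbone untouched; equal hashes before and
#' after a run certify the frozen contract.
#'
#' @param model `chemseg_model` or checkpoint
#' @return md5 string
#' @export
backbone_hash <- function(model) {
  if (inherits(model, "chemseg_checkpoint")) model <- model$model
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(model$backbone, tmp, compress = FALSE)
  unname(tools::md5sum(tmp))
}
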