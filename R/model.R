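#' Encoder/model configuration
#'
#' Architecture hyperparameters of the adapter-augmented ViT segmentation
#' model. The default is a desk-scale "tiny" configuration (64-px images,
#' 2 blocks) used throughout the test-suite; [encoder_config_base()] gives
#' the full-scale configuration (512-px images, 12 blocks, two adapters
#' per block) matching the production architecture. Every configuration
#' obeys the same shape algebra: the token grid is
#' `image_size / patch_size` per side and the decoder output is 4x the
#' grid resolution.
#'
#' @param image_size model input side (pixels); must be divisible by
#'   `patch_size`
#' @param patch_size ViT patch side
#' @param embed_dim token embedding width
#' @param n_blocks number of encoder blocks (each carries two adapters:
#'   one after multi-head attention, one before the MLP sublayer)
#' @param n_heads attention heads (`embed_dim` divisible by `n_heads`)
#' @param adapter_dim adapter bottleneck width (< `embed_dim`)
#' @param neck_dim channels of the final image embedding
#' @param mlp_ratio MLP hidden width multiplier
#' @param dec_dim1,dec_dim2 channels after the first/second transposed
#'   convolution of the mask decoder
#' @return object of class `chemseg_encoder_config`
#' @export
encoder_config <- function(image_size = 64L, patch_size = 8L,
                           embed_dim = 48L, n_blocks = 2L, n_heads = 4L,
                           adapter_dim = 8L, neck_dim = 48L, mlp_ratio = 4L,
                           dec_dim1 = 32L, dec_dim2 = 16L) {
  stopifnot(image_size %% patch_size == 0, n_blocks >= 1,
            adapter_dim < embed_dim, embed_dim %% n_heads == 0,
            dec_dim1 >= 1, dec_dim2 >= 1)
  structure(list(image_size = as.integer(image_size),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 adapter_dim = as.integer(adapter_dim),
                 neck_dim = as.integer(neck_dim),
                 mlp_ratio = as.integer(mlp_ratio),
                 dec_dim1 = as.integer(dec_dim1),
                 dec_dim2 = as.integer(dec_dim2),
                 adapters_per_block = 2L),
            class = "chemseg_encoder_config")
}

#' @rdname encoder_config
#' @export
encoder_config_base <- function() {
  encoder_config(image_size = 512L, patch_size = 16L, embed_dim = 768L,
                 n_blocks = 12L, n_heads = 12L, adapter_dim = 64L,
                 neck_dim = 256L, dec_dim1 = 64L, dec_dim2 = 32L)
}

#' Training configuration
#'
#' @param batch_size images per gradient step
#' @param learning_rate SGD learning rate
#' @param momentum SGD momentum
#' @param steps number of gradient steps; if `NULL`, derived from `epochs`
#' @param epochs passes over the dataset (used when `steps` is `NULL`)
#' @param clip_norm global gradient-norm clip. The loss is the per-image
#'   *sum* of pixel cross-entropies (averaged over the batch); clipping
#'   keeps SGD + momentum stable under that scaling
#' @param seed RNG seed for batching
#' @return object of class `chemseg_train_config`
#' @export
train_config <- function(batch_size = 4L, learning_rate = 0.001,
                         momentum = 0.9, steps = 200L, epochs = NULL,
                         clip_norm = 50, seed = 0L) {
  stopifnot(batch_size >= 1, learning_rate > 0, momentum >= 0, momentum < 1,
            clip_norm > 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 steps = if (is.null(steps)) NULL else as.integer(steps),
                 epochs = if (is.null(epochs)) NULL else as.integer(epochs),
                 clip_norm = clip_norm,
                 seed = as.integer(seed), loss = "pixelwise_bce_sum"),
            class = "chemseg_train_config")
}

# ---- initialization -----------------------------------------------------

rmat <- function(nr, nc, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / nr)
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

init_adapter <- function(D, r) {
  list(Wd = rmat(D, r, sd = 0.02), bd = numeric(r),
       Wu = matrix(0, r, D), bu = numeric(D))  # zero up-projection: identity
}

#' Build a model with random (or zero-adapter) initialization
#'
#' Adapter up-projections initialize to zero, so a freshly built model's
#' encoder reproduces its frozen backbone exactly; training moves only the
#' adapters, the prompt embeddings, and the mask decoder.
#'
#' @param cfg an [encoder_config()]
#' @param seed RNG seed for the initialization
#' @return object of class `chemseg_model`
#' @export
build_model <- function(cfg = encoder_config(), seed = 0L) {
  local_seed(seed, {
    D <- cfg$embed_dim; C <- cfg$neck_dim; r <- cfg$adapter_dim
    S <- cfg$image_size %/% cfg$patch_size; TT <- S * S
    Hd <- cfg$mlp_ratio * D
    ps2 <- cfg$patch_size^2
    backbone <- list(
      patch_W = rmat(ps2, D), patch_b = numeric(D),
      pos = rmat(TT, D, sd = 0.02),
      blocks = lapply(seq_len(cfg$n_blocks), function(k) list(
        ln1_g = rep(1, D), ln1_b = numeric(D),
        Wq = rmat(D, D), bq = numeric(D),
        Wk = rmat(D, D), bk = numeric(D),
        Wv = rmat(D, D), bv = numeric(D),
        Wo = rmat(D, D), bo = numeric(D),
        ln2_g = rep(1, D), ln2_b = numeric(D),
        W1 = rmat(D, Hd), b1 = numeric(Hd),
        W2 = rmat(Hd, D), b2 = numeric(D))),
      neck = list(W1 = rmat(D, C), b1 = numeric(C),
                  ln1_g = rep(1, C), ln1_b = numeric(C),
                  W2 = rmat(C, C), b2 = numeric(C),
                  ln2_g = rep(1, C), ln2_b = numeric(C)))
    names(backbone$blocks) <- paste0("b", seq_len(cfg$n_blocks))
    adapters <- lapply(seq_len(cfg$n_blocks), function(k)
      list(a1 = init_adapter(D, r), a2 = init_adapter(D, r)))
    names(adapters) <- paste0("b", seq_len(cfg$n_blocks))
    prompt <- list(no_mask = stats::rnorm(C, sd = 0.02),
                   mask_w = stats::rnorm(C, sd = 0.02), mask_b = numeric(C),
                   fourier = matrix(stats::rnorm(2 * (C %/% 2)), 2, C %/% 2),
                   point_embed = stats::rnorm(C, sd = 0.02),
                   box_embed = rmat(2, C, sd = 0.02))
    decoder <- list(out_token = stats::rnorm(C, sd = 0.02),
                    up1_W = rmat(C, 4L * cfg$dec_dim1),
                    up1_b = numeric(4L * cfg$dec_dim1),
                    up2_W = rmat(cfg$dec_dim1, 4L * cfg$dec_dim2),
                    up2_b = numeric(4L * cfg$dec_dim2),
                    hyper_Wh = rmat(C, C), hyper_bh = numeric(C),
                    hyper_Ww = rmat(C, cfg$dec_dim2), hyper_bw = numeric(cfg$dec_dim2),
                    b0 = 0,
                    iou_Wq = rmat(C, C %/% 2), iou_bq = numeric(C %/% 2),
                    iou_w = stats::rnorm(C %/% 2, sd = 0.02), iou_b = 0)
    structure(list(cfg = cfg, backbone = backbone, adapters = adapters,
                   prompt = prompt, decoder = decoder),
              class = "chemseg_model")
  })
}

# ---- primitive layers ---------------------------------------------------

gelu <- function(x) 0.5 * x * (1 + tanh(0.7978845608 * (x + 0.044715 * x^3)))

gelu_grad <- function(x) {
  u <- 0.7978845608 * (x + 0.044715 * x^3)
  t <- tanh(u)
  0.5 * (1 + t) + 0.5 * x * (1 - t^2) * 0.7978845608 * (1 + 3 * 0.044715 * x^2)
}

sigmoid <- function(x) 1 / (1 + exp(-clamp(x, -40, 40)))

lin <- function(X, W, b) sweep(X %*% W, 2, b, "+")

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd
  list(Y = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"), xhat = xhat, sd = sd, g = g)
}

ln_bwd <- function(dY, cache) {
  dxhat <- sweep(dY, 2, cache$g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  (dxhat - m1 - cache$xhat * m2) / cache$sd
}

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

#' Adapter forward pass
#'
#' Residual bottleneck: `x + up(ReLU(down(x)))`. With a zero-initialized
#' up-projection the adapter is the identity, so inserting untrained
#' adapters leaves the frozen backbone unchanged.
#'
#' @param x token embedding matrix (tokens x embed_dim)
#' @param p adapter parameters (`Wd`, `bd`, `Wu`, `bu`)
#' @return matrix of the same shape as `x`
#' @export
adapter_forward <- function(x, p) {
  if (!is.matrix(x) || ncol(x) != nrow(p$Wd))
    stop("x must be a token matrix with ", nrow(p$Wd), " columns")
  adapter_fwd(x, p)$Y
}

adapter_fwd <- function(X, p) {
  pre <- lin(X, p$Wd, p$bd)
  Hr <- pmax(pre, 0)
  Y <- X + sweep(Hr %*% p$Wu, 2, p$bu, "+")
  list(Y = Y, X = X, pre = pre, Hr = Hr)
}

adapter_bwd <- function(dY, cache, p) {
  dHr <- dY %*% t(p$Wu)
  dpre <- dHr * (cache$pre > 0)
  list(dX = dY + dpre %*% t(p$Wd),
       gWd = crossprod(cache$X, dpre), gbd = colSums(dpre),
       gWu = crossprod(cache$Hr, dY), gbu = colSums(dY))
}

attn_fwd <- function(X, bp, nh) {
  D <- ncol(X); dh <- D %/% nh
  Q <- lin(X, bp$Wq, bp$bq); K <- lin(X, bp$Wk, bp$bk); V <- lin(X, bp$Wv, bp$bv)
  O <- matrix(0, nrow(X), D)
  A <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    A[[h]] <- softmax_rows(S)
    O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
  }
  list(Y = lin(O, bp$Wo, bp$bo), Q = Q, K = K, V = V, A = A, O = O)
}

attn_bwd <- function(dY, cache, bp, nh) {
  D <- ncol(dY); dh <- D %/% nh
  dO <- dY %*% t(bp$Wo)
  dQ <- matrix(0, nrow(dY), D); dK <- dQ; dV <- dQ
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, cols] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  dQ %*% t(bp$Wq) + dK %*% t(bp$Wk) + dV %*% t(bp$Wv)
}

mlp_fwd <- function(X, bp) {
  H1 <- lin(X, bp$W1, bp$b1)
  G <- gelu(H1)
  list(Y = lin(G, bp$W2, bp$b2), X = X, H1 = H1, G = G)
}

mlp_bwd <- function(dY, cache, bp) {
  dG <- dY %*% t(bp$W2)
  dH1 <- dG * gelu_grad(cache$H1)
  dH1 %*% t(bp$W1)
}

# One encoder block: adapter 1 after multi-head attention, adapter 2
# before the MLP sublayer.
block_fwd <- function(X, bp, ap, nh) {
  l1 <- ln_fwd(X, bp$ln1_g, bp$ln1_b)
  at <- attn_fwd(l1$Y, bp, nh)
  a1 <- adapter_fwd(at$Y, ap$a1)
  X1 <- X + a1$Y
  l2 <- ln_fwd(X1, bp$ln2_g, bp$ln2_b)
  a2 <- adapter_fwd(l2$Y, ap$a2)
  ml <- mlp_fwd(a2$Y, bp)
  list(Y = X1 + ml$Y, l1 = l1, at = at, a1 = a1, X1 = X1,
       l2 = l2, a2 = a2, ml = ml)
}

block_bwd <- function(dY, cache, bp, ap, nh) {
  dml <- mlp_bwd(dY, cache$ml, bp)
  a2b <- adapter_bwd(dml, cache$a2, ap$a2)
  dX1 <- dY + ln_bwd(a2b$dX, cache$l2)
  a1b <- adapter_bwd(dX1, cache$a1, ap$a1)
  dat <- attn_bwd(a1b$dX, cache$at, bp, nh)
  dX <- dX1 + ln_bwd(dat, cache$l1)
  list(dX = dX, a1 = a1b[c("gWd", "gbd", "gWu", "gbu")],
       a2 = a2b[c("gWd", "gbd", "gWu", "gbu")])
}

# ---- patching and the encoder -------------------------------------------

# Image matrix (is x is) -> patch matrix (S^2 x ps^2), tokens row-major.
patchify <- function(img, ps) {
  H <- nrow(img)
  S <- H %/% ps
  a <- array(img, c(ps, S, ps, S))
  matrix(aperm(a, c(4, 2, 1, 3)), nrow = S * S)
}

# Normalize a 0-255 page to model input scale: ink positive, background 0.
normalize_input <- function(img) {
  if (max(img) > 1.5) img <- img / 255
  1 - img
}

encoder_fwd <- function(model, image, cache = FALSE) {
  cfg <- model$cfg
  if (!all(dim(image)[1:2] == cfg$image_size))
    stop("image must be ", cfg$image_size, " x ", cfg$image_size,
         " (resizing is the caller's responsibility)")
  img <- as_gray(image)
  x <- normalize_input(img)
  P <- patchify(x, cfg$patch_size)
  X <- lin(P, model$backbone$patch_W, model$backbone$patch_b) + model$backbone$pos
  blocks <- vector("list", cfg$n_blocks)
  for (k in seq_len(cfg$n_blocks)) {
    bc <- block_fwd(X, model$backbone$blocks[[k]], model$adapters[[k]], cfg$n_heads)
    blocks[[k]] <- bc
    X <- bc$Y
  }
  nk <- model$backbone$neck
  H1 <- lin(X, nk$W1, nk$b1)
  L1 <- ln_fwd(H1, nk$ln1_g, nk$ln1_b)
  H2 <- lin(L1$Y, nk$W2, nk$b2)
  L2 <- ln_fwd(H2, nk$ln2_g, nk$ln2_b)
  S <- cfg$image_size %/% cfg$patch_size
  out <- list(grid = L2$Y, S = S, dim = cfg$neck_dim)
  if (cache) out$cache <- list(blocks = blocks, L1 = L1, L2 = L2, Xin = P)
  out
}

encoder_bwd <- function(dgrid, enc, model) {
  nk <- model$backbone$neck
  cfg <- model$cfg
  dH2 <- ln_bwd(dgrid, enc$cache$L2)
  dL1 <- dH2 %*% t(nk$W2)
  dX <- ln_bwd(dL1, enc$cache$L1) %*% t(nk$W1)
  grads <- vector("list", cfg$n_blocks)
  for (k in rev(seq_len(cfg$n_blocks))) {
    bb <- block_bwd(dX, enc$cache$blocks[[k]], model$backbone$blocks[[k]],
                    model$adapters[[k]], cfg$n_heads)
    dX <- bb$dX
    grads[[k]] <- list(a1 = bb$a1, a2 = bb$a2)
  }
  names(grads) <- paste0("b", seq_len(cfg$n_blocks))
  grads
}

#' Encode an image into the model's embedding grid
#'
#' @param image grayscale matrix or H x W x 3 array, exactly
#'   `image_size` per side (the caller resizes)
#' @param model a [build_model()] result
#' @return image embedding: list with `grid`
#'   (`(image_size/patch_size)^2` x `neck_dim` matrix, tokens row-major),
#'   `S` (grid side), `dim`
#' @export
encode_image <- function(image, model) {
  enc <- encoder_fwd(model, image, cache = FALSE)
  enc[c("grid", "S", "dim")]
}
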