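test_that("adapter is residual and identity at zero initialization", {
  set.seed(71)
  p <- list(Wd = matrix(rnorm(16 * 4), 16, 4), bd = rnorm(4),
            Wu = matrix(0, 4, 16), bu = rep(0, 16))
  x <- matrix(rnorm(10 * 16), 10, 16)
  expect_equal(adapter_forward(x, p), x)
  # zero input with zero biases stays zero
  p0 <- list(Wd = matrix(rnorm(16 * 4), 16, 4), bd = rep(0, 4),
             Wu = matrix(rnorm(4 * 16), 4, 16), bu = rep(0, 16))
  expect_equal(adapter_forward(matrix(0, 3, 16), p0), matrix(0, 3, 16))
  expect_error(adapter_forward(matrix(0, 3, 8), p), "16 columns")
})

test_that("adapter output matches an explicit loop-based oracle", {
  set.seed(72)
  p <- list(Wd = matrix(rnorm(16 * 4), 16, 4), bd = rnorm(4),
            Wu = matrix(rnorm(4 * 16), 4, 16), bu = rnorm(16))
  x <- matrix(rnorm(6 * 16), 6, 16)
  got <- adapter_forward(x, p)
  want <- x * 0
  for (i in seq_len(nrow(x))) {
    h <- numeric(4)
    for (j in 1:4) h[j] <- max(0, sum(x[i, ] * p$Wd[, j]) + p$bd[j])
    for (j in 1:16) want[i, j] <- x[i, j] + sum(h * p$Wu[, j]) + p$bu[j]
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("encoder and decoder obey the shape algebra for any config", {
  for (cfg in list(encoder_config(),
                   encoder_config(image_size = 96, patch_size = 8,
                                  embed_dim = 32, n_blocks = 2, n_heads = 4,
                                  adapter_dim = 8, neck_dim = 24,
                                  dec_dim1 = 16, dec_dim2 = 8))) {
    m <- build_model(cfg, seed = 1)
    S <- cfg$image_size / cfg$patch_size
    img <- matrix(runif(cfg$image_size^2, 0, 255),
                  cfg$image_size, cfg$image_size)
    emb <- encode_image(img, m)
    expect_equal(emb$S, S)
    expect_equal(dim(emb$grid), c(S * S, cfg$neck_dim))
    pred <- decode_mask(emb, encode_prompts(m), m)
    expect_equal(dim(pred$prob_map), c(4 * S, 4 * S))
    expect_gte(min(pred$prob_map), 0)
    expect_lte(max(pred$prob_map), 1)
    expect_gte(pred$iou_estimate, 0)
    expect_lte(pred$iou_estimate, 1)
  }
  m <- build_model(encoder_config(), seed = 1)
  expect_error(encode_image(matrix(0, 32, 32), m), "caller")
})

test_that("zero-initialized adapters reproduce the frozen backbone exactly", {
  cfg <- encoder_config()
  m <- build_model(cfg, seed = 3)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  base <- encode_image(img, m)
  # perturb only down-projections: with zero up-projections the encoder
  # output must be bit-identical
  m2 <- m
  set.seed(73)
  for (b in names(m2$adapters)) {
    m2$adapters[[b]]$a1$Wd[] <- rnorm(length(m2$adapters[[b]]$a1$Wd))
    m2$adapters[[b]]$a2$bd[] <- rnorm(length(m2$adapters[[b]]$a2$bd))
  }
  expect_identical(encode_image(img, m2)$grid, base$grid)
})

test_that("prompt encoding covers dense defaults, points, boxes, errors", {
  m <- build_model(encoder_config(), seed = 4)
  S <- 8
  pr <- encode_prompts(m)
  expect_equal(dim(pr$dense), c(S * S, m$cfg$neck_dim))
  expect_equal(nrow(pr$sparse), 0L)
  # no-prompt dense grid is the learned embedding broadcast
  expect_true(all(apply(pr$dense, 2, function(col) length(unique(col)) == 1)))
  p1 <- encode_prompts(m, points = c(10, 20))
  expect_equal(nrow(p1$sparse), 1L)
  p2 <- encode_prompts(m, points = rbind(c(10, 20), c(10, 20)))
  expect_equal(p2$sparse[1, ], p2$sparse[2, ])
  pb <- encode_prompts(m, boxes = c(1, 1, 30, 30))
  expect_equal(nrow(pb$sparse), 2L)
  expect_error(encode_prompts(m, points = c(100, 10)), "bounds")
  expect_error(encode_prompts(m, text = "a molecule"), "unsupported")
  pm <- encode_prompts(m, prior_mask = matrix(1, 64, 64))
  expect_equal(dim(pm$dense), c(S * S, m$cfg$neck_dim))
})

test_that("inference is deterministic at any page size", {
  m <- build_model(encoder_config(), seed = 5)
  set.seed(74)
  page <- matrix(runif(96 * 128, 0, 255), 96, 128)
  p1 <- predict_page_mask(page, m)
  p2 <- predict_page_mask(page, m)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(96, 128))
  blank <- matrix(255, 70, 50)
  pb <- predict_page_mask(blank, m)
  expect_true(all(is.finite(pb)))
  expect_gte(min(pb), 0); expect_lte(max(pb), 1)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 6)
  set.seed(75)
  for (b in names(m$adapters)) for (a in c("a1", "a2")) {
    m$adapters[[b]][[a]]$Wu[] <- rnorm(length(m$adapters[[b]][[a]]$Wu), sd = 0.1)
  }
  img <- matrix(runif(16 * 16, 0, 255), 16, 16)
  y <- as.numeric(runif(64) > 0.7)
  lossfn <- function(model) {
    enc <- chemseg:::encoder_fwd(model, img, cache = TRUE)
    dc <- chemseg:::decoder_fwd(model, enc, encode_prompts(model))
    p <- pmin(pmax(dc$prob, 1e-7), 1 - 1e-7)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  g <- chemseg:::grad_one(m, img, y)
  eps <- 1e-5
  checks <- list(list(c("adapters", "b1", "a1", "Wd"), 3),
                 list(c("adapters", "b1", "a2", "Wu"), 5),
                 list(c("decoder", "up1_W"), 7),
                 list(c("decoder", "hyper_Ww"), 2),
                 list(c("decoder", "out_token"), 1),
                 list(c("prompt", "no_mask"), 4))
  for (ch in checks) {
    path <- ch[[1]]; k <- ch[[2]]
    analytic <- g$grads[[paste(path, collapse = "/")]][k]
    m1 <- m; m1[[path]][k] <- m1[[path]][k] + eps
    m2 <- m; m2[[path]][k] <- m2[[path]][k] - eps
    numeric <- (lossfn(m1) - lossfn(m2)) / (2 * eps)
    expect_equal(analytic, numeric, tolerance = 1e-4)
  }
})
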