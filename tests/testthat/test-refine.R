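test_that("mean-threshold binarization follows its definition", {
  expect_equal(binarize_image(matrix(255, 4, 4)), matrix(0, 4, 4))
  page <- matrix(c(0, 255, 255, 255), 2, 2, byrow = TRUE)
  expect_equal(binarize_image(page),
               matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE))
  # constant page: nothing strictly below the mean
  expect_equal(binarize_image(matrix(7, 3, 3)), matrix(0, 3, 3))
  # uniform offset shifts the mean with the data: identical ink map
  set.seed(51)
  pg <- matrix(sample(c(20, 60, 210, 230), 64, TRUE), 8, 8)
  expect_equal(binarize_image(pg), binarize_image(pg + 20))
})

test_that("long straight lines are removed; blobs and diagonals survive", {
  cfg <- refine_config()
  expect_equal(remove_straight_lines(matrix(0, 32, 32), cfg),
               matrix(0, 32, 32))
  m <- matrix(0, 512, 512)
  m[100:101, ] <- 1                       # full-width 2 px horizontal line
  m[200:229, 50:79] <- 1                  # 30 x 30 blob
  out <- remove_straight_lines(m, cfg)
  expect_equal(sum(out[200:229, 50:79]), 900)
  expect_equal(sum(out[100:101, ]), 0)
  # vertical line likewise
  mv <- matrix(0, 512, 512); mv[, 300] <- 1
  expect_equal(sum(remove_straight_lines(mv, cfg)), 0)
  # a 45-degree diagonal is untouched
  d <- matrix(0, 512, 512)
  d[cbind(1:512, 1:512)] <- 1
  expect_equal(remove_straight_lines(d, cfg), d)
})

test_that("line removal never adds pixels and respects the gap rule", {
  cfg <- refine_config()
  # co-linear short dashes with large gaps survive
  m <- matrix(0, 512, 512)
  for (s in seq(1, 450, by = 60)) m[250, s:(s + 20)] <- 1
  expect_equal(remove_straight_lines(m, cfg), m)
  set.seed(52)
  r <- matrix(as.numeric(runif(128 * 128) < 0.2), 128, 128)
  out <- remove_straight_lines(r, cfg)
  expect_true(all(out <= r))
})

test_that("dilation grows by the scaled square kernel", {
  cfg <- refine_config()
  expect_equal(dilate_mask(matrix(0, 16, 16), cfg), matrix(0, 16, 16))
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  out <- dilate_mask(m, cfg)   # side max(3, round(0.01*9)) = 3
  expect_equal(sum(out), 9)
  expect_equal(out[4:6, 4:6], matrix(1, 3, 3))
  # two pixels two apart become one component
  m2 <- matrix(0, 9, 9); m2[5, 3] <- 1; m2[5, 6] <- 1
  out2 <- dilate_mask(m2, cfg)
  expect_equal(max(label_components(out2, 8)), 1L)
  # monotone: never removes pixels
  set.seed(53)
  r <- matrix(as.numeric(runif(64 * 64) < 0.1), 64, 64)
  expect_true(all(dilate_mask(r, cfg) >= r))
  # 512-scale kernel is 5: a pixel grows to 25
  big <- matrix(0, 512, 512); big[256, 256] <- 1
  expect_equal(sum(dilate_mask(big, cfg)), 25)
})

test_that("probability thresholding keeps the >= convention", {
  cfg <- refine_config(prob_threshold = 0.5)
  expect_equal(threshold_prob_mask(matrix(0, 4, 4), cfg), matrix(0, 4, 4))
  expect_equal(threshold_prob_mask(matrix(0.5, 2, 2), cfg), matrix(1, 2, 2))
  set.seed(54)
  p <- matrix(runif(100), 10, 10)
  loop <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) loop[i, j] <- as.numeric(p[i, j] >= 0.5)
  expect_equal(threshold_prob_mask(p, cfg), loop)
  expect_error(threshold_prob_mask(matrix(1.2, 2, 2), cfg), "\\[0, 1\\]")
})

test_that("mask update adds touched components and deletes the rest", {
  cfg <- refine_config()
  ink <- matrix(0, 30, 30)
  ink[5:14, 5:14] <- 1        # blob A
  ink[20:27, 20:27] <- 1      # blob B
  seed <- matrix(0, 30, 30)
  seed[5:9, 5:14] <- 1        # covers 50% of A only
  out <- update_mask(ink, seed, cfg)
  expect_equal(sum(out[5:14, 5:14]), 100)   # A in full
  expect_equal(sum(out[20:27, 20:27]), 0)   # B absent
  # empty seed -> empty output
  expect_equal(sum(update_mask(ink, matrix(0, 30, 30), cfg)), 0)
  # seed on background only -> deletion of unsupported mask
  s2 <- matrix(0, 30, 30); s2[1, 1] <- 1
  expect_equal(sum(update_mask(ink, s2, cfg)), 0)
  # idempotence
  expect_equal(update_mask(ink, out, cfg), out)
  expect_error(update_mask(ink, matrix(0, 5, 5), cfg), "same shape")
})

test_that("mask update equals the brute-force component oracle", {
  cfg <- refine_config()
  set.seed(55)
  for (i in 1:25) {
    ink <- matrix(as.numeric(runif(64 * 64) < 0.3), 64, 64)
    seed <- matrix(as.numeric(runif(64 * 64) < 0.05), 64, 64)
    expect_equal(update_mask(ink, seed, cfg), oracle_update(ink, seed, 8L))
  }
  # and under 4-connectivity
  cfg4 <- refine_config(connectivity = 4)
  ink <- matrix(as.numeric(runif(64 * 64) < 0.3), 64, 64)
  seed <- matrix(as.numeric(runif(64 * 64) < 0.05), 64, 64)
  expect_equal(update_mask(ink, seed, cfg4), oracle_update(ink, seed, 4L))
})

test_that("gap bridging connects nearby ink without inventing pixels", {
  cfg <- refine_config(gap_bridge_px = 2)
  ink <- matrix(0, 20, 20)
  ink[10, 2:8] <- 1
  ink[10, 12:18] <- 1   # 3-px gap
  seed <- matrix(0, 20, 20); seed[10, 3] <- 1
  out <- update_mask(ink, seed, cfg)
  expect_equal(out, ink)                      # far piece pulled in
  out0 <- update_mask(ink, seed, refine_config())
  expect_equal(sum(out0[10, 12:18]), 0)       # without bridging it is not
  expect_true(all(out <= ink))                # never adds non-ink pixels
})

test_that("small-region filtering applies the area-scaled 400-px cut", {
  cfg <- refine_config()
  m <- matrix(0, 512, 512)
  m[1:19, 1:21] <- 1          # 399 px
  expect_equal(sum(m[1:19, 1:21]), 399)
  m[100:119, 100:119] <- 1    # 400 px
  out <- filter_small_regions(m, cfg)
  expect_equal(sum(out[1:19, 1:21]), 0)
  expect_equal(sum(out[100:119, 100:119]), 400)
  expect_equal(filter_small_regions(matrix(0, 16, 16), cfg),
               matrix(0, 16, 16))
  expect_equal(small_region_threshold(c(512, 512), cfg), 400L)
  expect_equal(small_region_threshold(c(1024, 1024), cfg), 1600L)
  big <- matrix(0, 1024, 1024)
  big[1:39, 1:41] <- 1   # 1599 px
  expect_equal(sum(filter_small_regions(big, cfg)), 0)
  # idempotent and never adds pixels
  out2 <- filter_small_regions(out, cfg)
  expect_equal(out2, out)
})

test_that("crops preserve source pixels, clip at borders, and rescale", {
  cfg <- refine_config(crop_pad = 0)
  page <- matrix(seq_len(40 * 40), 40, 40)
  reg <- list(list(pixels = matrix(0, 0, 2), bbox = c(10, 10, 20, 20),
                   pixel_count = 100))
  crops <- crop_structures(page, reg, cfg)
  expect_equal(dim(crops[[1]]$image), c(10, 10))
  expect_equal(crops[[1]]$image, page[11:20, 11:20])
  # padding clips at the page corner
  cfg5 <- refine_config(crop_pad = 5)
  reg2 <- list(list(pixels = matrix(0, 0, 2), bbox = c(0, 0, 4, 4),
                    pixel_count = 16))
  crops2 <- crop_structures(page, reg2, cfg5)
  expect_equal(crops2[[1]]$bbox, c(0, 0, 9, 9))
  # mask at half resolution: bbox doubles
  crops3 <- crop_structures(page, reg, cfg, mask_dim = c(20, 20))
  expect_equal(crops3[[1]]$bbox, c(20, 20, 40, 40))
  expect_length(crop_structures(page, list(), cfg), 0L)
})

test_that("refinement restores exact ground truth from a perfect seed", {
  pairs <- fixture_pages(4, 61)
  for (pair in pairs) {
    ref <- refine_mask(as_gray(pair$page), pair$mask * 1, refine_config())
    keep <- filter_small_regions(pair$mask, refine_config())
    expect_equal(ref$mask, keep)
  }
})
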