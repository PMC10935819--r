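test_that("empty composition returns the base page and an empty mask", {
  cfg <- synthesis_config()
  base <- matrix(255, 512, 512)
  pair <- compose_page(base, list(), cfg)
  expect_equal(pair$page, base)
  expect_equal(sum(pair$mask), 0)
  expect_equal(nrow(pair$placements), 0L)
})

test_that("a placed molecule's mask count equals its ink count", {
  cfg <- synthesis_config(grid_prob = 0)
  lib <- fixture_library()
  dep <- render_depiction(lib[lib$id == "nicotine", ], 2, cfg)
  set.seed(4)
  pair <- compose_page(matrix(255, 512, 512),
                       list(list(kind = "molecule", id = "nicotine", dep = dep)),
                       cfg)
  expect_equal(sum(pair$mask), sum(dep$ink_mask))
  b <- pair$placements[1, ]
  expect_equal(c(b$row1 - b$row0, b$col1 - b$col0), dim(dep$bitmap))
})

test_that("molecules and negatives never overlap (brute-force bbox check)", {
  cfg <- synthesis_config(grid_prob = 0, placement_margin = 8L)
  lib <- fixture_library()
  set.seed(6)
  mols <- select_single_molecules(lib, cfg, 6)
  assets <- lapply(seq_len(6), function(k)
    list(kind = "molecule", id = mols$id[k],
         dep = render_depiction(mols[k, ], 2, cfg, max_px = 120)))
  assets <- c(assets, lapply(1:2, function(k)
    list(kind = "negative", id = paste0("neg", k), bitmap = synth_negative())))
  pair <- compose_page(matrix(255, 512, 512), assets, cfg)
  expect_equal(nrow(pair$placements), 8L)
  boxes <- lapply(seq_len(nrow(pair$placements)), function(k)
    as.numeric(pair$placements[k, c("row0", "col0", "row1", "col1")]))
  expect_false(any_boxes_overlap(boxes))
})

test_that("impossible placements error with the asset id", {
  cfg <- synthesis_config()
  big <- matrix(0, 480, 480)
  asset <- list(kind = "negative", id = "huge", bitmap = big)
  expect_error(compose_page(matrix(255, 512, 512), list(asset), cfg),
               "huge")
})

test_that("grid lines and negatives appear on the page but not the mask", {
  cfg <- synthesis_config(grid_prob = 1, negative_prob = 1,
                          cluster_prob = 0, base_text_prob = 0)
  lib <- fixture_library()
  set.seed(12)
  pair <- generate_page_pair(lib, cfg)
  kinds <- pair$placements$kind
  expect_true("gridline" %in% kinds)
  ink <- binarize_image(pair$page)
  # every mask pixel is page ink, but the page has non-mask ink (grid etc.)
  expect_true(all(ink[pair$mask == 1] == 1))
  expect_gt(sum(ink), sum(pair$mask))
  # mask is exactly the page ink inside molecule bboxes
  mols <- pair$placements[pair$placements$kind == "molecule", ]
  for (k in seq_len(nrow(mols))) {
    rr <- (mols$row0[k] + 1):mols$row1[k]
    cc <- (mols$col0[k] + 1):mols$col1[k]
    expect_equal(ink[rr, cc], pair$mask[rr, cc])
  }
})

test_that("cluster pages carry one ground-truth box per fragment", {
  cfg <- synthesis_config(cluster_prob = 1, negative_prob = 0,
                          base_text_prob = 0)
  lib <- fixture_library()
  set.seed(21)
  pair <- generate_page_pair(lib, cfg)
  mols <- pair$placements[pair$placements$kind == "molecule", ]
  expect_gt(nrow(mols), 1L)
  expect_true(all(grepl("_f\\d+$", mols$asset_id)))
  expect_equal(length(unique(mols$angle)), 1L)
})

test_that("dataset generation is deterministic and respects n_pages", {
  d0 <- file.path(tempdir(), "chemseg_ds0")
  mani0 <- generate_dataset(synthesis_config(n_pages = 0), d0)
  expect_equal(nrow(mani0), 0L)
  expect_equal(nrow(read_dataset_manifest(d0)), 0L)

  cfg <- synthesis_config(n_pages = 3, seed = 5)
  d1 <- file.path(tempdir(), "chemseg_ds1")
  d2 <- file.path(tempdir(), "chemseg_ds2")
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  mani <- read_dataset_manifest(d1)
  expect_equal(sort(unique(mani$page)), c("0000", "0001", "0002"))
  mols <- mani[mani$kind == "molecule", ]
  expect_true(all(mols$angle >= 0 & mols$angle <= 30))
  unlink(c(d0, d1, d2), recursive = TRUE)
})

test_that("placements sit on white background within page bounds", {
  pairs <- fixture_pages(5, 31)
  for (pair in pairs) {
    pl <- pair$placements
    expect_true(all(pl$row0 >= 0 & pl$col0 >= 0 &
                    pl$row1 <= nrow(pair$page) & pl$col1 <= ncol(pair$page)))
    mols <- pl[pl$kind %in% c("molecule", "negative"), ]
    grp <- sub("_f\\d+$", "", mols$asset_id)
    # fragments of one cluster may sit close; distinct assets never overlap
    per_asset <- lapply(unique(grp), function(g) {
      rows <- mols[grp == g, ]
      c(min(rows$row0), min(rows$col0), max(rows$row1), max(rows$col1))
    })
    expect_false(any_boxes_overlap(per_asset))
  }
})
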