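test_that("heuristic scoring follows its closed form at the extremes", {
  white <- score_segment_heuristic(matrix(255, 50, 50))
  expect_equal(white$score, 0)
  expect_false(white$is_structure)
  solid <- score_segment_heuristic(matrix(0, 50, 50))
  expect_lt(solid$score, 0.5)
  expect_false(solid$is_structure)
  expect_error(score_segment_heuristic(matrix(0, 0, 0)), "zero-area")
})

test_that("a rendered molecule crop is accepted at the default threshold", {
  lib <- fixture_library()
  dep <- render_depiction(lib[lib$id == "caffeine", ], 2)
  pad <- matrix(255, nrow(dep$bitmap) + 8, ncol(dep$bitmap) + 8)
  pad[5:(4 + nrow(dep$bitmap)), 5:(4 + ncol(dep$bitmap))] <- dep$bitmap
  v <- score_segment_heuristic(pad)
  expect_true(v$is_structure)
  expect_equal(v$method, "heuristic")
  # deterministic
  expect_identical(v, score_segment_heuristic(pad))
})

test_that("filtering partitions the input and preserves order", {
  lib <- fixture_library()
  dep <- render_depiction(lib[lib$id == "nicotine", ], 2)
  segs <- list(dep$bitmap, matrix(255, 30, 30), dep$bitmap,
               matrix(0, 30, 30))
  fl <- filter_segments(segs)
  idx <- c(vapply(fl$kept, function(x) x$index, 0L),
           vapply(fl$rejected, function(x) x$index, 0L))
  expect_setequal(idx, 1:4)
  expect_equal(vapply(fl$kept, function(x) x$index, 0L),
               sort(vapply(fl$kept, function(x) x$index, 0L)))
  expect_true(all(vapply(fl$rejected, function(x) x$label, "") ==
                  "non-molecule"))
  # empty input
  fl0 <- filter_segments(list())
  expect_length(fl0$kept, 0L); expect_length(fl0$rejected, 0L)
  # threshold 0 keeps everything
  expect_length(filter_segments(segs, threshold = 0)$rejected, 0L)
})

test_that("raising the threshold never keeps more segments", {
  lib <- fixture_library()
  dep <- render_depiction(lib[lib$id == "aspirin", ], 3)
  segs <- list(dep$bitmap, matrix(255, 20, 20), matrix(0, 20, 20),
               synth_negative_fixture())
  kept <- vapply(seq(0, 1, by = 0.2), function(th)
    length(filter_segments(segs, threshold = th)$kept), 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("batch filtering equals a per-item scoring loop", {
  lib <- fixture_library()
  segs <- list(render_depiction(lib[lib$id == "phenol", ], 2)$bitmap,
               matrix(255, 25, 25),
               render_depiction(lib[lib$id == "caffeine", ], 4)$bitmap)
  fl <- filter_segments(segs, threshold = 0.5)
  oracle_kept <- which(vapply(segs, function(s)
    score_segment_heuristic(s, 0.5)$is_structure, TRUE))
  expect_equal(vapply(fl$kept, function(x) x$index, 0L), oracle_kept)
})

test_that("the learned scorer scaffold produces valid verdicts", {
  m <- build_model(encoder_config(), seed = 9)
  scorer <- make_learned_scorer(m)
  v <- scorer(matrix(runif(40 * 40, 0, 255), 40, 40))
  expect_equal(v$method, "learned")
  expect_gte(v$score, 0); expect_lte(v$score, 1)
})
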