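test_that("library records carry valid annotations", {
  lib <- fixture_library()
  expect_true(all(lib$heavy_atoms >= 1))
  expect_true(all(lib$total_atoms >= lib$heavy_atoms))
  expect_false(anyDuplicated(lib$id) > 0)
  expect_true(any(lib$n_fragments > 1))
})

test_that("heavy-atom annotation matches an independent SMILES counter", {
  lib <- fixture_library()
  singles <- lib[lib$n_fragments == 1L, ]
  oracle <- vapply(singles$smiles, regex_heavy_count, 0L)
  expect_equal(unname(oracle), singles$heavy_atoms)
})

test_that("single-molecule selection keeps only the 15-28 heavy band", {
  cfg <- synthesis_config()
  lib <- data.frame(id = paste0("m", 1:4),
                    smiles = c("C", "C", "C", "C"),
                    heavy_atoms = c(10L, 15L, 28L, 40L),
                    total_atoms = c(20L, 30L, 50L, 80L),
                    n_fragments = 1L)
  set.seed(1)
  sel <- select_single_molecules(lib, cfg, 2)
  expect_setequal(sel$heavy_atoms, c(15L, 28L))
  # eligible count on the packaged fixtures equals a brute-force scan
  full <- fixture_library()
  singles <- full[full$n_fragments == 1L, ]
  brute <- sum(vapply(singles$smiles, regex_heavy_count, 0L) >= 15 &
               vapply(singles$smiles, regex_heavy_count, 0L) <= 28)
  got <- sum(singles$heavy_atoms >= cfg$min_heavy &
             singles$heavy_atoms <= cfg$max_heavy)
  expect_equal(got, brute)
  # all eligible: request is honoured with distinct records
  lib2 <- data.frame(id = paste0("m", 1:5), smiles = "C",
                     heavy_atoms = 20L, total_atoms = 40L, n_fragments = 1L)
  sel2 <- select_single_molecules(lib2, cfg, 3)
  expect_equal(nrow(sel2), 3L)
  expect_false(anyDuplicated(sel2$id) > 0)
})

test_that("selection errors are explicit when nothing is eligible", {
  cfg <- synthesis_config()
  lib <- data.frame(id = "m1", smiles = "C", heavy_atoms = 5L,
                    total_atoms = 10L, n_fragments = 1L)
  expect_error(select_single_molecules(lib, cfg, 1), "no eligible molecules")
  expect_error(select_cluster_record(lib, cfg), "no eligible molecules")
})

test_that("cluster selection keeps the 250-300 total-atom band", {
  cfg <- synthesis_config()
  lib <- data.frame(id = paste0("c", 1:4), smiles = "C.C",
                    heavy_atoms = 100L,
                    total_atoms = c(249L, 250L, 300L, 301L),
                    n_fragments = 2L)
  set.seed(2)
  got <- unique(vapply(1:50, function(i)
    select_cluster_record(lib, cfg)$total_atoms, 0L))
  expect_setequal(got, c(250L, 300L))
  # single eligible record is a forced choice
  lib1 <- lib[2, ]
  expect_equal(select_cluster_record(lib1, cfg)$id, "c2")
})

test_that("cluster draws are uniform over the eligible set", {
  lib <- fixture_library()
  cfg <- synthesis_config()
  elig <- lib$id[lib$total_atoms >= 250 & lib$total_atoms <= 300]
  set.seed(11)
  draws <- vapply(1:1000, function(i) select_cluster_record(lib, cfg)$id, "")
  expect_true(all(draws %in% elig))
  tab <- table(factor(draws, levels = elig))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})
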