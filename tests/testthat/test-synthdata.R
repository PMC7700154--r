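# Synthetic molecule libraries, planted activity signals, decoys, fixtures.

test_that("generated libraries are valid, unique-id and seed-deterministic", {
  lib <- generate_library(100, seed = 41)
  expect_equal(nrow(lib), 100)
  expect_false(anyDuplicated(lib$compound_id) > 0)
  can <- canonical_smiles(lib$smiles)
  expect_false(anyNA(can))
  std <- vapply(lib$smiles, standardize_structure, character(1),
                USE.NAMES = FALSE)
  expect_false(anyNA(std))
  lib2 <- generate_library(100, seed = 41)
  expect_identical(lib, lib2)
  expect_false(identical(lib, generate_library(100, seed = 42)))
})

test_that("planted signals follow substructure membership", {
  lib <- generate_library(150, seed = 13, motif = "[N+](=O)[O-]",
                          motif_frac = 0.4)
  act0 <- plant_activity_signal(lib, "[N+](=O)[O-]", noise_rate = 0,
                                seed = 2)
  member <- attr(act0, "member")
  expect_identical(attr(act0, "label"), as.integer(member))
  expect_true(all(act0$standard_value[member] < 10))
  expect_true(all(act0$standard_value[!member] > 10))
  expect_false(any(act0$standard_value == 10))
  expect_true(all(act0$assay_type %in% c("IC50", "GI50", "EC50")))
  # downstream curation at noise 0 reproduces the membership exactly
  cur <- curate_compounds(act0)
  m <- match(cur$compounds$compound_id, act0$compound_id)
  expect_identical(cur$compounds$label, as.integer(member[m]))
})

test_that("label flips occur at the configured noise rate", {
  lib <- generate_library(500, seed = 19, motif = "C(F)(F)F", motif_frac = 0.4)
  act <- plant_activity_signal(lib, "C(F)(F)F", noise_rate = 0.1, seed = 3)
  flipped <- attr(act, "label") != as.integer(attr(act, "member"))
  ci <- qbinom(c(0.005, 0.995), 500, 0.1) / 500
  expect_gte(mean(flipped), ci[1])
  expect_lte(mean(flipped), ci[2])
})

test_that("degenerate pharmacophores are refused", {
  lib <- generate_library(30, seed = 5)
  expect_error(plant_activity_signal(lib, "[#92]"), "no learnable signal")
  expect_error(plant_activity_signal(lib, "[#6]"), "no learnable signal")
})

test_that("decoys are property-matched and exclude the actives themselves", {
  actives <- c("c1cc([N+](=O)[O-])cc(C(=O)O)c1C(F)(F)F",
               "OC(=O)C1CCCCC1")
  pool <- generate_library(400, seed = 23, id_prefix = "P")
  dec <- generate_decoys(actives, pool, n_per_active = 30)
  per <- attr(dec, "per_active")
  expect_length(per, 2)
  expect_true(all(lengths(per) == 30))
  expect_lte(nrow(dec), 60)
  expect_false(anyDuplicated(dec$compound_id) > 0)
  # decoys sit closer to their active than the bulk of the pool
  props <- deqsar:::.simple_properties
  P_pool <- props(standardize_structures(pool$smiles)$smiles_std)
  P_act <- props(vapply(actives, standardize_structure, character(1),
                        USE.NAMES = FALSE))
  sc <- apply(P_pool, 2, sd); sc[sc == 0] <- 1
  d_all <- sqrt(colSums(((t(P_pool) - P_act[1, ]) / sc)^2))
  d_dec <- d_all[match(per[[1]], pool$compound_id)]
  expect_lt(median(d_dec), median(d_all))
  # a pool consisting only of the actives is rejected
  selfpool <- data.frame(compound_id = c("s1", "s2"), smiles = actives,
                         stringsAsFactors = FALSE)
  expect_error(generate_decoys(actives, selfpool, n_per_active = 2),
               "shortfall|too small")
})

test_that("ranked fixtures place actives exactly and validate inputs", {
  rl <- make_ranked_fixture(772, 14, c(1, 2, 3, 5, 400 + 1:10))
  expect_equal(rl$N, 772); expect_equal(rl$n, 14)
  expect_equal(rl$ranks, c(1, 2, 3, 5, 401:410))
  expect_error(make_ranked_fixture(10, 2, c(3, 3)), "duplicate")
  expect_error(make_ranked_fixture(10, 3, c(1, 2)), "exactly n")
  expect_error(make_ranked_fixture(10, 2, c(0, 4)), "1..N")
  # degenerate all-active list exists for error-path tests
  expect_equal(make_ranked_fixture(10, 10, 1:10)$n, 10)
})

test_that("a synthetic study is reproducible and internally consistent", {
  st1 <- synthetic_study(n_compounds = 50, n_cell_lines = 2, n_reference = 4,
                         n_decoys_per_active = 8, pool_size = 150, seed = 77)
  st2 <- synthetic_study(n_compounds = 50, n_cell_lines = 2, n_reference = 4,
                         n_decoys_per_active = 8, pool_size = 150, seed = 77)
  expect_identical(st1, st2)
  # reference actives carry every line's pharmacophore
  for (ln in names(st1$cell_lines)) {
    expect_true(all(has_substructure(st1$reference$smiles,
                                     st1$cell_lines[[ln]]$pharmacophore)))
  }
  # the decoy pool is pharmacophore-free
  for (ln in names(st1$cell_lines)) {
    expect_false(any(has_substructure(st1$decoys$smiles,
                                      st1$cell_lines[[ln]]$pharmacophore)))
  }
  expect_setequal(st1$blocklist, st1$reference$compound_id)
  # study files round-trip through the curation reader
  dir <- withr::local_tempdir()
  write_study(st1, dir)
  parsed <- parse_activity_table(file.path(dir, "activity_CL1.csv"))
  expect_equal(nrow(parsed$records), nrow(st1$cell_lines$CL1$activity))
  expect_equal(nrow(parsed$rejections), 0)
})
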