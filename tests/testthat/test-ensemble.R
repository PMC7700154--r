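# Desirability scores, combination enumeration, screening.

test_that("desirability values are geometric means", {
  expect_equal(cell_line_desirability(0.7), 0.7)
  expect_equal(cell_line_desirability(c(0.9, 0.4)), 0.6)
  expect_equal(cell_line_desirability(c(0.3, 0.3, 0.3)), 0.3)
  expect_equal(global_desirability(c(0.5, 0.5, 0.5, 0.5)), 0.5)
  expect_equal(global_desirability(c(1, 1, 1, 1)), 1)
  expect_equal(global_desirability(c(0.9, 0.4, 0.1)), (0.9 * 0.4 * 0.1)^(1 / 3))
  expect_error(cell_line_desirability(numeric(0)), "no scores")
  expect_error(global_desirability(c(0.5, 0)), "positive")
})

test_that("D1 is monotone and bounded by the member scores", {
  withr::with_seed(14, {
    for (i in 1:20) {
      d <- runif(4, 0.05, 1)
      D1 <- global_desirability(d)
      expect_lte(D1, max(d)); expect_gte(D1, min(d))
      j <- sample(4, 1)
      d2 <- d; d2[j] <- min(1, d2[j] + runif(1, 0, 1 - d2[j]))
      expect_gte(global_desirability(d2), D1 - 1e-12)
    }
  })
})

test_that("combination enumeration covers the nonempty-subset product", {
  models <- c(
    lapply(c("SVM", "RF", "XGBoost"), function(l) stub_model("HOS", l)),
    lapply(c("SVM", "KNN"), function(l) stub_model("MG63", l)),
    list(stub_model("SAOS2", "KNN")),
    lapply(c("SVM", "RF", "NN", "KNN"), function(l) stub_model("U2OS", l))
  )
  combos <- enumerate_model_combinations(models)
  expect_length(combos, (2^3 - 1) * (2^2 - 1) * (2^1 - 1) * (2^4 - 1))  # 315
  keys <- vapply(combos, function(cmb) {
    paste(sort(member_ids <- unlist(lapply(cmb$groups, function(g) {
      vapply(g, function(m) m$model_id, character(1))
    })), method = "radix"), collapse = "+")
  }, character(1))
  expect_false(anyDuplicated(keys) > 0)
  # the reported best combination is a member of the enumeration
  target <- paste(sort(c("HOS-SVM", "HOS-RF", "MG63-SVM", "SAOS2-KNN",
                         "U2OS-NN", "U2OS-KNN"), method = "radix"),
                  collapse = "+")
  expect_true(target %in% keys)
  # one model per cell line -> exactly one combination
  single <- list(stub_model("A", "SVM"), stub_model("B", "KNN"))
  expect_length(enumerate_model_combinations(single), 1)
})

test_that("unqualified members are refused", {
  expect_error(ensemble_model(list(stub_model("A", "SVM", qualified = FALSE))),
               "qualified")
})

test_that("screening is deterministic and invariant to library permutation", {
  ds <- toy_signal_dataset(n = 60, p = 4, flips = 0, seed = 3)
  sp <- split_train_external(ds, seed = 1)
  bm1 <- train_base_model(sp, "DTREE", c(TRUE, FALSE, FALSE, FALSE))
  bm2 <- train_base_model(sp, "KNN", c(TRUE, TRUE, FALSE, FALSE))
  ens <- ensemble_model(list(bm1, bm2))
  withr::with_seed(4, {
    lib <- matrix(rbinom(30 * 4, 1, 0.5), 30, 4,
                  dimnames = list(sprintf("v%02d", 1:30),
                                  colnames(ds$x)))
  })
  r1 <- screen_library(ens, lib)
  expect_equal(r1$rank, seq_len(nrow(lib)))
  expect_true(all(diff(r1$D1) <= 0))
  perm <- withr::with_seed(9, sample(nrow(lib)))
  r2 <- screen_library(ens, lib[perm, , drop = FALSE])
  expect_identical(r1$compound_id, r2$compound_id)
  expect_equal(r1$D1, r2$D1)
  # predict() is the same interface
  r3 <- predict(ens, lib)
  expect_identical(r1$compound_id, r3$compound_id)
})

test_that("combination selection prefers an informative model over noise", {
  ds <- toy_signal_dataset(n = 80, p = 6, flips = 0, seed = 5)
  sp <- split_train_external(ds, seed = 2)
  good <- train_base_model(sp, "KNN", c(TRUE, rep(FALSE, 5)))
  noisy <- train_base_model(sp, "DTREE", c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  noisy$qualified <- TRUE  # force into the candidate pool
  combos <- enumerate_model_combinations(list(good, noisy))
  # single cell line with 2 models -> 3 combinations
  expect_length(combos, 3)
  tab <- ds$x
  sel <- select_best_combination(combos, tab, ds$y == 1, alpha = 20)
  expect_equal(nrow(sel$table), 3)
  winner <- deqsar:::member_ids(sel$best)
  expect_true("TOY-KNN" %in% winner)
  best_row <- sel$table[sel$best_index, ]
  expect_true(all(sel$table$BEDROC <= best_row$BEDROC + 1e-12))
})
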