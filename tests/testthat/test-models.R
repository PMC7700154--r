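# Performance metrics, bootstrap BCR fitness, GA wrapper, base models.

test_that("metrics follow the AC/SN/SP/BCR definitions", {
  m <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(m[c("AC", "SN", "SP", "BCR")]), c(AC = 1, SN = 1, SP = 1, BCR = 1))
  # SN = 1, SP = 0.5 -> BCR = 0.75 * 0.5 = 0.375
  m2 <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 1, 0))
  expect_equal(m2$SN, 1); expect_equal(m2$SP, 0.5)
  expect_equal(m2$BCR, 0.375)
  # everything predicted active on balanced truth -> BCR = 0
  m3 <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(m3$AC, 0.5); expect_equal(m3$BCR, 0)
  expect_error(compute_metrics(c(1, 1), c(1, 0)), "SP undefined")
  expect_error(compute_metrics(c(0, 0), c(1, 0)), "SN undefined")
})

test_that("BCR never exceeds the sensitivity/specificity mean", {
  withr::with_seed(2, {
    for (i in 1:25) {
      y <- c(0, 1, rbinom(18, 1, 0.5))
      p <- rbinom(20, 1, 0.5)
      m <- compute_metrics(y, p)
      expect_lte(m$BCR, (m$SN + m$SP) / 2 + 1e-12)
      if (abs(m$SN - m$SP) < 1e-12) expect_equal(m$BCR, (m$SN + m$SP) / 2)
      expect_true(m$BCR >= 0 && m$BCR <= 1)
    }
  })
})

test_that("bootstrap BCR fitness separates signal masks from noise masks", {
  ds <- toy_signal_dataset(n = 60, p = 6, flips = 0, seed = 4)
  sig <- c(TRUE, rep(FALSE, 5))
  noise <- c(FALSE, rep(TRUE, 5))
  f_sig <- bootstrap_bcr_fitness(sig, ds, "DTREE", n_splits = 15, seed = 9)
  f_noise <- bootstrap_bcr_fitness(noise, ds, "DTREE", n_splits = 15, seed = 9)
  expect_gt(f_sig, 0.95)
  expect_lt(f_noise, f_sig)
  # determinism
  expect_identical(
    bootstrap_bcr_fitness(sig, ds, "KNN", n_splits = 1, seed = 3),
    bootstrap_bcr_fitness(sig, ds, "KNN", n_splits = 1, seed = 3))
  expect_error(bootstrap_bcr_fitness(rep(FALSE, 6), ds, "DTREE"), "no features")
})

test_that("GA traces are nondecreasing and a single generation returns the initial best", {
  ds <- toy_signal_dataset(n = 40, p = 8, flips = 2, seed = 6)
  cfg <- ga_config(population = 8, generations = 5, bootstrap_splits = 8, seed = 2)
  res <- ga_select_features(ds, "DTREE", cfg)
  expect_length(res$trace, 5)
  expect_true(all(diff(res$trace) >= 0))
  expect_equal(res$fitness, max(res$trace))
  cfg1 <- ga_config(population = 8, generations = 1, bootstrap_splits = 8, seed = 2)
  res1 <- ga_select_features(ds, "DTREE", cfg1)
  expect_length(res1$trace, 1)
  expect_equal(res1$trace[1], res$trace[1])  # same seed -> same initial population
})

test_that("base models qualify on separable data and scores are bounded", {
  ds <- toy_signal_dataset(n = 80, p = 5, flips = 0, seed = 12)
  sp <- split_train_external(ds, seed = 1)
  mask <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  for (learner in c("SVM", "RF", "NN", "DTREE", "KNN", "XGBoost")) {
    bm <- train_base_model(sp, learner, mask, seed = 3)
    expect_s3_class(bm, "base_model")
    expect_equal(bm$metrics$AC, 1, info = learner)
    expect_true(bm$qualified, info = learner)
    tab <- ds$x[, mask, drop = FALSE]
    colnames(tab) <- bm$features
    s <- score_compounds(bm, tab)
    expect_true(all(s >= 1e-6 & s <= 1), info = learner)
    expect_gt(mean(s[ds$y == 1]), mean(s[ds$y == 0]))
  }
  expect_error(train_base_model(sp, "LDA", mask), "unknown learner")
})

test_that("scoring imputes absent fragments as zero counts", {
  ds <- toy_signal_dataset(n = 60, p = 4, flips = 0, seed = 2)
  sp <- split_train_external(ds, seed = 1)
  bm <- train_base_model(sp, "DTREE", c(TRUE, TRUE, FALSE, FALSE))
  # a table sharing no columns with the model is still scoreable
  alien <- matrix(1, 3, 2, dimnames = list(NULL, c("other1", "other2")))
  s <- score_compounds(bm, alien)
  expect_length(s, 3)
  expect_true(all(s >= 1e-6 & s <= 1))
})
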