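# AUC, enrichment factor, BEDROC, the alpha solver, accumulation curves.

test_that("AUC equals one minus the mean relative rank of the actives", {
  expect_equal(auc(make_ranked_fixture(10, 2, c(1, 2))), 0.85)
  expect_equal(auc(make_ranked_fixture(10, 2, c(9, 10))), 0.05)
  expect_error(auc(make_ranked_fixture(10, 0, integer(0))), "no actives")
})

test_that("AUC of a list and its reversal satisfy the exact rank identity", {
  withr::with_seed(31, {
    for (i in 1:10) {
      N <- sample(20:200, 1); n <- sample(2:10, 1)
      pos <- sort(sample(N, n))
      rl <- make_ranked_fixture(N, n, pos)
      rev_rl <- ranked_list(rev(rl$ids), rev(rl$active))
      expect_equal(auc(rl) + auc(rev_rl), 2 - (N + 1) / N)
    }
  })
})

test_that("random rankings average to AUC 0.5 and EF 1", {
  withr::with_seed(17, {
    aucs <- replicate(2000, auc(make_ranked_fixture(60, 6, sample(60, 6))))
    efs <- replicate(2000, enrichment_factor(
      make_ranked_fixture(60, 6, sample(60, 6)), 0.25))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.01)
  expect_lt(abs(mean(efs) - 1), 0.05)
})

test_that("EF uses the ceiling cutoff and is 1 at chi = 1", {
  rl <- make_ranked_fixture(772, 14, c(1, 2, 3, 5, 200 + 1:10))
  expect_equal(enrichment_factor(rl, 0.01), (4 / 14) / (8 / 772))
  expect_equal(enrichment_factor(rl, 1), 1)
  # cutoff is ceil(chi*N): for N=10, chi=0.25 -> top 3
  rl2 <- make_ranked_fixture(10, 2, c(3, 10))
  expect_equal(enrichment_factor(rl2, 0.25), (1 / 2) / (3 / 10))
  expect_error(enrichment_factor(rl2, 0), "chi")
  expect_error(enrichment_factor(rl2, 1.2), "chi")
})

test_that("BEDROC hits exactly 1 and 0 at the best and worst orderings", {
  withr::with_seed(23, {
    for (i in 1:15) {
      N <- sample(30:500, 1); n <- sample(2:12, 1)
      alpha <- runif(1, 1, 200)
      best <- make_ranked_fixture(N, n, 1:n)
      worst <- make_ranked_fixture(N, n, (N - n + 1):N)
      expect_equal(bedroc(best, alpha), 1)
      expect_equal(bedroc(worst, alpha), 0)
    }
  })
  expect_error(bedroc(make_ranked_fixture(5, 5, 1:5), 20), "BEDROC undefined")
  expect_error(bedroc(make_ranked_fixture(10, 2, 1:2), -1), "positive")
})

test_that("BEDROC agrees with the literal dual implementation to 1e-12", {
  withr::with_seed(29, {
    for (i in 1:15) {
      N <- sample(50:800, 1); n <- sample(3:20, 1)
      alpha <- sample(c(5, 20, 80.5, 160.9), 1)
      pos <- sort(sample(N, n))
      rl <- make_ranked_fixture(N, n, pos)
      expect_equal(bedroc(rl, alpha), oracle_bedroc(pos, n, N, alpha),
                   tolerance = 1e-12)
      expect_true(bedroc(rl, alpha) >= 0 && bedroc(rl, alpha) <= 1)
    }
  })
})

test_that("the alpha solver finds the positive root with tiny residual", {
  a <- solve_alpha(0.80, 0.01)
  f <- function(al, theta, z) theta * (1 - exp(-al)) - 1 + exp(-al * z)
  expect_lt(abs(f(a, 0.80, 0.01)), 1e-10)
  expect_gt(a, 1)  # the trivial root at 0 is excluded
  # large-alpha closed form: alpha ~ -log(1 - theta) / z
  a2 <- solve_alpha(0.80, 0.02)
  expect_equal(a2, -log(0.2) / 0.02, tolerance = 1e-6)
  expect_lt(abs(f(a2, 0.80, 0.02)), 1e-10)
  expect_error(solve_alpha(0.005, 0.01), "positive root")
})

test_that("accumulation curves are monotone step curves from (0,0) to (1,1)", {
  rl <- make_ranked_fixture(20, 4, 1:4)
  cv <- accumulation_curve(rl)
  expect_equal(cv$fraction_screened[1], 0)
  expect_equal(cv$fraction_retrieved[1], 0)
  expect_equal(utils::tail(cv$fraction_screened, 1), 1)
  expect_equal(utils::tail(cv$fraction_retrieved, 1), 1)
  expect_true(all(diff(cv$fraction_retrieved) >= 0))
  # all actives first: full retrieval at fraction n/N
  expect_equal(cv$fraction_retrieved[cv$fraction_screened == 4 / 20], 1)
  # a front-loaded list dominates the diagonal
  expect_true(all(cv$fraction_retrieved >= cv$fraction_screened - 1e-12))
})

test_that("ranked lists round-trip through TSV", {
  rl <- make_ranked_fixture(15, 3, c(2, 5, 11))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_list(rl, p)
  back <- read_ranked_list(p)
  expect_identical(back$ids, rl$ids)
  expect_identical(back$active, rl$active)
})
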