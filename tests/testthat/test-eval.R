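test_that("Wasserstein distance closed forms", {
  expect_equal(wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_1d(c(0, 0), c(1, 1)), 1)
  expect_equal(wasserstein_1d(c(1, 2, 3), c(2, 3, 4)), 1)
  # unequal sizes: CDF-integral form
  expect_equal(wasserstein_1d(c(0, 1), c(0.5)), 0.5)
  expect_error(wasserstein_1d(numeric(0), 1), "empty")
})

test_that("Wasserstein metric properties hold on random samples", {
  set.seed(42)
  for (r in 1:20) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2))
    z <- rexp(sample(5:40, 1))
    cc <- runif(1, -5, 5)
    expect_equal(wasserstein_1d(x, y), wasserstein_1d(y, x))
    expect_lte(wasserstein_1d(x, z),
               wasserstein_1d(x, y) + wasserstein_1d(y, z) + 1e-12)
    expect_equal(wasserstein_1d(x + cc, y + cc), wasserstein_1d(x, y),
                 tolerance = 1e-10)
    expect_equal(wasserstein_1d(x, x + cc), abs(cc), tolerance = 1e-10)
    expect_gte(wasserstein_1d(x, y), 0)
  }
})

test_that("standard metrics implement the three definitional ratios", {
  train <- parse_molecules(c("CCO", "CCC"))
  # 10 samples, 9 parse -> validity 0.9
  raw <- c(rep("CC", 3), "CCO", "OCC", "CCN", "CCC", "CCF", "CCCl", "c1ccccc")
  g <- standard_metrics(raw, "smiles", train)
  expect_equal(g$validity, 0.9)
  # valid: CC x3, CCO, OCC, CCN, CCC, CCF, CCCl -> unique: CC, CCO, CCN,
  # CCC, CCF, CCCl (6 of 9 valid)
  expect_equal(g$uniqueness, 6 / 9)
  # novel: CC, CCN, CCF, CCCl (CCO and CCC are training molecules)
  expect_equal(g$novelty, 4 / 6)
  expect_false(g$degenerate)
  # all-invalid batch: ratios defined as 0 and flagged
  g0 <- standard_metrics(c("xx", "yy"), "smiles", train)
  expect_equal(g0$validity, 0)
  expect_equal(g0$uniqueness, 0)
  expect_equal(g0$novelty, 0)
  expect_true(g0$degenerate)
  expect_true(all(unlist(g[, c("validity", "uniqueness", "novelty")]) >= 0 &
                  unlist(g[, c("validity", "uniqueness", "novelty")]) <= 1))
})

test_that("oracle distance is seeded, non-negative, zero on constants", {
  expect_equal(oracle_distance(rep(3.5, 40), seed = 1), 0)
  v <- rnorm(100)
  expect_identical(oracle_distance(v, n_splits = 1, seed = 7),
                   oracle_distance(v, n_splits = 1, seed = 7))
  expect_gte(oracle_distance(v, seed = 2), 0)
  expect_error(oracle_distance(c(1, 2, 3)), "at least 4")
})

test_that("oracle distance shrinks as the training set grows", {
  for (s in 1:3) {
    set.seed(1000 + s)
    small <- rnorm(200, 50, 10)
    big <- rnorm(5000, 50, 10)
    expect_lt(oracle_distance(big, seed = s), oracle_distance(small, seed = s))
  }
})

test_that("KDE curves integrate to one and share the train bandwidth", {
  set.seed(7)
  train_v <- rnorm(200, 10, 2)
  k <- kde_curves(train_v, list(m1 = rnorm(150, 11, 2), m2 = rexp(80)))
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  for (s in unique(k$set)) {
    sub <- k[k$set == s, ]
    expect_equal(trap(sub$x, sub$density), 1, tolerance = 1e-3)
  }
  expect_length(attr(k, "bandwidth"), 1L)
  expect_error(kde_curves(rnorm(5)), "at least 10")
})

test_that("a two-component mixture yields a bimodal train curve", {
  set.seed(8)
  vals <- c(rnorm(150, 0, 1), rnorm(150, 10, 1)) # components at +/- 5 SD
  k <- kde_curves(vals)
  expect_equal(molgenlm:::kde_modes(k), 2L)
})

test_that("2-D histogram counts are conserved and transpose under swap", {
  p <- compute_properties(druglike_small()[1:50, ])
  h <- histogram2d(p, "mw", "sa", bins = c(12, 10))
  expect_equal(sum(h$counts), 50L)
  ht <- histogram2d(p, "sa", "mw", bins = c(10, 12))
  expect_identical(ht$counts, t(h$counts))
  single <- histogram2d(p[1, ], "mw", "sa")
  expect_equal(sum(single$counts > 0), 1L)
})

test_that("report pipeline removes overlap, equalizes and leaves inputs intact", {
  pool <- druglike_1000()
  train <- pool[1:150, ]
  gen_a <- pool[151:290, ]                       # disjoint sample
  gen_b <- dplyr::bind_rows(pool[291:400, ], train[1:20, ]) # 110 survive
  before <- list(train$canonical, gen_a$canonical)
  n_want <- min(nrow(remove_overlap(gen_a, train)),
                nrow(remove_overlap(gen_b, train)))
  reports <- compare_generations(list(a = gen_a, b = gen_b), train, seed = 3)
  expect_equal(attr(reports, "n_compared"), n_want)
  expect_equal(reports$a$n_compared, n_want)
  expect_equal(reports$b$n_compared, n_want)
  expect_lt(n_want, nrow(remove_overlap(gen_a, train)) + 1L)
  expect_identical(before, list(train$canonical, gen_a$canonical))
  expect_true(all(reports$a$distances$w_model >= 0))
  expect_true(all(reports$a$distances$w_oracle >= 0))
})

test_that("a constructed +MW shift blows up the MW distance only", {
  pool <- druglike_1000()
  train <- pool[1:500, ]
  shifted <- parse_molecules(paste0(pool$canonical[701:900], "CCCCCCC"),
                             source = "shifted")
  expect_true(all(shifted$is_valid))
  rep_s <- distribution_report(shifted, train, properties = c("mw"),
                               seed = 5)
  d <- rep_s$distances
  expect_gt(d$w_model[d$property == "mw"],
            10 * d$w_oracle[d$property == "mw"])
})

test_that("a fresh disjoint sample of the training distribution scores near the oracle", {
  pool <- druglike_1000()
  train <- pool[1:400, ]
  gen <- pool[401:800, ]
  rep1 <- distribution_report(gen, train, seed = 11)
  ratios <- rep1$distances$w_model / rep1$distances$w_oracle
  # same-generator samples should land within a small multiple of the
  # train/train baseline on every property
  expect_true(all(ratios < 4))
  expect_lt(stats::median(ratios), 2.5)
})

test_that("empty post-overlap generation set is an error with counts", {
  train <- parse_molecules(c("CCO", "CCC"))
  gen <- parse_molecules(c("CCO", "OCC"))
  expect_error(distribution_report(gen, train), "survive")
})
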