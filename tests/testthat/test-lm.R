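test_that("configuration bounds follow the search space", {
  expect_error(lm_config(n_layers = 6), "n_layers")
  expect_error(lm_config(hidden_units = 50), "hidden_units")
  expect_error(lm_config(dropout_last = 0.6), "dropout_last")
  expect_error(lm_config(learning_rate = 5e-3), "learning_rate")
  cfg <- task_default_config("logp/sm")
  expect_equal(cfg$n_layers, 2L)
  expect_equal(cfg$hidden_units, 400L)
  expect_equal(cfg$dropout_last, 0.2)
  expect_equal(cfg$learning_rate, 1e-4)
  cfg2 <- task_default_config("large/sf")
  expect_equal(cfg2$n_layers, 2L)
  expect_equal(cfg2$hidden_units, 800L)
  expect_equal(cfg2$dropout_last, 0.4)
  expect_equal(cfg2$learning_rate, 1e-4)
  expect_equal(cfg2$max_sample_len, 1000L)
})

memorizable_corpus <- function() {
  parse_molecules(rep(c("CC", "CCO", "CCC", "CCN", "CO",
                        "CN", "CCCO", "CCCC", "CCCN", "CCCl"), 5))
}

# ten distinct molecules long enough that the irreducible which-string
# entropy per token is small, so near-complete memorization is possible
memorizable_long_corpus <- function() {
  parse_molecules(rep(c(
    "CCCCCCCCCCCCCCCC", "CCCCCCOCCCCCCCCC", "CCCCCCCCNCCCCCCC",
    "CCCCCCCCCCCCCCCO", "CCCCSCCCCCCCCCCC", "CCCCCCCCCCOCCCCO",
    "NCCCCCCCCCCCCCCC", "CCCCCCCCCCCCCCCN", "OCCCCCCCCCCCCCCO",
    "CCCOCCCCCCCCCCCC"), 5))
}

test_that("training NLL falls and is near-monotone on a memorizable corpus", {
  cfg <- lm_config(n_layers = 1, hidden_units = 100, learning_rate = 1e-3,
                   epochs = 40, batch_size = 8, seed = 11)
  m <- train_lm(memorizable_long_corpus(), "smiles", cfg, heldout_frac = 0)
  expect_length(m$curve, 40)
  expect_lt(tail(m$curve, 1), 0.2 * m$curve[1])
  # material upticks only: jitter at convergence is not a transient uptick
  upticks <- mean(diff(m$curve) > 0.005 * m$curve[1])
  expect_lte(upticks, 0.05)
})

test_that("a one-string corpus is memorized and sampling is deterministic", {
  cfg <- lm_config(n_layers = 1, hidden_units = 100, learning_rate = 1e-3,
                   epochs = 30, batch_size = 16, seed = 3)
  m <- train_lm(parse_molecules(rep("CC", 50)), "smiles", cfg,
                heldout_frac = 0)
  expect_lt(tail(m$curve, 1), m$curve[1])
  s <- sample_lm(m, 200, seed = 9)
  expect_gte(mean(s$raw == "CC"), 0.95)
  s2 <- sample_lm(m, 200, seed = 9)
  expect_identical(s$raw, s2$raw)
  expect_error(sample_lm(m, 0), "at least 1")
})

test_that("softmax emits a probability distribution at every step", {
  cfg <- lm_config(n_layers = 2, hidden_units = 100, learning_rate = 1e-3,
                   epochs = 2, batch_size = 16, seed = 5)
  m <- train_lm(memorizable_corpus(), "smiles", cfg, heldout_frac = 0)
  seq <- encode_tokens(tokenize_smiles("CCO"), m$vocab)
  p <- molgenlm:::cpp_lstm_probs(m$params, seq)
  expect_true(all(abs(colSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
})

test_that("an untrained model scores near the uniform baseline", {
  corpus <- memorizable_corpus()
  toks <- lapply(corpus$canonical, tokenize_smiles)
  v <- build_vocabulary(toks)
  set.seed(1)
  params <- molgenlm:::cpp_lstm_new(length(v), 1L, 100L, 100L)
  seqs <- lapply(toks, encode_tokens, vocab = v)
  nll <- molgenlm:::cpp_lstm_nll(params, seqs, attr(v, "pad"))
  expect_gte(nll, 0)
  expect_lt(abs(nll - log(length(v))) / log(length(v)), 0.05)
})

test_that("held-out NLL is non-negative and near zero for a memorized model", {
  cfg <- lm_config(n_layers = 1, hidden_units = 100, learning_rate = 1e-3,
                   epochs = 40, batch_size = 8, seed = 3)
  corpus <- parse_molecules(rep("CCO", 30))
  m <- train_lm(corpus, "smiles", cfg, heldout_frac = 0)
  nll <- heldout_nll(m, parse_molecules("CCO"))
  expect_gte(nll, 0)
  expect_lt(nll, 0.15)
  expect_error(heldout_nll(m, parse_molecules("CCBr")), "not in vocabulary")
})

test_that("training with a fixed seed is reproducible run to run", {
  cfg <- lm_config(n_layers = 1, hidden_units = 100, learning_rate = 1e-3,
                   epochs = 3, batch_size = 16, seed = 21)
  m1 <- train_lm(memorizable_corpus(), "smiles", cfg, heldout_frac = 0)
  m2 <- train_lm(memorizable_corpus(), "smiles", cfg, heldout_frac = 0)
  expect_identical(m1$curve, m2$curve)
  expect_identical(m1$params$Wy, m2$params$Wy)
})

test_that("random search draws reproducible in-bound configs from the grids", {
  grids <- list(n_layers = 1:3,
                hidden_units = c(100, 200, 400),
                dropout_last = c(0, 0.2, 0.4),
                learning_rate = c(1e-4, 5e-4, 1e-3))
  corpus <- memorizable_corpus()
  rs1 <- random_search(grids, k = 4, corpus, seed = 7,
                       epochs = 1L, batch_size = 16L)
  rs2 <- random_search(grids, k = 4, corpus, seed = 7,
                       epochs = 1L, batch_size = 16L)
  expect_equal(rs1[, 1:5], rs2[, 1:5])
  expect_true(all(rs1$learning_rate >= 1e-4 & rs1$learning_rate <= 1e-3))
  expect_s3_class(rs1$model[[1]], "trained_lm")
  bad <- grids
  bad$hidden_units <- c(100, 200, 300, 400, 500, 600)
  expect_error(random_search(bad, 2, corpus), "3-5 values")
  out_of_bounds <- grids
  out_of_bounds$learning_rate <- c(1e-4, 1e-3, 1e-2)
  expect_error(random_search(out_of_bounds, 2, corpus), "learning_rate")
})

test_that("model selection keeps the top decile then counts metric wins", {
  fake_report <- function(v, u, n, w) {
    structure(list(
      standard = tibble::tibble(validity = v, uniqueness = u, novelty = n),
      distances = tibble::tibble(
        property = c("logp", "sa", "qed", "mw", "bertz", "np"),
        w_model = w, w_oracle = w / 10)
    ), class = "distribution_report")
  }
  models <- lapply(1:10, function(i) structure(list(id = i),
                                               class = "trained_lm"))
  # model 4 and 7 have the best standard metrics; 10 candidates -> 1 survivor
  reports <- lapply(1:10, function(i) {
    fake_report(0.5 + 0.04 * (i == 4), 0.5, 0.5, rep(1, 6))
  })
  sel <- select_model(models, reports)
  expect_equal(attr(sel, "selected"), 4L)
  # 20 candidates -> 2 survivors; majority of the six metrics decides
  models20 <- lapply(1:20, function(i) structure(list(id = i),
                                                 class = "trained_lm"))
  reports20 <- lapply(1:20, function(i) {
    base <- 0.5 + 0.02 * (i %in% c(13, 17))
    w <- if (i == 13) c(1, 1, 1, 1, 2, 2) else c(2, 2, 2, 2, 1, 1)
    fake_report(base, base, base, w)
  })
  sel2 <- select_model(models20, reports20)
  expect_equal(attr(sel2, "selected"), 13L) # wins 4 of 6 distances
  # full 3/3 tie on wins -> primary-property distance breaks it
  reports20b <- lapply(1:20, function(i) {
    base <- 0.5 + 0.02 * (i %in% c(13, 17))
    w <- if (i == 13) c(1, 1, 1, 2, 2, 2) else c(2, 2, 2, 1, 1, 1)
    fake_report(base, base, base, w)
  })
  sel3 <- select_model(models20, reports20b, primary_property = "mw")
  expect_equal(attr(sel3, "selected"), 17L) # lower w_model on mw
  expect_error(select_model(list(), list()), "empty")
})

test_that("tidy/glance expose the training curve and settings", {
  cfg <- lm_config(n_layers = 1, hidden_units = 100, learning_rate = 1e-3,
                   epochs = 2, batch_size = 16, seed = 2)
  m <- train_lm(memorizable_corpus(), "smiles", cfg, heldout_frac = 0.2)
  td <- tidy(m)
  expect_equal(nrow(td), 2)
  expect_named(td, c("epoch", "train_nll", "heldout_nll"))
  g <- glance(m)
  expect_equal(g$hidden_units, 100L)
  expect_equal(g$best_epoch, m$best_epoch)
})

test_that("checkpoints round trip through the directory format", {
  cfg <- lm_config(n_layers = 1, hidden_units = 100, learning_rate = 1e-3,
                   epochs = 2, batch_size = 16, seed = 2)
  m <- train_lm(memorizable_corpus(), "smiles", cfg, heldout_frac = 0)
  dir <- withr::local_tempdir()
  save_checkpoint(m, dir)
  m2 <- load_checkpoint(dir)
  expect_identical(m2$vocab, m$vocab)
  expect_equal(m2$config$hidden_units, m$config$hidden_units)
  s1 <- sample_lm(m, 20, seed = 4)
  s2 <- sample_lm(m2, 20, seed = 4)
  expect_identical(s1$raw, s2$raw)
})
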