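#' Language-model configuration
#'
#' Architecture and optimization settings for the stacked-LSTM chemical
#' language model. The constructor enforces the hyper-parameter search
#' bounds used throughout: `n_layers` in \[1, 5\], `hidden_units` in
#' \[100, 1000\], `dropout_last` in \[0, 0.5\] and `learning_rate` in
#' \[1e-4, 1e-3\].
#'
#' @param n_layers Number of stacked LSTM layers.
#' @param hidden_units Units per layer (the embedding width follows it).
#' @param dropout_last Dropout probability on the last layer's output.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size (sequences).
#' @param epochs Training epochs; the best epoch by held-out NLL is kept.
#' @param max_sample_len Sampling length cap in tokens.
#' @param seed Run seed (initialization, shuffling, dropout).
#' @return An `lm_config` list.
#' @export
lm_config <- function(n_layers = 2L, hidden_units = 400L, dropout_last = 0.2,
                      learning_rate = 1e-4, batch_size = 64L, epochs = 100L,
                      max_sample_len = 120L, seed = 1L) {
  abort_if(n_layers < 1L || n_layers > 5L, "`n_layers` must be in [1, 5]")
  abort_if(hidden_units < 100L || hidden_units > 1000L,
           "`hidden_units` must be in [100, 1000]")
  abort_if(dropout_last < 0 || dropout_last > 0.5,
           "`dropout_last` must be in [0, 0.5]")
  abort_if(learning_rate < 1e-4 || learning_rate > 1e-3,
           "`learning_rate` must be in [1e-4, 1e-3]")
  abort_if(epochs < 1L, "`epochs` must be positive")
  structure(list(
    n_layers = as.integer(n_layers), hidden_units = as.integer(hidden_units),
    dropout_last = dropout_last, learning_rate = learning_rate,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    max_sample_len = as.integer(max_sample_len), seed = as.integer(seed)
  ), class = "lm_config")
}

#' Per-task default configurations
#'
#' The published per-task LSTM settings, keyed `"<task>/<encoding>"` with
#' task in `logp`, `multi`, `large` and encoding `sm` (SMILES) / `sf`
#' (robust bracket strings).
#'
#' @param name Configuration key, e.g. `"logp/sm"`.
#' @param ... Overrides passed to [lm_config()].
#' @return An `lm_config`.
#' @export
task_default_config <- function(name, ...) {
  defaults <- list(
    "logp/sm"  = list(n_layers = 2L, hidden_units = 400L, dropout_last = 0.20, learning_rate = 1e-4, max_sample_len = 120L),
    "logp/sf"  = list(n_layers = 2L, hidden_units = 600L, dropout_last = 0.40, learning_rate = 2e-4, max_sample_len = 120L),
    "multi/sm" = list(n_layers = 3L, hidden_units = 512L, dropout_last = 0.50, learning_rate = 1e-4, max_sample_len = 120L),
    "multi/sf" = list(n_layers = 2L, hidden_units = 500L, dropout_last = 0.20, learning_rate = 3e-4, max_sample_len = 120L),
    "large/sm" = list(n_layers = 2L, hidden_units = 512L, dropout_last = 0.25, learning_rate = 1e-3, max_sample_len = 1000L),
    "large/sf" = list(n_layers = 2L, hidden_units = 800L, dropout_last = 0.40, learning_rate = 1e-4, max_sample_len = 1000L)
  )
  abort_if(!name %in% names(defaults),
           paste0("unknown task config `", name, "`"))
  args <- utils::modifyList(defaults[[name]], list(...))
  do.call(lm_config, args)
}

# training strings for a corpus under an encoding
corpus_strings <- function(mols, encoding, min_n = 2L) {
  valid <- mols[mols$is_valid, , drop = FALSE]
  abort_if(nrow(valid) < min_n,
           paste0("corpus must contain at least ", min_n, " valid molecules"))
  if (encoding == "smiles") {
    valid$canonical
  } else if (all(valid$encoding == "selfies")) {
    valid$raw
  } else {
    vapply(valid$canonical, smiles_to_selfies, "", USE.NAMES = FALSE)
  }
}

#' Train a chemical language model
#'
#' Teacher-forced next-token training of an embedding + stacked-LSTM +
#' softmax model on the corpus, minimizing mean per-token negative
#' log-likelihood with Adam; dropout is applied to the last recurrent
#' layer's output. A fraction of the corpus is held out and the parameters
#' of the best epoch by held-out NLL are kept. With a fixed `config$seed`
#' training is reproducible run to run.
#'
#' @param corpus A `mol_tbl` with at least two valid molecules.
#' @param encoding `"smiles"` or `"selfies"` (robust bracket strings).
#' @param config An [lm_config()].
#' @param heldout_frac Fraction held out for epoch selection (0 disables;
#'   the full corpus is then used for training and the last epoch kept).
#' @return A `trained_lm` object with elements `config`, `encoding`,
#'   `vocab`, `params`, `curve` (per-epoch training NLL), `heldout_curve`
#'   and `best_epoch`.
#' @export
train_lm <- function(corpus, encoding = c("smiles", "selfies"),
                     config = lm_config(), heldout_frac = 0.1) {
  encoding <- match.arg(encoding)
  strings <- corpus_strings(corpus, encoding)
  token_seqs <- tokenize_all(strings, encoding)
  vocab <- build_vocabulary(token_seqs)
  encoded <- lapply(token_seqs, encode_tokens, vocab = vocab)
  pad <- attr(vocab, "pad")

  local_seed(config$seed, {
    n <- length(encoded)
    n_hold <- if (heldout_frac > 0 && n >= 20L) floor(heldout_frac * n) else 0L
    hold_idx <- if (n_hold > 0) sample.int(n, n_hold) else integer(0)
    train_set <- if (n_hold > 0) encoded[-hold_idx] else encoded
    hold_set <- encoded[hold_idx]

    params <- cpp_lstm_new(length(vocab), config$n_layers,
                           config$hidden_units, config$hidden_units)
    opt <- list()
    curve <- heldout_curve <- numeric(config$epochs)
    best <- list(params = params, nll = Inf, epoch = 0L)
    for (e in seq_len(config$epochs)) {
      res <- cpp_lstm_epoch(params, opt, train_set, config$batch_size,
                            config$learning_rate, config$dropout_last,
                            pad, 5.0)
      params <- res$params
      opt <- res$opt
      curve[e] <- res$nll
      heldout_curve[e] <- if (n_hold > 0) {
        cpp_lstm_nll(params, hold_set, pad)
      } else {
        res$nll
      }
      if (heldout_curve[e] < best$nll) {
        best <- list(params = params, nll = heldout_curve[e], epoch = e)
      }
    }
    structure(list(
      config = config, encoding = encoding, vocab = vocab,
      params = best$params, final_params = params,
      curve = curve, heldout_curve = heldout_curve,
      best_epoch = best$epoch, n_train = length(train_set),
      n_heldout = n_hold
    ), class = "trained_lm")
  })
}

#' @export
print.trained_lm <- function(x, ...) {
  cat("<trained_lm> ", x$encoding, ", ", x$config$n_layers, "x",
      x$config$hidden_units, " LSTM, vocab ", length(x$vocab),
      ", best epoch ", x$best_epoch, "/", x$config$epochs,
      " (held-out NLL ", signif(min(x$heldout_curve), 4), ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.trained_lm <- function(x, ...) {
  tibble::tibble(
    epoch = seq_along(x$curve),
    train_nll = x$curve,
    heldout_nll = x$heldout_curve
  )
}

#' @export
glance.trained_lm <- function(x, ...) {
  tibble::tibble(
    encoding = x$encoding,
    n_layers = x$config$n_layers,
    hidden_units = x$config$hidden_units,
    dropout_last = x$config$dropout_last,
    learning_rate = x$config$learning_rate,
    epochs = x$config$epochs,
    best_epoch = x$best_epoch,
    train_nll = x$curve[length(x$curve)],
    heldout_nll = min(x$heldout_curve),
    vocab_size = length(x$vocab),
    n_train = x$n_train
  )
}

#' Sample molecules from a trained model
#'
#' Ancestral sampling at temperature 1: starting from BOS, each token is
#' drawn from the model's softmax distribution until EOS or
#' `config$max_sample_len` tokens. Raw strings are returned unfiltered —
#' validity is judged downstream. Sequences that hit the length cap are
#' flagged `truncated`. The first draw excludes EOS (a molecule has at
#' least one token), so the empty sequence is never emitted.
#'
#' @param model A `trained_lm`.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; the same seed and model give identical output.
#' @return A tibble with columns `raw` and `truncated`.
#' @export
sample_lm <- function(model, n, seed = 1L) {
  abort_if(!inherits(model, "trained_lm"), "`model` must be a trained_lm")
  abort_if(n < 1L, "`n` must be at least 1")
  vocab <- model$vocab
  codes <- local_seed(seed, {
    cpp_lstm_sample(model$params, as.integer(n), model$config$max_sample_len,
                    attr(vocab, "bos"), attr(vocab, "eos"), attr(vocab, "pad"),
                    TRUE)
  })
  pad <- attr(vocab, "pad")
  raw <- character(n)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    row <- codes[i, ]
    row <- row[row != pad]
    raw[i] <- paste0(names(vocab)[row + 1L], collapse = "")
    truncated[i] <- length(row) == model$config$max_sample_len
  }
  tibble::tibble(raw = raw, truncated = truncated)
}

#' Held-out negative log-likelihood
#'
#' Mean per-token NLL of a molecule set under the model (teacher forcing,
#' no dropout). Tokens outside the model's vocabulary are an error.
#'
#' @param model A `trained_lm`.
#' @param mols A `mol_tbl`.
#' @return A single non-negative number.
#' @export
heldout_nll <- function(model, mols) {
  strings <- corpus_strings(mols, model$encoding, min_n = 1L)
  seqs <- lapply(tokenize_all(strings, model$encoding),
                 encode_tokens, vocab = model$vocab)
  cpp_lstm_nll(model$params, seqs, attr(model$vocab, "pad"))
}

#' Hyper-parameter random search
#'
#' Draws `k` configurations by sampling each hyper-parameter independently
#' and uniformly from its discrete grid (3-5 roughly equally spaced values
#' per grid, inside the published bounds), trains a model per draw, and
#' returns everything as a tibble. The number of epochs is not searched.
#'
#' @param grids Named list of value grids for `n_layers`, `hidden_units`,
#'   `dropout_last`, `learning_rate`.
#' @param k Number of draws.
#' @param train A `mol_tbl` training corpus.
#' @param encoding `"smiles"` or `"selfies"`.
#' @param seed Seed for the draws (training seeds are derived from it).
#' @param ... Fixed [lm_config()] fields (e.g. `epochs`, `batch_size`).
#' @return A tibble with the drawn hyper-parameters and a `model`
#'   list-column of `trained_lm` objects.
#' @export
random_search <- function(grids, k, train, encoding = "smiles", seed = 1L, ...) {
  needed <- c("n_layers", "hidden_units", "dropout_last", "learning_rate")
  abort_if(!all(needed %in% names(grids)),
           paste0("`grids` must cover: ", paste(needed, collapse = ", ")))
  for (nm in needed) {
    g <- grids[[nm]]
    abort_if(length(g) < 3L || length(g) > 5L,
             paste0("grid `", nm, "` must have 3-5 values"))
  }
  # constructing a config validates each grid value against the bounds
  for (nl in grids$n_layers) for (lr in grids$learning_rate) {
    lm_config(n_layers = nl, hidden_units = max(grids$hidden_units),
              dropout_last = max(grids$dropout_last), learning_rate = lr)
  }
  draws <- local_seed(seed, {
    tibble::tibble(
      draw = seq_len(k),
      n_layers = sample(grids$n_layers, k, replace = TRUE),
      hidden_units = sample(grids$hidden_units, k, replace = TRUE),
      dropout_last = sample(grids$dropout_last, k, replace = TRUE),
      learning_rate = sample(grids$learning_rate, k, replace = TRUE)
    )
  })
  draws$model <- purrr::pmap(
    draws,
    function(draw, n_layers, hidden_units, dropout_last, learning_rate) {
      cfg <- lm_config(n_layers = n_layers, hidden_units = hidden_units,
                       dropout_last = dropout_last,
                       learning_rate = learning_rate,
                       seed = derive_seed(seed, paste0("draw", draw)), ...)
      train_lm(train, encoding, cfg)
    }
  )
  draws
}

#' Select the best model from evaluated candidates
#'
#' Two-stage selection: (1) keep the top 10 percent (ceiling) of candidates
#' by the sum validity + uniqueness + novelty; (2) among survivors, return
#' the model that scores lowest on the largest number of the six
#' per-property Wasserstein distance metrics, breaking ties by the distance
#' on `primary_property`.
#'
#' @param models List of `trained_lm` candidates.
#' @param reports List of matching [distribution_report()] objects (one per
#'   candidate; each carries the standard metrics and the distances).
#' @param primary_property Property name for the tie-break (e.g. `"plogp"`
#'   or `"mw"`).
#' @return The selected `trained_lm`, with attribute `selected` giving its
#'   index.
#' @export
select_model <- function(models, reports, primary_property = "mw") {
  abort_if(length(models) == 0L, "empty candidate list")
  abort_if(length(models) != length(reports),
           "need exactly one report per candidate")
  score <- vapply(reports, function(r) {
    sum(r$standard$validity, r$standard$uniqueness, r$standard$novelty)
  }, numeric(1))
  n_keep <- ceiling(0.1 * length(models))
  survivors <- order(score, decreasing = TRUE)[seq_len(n_keep)]
  if (length(survivors) == 1L) {
    out <- models[[survivors]]
    attr(out, "selected") <- survivors
    return(out)
  }
  dist_mat <- vapply(reports[survivors], function(r) {
    stats::setNames(r$distances$w_model, r$distances$property)
  }, numeric(nrow(reports[[1]]$distances)))
  wins <- integer(length(survivors))
  for (p in rownames(dist_mat)) {
    wins[which.min(dist_mat[p, ])] <- wins[which.min(dist_mat[p, ])] + 1L
  }
  top <- which(wins == max(wins))
  if (length(top) > 1L) {
    abort_if(!primary_property %in% rownames(dist_mat),
             paste0("primary property `", primary_property,
                    "` not in the reports"))
    top <- top[which.min(dist_mat[primary_property, top])]
  }
  out <- models[[survivors[top]]]
  attr(out, "selected") <- survivors[top]
  out
}

#' Save / load a model checkpoint directory
#'
#' A checkpoint is a directory with the learned parameters
#' (`params.rds`), the vocabulary as a plain-text token list
#' (`vocab.txt`) and the configuration as a flat key-value text file
#' (`config.txt`).
#'
#' @param model A `trained_lm`.
#' @param dir Checkpoint directory (created if missing).
#' @return `load_checkpoint` returns a `trained_lm`.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "params.rds"))
  write_vocabulary(model$vocab, file.path(dir, "vocab.txt"))
  cfg <- c(model$config[names(model$config) != "seed"],
           list(seed = model$config$seed, encoding = model$encoding,
                best_epoch = model$best_epoch))
  writeLines(paste0(names(cfg), ": ", unlist(cfg)),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  params <- readRDS(file.path(dir, "params.rds"))
  vocab <- read_vocabulary(file.path(dir, "vocab.txt"))
  kv <- strsplit(readLines(file.path(dir, "config.txt")), ": ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  cfg <- lm_config(
    n_layers = as.integer(vals[["n_layers"]]),
    hidden_units = as.integer(vals[["hidden_units"]]),
    dropout_last = as.numeric(vals[["dropout_last"]]),
    learning_rate = as.numeric(vals[["learning_rate"]]),
    batch_size = as.integer(vals[["batch_size"]]),
    epochs = as.integer(vals[["epochs"]]),
    max_sample_len = as.integer(vals[["max_sample_len"]]),
    seed = as.integer(vals[["seed"]])
  )
  structure(list(
    config = cfg, encoding = vals[["encoding"]], vocab = vocab,
    params = params, curve = numeric(0), heldout_curve = numeric(0),
    best_epoch = as.integer(vals[["best_epoch"]])
  ), class = "trained_lm")
}
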