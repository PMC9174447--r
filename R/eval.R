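# Distribution-matching evaluation protocol: validity/uniqueness/novelty,
# per-property 1-D Wasserstein distances with a train/train oracle
# baseline, cross-validated Gaussian KDE overlays and 2-D histograms.

EVAL_PROPERTIES <- c("logp", "sa", "qed", "mw", "bertz", "np")

#' Standard generation metrics
#'
#' The three standard ratios over a generated batch, under canonical-form
#' molecule identity: validity = valid / generated, uniqueness = unique /
#' valid, novelty = (unique not in train) / unique. Any 0/0 ratio is
#' defined as 0 and flagged in the `degenerate` column.
#'
#' @param raw_samples Character vector of raw generated strings, or a
#'   tibble with a `raw` column (e.g. from [sample_lm()]).
#' @param encoding Encoding of the raw strings.
#' @param train Training `mol_tbl` (for novelty).
#' @return A one-row tibble with counts and the three ratios.
#' @export
standard_metrics <- function(raw_samples, encoding = c("smiles", "selfies"),
                             train) {
  encoding <- match.arg(encoding)
  if (is.data.frame(raw_samples)) raw_samples <- raw_samples$raw
  abort_if(length(raw_samples) == 0L, "`raw_samples` must be non-empty")
  parsed <- parse_molecules(raw_samples, encoding = encoding,
                            source = "generated")
  n_gen <- nrow(parsed)
  valid <- parsed$canonical[parsed$is_valid]
  n_valid <- length(valid)
  uniq <- unique(valid)
  n_unique <- length(uniq)
  train_can <- train$canonical[train$is_valid]
  n_novel <- sum(!uniq %in% train_can)
  ratio <- function(num, den) if (den == 0) 0 else num / den
  tibble::tibble(
    n_generated = n_gen, n_valid = n_valid, n_unique = n_unique,
    n_novel = n_novel,
    validity = ratio(n_valid, n_gen),
    uniqueness = ratio(n_unique, n_valid),
    novelty = ratio(n_novel, n_unique),
    degenerate = n_valid == 0 || n_unique == 0
  )
}

#' 1-D Wasserstein (earth mover's) distance
#'
#' First Wasserstein distance between the equal-weight empirical
#' distributions of two samples: the integral of the absolute difference
#' of their empirical CDFs. For equal-size samples this equals the mean
#' absolute difference of sorted values. Units are the property's units.
#'
#' @param x,y Non-empty numeric samples.
#' @return A single non-negative distance.
#' @examples
#' wasserstein_1d(c(1, 2, 3), c(2, 3, 4)) # 1
#' @export
wasserstein_1d <- function(x, y) {
  abort_if(length(x) == 0L || length(y) == 0L, "empty sample")
  abort_if(anyNA(x) || anyNA(y), "NA in sample")
  all_v <- sort(c(x, y))
  if (length(all_v) == 1L) return(0)
  deltas <- diff(all_v)
  cdf_x <- stats::ecdf(x)(all_v[-length(all_v)])
  cdf_y <- stats::ecdf(y)(all_v[-length(all_v)])
  sum(abs(cdf_x - cdf_y) * deltas)
}

#' Train/train oracle distance
#'
#' The best-achievable Wasserstein distance for a perfect generator:
#' the mean, over `n_splits` random disjoint half/half partitions of the
#' training values, of the Wasserstein distance between the two halves.
#'
#' @param values Numeric property values of the training set (>= 4).
#' @param n_splits Number of random partitions.
#' @param seed Integer seed.
#' @return A single non-negative distance.
#' @export
oracle_distance <- function(values, n_splits = 10L, seed = 1L) {
  abort_if(length(values) < 4L, "need at least 4 training values")
  n <- length(values)
  half <- floor(n / 2)
  local_seed(seed, {
    mean(vapply(seq_len(n_splits), function(s) {
      idx <- sample.int(n, half)
      wasserstein_1d(values[idx], values[-idx][seq_len(half)])
    }, numeric(1)))
  })
}

#' Distribution report for a generated set
#'
#' The full comparison pipeline: generated molecules are stripped of
#' training overlap and internal duplicates, properties are computed for
#' the survivors and for the training set, and a per-property Wasserstein
#' distance to the training values is reported next to the train/train
#' oracle distance. Optionally the survivor set is first truncated to
#' `n_compare` molecules by seeded subsampling — when several models are
#' compared, pass the common minimum so all are evaluated on the same
#' count (see [compare_generations()]).
#'
#' @param gen Generated `mol_tbl` (parse raw samples first), or a tibble
#'   from [sample_lm()] plus `encoding`.
#' @param train Training `mol_tbl`.
#' @param properties Property columns to compare; penalized LogP is added
#'   for the high-LogP task via `c(EVAL_PROPERTIES, "plogp")`.
#' @param n_compare Truncate survivors to this count (NULL = all).
#' @param n_splits Oracle half-split count.
#' @param seed Seed for subsampling and oracle splits.
#' @param train_props,gen_props Optional precomputed property tables
#'   (from [compute_properties()]) to avoid recomputation.
#' @param encoding Used only when `gen` is a raw sample tibble.
#' @return A `distribution_report` object: list with `standard` (one-row
#'   metric tibble), `distances` (per-property `w_model`, `w_oracle`),
#'   `n_compared`, and the property tables.
#' @export
distribution_report <- function(gen, train, properties = EVAL_PROPERTIES,
                                n_compare = NULL, n_splits = 10L, seed = 1L,
                                train_props = NULL, gen_props = NULL,
                                encoding = "smiles") {
  if (!"is_valid" %in% names(gen)) {
    gen <- parse_molecules(gen, encoding = encoding, source = "generated")
  }
  std <- standard_metrics(gen$raw, encoding = gen$encoding[1] %||% encoding,
                          train = train)
  survivors <- remove_overlap(gen, train)
  abort_if(nrow(survivors) == 0L,
           paste0("no generated molecules survive overlap removal (",
                  nrow(gen), " in, ", std$n_valid, " valid)"))
  if (!is.null(n_compare)) {
    abort_if(n_compare > nrow(survivors),
             "`n_compare` exceeds the number of surviving molecules")
    survivors <- local_seed(seed, {
      survivors[sort(sample.int(nrow(survivors), n_compare)), , drop = FALSE]
    })
  }
  if (is.null(gen_props)) gen_props <- compute_properties(survivors)
  if (is.null(train_props)) train_props <- compute_properties(train)
  train_props <- train_props[train_props$is_valid, , drop = FALSE]
  distances <- purrr::map_dfr(properties, function(p) {
    tv <- train_props[[p]]
    gv <- gen_props[[p]][gen_props$is_valid]
    tibble::tibble(
      property = p,
      w_model = wasserstein_1d(gv, tv),
      w_oracle = oracle_distance(tv, n_splits = n_splits,
                                 seed = derive_seed(seed, p))
    )
  })
  structure(list(
    standard = std, distances = distances, n_compared = nrow(survivors),
    gen_props = gen_props, train_props = train_props
  ), class = "distribution_report")
}

#' @export
print.distribution_report <- function(x, ...) {
  cat("<distribution_report> ", x$n_compared, " generated molecules compared\n",
      sep = "")
  cat(sprintf("  validity %.3f  uniqueness %.3f  novelty %.3f\n",
              x$standard$validity, x$standard$uniqueness, x$standard$novelty))
  print(x$distances)
  invisible(x)
}

#' @export
tidy.distribution_report <- function(x, ...) x$distances

#' @export
glance.distribution_report <- function(x, ...) {
  dplyr::bind_cols(
    x$standard[, c("validity", "uniqueness", "novelty")],
    tidyr::pivot_wider(x$distances[, c("property", "w_model")],
                       names_from = "property", values_from = "w_model",
                       names_prefix = "w_"),
    tibble::tibble(n_compared = x$n_compared)
  )
}

#' Compare several generated sets on equal footing
#'
#' Runs [distribution_report()] for every model with the survivor count
#' equalized to the common minimum (seeded subsampling), so the reported
#' distances are comparable across models.
#'
#' @param gens Named list of generated `mol_tbl`s.
#' @param train Training `mol_tbl`.
#' @param ... Passed to [distribution_report()].
#' @param seed Seed for the equalizing subsample.
#' @return Named list of `distribution_report`s (attribute `n_compared`
#'   gives the common count).
#' @export
compare_generations <- function(gens, train, ..., seed = 1L) {
  abort_if(length(gens) == 0L, "no generated sets supplied")
  n_surv <- vapply(gens, function(g) nrow(remove_overlap(g, train)),
                   integer(1))
  n_common <- min(n_surv)
  abort_if(n_common == 0L, "a model has no surviving molecules")
  train_props <- compute_properties(train)
  out <- purrr::imap(gens, function(g, nm) {
    distribution_report(g, train, n_compare = n_common, seed = seed,
                        train_props = train_props, ...)
  })
  attr(out, "n_compared") <- n_common
  out
}

#' Kernel density comparison curves
#'
#' Gaussian KDE curves for the training values and any number of model
#' value sets on a shared grid. The bandwidth is tuned on the TRAIN values
#' only — maximizing 5-fold cross-validated log-likelihood over a
#' logarithmic grid of 20 bandwidths spanning \[0.01, 10\] times the
#' training standard deviation — and the same bandwidth is applied to
#' every model's KDE. Each curve integrates to 1 (trapezoid rule).
#'
#' @param train_values Numeric vector (>= 10 values).
#' @param model_values Named list of numeric vectors (may be empty).
#' @param n_grid Grid resolution.
#' @param grid Optional explicit grid (range is padded otherwise).
#' @param seed Seed for the CV fold assignment.
#' @param bandwidth Fixed bandwidth in property units; skips the
#'   cross-validated tuning when supplied.
#' @return A `kde_curves` object: tibble with columns `x`, `density`,
#'   `set`; attributes `bandwidth` and `grid`.
#' @export
kde_curves <- function(train_values, model_values = list(), n_grid = 512L,
                       grid = NULL, seed = 1L, bandwidth = NULL) {
  abort_if(length(train_values) < 10L, "need at least 10 training values")
  stopifnot(is.list(model_values))
  if (is.null(bandwidth)) {
    sdv <- stats::sd(train_values)
    abort_if(!is.finite(sdv) || sdv == 0, "training values are degenerate")
    bws <- exp(seq(log(0.01 * sdv), log(10 * sdv), length.out = 20L))
    folds <- local_seed(seed, {
      sample(rep_len(1:5, length(train_values)))
    })
    cv_ll <- vapply(bws, function(h) {
      ll <- 0
      for (f in 1:5) {
        tr <- train_values[folds != f]
        te <- train_values[folds == f]
        dens <- vapply(te, function(z) mean(stats::dnorm(z, tr, h)), numeric(1))
        ll <- ll + sum(log(pmax(dens, 1e-300)))
      }
      ll
    }, numeric(1))
    bandwidth <- bws[which.max(cv_ll)]
  }
  h <- bandwidth
  all_v <- c(train_values, unlist(model_values, use.names = FALSE))
  if (is.null(grid)) {
    pad <- 3 * h
    grid <- seq(min(all_v) - pad, max(all_v) + pad, length.out = n_grid)
  }
  kde_on <- function(vals) {
    vapply(grid, function(z) mean(stats::dnorm(z, vals, h)), numeric(1))
  }
  sets <- c(list(train = train_values), model_values)
  curves <- purrr::imap_dfr(sets, function(vals, nm) {
    tibble::tibble(x = grid, density = kde_on(vals), set = nm)
  })
  structure(curves, bandwidth = h, grid = grid, class = c("kde_curves",
                                                          class(curves)))
}

# count of prominent local maxima of a kde curve; maxima below
# `prominence` times the global maximum are treated as micro-structure,
# not modes
kde_modes <- function(curves, set = "train", prominence = 0.1) {
  d <- curves$density[curves$set == set]
  peaks <- which(diff(sign(diff(d))) == -2) + 1L
  sum(d[peaks] >= prominence * max(d))
}

#' 2-D property histogram
#'
#' Joint histogram of two property columns; counts sum to the number of
#' rows.
#'
#' @param rows A data frame of property rows (see [compute_properties()]).
#' @param prop_x,prop_y Column names.
#' @param bins Bin counts `c(nx, ny)`.
#' @param limits Optional list with `x` and `y` ranges.
#' @return A `hist2d` object: list with `counts` (nx x ny matrix),
#'   `x_edges`, `y_edges`, `prop_x`, `prop_y`.
#' @export
histogram2d <- function(rows, prop_x, prop_y, bins = c(30L, 30L),
                        limits = NULL) {
  x <- rows[[prop_x]]
  y <- rows[[prop_y]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  abort_if(length(x) == 0L, "no complete property rows")
  bins <- rep_len(bins, 2L)
  xr <- limits$x %||% range(x)
  yr <- limits$y %||% range(y)
  if (diff(xr) == 0) xr <- xr + c(-0.5, 0.5)
  if (diff(yr) == 0) yr <- yr + c(-0.5, 0.5)
  x_edges <- seq(xr[1], xr[2], length.out = bins[1] + 1L)
  y_edges <- seq(yr[1], yr[2], length.out = bins[2] + 1L)
  xi <- findInterval(x, x_edges, rightmost.closed = TRUE, all.inside = TRUE)
  yi <- findInterval(y, y_edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins[1], bins[2])
  for (k in seq_along(xi)) counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1L
  structure(list(counts = counts, x_edges = x_edges, y_edges = y_edges,
                 prop_x = prop_x, prop_y = prop_y), class = "hist2d")
}
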