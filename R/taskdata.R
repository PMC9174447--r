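# Training-distribution builders and seeded synthetic molecule pools.
#
# The three benchmark distributions are (1) a high penalized-LogP screen
# (score > 4.0), (2) a four-window molecular-weight composite and (3) a
# large-molecule screen (> 100 heavy atoms). The synthetic pool generator
# stands in for the ZINC / GDB13 / CEP / POLYMERS / PubChem extracts those
# screens would normally consume, so the full pipeline runs without
# downloads.

#' Screen a pool for high penalized LogP
#'
#' Keeps exactly the valid molecules with penalized LogP strictly above
#' `threshold` (default 4.0, the benchmark screening value), in their
#' original order.
#'
#' @param mols A `mol_tbl`.
#' @param threshold Penalized-LogP cutoff (exclusive).
#' @return The surviving records, with a `plogp` column attached.
#' @export
screen_penalized_logp <- function(mols, threshold = 4.0) {
  valid <- mols[mols$is_valid, , drop = FALSE]
  if (nrow(valid) == 0L) {
    warning("no valid molecules to screen")
    return(dplyr::mutate(valid, plogp = double(0)))
  }
  plogp <- properties_for_smiles(valid$canonical)$plogp
  out <- dplyr::mutate(valid, plogp = plogp)
  out <- out[plogp > threshold, , drop = FALSE]
  if (nrow(out) == 0L) warning("screen produced an empty set")
  out
}

#' Screen a pool for large molecules
#'
#' Keeps exactly the valid molecules with strictly more than
#' `min_heavy_exclusive` heavy (non-hydrogen) atoms; the default boundary of
#' 100 makes 101 the smallest surviving atom count.
#'
#' @param mols A `mol_tbl`.
#' @param min_heavy_exclusive Heavy-atom cutoff (exclusive).
#' @return The surviving records, with an `n_atoms` column attached.
#' @export
screen_large <- function(mols, min_heavy_exclusive = 100L) {
  valid <- mols[mols$is_valid, , drop = FALSE]
  if (nrow(valid) == 0L) return(dplyr::mutate(valid, n_atoms = integer(0)))
  n_atoms <- heavy_atom_count(valid$canonical)
  out <- dplyr::mutate(valid, n_atoms = n_atoms)
  out[n_atoms > min_heavy_exclusive, , drop = FALSE]
}

# the four molecular-weight windows of the multi-distribution task;
# boundaries are inclusive as printed except the strict > 600
MULTI_WINDOWS <- list(
  gdb13    = c(-Inf, 185),
  zinc     = c(185, 425),
  cep      = c(460, 600),
  polymers = c(600, Inf)
)

multi_window_ok <- function(mw, window) {
  lo <- MULTI_WINDOWS[[window]][1]
  hi <- MULTI_WINDOWS[[window]][2]
  if (window == "polymers") mw > lo else mw >= lo & mw <= hi
}

#' Compose the four-window multi-modal training set
#'
#' Draws a composite of `total` molecules from four pools keyed
#' `gdb13` (MW <= 185), `zinc` (185 <= MW <= 425), `cep` (460 <= MW <= 600)
#' and `polymers` (MW > 600), with fractions 1/6, 1/3, 1/6 and 1/3: the
#' small-molecule (gdb13) and photovoltaic (cep) pools jointly contribute
#' one third, while the drug-like (zinc) and polymer pools contribute one
#' third each. Quotas are rounded with total deviation at most 1 per
#' component; sampling is without replacement under `seed`. Every pool is
#' validated against its own window first (exact molecular weight); a
#' violator or an under-sized pool is an error.
#'
#' @param pools Named list of four `mol_tbl`s (`gdb13`, `zinc`, `cep`,
#'   `polymers`).
#' @param total Target size of the composite.
#' @param seed Integer seed for the subsampling.
#' @param fractions Named fractions per pool (must sum to 1); override of
#'   the default 1/6, 1/3, 1/6, 1/3 split.
#' @return A `mol_tbl` of size `total` with `source` set to the pool key.
#' @export
compose_multimodal <- function(pools, total, seed = 1L,
                               fractions = c(gdb13 = 1 / 6, zinc = 1 / 3,
                                             cep = 1 / 6, polymers = 1 / 3)) {
  abort_if(!setequal(names(pools), names(MULTI_WINDOWS)),
           "`pools` must be named gdb13, zinc, cep, polymers")
  abort_if(abs(sum(fractions) - 1) > 1e-8, "`fractions` must sum to 1")
  for (w in names(pools)) {
    mw <- ob_exact_mass(pools[[w]]$canonical[pools[[w]]$is_valid])
    bad <- which(!multi_window_ok(mw, w))
    abort_if(length(bad) > 0L,
             paste0("pool `", w, "` violates its MW window: ",
                    paste0(utils::head(pools[[w]]$canonical[pools[[w]]$is_valid][bad], 5),
                           collapse = ", ")))
  }
  quota <- floor(fractions[names(MULTI_WINDOWS)] * total)
  rem <- total - sum(quota)
  if (rem > 0) {
    top <- order(fractions[names(MULTI_WINDOWS)] * total - quota,
                 decreasing = TRUE)[seq_len(rem)]
    quota[top] <- quota[top] + 1
  }
  out <- list()
  local_seed(seed, {
    for (w in names(MULTI_WINDOWS)) {
      pool <- pools[[w]][pools[[w]]$is_valid, , drop = FALSE]
      abort_if(nrow(pool) < quota[[w]],
               paste0("pool `", w, "` has ", nrow(pool),
                      " molecules but the quota is ", quota[[w]]))
      take <- sort(sample.int(nrow(pool), quota[[w]]))
      sel <- pool[take, , drop = FALSE]
      sel$source <- w
      out[[w]] <- sel
    }
  })
  dplyr::bind_rows(out)
}

# ---------------------------------------------------------------------------
# synthetic pools

RING_FRAGS <- c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "C1CCNCC1", "c1ccoc1",
                "c1ccsc1", "C1CCCC1", "C1CCOCC1")
# substituents written as SMILES branch bodies
SUBSTITUENTS <- c("C", "CC", "CCC", "C(C)C", "O", "OC", "N", "NC", "F", "Cl",
                  "Br", "C(=O)O", "C(=O)N", "C#N", "C(=O)C", "CO", "CCO",
                  "OCC", "CN")
LINKERS <- c("C", "CC", "CCC", "O", "N", "CO", "CN", "C(=O)", "C(=O)N", "CC(=O)")

AA_SIDE_CHAINS <- c(
  G = "", A = "C", V = "C(C)C", L = "CC(C)C", I = "C(C)CC", M = "CCSC",
  F = "Cc1ccccc1", W = "Cc1c[nH]c2ccccc12", P = "proline", S = "CO",
  T = "C(C)O", C = "CS", Y = "Cc1ccc(O)cc1", N = "CC(=O)N", Q = "CCC(=O)N",
  D = "CC(=O)O", E = "CCC(=O)O", K = "CCCCN", R = "CCCNC(=N)N",
  H = "Cc1cnc[nH]1"
)

# one ring with 1..3 substituents at ring positions, optionally linked to a
# second ring
assemble_druglike <- function() {
  ring <- sample(RING_FRAGS, 1)
  n_sub <- sample(1:3, 1)
  subs <- sample(SUBSTITUENTS, n_sub, replace = TRUE)
  body <- attach_substituents(ring, subs)
  if (stats::runif(1) < 0.4) {
    ring2 <- sample(RING_FRAGS, 1)
    link <- sample(LINKERS, 1)
    subs2 <- sample(SUBSTITUENTS, sample(0:2, 1), replace = TRUE)
    body <- paste0(body, link, attach_substituents(ring2, subs2))
  }
  body
}

# insert branch substituents after ring atoms (never at a fusion or
# two-digit position); works on the simple single-ring fragments above
attach_substituents <- function(ring, subs) {
  if (length(subs) == 0L) return(ring)
  toks <- tokenize_smiles(ring)
  atom_pos <- which(toks %in% ATOM_ORGANIC | startsWith(toks, "["))
  # skip the first ring atom (carries the opening digit context)
  cand <- setdiff(atom_pos, atom_pos[1])
  # only substitute at plain carbons to keep valences safe, and never at an
  # atom whose ring-closure digit follows (the branch would split them)
  cand <- cand[toks[cand] %in% c("c", "C")]
  nxt <- toks[pmin(cand + 1L, length(toks))]
  cand <- cand[!(nxt %in% as.character(0:9) | startsWith(nxt, "%"))]
  if (length(cand) == 0L) return(ring)
  at <- cand[sample.int(length(cand), min(length(subs), length(cand)))]
  for (j in seq_along(at)) {
    toks[at[j]] <- paste0(toks[at[j]], "(", subs[j], ")")
  }
  paste0(toks, collapse = "")
}

# chain-rich high-LogP molecule: a long alkyl chain, occasional methyl
# branches, rarely a terminal ring
assemble_highlogp <- function() {
  len <- sample(14:32, 1)
  toks <- rep("C", len)
  n_branch <- stats::rbinom(1, 3, 0.3)
  if (n_branch > 0) {
    pos <- sample(2:(len - 1), min(n_branch, len - 2))
    toks[pos] <- "C(C)"
  }
  body <- paste0(toks, collapse = "")
  if (stats::runif(1) < 0.15) body <- paste0(body, "c1ccccc1")
  body
}

# linear peptide SMILES for a residue sequence (one-letter codes)
peptide_smiles <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  abort_if(!all(res %in% names(AA_SIDE_CHAINS)),
           "unknown residue in peptide sequence")
  units <- character(length(res))
  ring_digit <- 8L # proline backbone ring: cycle through %80..%99 if needed
  for (i in seq_along(res)) {
    sc <- AA_SIDE_CHAINS[[res[i]]]
    if (identical(sc, "proline")) {
      lab <- sprintf("%%%02d", ring_digit)
      ring_digit <- ring_digit + 1L
      units[i] <- paste0("N", lab, "CCCC", lab, "C(=O)")
    } else if (sc == "") {
      units[i] <- "NCC(=O)"
    } else {
      units[i] <- paste0("NC(", sc, ")C(=O)")
    }
  }
  paste0(paste0(units, collapse = ""), "O")
}

random_peptide <- function(length) {
  paste0(sample(names(AA_SIDE_CHAINS), length, replace = TRUE), collapse = "")
}

#' Generate a seeded synthetic molecule pool
#'
#' Deterministic (per seed) molecule pools emulating the screening sources
#' of the three benchmark tasks:
#'
#' * `druglike` — small ring/chain molecules assembled from a fragment
#'   grammar, rejection-sampled into MW 150-450 (the drug-like regime);
#' * `window` — the same grammar (plus chain extension / oligomer repeats at
#'   the extremes) rejection-sampled into the MW window `c(lo, hi)`;
#' * `highlogp` — long-carbon-chain, ring-poor molecules, the motif of the
#'   high penalized-LogP screen (the majority score above 4.0);
#' * `peptide` — linear peptides with uniformly random standard-residue
#'   sequences of length `peptide_length`;
#' * `alkane` — the linear alkane series C`lo`..C`hi` (no randomness beyond
#'   ordering).
#'
#' @param kind One of `"druglike"`, `"window"`, `"highlogp"`, `"peptide"`,
#'   `"alkane"`.
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @param window MW window `c(lo, hi)` for `kind = "window"`.
#' @param peptide_length Residue count for `kind = "peptide"`.
#' @param alkane_range Carbon-count range `c(k1, k2)` for `kind = "alkane"`.
#' @param max_tries Rejection-sampling budget per requested molecule.
#' @return A `mol_tbl` of `n` records tagged with the pool kind. For
#'   `peptide` pools the `source` tag carries the residue sequence.
#' @export
make_synthetic_pool <- function(kind = c("druglike", "window", "highlogp",
                                         "peptide", "alkane"),
                                n, seed = 1L,
                                window = NULL, peptide_length = 12L,
                                alkane_range = NULL, max_tries = 200L) {
  kind <- match.arg(kind)
  abort_if(n < 1L, "`n` must be at least 1")
  if (kind == "alkane") {
    rng <- alkane_range %||% c(1L, n)
    ks <- seq(rng[1], rng[2])
    if (length(ks) > n) ks <- ks[seq_len(n)]
    return(parse_molecules(vapply(ks, function(k) strrep("C", k), ""),
                           source = "alkane"))
  }
  if (kind == "druglike") window <- c(150, 450)
  gen <- local_seed(seed, {
    switch(kind,
      druglike = ,
      window = pool_in_window(n, window, max_tries),
      highlogp = replicate(n, assemble_highlogp()),
      peptide = replicate(n, random_peptide(peptide_length))
    )
  })
  if (kind == "peptide") {
    smis <- vapply(gen, peptide_smiles, "")
    return(parse_molecules(smis, source = gen))
  }
  parse_molecules(gen, source = kind)
}

# rejection-sample the fragment grammar into a MW window; heavier windows
# are reached by chain extension or thiophene-oligomer repeats
pool_in_window <- function(n, window, max_tries) {
  abort_if(is.null(window) || length(window) != 2L,
           "`window` must be c(lo, hi)")
  lo <- window[1]; hi <- window[2]
  out <- character(0)
  batch <- max(2L * n, 50L)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    abort_if(tries > max_tries,
             paste0("window [", lo, ", ", hi, "] infeasible after ",
                    max_tries, " rejection rounds"))
    cand <- vapply(seq_len(batch), function(i) {
      if (hi <= 200) {
        # small regime: bare fragments with 0-2 substituents
        attach_substituents(sample(RING_FRAGS, 1),
                            sample(SUBSTITUENTS, sample(0:2, 1), replace = TRUE))
      } else if (lo >= 425) {
        # heavy regime: conjugated thiophene/phenyl oligomers or long chains
        k <- sample(4:14, 1)
        paste0(c(sample(c("c1ccc(cc1)", "c1ccc(s1)"), k, replace = TRUE), "C"),
               collapse = "-")
      } else {
        assemble_druglike()
      }
    }, "")
    cand <- unique(cand)
    can <- ob_canonical(cand)
    ok <- !is.na(can)
    if (!any(ok)) next
    mw <- ob_exact_mass(can[ok])
    hit <- cand[ok][mw >= lo & mw <= hi]
    out <- c(out, hit)
  }
  out[seq_len(n)]
}
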