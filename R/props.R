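# Per-molecule property battery.
#
# LogP and the hydrogen-bond / polar-surface inputs of QED come from the
# OpenBabel descriptor backend (Wildman-Crippen-type atomic contributions
# for LogP); molecular weight is the exact (monoisotopic) mass. The
# remaining descriptors are implemented in-package on the molecular graph:
# a Bertz-style complexity index, an Ertl-Schuffenhauer-style synthetic
# accessibility score on [1, 10], a Bickerton QED from the published
# desirability (ADS) parameters, and a compact natural-product-likeness
# score on [-5, 5]. All values are computed on the canonical form, so they
# are invariant to SMILES respelling.

QED_ADS <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764, d = 2.419764353,
             e = 49.22325677, f = 65.37051707, dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431, d = 4.581497897,
             e = 0.822739154, f = 0.576295591, dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657, d = 4.435986202,
             e = 0.290141953, f = 1.300669958, dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388, d = 0.000000001,
             e = 0.713820843, f = 0.920922555, dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554, d = 87.83366614,
             e = 12.01999824, f = 28.51324732, dmax = 104.5686167),
  ROTB   = c(a = 0.010000091, b = 272.4121427, c = 2.558379970, d = 1.565547684,
             e = 1.271567166, f = 2.758063707, dmax = 105.4420403),
  AROM   = c(a = 3.217788970, b = 957.7374108, c = 2.274627939, d = 0.000000001,
             e = 1.317690384, f = 0.375760881, dmax = 312.3372610),
  ALERTS = c(a = 0.010000000, b = 1199.094025, c = -0.09002883, d = 0.000000001,
             e = 0.185904477, f = 0.875193782, dmax = 417.7253140)
)

QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# compact structural-alert set used by the QED ALERTS term
ALERT_SMARTS <- c(
  "[SH]", "N=N", "C(=O)Cl", "C(=O)Br", "N=C=O", "N=C=S",
  "C1OC1", "C1NC1", "OO", "SS", "[CH1]=O", "C(=S)S"
)

qed_ads <- function(x, p) {
  num <- p[["b"]] /
    (1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])) *
    (1 - 1 / (1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])))
  pmax((p[["a"]] + num) / p[["dmax"]], 1e-9)
}

# rotatable bonds: acyclic single bonds between two non-terminal heavy
# atoms, amide C-N excluded
count_rotatable <- function(g) {
  b <- g$bonds
  if (nrow(b) == 0L) return(0L)
  deg <- heavy_degree(g)
  cand <- b$order == 1L & !b$ring & deg[b$a1] > 1L & deg[b$a2] > 1L
  if (!any(cand)) return(0L)
  # amide: C(=O)-N
  has_carbonyl <- rep(FALSE, g$n_heavy)
  co <- b$order == 2L &
    ((g$elements[b$a1] == "C" & g$elements[b$a2] == "O") |
     (g$elements[b$a2] == "C" & g$elements[b$a1] == "O"))
  carbons <- ifelse(g$elements[b$a1] == "C", b$a1, b$a2)[co]
  has_carbonyl[carbons] <- TRUE
  amide <- (g$elements[b$a1] == "N" & has_carbonyl[b$a2]) |
           (g$elements[b$a2] == "N" & has_carbonyl[b$a1])
  sum(cand & !amide)
}

# per-atom circular environment classes (radius-r iterated relabelling)
morgan_classes <- function(g, radius = 2L) {
  inv <- paste0(g$elements, "|", heavy_degree(g), "|", implicit_h(g), "|",
                as.integer(g$aromatic))
  b <- g$bonds
  adj <- adjacency(g$n_heavy, b)
  for (r in seq_len(radius)) {
    nxt <- inv
    for (v in seq_len(g$n_heavy)) {
      nb <- adj$nbr[[v]]
      if (length(nb) > 0L) {
        lab <- sort(paste0(b$order[adj$eid[[v]]], ":", inv[nb]))
        nxt[v] <- paste0(inv[v], "{", paste0(lab, collapse = ","), "}")
      }
    }
    inv <- nxt
  }
  inv
}

# Ertl-Schuffenhauer-style synthetic accessibility on [1, 10]: graph
# complexity terms (branching, ring systems, macrocycles, heteroatom and
# unsaturation load, size) minus a repeated-environment (symmetry) credit.
sa_score_graph <- function(g, rings = NULL) {
  rings <- rings %||% sssr_rings(g)
  deg <- heavy_degree(g)
  sizes <- lengths(rings)
  n_fused_pairs <- 0L
  if (length(rings) >= 2L) {
    for (i in seq_len(length(rings) - 1L)) {
      for (j in (i + 1L):length(rings)) {
        if (length(intersect(rings[[i]], rings[[j]])) > 0L) {
          n_fused_pairs <- n_fused_pairs + 1L
        }
      }
    }
  }
  hetero <- mean(!g$elements %in% c("C", "H"))
  multi <- if (nrow(g$bonds) > 0) mean(g$bonds$order > 1L & !g$bonds$arom) else 0
  cls <- morgan_classes(g)
  symmetry <- 1 - length(unique(cls)) / g$n_heavy
  s <- 1 +
    0.012 * max(0, g$n_heavy - 10) +
    0.10 * sum(deg == 3L) + 0.25 * sum(deg >= 4L) +
    0.20 * length(rings) + 0.40 * n_fused_pairs +
    0.80 * sum(sizes > 8L) +
    1.50 * hetero + 0.50 * multi -
    2.00 * symmetry
  min(max(s, 1), 10)
}

# Bertz-style complexity: bond-pair connectivity term plus an
# element/environment information term
bertz_graph <- function(g) {
  deg <- heavy_degree(g)
  p <- sum(choose(deg, 2))
  conn <- if (p >= 1) 2 * p * log2(p) else 0
  cls <- table(paste0(g$elements, "|", deg))
  n <- g$n_heavy
  info <- n * log2(n) - sum(cls * log2(cls))
  conn + info
}

# compact natural-product-likeness on [-5, 5]
np_score_graph <- function(g) {
  el <- g$elements
  n <- g$n_heavy
  multi_at <- rep(FALSE, n)
  if (nrow(g$bonds) > 0) {
    mm <- g$bonds$order > 1L
    multi_at[c(g$bonds$a1[mm], g$bonds$a2[mm])] <- TRUE
  }
  sp3_c <- mean(el == "C" & !g$aromatic & !multi_at)
  ring_at <- rep(FALSE, n)
  if (nrow(g$bonds) > 0) {
    rr <- g$bonds$ring
    ring_at[c(g$bonds$a1[rr], g$bonds$a2[rr])] <- TRUE
  }
  s <- 3.0 * sp3_c + 1.2 * mean(el == "O") + 0.5 * mean(ring_at) -
    2.5 * mean(g$aromatic) - 2.0 * mean(el %in% c("F", "Cl", "Br", "I")) -
    0.8 * mean(el == "N")
  min(max(s, -5), 5)
}

# all properties for a vector of *canonical* SMILES
properties_for_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) {
    return(tibble::tibble(
      logp = double(), sa = double(), qed = double(), mw = double(),
      bertz = double(), np = double(), plogp = double(),
      n_atoms = integer(), n_rings = integer(), longest_chain = integer()
    ))
  }
  refs <- ob_mols(smiles)
  ob <- ob_descriptors(smiles, mols = refs)
  graphs <- mol_graphs(smiles)
  alerts <- integer(n)
  for (pat in ALERT_SMARTS) {
    alerts <- alerts + ob_smarts_count(smiles, pat, mols = refs)
  }
  sa <- qed <- bertz <- np <- ring_pen <- numeric(n)
  n_atoms <- n_rings <- chain <- integer(n)
  for (i in seq_len(n)) {
    g <- graphs[[i]]
    rings <- sssr_rings(g)
    sa[i] <- sa_score_graph(g, rings)
    bertz[i] <- bertz_graph(g)
    np[i] <- np_score_graph(g)
    ring_pen[i] <- sum(lengths(rings) > 6L)
    n_atoms[i] <- g$n_heavy
    n_rings[i] <- length(rings)
    chain[i] <- longest_carbon_chain_graph(g)
    vals <- c(MW = ob$mw_avg[i], ALOGP = ob$logp[i], HBA = ob$hba[i],
              HBD = ob$hbd[i], PSA = ob$tpsa[i],
              ROTB = count_rotatable(g), AROM = n_aromatic_rings(g),
              ALERTS = alerts[i])
    d <- vapply(names(QED_ADS), function(k) qed_ads(vals[[k]], QED_ADS[[k]]),
                numeric(1))
    qed[i] <- exp(sum(QED_WEIGHTS * log(d)) / sum(QED_WEIGHTS))
  }
  tibble::tibble(
    logp = ob$logp, sa = sa, qed = qed, mw = ob$exact_mass,
    bertz = bertz, np = np, plogp = ob$logp - sa - ring_pen,
    n_atoms = n_atoms, n_rings = n_rings, longest_chain = chain
  )
}

#' Compute the molecular property battery
#'
#' Adds the ten per-molecule property columns used throughout the
#' evaluation protocol to a molecule table: `logp` (Wildman-Crippen-type
#' octanol-water partition coefficient), `sa` (synthetic accessibility,
#' 1 easy to 10 hard), `qed` (drug-likeness desirability in \[0, 1\]), `mw`
#' (exact molecular weight, g/mol), `bertz` (complexity index), `np`
#' (natural-product likeness in \[-5, 5\]), `plogp` (penalized LogP),
#' `n_atoms` (heavy atoms), `n_rings` (smallest set of smallest rings),
#' `longest_chain` (atoms in the longest simple carbon path). Invalid
#' records receive `NA` in every property column.
#'
#' @param mols A `mol_tbl` (or data frame with `canonical` and `is_valid`).
#' @return The input with property columns appended.
#' @examples
#' \donttest{
#' parse_molecules(c("c1ccccc1", "CCCCCC")) |> compute_properties()
#' }
#' @export
compute_properties <- function(mols) {
  abort_if(!all(c("canonical", "is_valid") %in% names(mols)),
           "`mols` must have `canonical` and `is_valid` columns (see parse_molecules)")
  empty <- properties_for_smiles(character(0))
  out <- empty[rep(NA_integer_, nrow(mols)), ]
  if (any(mols$is_valid)) {
    out[mols$is_valid, ] <- properties_for_smiles(mols$canonical[mols$is_valid])
  }
  # a screen may already have attached e.g. plogp/n_atoms: recomputed values win
  mols <- mols[, setdiff(names(mols), names(out)), drop = FALSE]
  dplyr::bind_cols(mols, out)
}

#' Penalized LogP
#'
#' The composite screening score `logp - sa - ring_penalty`, where the ring
#' penalty is the number of SSSR rings with more than 6 atoms ("unrealistic"
#' rings). High scorers are typically long-carbon-chain molecules with few
#' rings. Raw (non-normalized) scale.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Numeric vector of penalized LogP values.
#' @export
penalized_logp <- function(smiles) {
  can <- canonical_smiles(smiles)
  properties_for_smiles(can)$plogp
}

#' Longest carbon chain
#'
#' Length (atom count) of the longest simple path in the subgraph induced
#' by carbon atoms and carbon-carbon bonds; exhaustive search. A molecule
#' with no carbon scores 0.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Integer vector of chain lengths.
#' @export
longest_carbon_chain <- function(smiles) {
  can <- canonical_smiles(smiles)
  graphs <- mol_graphs(can)
  vapply(graphs, function(g) {
    if (!any(g$elements == "C")) 0L else as.integer(longest_carbon_chain_graph(g))
  }, integer(1))
}

#' Heavy-atom counts
#'
#' @param smiles Character vector of valid SMILES.
#' @return Integer vector of non-hydrogen atom counts.
#' @export
heavy_atom_count <- function(smiles) {
  can <- canonical_smiles(smiles)
  vapply(mol_graphs(can), function(g) g$n_heavy, integer(1))
}
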