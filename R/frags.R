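# Large-molecule structural analyses: fragment decomposition, amino-acid
# substructure counting, fingerprint nearest-neighbour search.
#
# Fragmentation convention: every acyclic single bond (single-order,
# non-aromatic, not in any ring) is cut and the connected components that
# remain are the fragments. This is the simplest scheme that yields the
# four reported categories (single atoms, single rings, fused rings); it
# is a convention of this package, stated here and in the vignette.

# residue substructure patterns: backbone N-CA-C(=O) plus the full side
# chain. `ca` is the alpha-carbon atom index in the pattern's SMILES atom
# order; `open` atoms may carry extra bonds in the target (backbone N and
# carbonyl C), every other atom must match its heavy degree exactly.
aa_pattern_specs <- function() {
  side <- AA_SIDE_CHAINS[setdiff(names(AA_SIDE_CHAINS), "P")]
  specs <- lapply(names(side), function(code) {
    sc <- side[[code]]
    if (sc == "") {
      list(code = "G", smiles = "NCC=O", ca = 2L, open = c(1L, 3L))
    } else {
      smi <- paste0("NC(", sc, ")C=O")
      n_side <- length(smiles_atom_tokens(tokenize_smiles(sc))$element)
      list(code = code, smiles = smi, ca = 2L,
           open = c(1L, 3L + n_side))
    }
  })
  specs[[length(specs) + 1L]] <- list(code = "P", smiles = "O=CC1CCCN1",
                                      ca = 3L, open = c(2L, 7L))
  names(specs) <- vapply(specs, `[[`, "", "code")
  specs
}

pattern_env <- new.env(parent = emptyenv())

aa_patterns <- function() {
  if (is.null(pattern_env$aa)) {
    specs <- aa_pattern_specs()
    graphs <- mol_graphs(vapply(specs, `[[`, "", "smiles"))
    pattern_env$aa <- purrr::map2(specs, graphs, function(sp, g) {
      sp$graph <- g
      sp$igraph <- igraph::graph_from_data_frame(
        d = g$bonds[, c("a1", "a2")], directed = FALSE,
        vertices = data.frame(name = seq_len(g$n_heavy)))
      sp$degree <- heavy_degree(g)
      sp
    })
  }
  pattern_env$aa
}

mol_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = g$bonds[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_len(g$n_heavy)))
}

# all substructure matches of a pattern graph in a target graph; returns a
# list of integer maps (target atom per pattern atom)
match_pattern <- function(pat, tgt, tgt_ig, tgt_degree) {
  pg <- pat$graph
  n_pat <- pg$n_heavy
  domains <- vector("list", n_pat)
  closed <- setdiff(seq_len(n_pat), pat$open)
  for (v in seq_len(n_pat)) {
    ok <- toupper(tgt$elements) == toupper(pg$elements[v]) &
      tgt$aromatic == pg$aromatic[v]
    ok <- ok & if (v %in% closed) tgt_degree == pat$degree[v]
               else tgt_degree >= pat$degree[v]
    domains[[v]] <- which(ok)
    if (length(domains[[v]]) == 0L) return(list())
  }
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(pat$igraph, tgt_ig, method = "lad",
                                  induced = FALSE, domains = domains),
    error = function(e) list()
  )
  if (length(maps) == 0L) return(list())
  # bond-order compatibility: aromatic pattern bonds need aromatic target
  # bonds; plain bonds need the same order
  tb <- tgt$bonds
  tkey <- paste0(pmin(tb$a1, tb$a2), "-", pmax(tb$a1, tb$a2))
  t_order <- stats::setNames(tb$order, tkey)
  t_arom <- stats::setNames(tb$arom, tkey)
  pb <- pg$bonds
  keep <- vapply(maps, function(mp) {
    mp <- as.integer(mp)
    ka <- mp[pb$a1]; kb <- mp[pb$a2]
    keys <- paste0(pmin(ka, kb), "-", pmax(ka, kb))
    if (anyNA(t_order[keys])) return(FALSE)
    all(ifelse(pb$arom, t_arom[keys],
               !t_arom[keys] & t_order[keys] == pb$order))
  }, logical(1))
  lapply(maps[keep], as.integer)
}

#' Count amino-acid residues by substructure search
#'
#' Matches a fixed library of 20 residue patterns — backbone N-C(alpha)-C(=O)
#' plus the complete side chain, proline with its ring-closed backbone —
#' against each molecule. Side-chain atoms must match their heavy degree
#' exactly (so glycine does not fire inside every other residue); the
#' backbone nitrogen and carbonyl carbon are open to the chain context, so
#' terminal and chain-internal residues both match. Overlapping matches of
#' the same pattern are counted once per distinct alpha-carbon.
#'
#' @param mols A `mol_tbl` or character vector of valid SMILES.
#' @return A tibble with one row per molecule and one column per residue
#'   (one-letter codes), plus `total`.
#' @export
count_amino_acids <- function(mols) {
  smiles <- if (is.data.frame(mols)) {
    abort_if(!all(mols$is_valid), "all records must be valid")
    mols$canonical
  } else {
    canonical_smiles(mols)
  }
  pats <- aa_patterns()
  graphs <- mol_graphs(smiles)
  out <- matrix(0L, nrow = length(smiles), ncol = length(pats),
                dimnames = list(NULL, names(pats)))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    tgt_ig <- mol_igraph(g)
    degs <- heavy_degree(g)
    for (p in names(pats)) {
      maps <- match_pattern(pats[[p]], g, tgt_ig, degs)
      if (length(maps) > 0L) {
        cas <- unique(vapply(maps, function(mp) mp[pats[[p]]$ca], integer(1)))
        out[i, p] <- length(cas)
      }
    }
  }
  res <- tibble::as_tibble(as.data.frame(out))
  res$total <- as.integer(rowSums(out))
  res
}

#' Fragment decomposition profile
#'
#' Cuts every acyclic single bond and classifies the resulting connected
#' components: single-atom fragments (1 heavy atom), single-ring fragments
#' (exactly one SSSR ring) and fused-ring fragments (at least two SSSR
#' rings sharing an atom). The amino-acid count comes from
#' [count_amino_acids()] on the intact molecule.
#'
#' @param mols A `mol_tbl` or character vector of valid SMILES.
#' @return A tibble with columns `n_fragments`, `n_single_atom`,
#'   `n_single_ring`, `n_fused_ring`, `n_amino_acid`.
#' @export
fragment_profile <- function(mols) {
  smiles <- if (is.data.frame(mols)) {
    abort_if(!all(mols$is_valid), "all records must be valid")
    mols$canonical
  } else {
    canonical_smiles(mols)
  }
  graphs <- mol_graphs(smiles)
  aa <- count_amino_acids(smiles)
  rows <- purrr::map_dfr(graphs, function(g) {
    keep <- !(g$bonds$order == 1L & !g$bonds$ring)
    kept <- g$bonds[keep, , drop = FALSE]
    frag_id <- component_labels(g$n_heavy, kept)
    n_frag <- max(frag_id)
    single_atom <- single_ring <- fused <- 0L
    for (f in seq_len(n_frag)) {
      atoms <- which(frag_id == f)
      if (length(atoms) == 1L) {
        single_atom <- single_atom + 1L
        next
      }
      fb <- kept[kept$a1 %in% atoms & kept$a2 %in% atoms, , drop = FALSE]
      sub <- subgraph_of(g, atoms, fb)
      rings <- sssr_rings(sub)
      if (length(rings) == 1L) {
        single_ring <- single_ring + 1L
      } else if (length(rings) >= 2L) {
        share <- FALSE
        for (a in seq_len(length(rings) - 1L)) {
          for (b2 in (a + 1L):length(rings)) {
            if (length(intersect(rings[[a]], rings[[b2]])) > 0L) share <- TRUE
          }
        }
        if (share) fused <- fused + 1L
      }
    }
    tibble::tibble(n_fragments = n_frag, n_single_atom = single_atom,
                   n_single_ring = single_ring, n_fused_ring = fused)
  })
  rows$n_amino_acid <- aa$total
  rows
}

component_labels <- function(n_atoms, bonds) {
  adj <- adjacency(n_atoms, bonds)
  lab <- rep(0L, n_atoms)
  cur <- 0L
  for (s in seq_len(n_atoms)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj$nbr[[v]]) {
        if (lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

# induced subgraph on `atoms` with the given bonds, reindexed 1..k
subgraph_of <- function(g, atoms, bonds) {
  idx <- match(seq_len(g$n_heavy), atoms)
  nb <- bonds
  nb$a1 <- idx[nb$a1]
  nb$a2 <- idx[nb$a2]
  list(elements = g$elements[atoms], aromatic = g$aromatic[atoms],
       bonds = nb, n_heavy = length(atoms))
}

#' Circular (Morgan-style) fingerprints
#'
#' Radius-2 circular atom environments hashed onto `n_bits` bits. The
#' fingerprint of a molecule is the set of on-bits; Tanimoto similarity
#' between two molecules is intersection / union of their on-bit sets.
#'
#' @param smiles Character vector of valid SMILES.
#' @param radius Environment radius.
#' @param n_bits Fingerprint width.
#' @return A list of sorted integer vectors (on-bit indices, 0-based).
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  can <- canonical_smiles(smiles)
  graphs <- mol_graphs(can)
  lapply(graphs, function(g) {
    envs <- character(0)
    for (r in 0:radius) envs <- c(envs, morgan_classes(g, radius = r))
    sort(unique(vapply(unique(envs), hash_to_bit, integer(1),
                       n_bits = n_bits, USE.NAMES = FALSE)))
  })
}

hash_to_bit <- function(s, n_bits) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h %% n_bits)
}

#' Tanimoto similarity of two on-bit sets
#'
#' @param a,b Integer vectors of on-bits.
#' @return Similarity in \[0, 1\] (empty/empty defined as 0).
#' @export
tanimoto <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Nearest neighbours by Tanimoto similarity
#'
#' Ranks a generated set by circular-fingerprint Tanimoto similarity
#' (radius 2, 2048 bits) to a reference molecule; ties are broken by
#' canonical-SMILES order so the ranking is deterministic.
#'
#' @param gen A `mol_tbl` (invalid records are ignored).
#' @param reference A single valid SMILES string.
#' @param top_k Number of hits to return.
#' @return A tibble `canonical`, `similarity`, sorted descending.
#' @export
tanimoto_nearest <- function(gen, reference, top_k = 5L) {
  valid <- gen[gen$is_valid, , drop = FALSE]
  abort_if(nrow(valid) == 0L, "`gen` has no valid molecules")
  fps <- morgan_fingerprint(valid$canonical)
  ref_fp <- morgan_fingerprint(reference)[[1]]
  sims <- vapply(fps, tanimoto, numeric(1), b = ref_fp)
  ord <- order(-sims, valid$canonical)
  take <- utils::head(ord, top_k)
  tibble::tibble(canonical = valid$canonical[take], similarity = sims[take])
}
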