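# Internal molecular-graph layer.
#
# Graphs are built from (canonical) SMILES via the OpenBabel SDF route:
# the SDF atom block lists heavy atoms in SMILES order, so per-atom aromatic
# flags can be read off the lowercase atom tokens of the SMILES itself.
# A graph is a list:
#   elements  chr   element symbols, upper-case
#   aromatic  lgl   per-atom aromatic flag
#   bonds     data.frame(a1, a2, order, ring, arom)
#   n_heavy   int

ATOM_ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I",
                  "b", "c", "n", "o", "p", "s")

# atom tokens (in order) of a SMILES token vector; returns element + aromatic
smiles_atom_tokens <- function(tokens) {
  is_bracket <- startsWith(tokens, "[")
  is_org <- tokens %in% ATOM_ORGANIC
  keep <- is_bracket | is_org
  toks <- tokens[keep]
  el <- character(length(toks))
  arom <- logical(length(toks))
  for (i in seq_along(toks)) {
    t <- toks[i]
    if (startsWith(t, "[")) {
      m <- regmatches(t, regexec("^\\[[0-9]*([A-Za-z][a-z]?)", t))[[1]]
      sym <- if (length(m) == 2L) m[2] else ""
      # a trailing upper-H capture like "nH" keeps only the element letter
      if (nchar(sym) == 2L && substr(sym, 2, 2) == "H" &&
          tolower(substr(sym, 1, 1)) == substr(sym, 1, 1)) {
        sym <- substr(sym, 1, 1)
      }
      arom[i] <- substr(sym, 1, 1) == tolower(substr(sym, 1, 1))
      el[i] <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
    } else {
      arom[i] <- t == tolower(t)
      el[i] <- paste0(toupper(substr(t, 1, 1)), substring(t, 2))
    }
  }
  list(element = el, aromatic = arom)
}

# Build graphs for a vector of valid SMILES. Returns a list of graphs.
mol_graphs <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(list())
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  abort_if(length(sdfset) != n, "SDF conversion dropped molecules")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    at <- smiles_atom_tokens(tokenize_smiles(smiles[i]))
    if (length(at$element) == 1L) {
      # single heavy atom: the SDF route degenerates, build directly
      out[[i]] <- list(
        elements = at$element, aromatic = at$aromatic,
        bonds = data.frame(a1 = integer(), a2 = integer(), order = integer(),
                           ring = logical(), arom = logical()),
        n_heavy = 1L
      )
      next
    }
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    keep <- elements != "H"
    abort_if(!all(keep), "unexpected explicit hydrogens in atom block")
    na <- length(elements)
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0))
    bonds <- if (nrow(bb) > 0 && ncol(bb) >= 3) {
      data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    } else {
      data.frame(a1 = integer(), a2 = integer(), order = integer())
    }
    if (length(at$element) == na &&
        all(toupper(at$element) == toupper(elements))) {
      aromatic <- at$aromatic
    } else {
      aromatic <- rep(FALSE, na) # conservative fallback; never hit for OB output
    }
    ring_edge <- ring_bond_flags(na, bonds)
    bonds$ring <- ring_edge
    bonds$arom <- ring_edge & aromatic[bonds$a1] & aromatic[bonds$a2]
    out[[i]] <- list(elements = elements, aromatic = aromatic,
                     bonds = bonds, n_heavy = na)
  }
  out
}

# adjacency lists: nbr[[v]] = neighbour atoms, eid[[v]] = parallel bond ids
adjacency <- function(n_atoms, bonds) {
  nbr <- vector("list", n_atoms)
  eid <- vector("list", n_atoms)
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds$a1[k]; b <- bonds$a2[k]
      nbr[[a]] <- c(nbr[[a]], b); eid[[a]] <- c(eid[[a]], k)
      nbr[[b]] <- c(nbr[[b]], a); eid[[b]] <- c(eid[[b]], k)
    }
  }
  list(nbr = nbr, eid = eid)
}

n_components <- function(n_atoms, bonds, adj = NULL) {
  adj <- adj %||% adjacency(n_atoms, bonds)
  seen <- rep(FALSE, n_atoms)
  comps <- 0L
  for (s in seq_len(n_atoms)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj$nbr[[v]]) {
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
  }
  comps
}

# TRUE for bonds that lie in a ring (= non-bridge edges); Tarjan low-link
ring_bond_flags <- function(n_atoms, bonds) {
  m <- nrow(bonds)
  if (m == 0L) return(logical(0))
  adj <- adjacency(n_atoms, bonds)
  disc <- rep(0L, n_atoms); low <- rep(0L, n_atoms)
  is_bridge <- rep(FALSE, m)
  timer <- 0L
  dfs <- function(v, pe) {
    timer <<- timer + 1L
    disc[v] <<- timer; low[v] <<- timer
    nb <- adj$nbr[[v]]; ee <- adj$eid[[v]]
    for (j in seq_along(nb)) {
      w <- nb[j]; e <- ee[j]
      if (e == pe) next
      if (disc[w] == 0L) {
        dfs(w, e)
        low[v] <<- min(low[v], low[w])
        if (low[w] > disc[v]) is_bridge[e] <<- TRUE
      } else {
        low[v] <<- min(low[v], disc[w])
      }
    }
  }
  for (s in seq_len(n_atoms)) if (disc[s] == 0L) dfs(s, 0L)
  !is_bridge
}

# BFS shortest path from u to v avoiding edge `skip`; NULL if none
bfs_path <- function(adj, u, v, skip, n_atoms) {
  parent <- rep(0L, n_atoms)
  seen <- rep(FALSE, n_atoms)
  seen[u] <- TRUE
  queue <- u
  while (length(queue) > 0L) {
    x <- queue[[1L]]; queue <- queue[-1L]
    nb <- adj$nbr[[x]]; ee <- adj$eid[[x]]
    for (j in seq_along(nb)) {
      if (ee[j] == skip) next
      w <- nb[j]
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- x
        if (w == v) {
          path <- w
          while (path[1L] != u) path <- c(parent[path[1L]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

# Smallest set of smallest rings, as a list of atom-index vectors.
# Candidates are the shortest cycle through every ring bond; a greedy pass in
# increasing size keeps cycles that are independent over GF(2) in edge space
# until the cycle rank is reached.
sssr_rings <- function(g) {
  bonds <- g$bonds
  m <- nrow(bonds)
  if (m == 0L) return(list())
  adj <- adjacency(g$n_heavy, bonds)
  comp <- n_components(g$n_heavy, bonds, adj)
  rank <- m - g$n_heavy + comp
  if (rank <= 0L) return(list())
  ring_edges <- which(bonds$ring)
  cand <- list()
  for (e in ring_edges) {
    path <- bfs_path(adj, bonds$a1[e], bonds$a2[e], e, g$n_heavy)
    if (!is.null(path) && length(path) >= 2L) cand[[length(cand) + 1L]] <- path
  }
  if (length(cand) == 0L) return(list())
  sizes <- lengths(cand)
  cand <- cand[order(sizes)]
  edge_key <- function(a, b) paste0(pmin(a, b), "-", pmax(a, b))
  all_keys <- edge_key(bonds$a1, bonds$a2)
  basis <- matrix(logical(0), nrow = 0, ncol = m)
  rings <- list()
  for (cyc in cand) {
    if (nrow(basis) >= rank) break
    nxt <- c(cyc[-1], cyc[1])
    keys <- edge_key(cyc, nxt)
    vec <- all_keys %in% keys
    red <- vec
    if (nrow(basis) > 0) {
      for (r in seq_len(nrow(basis))) {
        piv <- which(basis[r, ])[1]
        if (red[piv]) red <- xor(red, basis[r, ])
      }
    }
    if (any(red)) {
      basis <- rbind(basis, red)
      rings[[length(rings) + 1L]] <- cyc
    }
  }
  rings
}

ring_sizes <- function(g) lengths(sssr_rings(g))

n_rings_sssr <- function(g) {
  m <- nrow(g$bonds)
  if (m == 0L) return(0L)
  as.integer(m - g$n_heavy + n_components(g$n_heavy, g$bonds))
}

# number of SSSR rings in which every atom carries the aromatic flag
n_aromatic_rings <- function(g) {
  rings <- sssr_rings(g)
  if (length(rings) == 0L) return(0L)
  sum(vapply(rings, function(r) all(g$aromatic[r]), logical(1)))
}

# Longest simple path (atom count) in the carbon-carbon subgraph.
# Exhaustive DFS per component with a global step budget; components in
# drug-like and chain-rich molecules are small or tree-like, so the budget
# is never hit there.
longest_carbon_chain_graph <- function(g, max_steps = 2e6) {
  carbon <- which(g$elements == "C")
  if (length(carbon) == 0L) return(0L)
  keep <- g$bonds$a1 %in% carbon & g$bonds$a2 %in% carbon
  cb <- g$bonds[keep, , drop = FALSE]
  adj <- vector("list", g$n_heavy)
  for (k in seq_len(nrow(cb))) {
    adj[[cb$a1[k]]] <- c(adj[[cb$a1[k]]], cb$a2[k])
    adj[[cb$a2[k]]] <- c(adj[[cb$a2[k]]], cb$a1[k])
  }
  best <- 1L
  steps <- 0L
  visited <- rep(FALSE, g$n_heavy)
  dfs <- function(v, depth) {
    steps <<- steps + 1L
    if (steps > max_steps) return(invisible(NULL))
    if (depth > best) best <<- depth
    visited[v] <<- TRUE
    for (w in adj[[v]]) {
      if (!visited[w]) dfs(w, depth + 1L)
    }
    visited[v] <<- FALSE
  }
  for (v in carbon) {
    if (steps > max_steps) break
    dfs(v, 1L)
  }
  best
}

# implicit hydrogen estimate from default valences (neutral organic subset)
DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                     F = 1, Cl = 1, Br = 1, I = 1)

implicit_h <- function(g) {
  bs <- rep(0, g$n_heavy)
  if (nrow(g$bonds) > 0) {
    for (k in seq_len(nrow(g$bonds))) {
      o <- g$bonds$order[k]
      bs[g$bonds$a1[k]] <- bs[g$bonds$a1[k]] + o
      bs[g$bonds$a2[k]] <- bs[g$bonds$a2[k]] + o
    }
  }
  val <- DEFAULT_VALENCE[g$elements]
  val[is.na(val)] <- 4
  pmax(0, val - bs)
}

heavy_degree <- function(g) {
  d <- rep(0L, g$n_heavy)
  if (nrow(g$bonds) > 0) {
    t1 <- tabulate(g$bonds$a1, nbins = g$n_heavy)
    t2 <- tabulate(g$bonds$a2, nbins = g$n_heavy)
    d <- t1 + t2
  }
  d
}
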