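# Shared fixtures, built once per test session and memoized.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

# 1000-molecule drug-like pool used by the round-trip and invariant suites
druglike_1000 <- function() {
  fixture("druglike_1000", function() {
    make_synthetic_pool("druglike", 1000, seed = 420)
  })
}

druglike_small <- function() {
  fixture("druglike_small", function() {
    make_synthetic_pool("druglike", 120, seed = 77)
  })
}

# independent brute-force longest-carbon-chain oracle: enumerate all simple
# paths in the carbon subgraph via depth-first search over an edge list
# derived from the SDF bond block (no package graph code involved)
oracle_longest_chain <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1]]
  ab <- rownames(ChemmineR::atomblock(sdf))
  el <- sub("_.*$", "", ab)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0))
  carbons <- which(el == "C")
  if (length(carbons) == 0) return(0L)
  edges <- list()
  if (nrow(bb) > 0 && ncol(bb) >= 3) {
    for (k in seq_len(nrow(bb))) {
      a <- bb[k, 1]; b <- bb[k, 2]
      if (el[a] == "C" && el[b] == "C") edges[[length(edges) + 1]] <- c(a, b)
    }
  }
  adj <- lapply(seq_along(el), function(v) integer(0))
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  best <- 1L
  walk <- function(v, seen) {
    best <<- max(best, length(seen))
    for (w in adj[[v]]) if (!w %in% seen) walk(w, c(seen, w))
  }
  for (s in carbons) walk(s, s)
  best
}
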