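# Robust bracket (SELFIES-style) molecular string codec.
#
# The codec guarantees, by construction, that EVERY string of alphabet
# tokens decodes to a chemically valid molecule: the decoder keeps explicit
# free-valence bookkeeping per atom, caps every requested bond order by the
# remaining valence of both endpoints, and silently skips tokens that cannot
# be realized. Aromatic systems are handled by encoding the Kekulé structure
# (the graphs produced by the parsing layer carry explicit 1/2/3 bond
# orders), so the decoder never needs aromaticity perception.
#
# Grammar
#   atom tokens     [C] [=C] [#C] [N] [=N] [#N] [O] [=O] [S] [=S] [P] [F]
#                   [Cl] [Br] [I]        (prefix = bond order to the
#                   previous atom; ignored for the first atom)
#   branch tokens   [Branch1] [Branch2] [Branch3]; the next 1/2/3 tokens are
#                   base-16 index digits giving Q, the branch spans the
#                   following Q+1 tokens
#   ring tokens     [Ring1] [Ring2] [=Ring1] [=Ring2]; the next 1/2 tokens
#                   are index digits giving Q, a bond is closed to the atom
#                   placed Q+1 positions earlier
#
# Every token doubles as an index digit through a fixed table (its position
# in the alphabet modulo 16), so any token is acceptable anywhere — the
# decode-anything contract has no holes. An atom-free derivation is defined
# to decode to methane ("C").

SELFIES_MAX_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                         F = 1, Cl = 1, Br = 1, I = 1)

SELFIES_ALPHABET <- c(
  "[C]", "[=C]", "[#C]", "[N]", "[=N]", "[#N]", "[O]", "[=O]",
  "[S]", "[=S]", "[P]", "[F]", "[Cl]", "[Br]", "[I]",
  "[Branch1]", "[Branch2]", "[Branch3]",
  "[Ring1]", "[Ring2]", "[=Ring1]", "[=Ring2]"
)

# digit value of a token: position in alphabet mod 16 (unknown tokens -> 0)
selfies_digit <- function(token) {
  i <- match(token, SELFIES_ALPHABET)
  ifelse(is.na(i), 0L, (i - 1L) %% 16L)
}

parse_atom_token <- function(token) {
  m <- regmatches(token, regexec("^\\[(=|#)?(C|N|O|S|P|F|Cl|Br|I)\\]$", token))[[1]]
  if (length(m) == 0L) return(NULL)
  order <- switch(m[2], "=" = 2L, "#" = 3L, 1L)
  list(element = m[3], order = order)
}

parse_ring_token <- function(token) {
  m <- regmatches(token, regexec("^\\[(=)?Ring([12])\\]$", token))[[1]]
  if (length(m) == 0L) return(NULL)
  list(order = if (m[2] == "=") 2L else 1L, ndigits = as.integer(m[3]))
}

parse_branch_token <- function(token) {
  m <- regmatches(token, regexec("^\\[Branch([123])\\]$", token))[[1]]
  if (length(m) == 0L) return(NULL)
  as.integer(m[2])
}

#' Decode a robust bracket string to SMILES
#'
#' Total function: any sequence of alphabet tokens yields a valid molecule.
#' Tokens that cannot be realized under the valence bookkeeping are skipped;
#' unknown bracketed tokens are skipped; an atom-free derivation decodes to
#' methane.
#'
#' @param s A bracket string (or character vector of tokens).
#' @return A SMILES string.
#' @examples
#' selfies_to_smiles("[C][C][O]")
#' @export
selfies_to_smiles <- function(s) {
  tokens <- if (length(s) == 1L && (grepl("\\[", s) || !nzchar(s))) {
    tokenize_selfies(s)
  } else {
    as.character(s)
  }
  elements <- character(0)
  free <- numeric(0)
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  # derivation walk over tokens with an explicit branch stack of attachment
  # points; `consume(i, limit)` processes tokens i..limit with current
  # attachment `prev`, returning the index after the last consumed token.
  n <- length(tokens)
  place_atom <- function(el) {
    elements[length(elements) + 1L] <<- el
    free[length(free) + 1L] <<- SELFIES_MAX_VALENCE[[el]]
    length(elements)
  }
  add_bond <- function(a, b, o) {
    bonds[nrow(bonds) + 1L, ] <<- list(a, b, o)
    free[a] <<- free[a] - o
    free[b] <<- free[b] - o
  }
  read_digits <- function(i, k, limit) {
    val <- 0L
    used <- 0L
    while (used < k && i + used <= limit) {
      val <- val * 16L + selfies_digit(tokens[i + used])
      used <- used + 1L
    }
    list(value = val, nxt = i + used)
  }
  consume <- function(i, limit, prev) {
    while (i <= limit) {
      tok <- tokens[i]
      at <- parse_atom_token(tok)
      if (!is.null(at)) {
        if (prev == 0L) {
          prev <- place_atom(at$element)
          i <- i + 1L
          next
        }
        cap <- SELFIES_MAX_VALENCE[[at$element]]
        b <- min(at$order, free[prev], cap)
        if (b >= 1L) {
          new <- place_atom(at$element)
          add_bond(prev, new, b)
          prev <- new
        } # else: previous atom saturated, token skipped
        i <- i + 1L
        next
      }
      rt <- parse_ring_token(tok)
      if (!is.null(rt)) {
        d <- read_digits(i + 1L, rt$ndigits, limit)
        i <- d$nxt
        if (prev > 0L) {
          target <- prev - (d$value + 1L)
          if (target >= 1L && target != prev &&
              !any((bonds$a1 == target & bonds$a2 == prev) |
                   (bonds$a1 == prev & bonds$a2 == target))) {
            b <- min(rt$order, free[prev], free[target])
            if (b >= 1L) add_bond(target, prev, b)
          }
        }
        next
      }
      bk <- parse_branch_token(tok)
      if (!is.null(bk)) {
        d <- read_digits(i + 1L, bk, limit)
        span_end <- min(d$nxt + d$value, limit)
        if (prev > 0L && free[prev] >= 1L && d$nxt <= limit) {
          consume(d$nxt, span_end, prev)
        }
        i <- span_end + 1L
        next
      }
      i <- i + 1L # unknown token: skipped
    }
    prev
  }
  consume(1L, n, 0L)
  if (length(elements) == 0L) return("C")
  write_smiles_graph(elements, bonds)
}

# Write a SMILES string for an explicit (kekulized) molecular graph.
# DFS spanning tree per component; back edges become numbered ring closures.
write_smiles_graph <- function(elements, bonds) {
  n <- length(elements)
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], k)
      adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], k)
    }
  }
  other <- function(k, v) if (bonds$a1[k] == v) bonds$a2[k] else bonds$a1[k]
  bond_sym <- c("", "=", "#")
  visited <- rep(FALSE, n)
  edge_used <- rep(FALSE, max(nrow(bonds), 1L))
  ring_num <- list() # per atom: character vector of closure annotations
  for (v in seq_len(n)) ring_num[[v]] <- character(0)
  next_ring <- 1L
  ring_label <- function() {
    lab <- if (next_ring <= 9L) as.character(next_ring) else sprintf("%%%02d", next_ring)
    next_ring <<- next_ring + 1L
    lab
  }
  # first pass: DFS to find tree/back edges and assign ring numbers
  tree_children <- vector("list", n)
  order_seen <- integer(0)
  dfs1 <- function(v) {
    visited[v] <<- TRUE
    order_seen <<- c(order_seen, v)
    for (k in adj[[v]]) {
      if (edge_used[k]) next
      w <- other(k, v)
      if (!visited[w]) {
        edge_used[k] <<- TRUE
        tree_children[[v]] <<- c(tree_children[[v]], k)
        dfs1(w)
      } else {
        edge_used[k] <<- TRUE
        lab <- ring_label()
        sym <- bond_sym[bonds$order[k]]
        ring_num[[v]] <<- c(ring_num[[v]], paste0(sym, lab))
        ring_num[[w]] <<- c(ring_num[[w]], paste0(sym, lab))
      }
    }
  }
  emit <- function(v) {
    s <- paste0(elements[v], paste0(ring_num[[v]], collapse = ""))
    ch <- tree_children[[v]]
    if (length(ch) > 0) {
      for (j in seq_along(ch)) {
        k <- ch[j]
        w <- other(k, v)
        sub <- paste0(bond_sym[bonds$order[k]], emit(w))
        s <- if (j < length(ch)) paste0(s, "(", sub, ")") else paste0(s, sub)
      }
    }
    s
  }
  parts <- character(0)
  for (v in seq_len(n)) {
    if (!visited[v]) {
      dfs1(v)
      parts <- c(parts, emit(v))
    }
  }
  paste0(parts, collapse = ".")
}

#' Encode a molecule as a robust bracket string
#'
#' The molecule is parsed, canonicalized and kekulized through the chemistry
#' backend, then written as a token string that round-trips exactly through
#' [selfies_to_smiles()]. Molecules outside the codec's organic-subset
#' alphabet (charged atoms, elements other than C/N/O/S/P/halogens, or atoms
#' exceeding the codec valence caps) are an error.
#'
#' @param smiles A single valid SMILES string.
#' @return A single bracket string.
#' @examples
#' smiles_to_selfies("CCO")
#' @export
smiles_to_selfies <- function(smiles) {
  g <- mol_graphs(smiles)[[1]]
  abort_if(!all(g$elements %in% names(SELFIES_MAX_VALENCE)),
           paste0("element outside codec alphabet in ", smiles))
  bsum <- rep(0, g$n_heavy)
  if (nrow(g$bonds) > 0) {
    for (k in seq_len(nrow(g$bonds))) {
      bsum[g$bonds$a1[k]] <- bsum[g$bonds$a1[k]] + g$bonds$order[k]
      bsum[g$bonds$a2[k]] <- bsum[g$bonds$a2[k]] + g$bonds$order[k]
    }
  }
  abort_if(any(bsum > SELFIES_MAX_VALENCE[g$elements]),
           paste0("valence exceeds codec cap in ", smiles))
  abort_if(n_components(g$n_heavy, g$bonds) > 1L,
           "multi-component molecules are not encodable")
  encode_graph_selfies(g)
}

# digit tokens for value q with k base-16 digits
index_tokens <- function(q, k) {
  digs <- integer(k)
  for (j in k:1) {
    digs[j] <- q %% 16L
    q <- q %/% 16L
  }
  SELFIES_ALPHABET[digs + 1L]
}

n_digits_for <- function(q) {
  if (q < 16L) 1L else if (q < 256L) 2L else 3L
}

encode_graph_selfies <- function(g) {
  n <- g$n_heavy
  bonds <- g$bonds
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], k)
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], k)
  }
  other <- function(k, v) if (bonds$a1[k] == v) bonds$a2[k] else bonds$a1[k]
  prefix <- c("", "=", "#")
  visited <- rep(FALSE, n)
  edge_used <- rep(FALSE, nrow(bonds))
  placement <- rep(NA_integer_, n) # placement order of each atom
  placed <- 0L
  # Emit tokens for the subtree rooted at v, reached via bond order `ord`
  # (0 for the root). Token counting must match the decoder exactly: the
  # decoder counts branch spans in TOKENS, so the emission is assembled
  # bottom-up and lengths measured on the flat token vectors.
  emit <- function(v, ord) {
    visited[v] <<- TRUE
    placed <<- placed + 1L
    placement[v] <<- placed
    toks <- paste0("[", prefix[max(ord, 1L)], g$elements[v], "]")
    if (ord <= 1L) toks <- paste0("[", g$elements[v], "]")
    out <- toks
    # ring closures to already-placed atoms
    for (k in adj[[v]]) {
      if (edge_used[k]) next
      w <- other(k, v)
      if (visited[w]) {
        edge_used[k] <<- TRUE
        q <- placement[v] - placement[w] - 1L
        o <- bonds$order[k]
        abort_if(o > 2L, "triple-bond ring closures are not encodable")
        nd <- n_digits_for(q)
        abort_if(nd > 2L, "ring closure span too large for the codec")
        rt <- paste0("[", if (o == 2L) "=" else "", "Ring", nd, "]")
        out <- c(out, rt, index_tokens(q, nd))
      }
    }
    # tree children: all but the last are branches
    ch <- Filter(function(k) !edge_used[k] && !visited[other(k, v)], adj[[v]])
    # mark them used now so sibling recursion does not re-take them
    if (length(ch) > 0) {
      for (j in seq_along(ch)) {
        k <- ch[[j]]
        if (edge_used[k] || visited[other(k, v)]) next
        edge_used[k] <<- TRUE
        sub <- emit(other(k, v), bonds$order[k])
        remaining <- any(vapply(adj[[v]], function(kk) {
          !edge_used[kk] && !visited[other(kk, v)]
        }, logical(1)))
        if (remaining) {
          q <- length(sub) - 1L
          nd <- n_digits_for(q)
          out <- c(out, paste0("[Branch", nd, "]"), index_tokens(q, nd), sub)
        } else {
          out <- c(out, sub)
        }
      }
    }
    out
  }
  tokens <- emit(1L, 0L)
  paste0(tokens, collapse = "")
}
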