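#' Tokenize a SMILES string
#'
#' Greedy left-to-right segmentation of a SMILES string into chemically
#' atomic tokens: bracket atoms `[...]` are single tokens, two-digit ring
#' closures `%dd` are single tokens, the two-character elements `Cl` and `Br`
#' are single tokens, and every other character is its own token.
#' Concatenating the tokens always reproduces the input exactly.
#'
#' @param s A single non-empty SMILES string.
#' @return A character vector of tokens.
#' @examples
#' tokenize_smiles("CC(Cl)Br")
#' @export
tokenize_smiles <- function(s) {
  abort_if(!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s),
           "`s` must be a single non-empty string")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      abort_if(j > n, paste0("unclosed '[' at position ", i, " in ", s))
      tokens <- c(tokens, paste0(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%" && i + 2L <= n &&
               all(chars[(i + 1L):(i + 2L)] %in% as.character(0:9))) {
      tokens <- c(tokens, paste0(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      tokens <- c(tokens, "Cl")
      i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      tokens <- c(tokens, "Br")
      i <- i + 2L
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  tokens
}

#' Tokenize a SELFIES-style bracket string
#'
#' One token per bracketed group `[...]`. The empty string yields an empty
#' token vector. Any character outside a bracket group is an error.
#'
#' @param s A string that is a concatenation of bracketed tokens.
#' @return A character vector of tokens.
#' @examples
#' tokenize_selfies("[C][C][O]")
#' @export
tokenize_selfies <- function(s) {
  abort_if(!is.character(s) || length(s) != 1L || is.na(s),
           "`s` must be a single string")
  if (!nzchar(s)) return(character(0))
  m <- gregexpr("\\[[^][]*\\]", s)[[1]]
  if (m[1] == -1L) {
    rlang::abort(paste0("stray character at position 1 in ", s))
  }
  lens <- attr(m, "match.length")
  # verify tokens tile the whole string; report first uncovered position
  covered <- rep(FALSE, nchar(s))
  for (k in seq_along(m)) covered[m[k]:(m[k] + lens[k] - 1L)] <- TRUE
  if (!all(covered)) {
    rlang::abort(paste0("stray character at position ", which(!covered)[1], " in ", s))
  }
  substring(s, m, m + lens - 1L)
}

#' Build a token vocabulary from a tokenized corpus
#'
#' The vocabulary is the union of the special tokens (`<pad>` at index 0,
#' `<bos>` at index 1, `<eos>` at index 2) with all distinct corpus tokens in
#' sorted order, so that two runs over the same corpus (in any order) yield
#' identical vocabularies.
#'
#' @param corpus A list of character vectors (token sequences).
#' @return An object of class `token_vocab`: a named integer vector of
#'   0-based indices, with attributes `pad`, `bos`, `eos`.
#' @export
build_vocabulary <- function(corpus) {
  abort_if(!is.list(corpus) || length(corpus) == 0L, "`corpus` must be a non-empty list")
  toks <- sort(unique(unlist(corpus, use.names = FALSE)))
  abort_if(any(toks %in% c("<pad>", "<bos>", "<eos>")),
           "corpus must not contain the reserved special tokens")
  all_tokens <- c("<pad>", "<bos>", "<eos>", toks)
  v <- stats::setNames(seq_along(all_tokens) - 1L, all_tokens)
  structure(v, class = "token_vocab", pad = 0L, bos = 1L, eos = 2L)
}

#' @export
print.token_vocab <- function(x, ...) {
  cat("<token_vocab> ", length(x), " tokens (3 special + ",
      length(x) - 3L, " corpus)\n", sep = "")
  invisible(x)
}

#' Encode a token sequence to integer codes
#'
#' Prepends `<bos>` and appends `<eos>`. Indices are 0-based, matching the
#' vocabulary.
#'
#' @param tokens Character vector of tokens.
#' @param vocab A `token_vocab`.
#' @return Integer vector of codes.
#' @export
encode_tokens <- function(tokens, vocab) {
  idx <- unname(vocab[tokens])
  if (anyNA(idx)) {
    bad <- tokens[which(is.na(idx))[1]]
    rlang::abort(paste0("token not in vocabulary: ", bad))
  }
  c(attr(vocab, "bos"), idx, attr(vocab, "eos"))
}

#' Decode integer codes back to a string
#'
#' Strips special tokens, stops at the first `<eos>`, and concatenates the
#' remaining tokens.
#'
#' @param codes Integer vector of 0-based codes.
#' @param vocab A `token_vocab`.
#' @return A single string.
#' @export
decode_tokens <- function(codes, vocab) {
  abort_if(any(codes < 0L | codes >= length(vocab)), "code out of vocabulary range")
  eos <- attr(vocab, "eos")
  stop_at <- match(eos, codes)
  if (!is.na(stop_at)) codes <- codes[seq_len(stop_at - 1L)]
  codes <- codes[!codes %in% c(attr(vocab, "pad"), attr(vocab, "bos"))]
  paste0(names(vocab)[codes + 1L], collapse = "")
}

#' Write / read a vocabulary as a plain-text token list
#'
#' One token per line; the 0-based index of a token is its line number minus
#' one.
#'
#' @param vocab A `token_vocab`.
#' @param path File path.
#' @return `read_vocabulary` returns a `token_vocab`.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(names(vocab), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  toks <- readLines(path, encoding = "UTF-8")
  abort_if(!identical(toks[1:3], c("<pad>", "<bos>", "<eos>")),
           "vocabulary file must start with the three special tokens")
  v <- stats::setNames(seq_along(toks) - 1L, toks)
  structure(v, class = "token_vocab", pad = 0L, bos = 1L, eos = 2L)
}

# Tokenize every molecule of a character vector under one encoding.
tokenize_all <- function(strings, encoding = c("smiles", "selfies")) {
  encoding <- match.arg(encoding)
  f <- if (encoding == "smiles") tokenize_smiles else tokenize_selfies
  lapply(strings, f)
}
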