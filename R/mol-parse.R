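#' Parse molecules into a molecule table
#'
#' Builds the package's central molecule container: a tibble with one row
#' per input record and columns `raw` (the input string), `encoding`
#' (`"smiles"` or `"selfies"`), `canonical` (canonical SMILES, `NA` when the
#' chemistry parser rejects the string), `is_valid`, and `source` (a free
#' text tag). Validity is decided by the OpenBabel parser for SMILES input;
#' bracket (SELFIES-style) input is first decoded by the robust codec, under
#' which any string of alphabet tokens yields a valid molecule — only stray
#' characters outside brackets make a bracket record invalid.
#'
#' Invalid records are retained (flagged, not dropped) so that validity
#' statistics can be computed on raw generated output.
#'
#' @param x A character vector of molecule strings, or a data frame with a
#'   `raw` column.
#' @param encoding `"smiles"` or `"selfies"`.
#' @param source Source tag recycled along records (or taken from a
#'   `source` column of `x` when present).
#' @return A `mol_tbl` tibble.
#' @examples
#' parse_molecules(c("CCO", "c1ccccc1", "c1ccccc"))
#' @export
parse_molecules <- function(x, encoding = c("smiles", "selfies"), source = "input") {
  encoding <- match.arg(encoding)
  if (is.data.frame(x)) {
    abort_if(!"raw" %in% names(x), "data-frame input must have a `raw` column")
    raw <- as.character(x$raw)
    if ("source" %in% names(x)) source <- as.character(x$source)
  } else {
    raw <- as.character(x)
  }
  n <- length(raw)
  source <- rep_len(source, n)
  reason <- rep(NA_character_, n)
  if (encoding == "smiles") {
    empty <- !nzchar(raw) | is.na(raw)
    reason[empty] <- "empty string"
    canonical <- ob_canonical(ifelse(empty, "", raw))
    reason[is.na(canonical) & !empty] <- "rejected by chemistry parser"
  } else {
    smi <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      if (is.na(raw[i]) || !nzchar(raw[i])) {
        reason[i] <- "empty string"
        next
      }
      smi[i] <- tryCatch(selfies_to_smiles(raw[i]),
                         error = function(e) NA_character_)
      if (is.na(smi[i])) reason[i] <- "stray characters outside bracket tokens"
    }
    canonical <- ob_canonical(ifelse(is.na(smi), "", smi))
    reason[is.na(canonical) & is.na(reason)] <- "decoded structure rejected"
  }
  tibble::new_tibble(
    tibble::tibble(
      raw = raw,
      encoding = encoding,
      canonical = canonical,
      is_valid = !is.na(canonical),
      source = source,
      failure = reason
    ),
    class = "mol_tbl"
  )
}

#' Canonicalize SMILES strings
#'
#' Deterministic canonical SMILES via the OpenBabel canonicalizer; equal
#' molecules map to equal strings and the map is idempotent. Strings the
#' parser rejects are an error (there is no structure to canonicalize).
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  out <- ob_canonical(smiles)
  if (anyNA(out)) {
    bad <- smiles[which(is.na(out))[1]]
    rlang::abort(paste0("cannot canonicalize invalid molecule: ", bad))
  }
  out
}

#' Read / write molecule line files
#'
#' `.smi` line files: one molecule per line, optionally `<string>\t<id>`;
#' UTF-8; lines starting with `#` are comments. Blank lines are skipped with
#' a message. `write_smi()` writes `raw` (and a tab-separated `source` tag
#' when `ids = TRUE`) so that a write/read round trip preserves raw strings
#' and order.
#'
#' @param path File path.
#' @param encoding Encoding of the strings in the file.
#' @param source Default source tag for lines without an identifier.
#' @return A `mol_tbl`.
#' @export
read_smi <- function(path, encoding = c("smiles", "selfies"), source = NULL) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  encoding <- match.arg(encoding)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(trimws(lines), "#")]
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    message(sum(blank), " blank line(s) skipped in ", path)
    lines <- lines[!blank]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  raw <- vapply(parts, function(p) p[1], "")
  tag <- vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_, "")
  default <- source %||% basename(path)
  parse_molecules(raw, encoding = encoding,
                  source = ifelse(is.na(tag), default, tag))
}

#' @rdname read_smi
#' @param mols A `mol_tbl` (or data frame with `raw`).
#' @param ids Write the `source` tag as a tab-separated identifier?
#' @export
write_smi <- function(mols, path, ids = FALSE) {
  lines <- if (ids && "source" %in% names(mols)) {
    paste0(mols$raw, "\t", mols$source)
  } else {
    mols$raw
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Deduplicate a molecule table
#'
#' Keeps the first occurrence of each canonical SMILES; canonical-form
#' string equality is the molecule-identity relation throughout the
#' package. Invalid records (no canonical form) are dropped.
#'
#' @param mols A `mol_tbl`.
#' @return A `mol_tbl` without duplicate molecules.
#' @export
dedup_molecules <- function(mols) {
  keep <- mols$is_valid & !duplicated(mols$canonical)
  dplyr::filter(mols, keep)
}

#' Remove reference overlap (and internal duplicates)
#'
#' Returns the records of `mols` whose canonical SMILES does not occur in
#' `reference`, with internal duplicates also removed; order of first
#' occurrence is preserved. This is the "after removing duplicates and
#' training molecules" step of the evaluation protocol. Idempotent.
#'
#' @param mols,reference Molecule tables.
#' @return A `mol_tbl`.
#' @export
remove_overlap <- function(mols, reference) {
  ref <- reference$canonical[reference$is_valid]
  keep <- mols$is_valid & !duplicated(mols$canonical) & !(mols$canonical %in% ref)
  dplyr::filter(mols, keep)
}

#' @export
print.mol_tbl <- function(x, ...) {
  if ("is_valid" %in% names(x)) {
    cat("<mol_tbl> ", nrow(x), " record(s), ", sum(x$is_valid), " valid\n",
        sep = "")
  }
  NextMethod()
}

# keep the class across dplyr verbs
#' @export
`[.mol_tbl` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("raw", "canonical", "is_valid") %in% names(out))) {
    class(out) <- unique(c("mol_tbl", class(out)))
  }
  out
}
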