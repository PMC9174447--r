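# Thin wrappers around the OpenBabel chemistry backend (ChemmineOB).
# These are the only functions in the package that talk to the toolkit
# directly; everything else consumes their output.

# Vectorized canonicalization. Returns NA_character_ for strings the
# chemistry parser rejects. OpenBabel's batch converter aborts at the first
# bad line, so the batch is restarted after each failure; a run with k
# invalid strings costs k + 1 converter calls.
ob_canonical <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  # strings with whitespace or empty strings can never be single molecules
  sendable <- nzchar(smiles) & !grepl("[[:space:]]", smiles)
  todo <- which(sendable)
  while (length(todo) > 0L) {
    inp <- paste0(smiles[todo], "\t", todo, collapse = "\n")
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(inp, "\n")),
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    k <- 0L
    if (length(lines) > 0L) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      ids <- suppressWarnings(as.integer(vapply(parts, function(p) p[length(p)], "")))
      cans <- vapply(parts, function(p) p[1L], "")
      keep <- !is.na(ids) & nzchar(cans)
      out[ids[keep]] <- cans[keep]
      k <- max(match(ids[keep], todo), 0L)
    }
    if (k + 1L >= length(todo)) break
    todo <- todo[-seq_len(k + 1L)] # k successes, then one failure: skip it
  }
  out
}

# materialize OpenBabel molecule references for a vector of valid SMILES
ob_mols <- function(smiles) {
  refs <- ChemmineOB::forEachMol("SMILES", paste0(smiles, collapse = "\n"),
                                 identity)
  abort_if(length(refs) != length(smiles),
           "OpenBabel processed a different number of molecules than supplied")
  refs
}

# Per-molecule OpenBabel descriptors for a vector of *valid* SMILES.
# Returns a tibble with logp (Wildman-Crippen-type atomic contributions as
# implemented by OpenBabel), mw_avg, tpsa, hba, hbd, exact_mass.
ob_descriptors <- function(smiles, mols = NULL) {
  if (length(smiles) == 0L) {
    return(tibble::tibble(
      logp = double(), mw_avg = double(), tpsa = double(),
      hba = double(), hbd = double(), exact_mass = double()
    ))
  }
  refs <- mols %||% ob_mols(smiles)
  p <- ChemmineOB::prop_OB(refs)
  tibble::tibble(
    logp = as.numeric(p$logP), mw_avg = as.numeric(p$MW),
    tpsa = as.numeric(p$TPSA), hba = as.numeric(p$HBA1),
    hbd = as.numeric(p$HBD),
    exact_mass = as.numeric(ChemmineOB::exactMass_OB(refs))
  )
}

# exact (monoisotopic) masses only — much lighter than the full battery
ob_exact_mass <- function(smiles) {
  if (length(smiles) == 0L) return(double())
  as.numeric(ChemmineOB::exactMass_OB(ob_mols(smiles)))
}

# Count SMARTS matches per molecule (OpenBabel match semantics) for a vector
# of valid SMILES and a single pattern.
ob_smarts_count <- function(smiles, smarts, mols = NULL) {
  if (length(smiles) == 0L) return(integer())
  refs <- mols %||% ob_mols(smiles)
  as.integer(ChemmineOB::smartsSearch_OB(refs, smarts, uniqueMatches = TRUE))
}
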