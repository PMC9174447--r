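test_that("parsing flags validity and canonicalizes", {
  m <- parse_molecules(c("c1ccccc1", "c1ccccc", "", "OCC", "CCO"))
  expect_equal(m$is_valid, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_true(is.na(m$canonical[2]))
  expect_match(m$failure[3], "empty")
  # same molecule, two spellings -> one canonical string
  expect_identical(m$canonical[4], m$canonical[5])
  # aromatic perception: kekulized and aromatic benzene agree
  two <- parse_molecules(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_identical(two$canonical[1], two$canonical[2])
})

test_that("canonicalization is an idempotent fixed point", {
  pool <- druglike_small()
  re <- canonical_smiles(pool$canonical)
  expect_identical(re, pool$canonical)
  expect_error(canonical_smiles("c1ccccc"), "invalid")
})

test_that("bracket-encoded records are valid for any alphabet string", {
  m <- parse_molecules(c("[C][C][O]", "[C]x[C]", ""), encoding = "selfies")
  expect_equal(m$is_valid, c(TRUE, FALSE, FALSE))
  # [C][C][O] is the ethanol skeleton
  expect_identical(m$canonical[1], parse_molecules("CCO")$canonical[1])
})

test_that("line-file round trip preserves raw strings, order and tags", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# comment", "CCO\tmol-a", "", "c1ccccc1", "not_a_molecule"),
             path)
  expect_message(m <- read_smi(path), "blank")
  expect_equal(nrow(m), 3L)
  expect_equal(m$raw, c("CCO", "c1ccccc1", "not_a_molecule"))
  expect_equal(m$source[1], "mol-a")
  expect_equal(sum(m$is_valid), 2L)

  out <- withr::local_tempfile(fileext = ".smi")
  write_smi(m, out)
  back <- read_smi(out)
  expect_equal(back$raw, m$raw)
  expect_error(read_smi(file.path(tempdir(), "absent.smi")), "no such file")
})

test_that("overlap removal deduplicates, filters and is idempotent", {
  set <- parse_molecules(c("CCO", "OCC", "CCC", "c1ccccc1"))
  ref <- parse_molecules("CCO")
  out <- remove_overlap(set, ref)
  expect_equal(out$raw, c("CCC", "c1ccccc1"))
  expect_identical(remove_overlap(out, ref), out)
  # set subset of reference -> empty
  expect_equal(nrow(remove_overlap(parse_molecules("OCC"), ref)), 0L)
  # empty reference -> dedup only
  out2 <- remove_overlap(parse_molecules(c("CCO", "OCC", "CC")),
                         parse_molecules(character(0)))
  expect_equal(out2$raw, c("CCO", "CC"))
})

test_that("dedup never grows a set and is exact on canonical forms", {
  pool <- druglike_small()
  dd <- dedup_molecules(pool)
  expect_lte(nrow(dd), nrow(pool))
  expect_equal(anyDuplicated(dd$canonical), 0L)
  expect_setequal(dd$canonical, unique(pool$canonical[pool$is_valid]))
})

test_that("parse -> canonicalize -> parse preserves canonical form on a pool", {
  pool <- druglike_1000()
  expect_true(all(pool$is_valid))
  reparsed <- parse_molecules(pool$canonical)
  expect_identical(reparsed$canonical, pool$canonical)
})
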