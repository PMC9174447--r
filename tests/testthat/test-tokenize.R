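test_that("SMILES segmentation keeps chemically atomic units intact", {
  expect_equal(tokenize_smiles("CC(Cl)Br"), c("C", "C", "(", "Cl", ")", "Br"))
  expect_equal(tokenize_smiles("c1ccccc1"),
               c("c", "1", "c", "c", "c", "c", "c", "1"))
  expect_equal(tokenize_smiles("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
  expect_equal(tokenize_smiles("c1cc[nH]c1"),
               c("c", "1", "c", "c", "[nH]", "c", "1"))
  expect_error(tokenize_smiles("C[NH"), "unclosed")
  expect_error(tokenize_smiles(""), "non-empty")
})

test_that("bracket-string tokenization is one token per group", {
  expect_equal(tokenize_selfies("[C][C][O]"), c("[C]", "[C]", "[O]"))
  expect_equal(tokenize_selfies(""), character(0))
  expect_error(tokenize_selfies("[C]x[C]"), "position 4")
  expect_error(tokenize_selfies("x[C]"), "position 1")
})

test_that("vocabulary is deterministic, sorted and permutation-invariant", {
  corp <- lapply(c("CC", "CO", "[nH]"), tokenize_smiles)
  v1 <- build_vocabulary(corp)
  v2 <- build_vocabulary(rev(corp))
  expect_identical(v1, v2)
  expect_identical(names(v1)[1:3], c("<pad>", "<bos>", "<eos>"))
  expect_equal(unname(v1[c("<pad>", "<bos>", "<eos>")]), 0:2)
  expect_true("[nH]" %in% names(v1))
  expect_error(build_vocabulary(list()), "non-empty")
})

test_that("encode adds BOS/EOS and decode stops at first EOS", {
  v <- build_vocabulary(lapply(c("CC", "CO"), tokenize_smiles))
  codes <- encode_tokens(c("C", "O"), v)
  expect_equal(codes[1], attr(v, "bos"))
  expect_equal(codes[length(codes)], attr(v, "eos"))
  expect_equal(decode_tokens(codes, v), "CO")
  # decode stops at the first EOS even with trailing tokens
  cC <- unname(v[["C"]])
  expect_equal(decode_tokens(c(1L, cC, cC, 2L, cC), v), "CC")
  expect_error(encode_tokens("N", v), "not in vocabulary")
})

test_that("tokenize/join round trip holds on a 1000-molecule pool", {
  pool <- druglike_1000()
  smi_ok <- vapply(pool$canonical, function(s) {
    paste0(tokenize_smiles(s), collapse = "") == s
  }, logical(1))
  expect_true(all(smi_ok))
  sf <- vapply(pool$canonical[1:200], smiles_to_selfies, "")
  sf_ok <- vapply(sf, function(s) {
    paste0(tokenize_selfies(s), collapse = "") == s
  }, logical(1))
  expect_true(all(sf_ok))
})

test_that("encode/decode round trip is exact over a pool", {
  pool <- druglike_1000()
  toks <- lapply(pool$canonical, tokenize_smiles)
  v <- build_vocabulary(toks)
  ok <- vapply(seq_along(toks), function(i) {
    decode_tokens(encode_tokens(toks[[i]], v), v) == pool$canonical[i]
  }, logical(1))
  expect_true(all(ok))
})

test_that("vocabulary text file round trips", {
  v <- build_vocabulary(lapply(c("CC(N)=O", "c1ccsc1"), tokenize_smiles))
  path <- withr::local_tempfile()
  write_vocabulary(v, path)
  expect_identical(read_vocabulary(path), v)
})
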