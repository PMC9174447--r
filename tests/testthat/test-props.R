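test_that("structure-forced counts are exact", {
  p <- compute_properties(parse_molecules(c("c1ccccc1", "CCCCCC", "O")))
  expect_equal(p$n_atoms, c(6L, 6L, 1L))
  expect_equal(p$n_rings, c(1L, 0L, 0L))
  expect_equal(p$longest_chain, c(6L, 6L, 0L))
})

test_that("descriptor backend values match the independently frozen oracle", {
  # frozen from a standalone run of the OpenBabel descriptor backend
  p <- compute_properties(parse_molecules(c("c1ccccc1", "CCCCCCCCCC")))
  expect_equal(p$logp, c(1.6866, 4.147), tolerance = 1e-6)
  expect_equal(p$mw, c(78.04695, 142.17215), tolerance = 1e-4)
  expect_true(all(p$qed > 0 & p$qed < 1))
  expect_true(all(p$sa >= 1 & p$sa <= 10))
})

test_that("penalized LogP follows logp - sa - ring penalty exactly", {
  m <- parse_molecules(c("CC(=O)Nc1ccc(O)cc1", "C1CCCCCCC1"))
  p <- compute_properties(m)
  # no ring > 6 atoms: zero penalty branch
  expect_equal(p$plogp[1], p$logp[1] - p$sa[1])
  # cyclooctane: one 8-ring, penalty exactly 1
  expect_equal(p$plogp[2], p$logp[2] - p$sa[2] - 1)
  # a long alkane scores far above the screening threshold
  c30 <- compute_properties(parse_molecules(strrep("C", 30)))
  expect_gt(c30$plogp, 4.0)
})

test_that("penalized LogP is bounded by logp - 1 (sa >= 1)", {
  pool <- druglike_small()
  p <- compute_properties(pool)
  expect_true(all(p$plogp <= p$logp - 1 + 1e-9))
})

test_that("longest carbon chain equals the brute-force path oracle", {
  expect_equal(longest_carbon_chain("CC(C)(C)C"), 3L) # neopentane
  pool <- druglike_1000()
  idx <- seq(1, 600, by = 3) # 200 molecules, all well under 25 heavy atoms
  got <- longest_carbon_chain(pool$canonical[idx])
  want <- vapply(pool$canonical[idx], oracle_longest_chain, integer(1),
                 USE.NAMES = FALSE)
  expect_equal(got, as.integer(want))
})

test_that("properties are invariant to SMILES respelling", {
  pairs <- list(c("OCC", "CCO"), c("C1=CC=CC=C1", "c1ccccc1"),
                c("C(C)(C)O", "CC(O)C"))
  for (pr in pairs) {
    p <- compute_properties(parse_molecules(pr))
    for (col in c("logp", "sa", "qed", "mw", "bertz", "np", "plogp")) {
      expect_equal(p[[col]][1], p[[col]][2])
    }
  }
})

test_that("score ranges hold across a generated pool", {
  p <- compute_properties(druglike_small())
  expect_true(all(p$qed >= 0 & p$qed <= 1))
  expect_true(all(p$sa >= 1 & p$sa <= 10))
  expect_true(all(p$np >= -5 & p$np <= 5))
  expect_true(all(p$n_atoms >= 1))
  expect_true(all(p$n_rings >= 0))
  expect_true(all(p$longest_chain >= 0))
})

test_that("invalid records get NA property rows, not errors", {
  p <- compute_properties(parse_molecules(c("CCO", "c1ccccc")))
  expect_false(anyNA(p[1, c("logp", "mw")]))
  expect_true(all(is.na(p[2, c("logp", "sa", "qed", "mw")])))
  expect_error(penalized_logp("c1ccccc"), "invalid")
})
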