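test_that("penalized-LogP screen equals a brute-force filter", {
  pool <- dplyr::bind_rows(
    make_synthetic_pool("highlogp", 40, seed = 5),
    druglike_small()[1:40, ]
  )
  out <- screen_penalized_logp(pool, threshold = 4.0)
  # independent recomputation per molecule
  want <- penalized_logp(pool$canonical[pool$is_valid]) > 4.0
  expect_equal(nrow(out), sum(want))
  expect_setequal(out$canonical, pool$canonical[pool$is_valid][want])
  expect_true(all(out$plogp > 4.0))
  # threshold -Inf keeps every valid molecule
  expect_equal(nrow(screen_penalized_logp(pool, -Inf)), sum(pool$is_valid))
})

test_that("large screen boundary is strict at 100 heavy atoms", {
  alkanes <- make_synthetic_pool("alkane", 16, alkane_range = c(95, 110))
  out <- screen_large(alkanes)
  expect_equal(nrow(out), 10L) # C101..C110
  expect_equal(min(out$n_atoms), 101L)
  expect_false(any(out$n_atoms == 100L))
  expect_equal(nrow(screen_large(alkanes[0, ])), 0L)
})

multi_pools <- function(n_each = 60) {
  fixture("multi_pools", function() {
    list(
      gdb13 = make_synthetic_pool("window", 60, seed = 31,
                                  window = c(-Inf, 185)),
      zinc = make_synthetic_pool("window", 60, seed = 32,
                                 window = c(185, 425)),
      cep = make_synthetic_pool("window", 60, seed = 33,
                                window = c(460, 600)),
      polymers = make_synthetic_pool("window", 60, seed = 34,
                                     window = c(601, 1400))
    )
  })
}

test_that("multimodal composer hits the 1/6-1/3-1/6-1/3 quotas", {
  pools <- multi_pools()
  out <- compose_multimodal(pools, total = 120, seed = 4)
  expect_equal(nrow(out), 120L)
  counts <- table(out$source)
  expect_equal(unname(counts[c("gdb13", "zinc", "cep", "polymers")]),
               c(20L, 40L, 20L, 40L), ignore_attr = TRUE)
  # reproducible draws
  out2 <- compose_multimodal(pools, total = 120, seed = 4)
  expect_identical(out$canonical, out2$canonical)
})

test_that("window validation rejects molecules in the 425-460 gap", {
  pools <- multi_pools()
  # C31 alkane, exact mass ~436.5: lands in the uncovered (425, 460) gap
  gap_mol <- parse_molecules(strrep("C", 31))
  bad <- pools
  bad$zinc <- dplyr::bind_rows(bad$zinc, gap_mol)
  expect_error(compose_multimodal(bad, 60, seed = 1), "violates")
  bad2 <- pools
  bad2$cep <- dplyr::bind_rows(bad2$cep, gap_mol)
  expect_error(compose_multimodal(bad2, 60, seed = 1), "violates")
})

test_that("an under-sized pool is reported with required vs available", {
  pools <- multi_pools()
  pools$cep <- pools$cep[1:3, ]
  expect_error(compose_multimodal(pools, 120, seed = 1), "has 3 .* quota is 20")
})

test_that("synthetic pools satisfy their own postconditions", {
  w <- make_synthetic_pool("window", 25, seed = 2, window = c(185, 425))
  expect_true(all(w$is_valid))
  mw <- molgenlm:::ob_exact_mass(w$canonical)
  expect_true(all(mw >= 185 & mw <= 425))

  pep <- make_synthetic_pool("peptide", 4, seed = 3, peptide_length = 19)
  expect_true(all(pep$is_valid))
  amides <- molgenlm:::ob_smarts_count(pep$canonical, "C(=O)N")
  expect_true(all(amides >= 18))

  d1 <- make_synthetic_pool("druglike", 30, seed = 8)
  d2 <- make_synthetic_pool("druglike", 30, seed = 8)
  expect_identical(d1$raw, d2$raw)
  mw_d <- molgenlm:::ob_exact_mass(d1$canonical)
  expect_true(all(mw_d >= 150 & mw_d <= 450))

  hl <- make_synthetic_pool("highlogp", 30, seed = 9)
  expect_gt(mean(penalized_logp(hl$canonical) > 4), 0.5)

  expect_error(make_synthetic_pool("window", 5, seed = 1,
                                   window = c(10, 12), max_tries = 3),
               "infeasible")
})

test_that("composite of the four windows is four-modal in MW", {
  pools <- multi_pools()
  out <- compose_multimodal(pools, total = 120, seed = 4)
  mw <- molgenlm:::ob_exact_mass(out$canonical)
  k <- kde_curves(mw, bandwidth = 15)
  expect_gte(molgenlm:::kde_modes(k), 4)
})
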