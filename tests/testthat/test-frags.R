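test_that("decomposition classifies the canonical examples", {
  prof <- fragment_profile(c("CCc1ccccc1", "c1ccc2ccccc2c1", "C"))
  # ethylbenzene: benzene ring + two single-atom carbons
  expect_equal(prof$n_fragments[1], 3L)
  expect_equal(prof$n_single_atom[1], 2L)
  expect_equal(prof$n_single_ring[1], 1L)
  # naphthalene: one fused-ring fragment, no acyclic single bonds
  expect_equal(prof$n_fragments[2], 1L)
  expect_equal(prof$n_fused_ring[2], 1L)
  # methane: one single-atom fragment
  expect_equal(prof$n_fragments[3], 1L)
  expect_equal(prof$n_single_atom[3], 1L)
})

test_that("fragment counts equal a brute-force component oracle on a pool", {
  pool <- druglike_small()[1:60, ]
  prof <- fragment_profile(pool)
  oracle_counts <- vapply(pool$canonical, function(smi) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))[[1]]
    bb <- ChemmineR::bondblock(sdf)
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0))
    n_atoms <- nrow(ChemmineR::atomblock(sdf))
    if (nrow(bb) == 0 || ncol(bb) < 3) return(n_atoms)
    g <- igraph::graph_from_data_frame(
      data.frame(a = bb[, 1], b = bb[, 2]), directed = FALSE,
      vertices = data.frame(name = seq_len(n_atoms)))
    # ring bonds = non-bridges; cut single-order bridges
    bridges <- as.integer(igraph::bridges(g))
    cut <- intersect(bridges, which(bb[, 3] == 1))
    igraph::components(igraph::delete_edges(g, cut))$no
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(prof$n_fragments, as.integer(oracle_counts))
  expect_true(all(prof$n_single_atom + prof$n_single_ring +
                  prof$n_fused_ring <= prof$n_fragments))
})

test_that("amino-acid substructure search recovers constructed ground truth", {
  # glycylglycine: two glycines
  aa <- count_amino_acids("NCC(=O)NCC(=O)O")
  expect_equal(aa$G, 2L)
  expect_equal(aa$total, 2L)
  expect_equal(count_amino_acids("c1ccccc1")$total, 0L)
  # generator-built peptides: residue multiset recovered exactly for all 20
  pep <- make_synthetic_pool("peptide", 6, seed = 44, peptide_length = 10)
  counts <- count_amino_acids(pep)
  for (i in seq_len(nrow(pep))) {
    truth <- table(strsplit(pep$source[i], "", fixed = TRUE)[[1]])
    expect_equal(counts$total[i], 10L)
    expect_equal(unlist(counts[i, names(truth)]), unlist(as.list(truth)),
                 ignore_attr = TRUE)
  }
  # a single peptide containing every residue once
  all20 <- paste0(names(molgenlm:::AA_SIDE_CHAINS), collapse = "")
  seq_smi <- molgenlm:::peptide_smiles(all20)
  c20 <- count_amino_acids(seq_smi)
  expect_equal(unname(unlist(c20[1, names(molgenlm:::AA_SIDE_CHAINS)])),
               rep(1L, 20))
})

test_that("Tanimoto similarity is a set identity with symmetric values", {
  # hand-computed toy bit vectors
  expect_equal(tanimoto(c(1L, 5L, 9L), c(5L, 9L)), 2 / 3)
  expect_equal(tanimoto(integer(0), integer(0)), 0)
  smis <- druglike_small()$canonical[1:10]
  fps <- morgan_fingerprint(smis)
  for (k in 1:5) {
    i <- sample(10, 1); j <- sample(10, 1)
    expect_equal(tanimoto(fps[[i]], fps[[j]]), tanimoto(fps[[j]], fps[[i]]))
  }
  expect_equal(tanimoto(fps[[1]], fps[[1]]), 1)
})

test_that("nearest-neighbour search ranks the reference itself first", {
  gen <- druglike_small()[1:40, ]
  ref <- gen$canonical[7]
  hits <- tanimoto_nearest(gen, ref, top_k = 5)
  expect_equal(hits$canonical[1], ref)
  expect_equal(hits$similarity[1], 1)
  expect_true(all(diff(hits$similarity) <= 0))
  hits2 <- tanimoto_nearest(gen, ref, top_k = 5)
  expect_identical(hits, hits2)
})
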