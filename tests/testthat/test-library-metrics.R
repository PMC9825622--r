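test_that("Tanimoto similarity follows set arithmetic", {
  a <- integer(16); a[c(1, 2, 3)] <- 1L
  b <- integer(16); b[c(2, 3, 4)] <- 1L
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, b), 0.5)  # 2 common / 4 union
  d <- integer(16); d[10] <- 1L
  expect_equal(tanimoto(a, d), 0)
  # both-empty convention
  expect_equal(tanimoto(integer(16), integer(16)), 1)
  expect_error(tanimoto(a, integer(8)), class = "declm_length_mismatch")

  # symmetry and range on random fingerprints
  withr::with_seed(4, {
    M <- matrix(rbinom(10 * 64, 1, 0.2), 10, 64)
    S <- tanimoto(M, M)
    expect_equal(S, t(S))
    expect_true(all(S >= 0 & S <= 1))
    expect_equal(unname(diag(S)), rep(1, 10))
  })
})

test_that("Morgan fingerprints are deterministic and discriminate structures", {
  fp <- morgan_fingerprints(c("CCO", "CCO", "c1ccccc1"))
  expect_equal(ncol(fp), 2048)
  expect_identical(fp[1, ], fp[2, ])
  expect_false(identical(fp[1, ], fp[3, ]))
  expect_true(all(fp %in% c(0, 1)))
  # folding preserves occupancy
  fp512 <- morgan_fingerprints("CCO", n_bits = 512)
  expect_equal(ncol(fp512), 512)
  expect_gt(sum(fp512), 0)
})

test_that("nearest-neighbor profiles match exhaustive brute force", {
  designs <- c("CCO", "CCCO", "c1ccccc1C")
  reference <- c("CCO", "c1ccccc1", "CCCCO")
  prof <- nn_similarity(designs, reference)
  dfp <- morgan_fingerprints(designs); rfp <- morgan_fingerprints(reference)
  brute <- tanimoto(dfp, rfp)
  for (i in seq_along(designs)) {
    expect_equal(prof$similarity[i], max(brute[i, ]))
    expect_equal(prof$nn_index[i], unname(which.max(brute[i, ])))
  }
  # identity: a design present in the reference has similarity 1
  expect_equal(prof$similarity[1], 1)
  # single-reference reduction equals the pairwise similarity
  one <- nn_similarity("CCO", "CCN")
  expect_equal(one$similarity, tanimoto(morgan_fingerprints("CCO")[1, ],
                                        morgan_fingerprints("CCN")[1, ]))
})

test_that("Bemis-Murcko scaffolds match the reference decomposition", {
  # expectations were computed independently with RDKit's Murcko module and
  # are compared molecule-wise through backend canonicalization
  sc <- murcko_scaffolds(c("Cc1ccccc1", "c1ccncc1", "O=C(O)c1ccccc1",
                           "O=C1CCCCC1", "CC(=O)Nc1ccc(O)cc1"))
  expect_equal(sc$atom_scaffold[1], canonicalize_smiles("c1ccccc1"))
  expect_equal(sc$graph_scaffold[1], canonicalize_smiles("C1CCCCC1"))
  expect_equal(sc$atom_scaffold[2], canonicalize_smiles("c1ccncc1"))
  expect_equal(sc$graph_scaffold[2], canonicalize_smiles("C1CCCCC1"))
  # side chains prune entirely; exocyclic double bonds survive
  expect_equal(sc$atom_scaffold[3], canonicalize_smiles("c1ccccc1"))
  expect_equal(sc$atom_scaffold[4], canonicalize_smiles("O=C1CCCCC1"))
  expect_equal(sc$atom_scaffold[5], canonicalize_smiles("c1ccccc1"))

  # acyclic molecules have no scaffold
  e <- murcko_scaffolds("CC")
  expect_true(is.na(e$atom_scaffold) && is.na(e$graph_scaffold))
  expect_error(murcko_scaffolds("CC", strict = TRUE),
               class = "declm_acyclic_molecule")

  # graph scaffold is invariant under heteroatom substitution
  hetero <- murcko_scaffolds(c("c1ccccc1", "c1ccncc1", "c1ccoc1", "C1CCNCC1"))
  expect_equal(hetero$graph_scaffold[2], hetero$graph_scaffold[1])
  expect_equal(hetero$graph_scaffold[4],
               murcko_scaffolds("C1CCCCC1")$graph_scaffold)
})

test_that("scaffold novelty percentages count unseen frameworks", {
  reference <- c("Cc1ccccc1")  # atom scaffold benzene, graph scaffold C6
  designs <- c("CCc1ccccc1",   # old atom, old graph
               "Clc1ccccc1",   # old atom, old graph
               "Cc1ccncc1",    # new atom (pyridine), old graph
               "Cc1c[nH]c2ccccc12",  # indole: new atom, new graph
               "Cc1ccc2ncccc2c1")    # quinoline: new atom, new graph
  nov <- scaffold_novelty(designs, reference)
  expect_equal(nov$pct_new_atom, 60)
  expect_equal(nov$pct_new_graph, 40)
  expect_equal(nov$n_scored, 5L)

  # identical sets have zero novelty; disjoint ring systems are fully new
  expect_equal(scaffold_novelty(reference, reference)$pct_new_atom, 0)
  all_new <- scaffold_novelty("C1CCOC1", reference)
  expect_equal(c(all_new$pct_new_atom, all_new$pct_new_graph), c(100, 100))
  # acyclic designs are excluded from the denominator
  mixed <- scaffold_novelty(c("CCO", "C1CCOC1"), reference)
  expect_equal(mixed$n_scored, 1L)
  expect_equal(mixed$pct_new_atom, 100)
})

test_that("the Frechet distance reduces to closed forms", {
  gauss1d <- function(mu, sd, n = 10) {
    structure(list(mean = mu, cov = matrix(sd^2, 1, 1), n = n,
                   featurizer = "test"), class = "declm_embedding_summary")
  }
  # identical summaries -> 0
  expect_equal(frechet_distance(gauss1d(0, 1), gauss1d(0, 1)), 0, tolerance = 1e-10)
  # 1-D closed form (mu1-mu2)^2 + (sd1-sd2)^2
  expect_equal(frechet_distance(gauss1d(0, 1), gauss1d(1, 1)), 1, tolerance = 1e-8)
  expect_equal(frechet_distance(gauss1d(0, 1), gauss1d(0, 2)), 1, tolerance = 1e-8)

  # symmetry on multivariate summaries built from real features
  f1 <- embedding_summary(descriptor_features(fx_corpus$canonical_smiles[1:30]))
  f2 <- embedding_summary(descriptor_features(fx_corpus$canonical_smiles[31:60]))
  expect_equal(frechet_distance(f1, f2), frechet_distance(f2, f1), tolerance = 1e-6)
  expect_gte(frechet_distance(f1, f2), 0)
  expect_equal(frechet_distance(f1, f1), 0, tolerance = 1e-8)

  # dimension / featurizer mismatches are rejected
  expect_error(frechet_distance(gauss1d(0, 1), f1),
               class = "declm_dimension_mismatch")
})
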