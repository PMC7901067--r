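# Scoring panel, fingerprints and analysis helpers.

test_that("score panel reports structural descriptors correctly", {
  p <- score_panel("C", test_scorer())
  expect_equal(p$atom_fractions[["C"]], 1)
  expect_equal(p$n_rings, 0L)
  expect_equal(p$n_rotatable, 0L)
  expect_equal(p$n_atoms, 1L)

  b <- score_panel("c1ccccc1", test_scorer())
  expect_equal(b$n_rings, 1L)
  expect_equal(b$ring_sizes, 6L)
  expect_equal(b$n_atoms, 6L)
  expect_equal(b$n_aromatic_rings, 1L)

  expect_error(score_panel("xx"), class = "molevolve_metric_error")
})

test_that("drug-likeness matches the reference implementation closely", {
  # reference values computed once with the standard cheminformatics
  # toolkit's QED and frozen; small deviations reflect the documented
  # descriptor-backend differences (logP source, acceptor rule, alert panel)
  ref <- c("CCO" = 0.40681, "C" = 0.35978, "c1ccccc1" = 0.44263,
           "OO" = 0.29250, "N=CC" = 0.38543, "O=C=O" = 0.36424,
           "CC(=O)NC" = 0.42066, "C1CO1" = 0.34899, "FC(F)F" = 0.40107,
           "N#CCO" = 0.38081, "c1ccncc1" = 0.45309, "CC(C)=O" = 0.39823,
           "OCC1CCCCC1O" = 0.54326)
  ours <- vapply(names(ref), function(s) score_panel(s, test_scorer())$qed,
                 numeric(1))
  expect_true(all(abs(ours - ref) < 0.06))
  expect_lt(mean(abs(ours - ref)), 0.02)
})

test_that("scores lie in their documented ranges on fixture molecules", {
  fx <- generate_fixture_molecules(80, max_atoms = 9, seed = 33)
  sc <- molevolve:::score_graphs(fx$graphs, test_scorer())
  expect_true(all(sc$qed >= 0 & sc$qed <= 1))
  expect_true(all(sc$sa >= 0 & sc$sa <= 1))
  expect_true(all(sc$solubility >= 0 & sc$solubility <= 1))
  # determinism: rescoring agrees bitwise
  sc2 <- molevolve:::score_graphs(fx$graphs, test_scorer())
  expect_identical(sc, sc2)
})

test_that("tanimoto distance equals brute-force set arithmetic", {
  fp <- function(bits, nbits = 16L)
    structure(as.integer(bits), nbits = nbits, class = "morgan_fp")
  expect_equal(tanimoto_distance(fp(c(1, 2, 3)), fp(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto_distance(fp(c(1, 2)), fp(c(1, 2))), 0)
  expect_equal(tanimoto_distance(fp(1:3), fp(4:6)), 1)
  expect_equal(tanimoto_distance(fp(integer(0)), fp(integer(0))), 0)
  expect_error(tanimoto_distance(fp(1, nbits = 16L), fp(1, nbits = 32L)),
               class = "molevolve_metric_error")
})

test_that("tanimoto distance is a pseudometric on molecule fingerprints", {
  fx <- generate_fixture_molecules(30, max_atoms = 9, seed = 5)
  fps <- lapply(fx$graphs, morgan_fingerprint)
  set.seed(5)
  for (rep in 1:50) {
    ijk <- sample(length(fps), 3, replace = TRUE)
    a <- fps[[ijk[1]]]; b <- fps[[ijk[2]]]; c3 <- fps[[ijk[3]]]
    expect_equal(tanimoto_distance(a, a), 0)
    expect_equal(tanimoto_distance(a, b), tanimoto_distance(b, a))
    expect_lte(tanimoto_distance(a, c3),
               tanimoto_distance(a, b) + tanimoto_distance(b, c3) + 1e-12)
  }
})

test_that("fingerprints separate identity from similarity", {
  f1 <- morgan_fingerprint(encode_molecule("CCO", 9))
  f2 <- morgan_fingerprint(encode_molecule("OCC", 9))
  f3 <- morgan_fingerprint(encode_molecule("c1ccccc1", 9))
  expect_equal(tanimoto_distance(f1, f2), 0)      # same molecule
  expect_gt(tanimoto_distance(f1, f3), 0.5)       # different molecule
  expect_gt(length(f1), 0)
})

test_that("nearest neighbour equals an exhaustive scan", {
  fx <- generate_fixture_molecules(50, max_atoms = 9, seed = 13)
  fps <- lapply(fx$graphs, morgan_fingerprint)
  probe <- fps[[17]]
  nn <- nearest_neighbor(probe, fps)
  d <- vapply(fps, function(f) tanimoto_distance(probe, f), numeric(1))
  expect_equal(nn$index, which.min(d))
  expect_equal(nn$distance, 0)  # probe is in the reference set
  one <- nearest_neighbor(probe, fps[30])
  expect_equal(one$index, 1L)
  expect_error(nearest_neighbor(probe, list()),
               class = "molevolve_metric_error")
})

test_that("top-performer counting uses a strict threshold", {
  expect_equal(count_top_performers(c(0.59, 0.6, 0.61), "qed", 0.6), 1L)
  expect_equal(count_top_performers(numeric(0)), 0L)
  df <- data.frame(qed = c(0.7, NA, 0.61, 0.2))
  expect_equal(count_top_performers(df, "drug"), 2L)
  set.seed(8)
  x <- runif(1000)
  expect_equal(count_top_performers(x, threshold = 0.6), sum(x > 0.6))
})

test_that("histogram bins are left-closed right-open, last closed", {
  expect_equal(unname(score_histogram(0.5, breaks = c(0, 1))), 1L)
  # edge value goes to the right bin except at the terminal edge
  counts <- score_histogram(c(0.2, 0.5, 0.5, 1.0), breaks = c(0, 0.5, 1))
  expect_equal(unname(counts), c(1L, 3L))
  expect_error(score_histogram(0.5, breaks = c(0, 0, 1)))
  # multinomial sanity on uniform scores
  set.seed(21)
  counts <- score_histogram(runif(10000), breaks = seq(0, 1, 0.1))
  expect_equal(sum(counts), 10000L)
  expect_true(all(abs(counts - 1000) < 3 * sqrt(10000 * 0.1 * 0.9)))
})

test_that("synthetic-accessibility calibration behaves sensibly", {
  tbl <- test_scorer()$sa_table
  expect_s3_class(tbl, "sa_table")
  chem_easy <- molevolve:::mol_chem(encode_molecule("CCCO", 9))
  chem_hard <- molevolve:::mol_chem(encode_molecule("C1C2C1C2", 9))
  ctx_e <- molevolve:::mol_context(chem_easy)
  ctx_h <- molevolve:::mol_context(chem_hard)
  sa_e <- molevolve:::sa_normalized(chem_easy, ctx_e, tbl)
  sa_h <- molevolve:::sa_normalized(chem_hard, ctx_h, tbl)
  expect_gt(sa_e, sa_h)  # fused bicycle is harder than a short chain
})
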