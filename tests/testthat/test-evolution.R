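# Evolutionary operators: novelty filtering, replacement, crossover,
# parent sampling and batch recombination.

test_that("novelty filtering applies set semantics on canonical SMILES", {
  led <- novelty_ledger("CCO")
  graphs <- lapply(c("CCO", "CCN", "CCN"), encode_molecule, max_atoms = 9)
  out <- filter_valid_novel(graphs, led, test_scorer())
  expect_equal(out$smiles, canonical_smiles("CCN"))
  expect_equal(led$cumulative_new, 1L)
  # non-canonical alias of a seen molecule is not novel
  led2 <- novelty_ledger(canonical_smiles("CCO"))
  out2 <- filter_valid_novel(list(encode_molecule("OCC", 9)), led2,
                             test_scorer())
  expect_equal(length(out2), 0L)
  expect_equal(led2$cumulative_new, 0L)
})

test_that("all-invalid batches leave the ledger untouched", {
  led <- novelty_ledger("CCO")
  bad <- list(mol_graph(diag(0L, 4)),
              make_graph(c("O", "F"), cbind(1, 2, 3), max_atoms = 4))
  out <- filter_valid_novel(bad, led, test_scorer())
  expect_equal(length(out), 0L)
  expect_equal(led$cumulative_new, 0L)
  expect_equal(attr(out, "n_valid"), 0L)
})

test_that("ledger interval accounting is consistent and monotone", {
  led <- novelty_ledger(c("C", "CC"))
  g1 <- lapply(c("CCO", "CCN"), encode_molecule, max_atoms = 9)
  filter_valid_novel(g1, led, test_scorer())
  molevolve:::ledger_mark_interval(led)
  g2 <- lapply(c("CCO", "CCC"), encode_molecule, max_atoms = 9)
  filter_valid_novel(g2, led, test_scorer())
  molevolve:::ledger_mark_interval(led)
  expect_equal(led$per_interval_new, c(2L, 1L))
  expect_equal(led$cumulative_new, sum(led$per_interval_new))
})

test_that("random replacement is one-for-one and conserves capacity", {
  pop <- make_population(c("CCO", "CCN", "CCC"))
  set.seed(1)
  same <- replace_random(pop, make_candidates(character(0)))
  expect_identical(same$smiles, pop$smiles)
  expect_equal(attr(same, "n_replaced"), 0L)

  one <- replace_random(pop, make_candidates("CCF"))
  expect_equal(sum(one$smiles != pop$smiles), 1L)
  expect_equal(length(one$smiles), 3L)

  # many candidates, small population: capacity conserved, collisions allowed
  cands <- make_candidates(c("CCF", "CC=C", "CCCO", "NCC=O", "OCCO",
                             "CNC", "CCCC", "C#N"))
  big <- replace_random(pop, cands)
  expect_equal(length(big$smiles), 3L)
  expect_true(all(big$smiles %in% cands$smiles))
  expect_lte(attr(big, "n_replaced"), 3L)
})

test_that("guided replacement pairs best candidates with weakest incumbents", {
  pop <- make_population(c("CCO", "CCN", "CCC"), qed = c(0.1, 0.2, 0.3))
  # single middling candidate replaces only the weakest incumbent
  out <- replace_guided(pop, make_candidates("CCF", qed = 0.25), "qed")
  expect_equal(sort(out$scores$qed), c(0.2, 0.25, 0.3))
  expect_equal(attr(out, "n_replaced"), 1L)

  # candidates all below the minimum leave the population unchanged
  none <- replace_guided(pop, make_candidates(c("CCF", "CNC"),
                                              qed = c(0.05, 0.1)), "qed")
  expect_identical(none$smiles, pop$smiles)
  expect_equal(attr(none, "n_replaced"), 0L)

  # mixed case: the second candidate (0.15) does not beat the next-weakest
  # incumbent (0.2), so pairing stops after one replacement
  two <- replace_guided(pop, make_candidates(c("CCF", "CNC"),
                                             qed = c(0.9, 0.15)), "qed")
  expect_equal(sort(two$scores$qed), c(0.2, 0.3, 0.9))

  # ties are not replacements (strict inequality)
  tie <- replace_guided(pop, make_candidates("CCF", qed = 0.1), "qed")
  expect_equal(attr(tie, "n_replaced"), 0L)
})

test_that("guided replacement equals the sorted-pairing oracle", {
  base <- make_population(c("CCO", "CCN", "CCC", "CCF", "CNC", "COC"))
  cand_pool <- make_candidates(c("OCCO", "NCC=O", "CC=C", "CCCO",
                                 "C#N", "CCCC", "CC(C)C", "OC=O"))
  set.seed(42)
  for (case in 1:500) {
    pop <- base
    pop$scores$qed <- round(runif(6), 3)
    k <- sample(0:8, 1)
    cands <- molevolve:::subset_molecule_set(cand_pool,
                                             sample(8, k))
    if (k > 0) cands$scores$qed <- round(runif(k), 3)
    out <- replace_guided(pop, cands, "qed")
    expect_equal(sort(out$scores$qed),
                 oracle_guided_scores(pop$scores$qed, cands$scores$qed))
    # pointwise improvement invariant
    expect_true(all(sort(out$scores$qed) >= sort(pop$scores$qed)))
  }
})

test_that("guided replacement demands metric scores", {
  pop <- make_population(c("CCO", "CCN"))
  cands <- make_candidates("CCF")
  cands$scores$qed <- NA_real_
  expect_error(replace_guided(pop, cands, "qed"),
               class = "molevolve_metric_error")
})

test_that("crossover overwrites the leading slice, matching the oracle", {
  # worked example: k = 2 takes rows/columns 1-2 from the generated matrix
  parent <- make_graph(c("C", "O", "N"))
  gen <- make_graph(c("N", "C", "F"), cbind(1, 2, 1))
  child <- crossover(parent, gen, 2)
  expect_equal(diag(child), c(2L, 1L, 2L))   # N, C from gen; N from parent
  expect_equal(child[1, 2], 1L)
  expect_equal(child[1, 3], 0L); expect_equal(child[2, 3], 0L)

  # boundary cases
  expect_identical(crossover(parent, gen, 3), gen)
  k1 <- crossover(parent, gen, 1)
  expect_equal(diag(k1), c(2L, 3L, 2L))
  expect_equal(unclass(k1)[1, ], unclass(gen)[1, ])

  expect_error(crossover(parent, make_graph("C"), 1),
               class = "molevolve_size_error")
  expect_error(crossover(parent, gen, 0), class = "molevolve_range_error")
  expect_error(crossover(parent, gen, 4), class = "molevolve_range_error")
})

test_that("crossover equals brute-force assembly on random triples", {
  set.seed(7)
  for (rep in 1:1000) {
    L <- sample(2:8, 1)
    p <- random_any_graph(L); g <- random_any_graph(L)
    k <- sample(L, 1)
    child <- crossover(p, g, k)
    expect_identical(unclass(child), oracle_crossover(p, g, k))
    expect_identical(unclass(child), t(unclass(child)))
  }
})

test_that("parent sampling follows the softmax of raw scores", {
  pop <- make_population(c("CCO", "CCN"), qed = c(0, log(2)))
  set.seed(123)
  draws <- molevolve:::sample_parent_idx(pop, "qed", 30000L)
  p2 <- mean(draws == 2L)
  se <- sqrt(2 / 3 * 1 / 3 / 30000)
  expect_lt(abs(p2 - 2 / 3), 3 * se)

  # equal scores give the uniform distribution
  pop_eq <- make_population(c("CCO", "CCN", "CCC"), qed = c(0.4, 0.4, 0.4))
  draws <- molevolve:::sample_parent_idx(pop_eq, "qed", 30000L)
  expect_true(all(abs(tabulate(draws, 3) / 30000 - 1 / 3) < 0.02))

  # uniform draws when no metric is given
  draws <- molevolve:::sample_parent_idx(pop_eq, NULL, 30000L)
  expect_true(all(abs(tabulate(draws, 3) / 30000 - 1 / 3) < 0.02))

  one <- sample_parent(pop, "qed")
  expect_true(one$index %in% 1:2)
  expect_identical(one$smiles, pop$smiles[one$index])
})

test_that("softmax parent draws match exact weights at scale", {
  fx <- generate_fixture_molecules(200, max_atoms = 9, seed = 17)
  pop <- training_population(fx, scorer = test_scorer())
  s <- pop$scores$qed
  w <- exp(s - max(s)); w <- w / sum(w)
  set.seed(99)
  draws <- molevolve:::sample_parent_idx(pop, "qed", 1e5L)
  freq <- tabulate(draws, 200) / 1e5
  se <- sqrt(w * (1 - w) / 1e5)
  expect_true(all(abs(freq - w) <= 3 * se + 1e-9))
})

test_that("recombination respects the fraction and passes the rest through", {
  pop <- make_population(c("CCO", "CCN", "CCC"))
  set.seed(31)
  gen <- replicate(10, random_any_graph(9), simplify = FALSE)
  expect_identical(recombine_batch(gen, pop, fraction = 0), gen)
  out <- recombine_batch(gen, pop, fraction = 0.5)
  expect_equal(length(out), 10L)
  changed <- sum(!mapply(identical, out, gen))
  expect_lte(changed, 5L)  # exactly 5 crossed, some may coincide
  out1 <- recombine_batch(gen, pop, fraction = 1)
  expect_equal(length(out1), 10L)
})

test_that("population construction checks capacity and scores members", {
  fx <- generate_fixture_molecules(20, max_atoms = 9, seed = 3)
  pop <- training_population(fx, capacity = 10, scorer = test_scorer())
  expect_equal(pop$capacity, 10L)
  expect_equal(length(pop$smiles), 10L)
  expect_false(anyNA(pop$scores$qed))
  expect_error(training_population(fx, capacity = 21), "need")
})
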