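# Dataset loaders and the fixture generator.

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".smi")
  writeLines(lines, f)
  f
}

test_that("loader applies element and atom-count filters in file order", {
  f <- write_tmp(c("CCO", "CCS", paste(rep("C", 22), collapse = "")))
  out <- load_smiles_file(f, max_atoms = 25, elements = c("C", "N", "O"),
                          max_filter_atoms = 20, take_first = 10)
  expect_equal(out$smiles, "CCO")
  unlink(f)
})

test_that("unparseable lines are dropped silently", {
  f <- write_tmp(c("CCO", "xyz(", "CCN"))
  out <- load_smiles_file(f, max_atoms = 9)
  expect_equal(out$smiles, canonical_smiles(c("CCO", "CCN")))
  unlink(f)
})

test_that("the 10-20 atom window keeps only mid-size molecules", {
  five <- "CCCCC"
  fifteen <- paste(rep("C", 15), collapse = "")
  twentyfive <- paste(rep("C", 25), collapse = "")
  f <- write_tmp(c(five, fifteen, twentyfive))
  out <- load_smiles_file(f, max_atoms = 30, min_atoms = 10,
                          max_filter_atoms = 20)
  expect_equal(out$smiles, canonical_smiles(fifteen))
  unlink(f)
})

test_that("delimited files with a smiles column are auto-detected", {
  f <- write_tmp(c("id,smiles,score", "a,CCO,1.2", "b,OCC,0.3", "c,CCS,9"))
  out <- load_smiles_file(f, max_atoms = 9)
  # OCC canonicalizes onto CCO; both survive as records, in file order
  expect_equal(out$smiles, c("CCO", "CCO"))
  unlink(f)
})

test_that("loader errors are classed", {
  expect_error(load_smiles_file(tempfile(), max_atoms = 9),
               class = "molevolve_io_error")
  f <- write_tmp(c("CCS", "xx"))
  expect_error(load_smiles_file(f, max_atoms = 9, elements = c("C", "O")),
               class = "molevolve_empty_dataset_error")
  unlink(f)
})

test_that("loading is idempotent and order-stable", {
  f <- write_tmp(c("CCN", "CCO", "c1ccccc1", "CC(=O)O"))
  a <- load_smiles_file(f, max_atoms = 9)
  b <- load_smiles_file(f, max_atoms = 9)
  expect_identical(a$smiles, b$smiles)
  expect_identical(a$graphs, b$graphs)
  expect_equal(a$smiles[1:2], canonical_smiles(c("CCN", "CCO")))
  unlink(f)
})

test_that("mixed datasets splice the secondary prefix over the primary", {
  prim <- generate_fixture_molecules(5, max_atoms = 9, seed = 1)
  sec <- generate_fixture_molecules(2, max_atoms = 9, seed = 2)
  mix <- build_mixed_dataset(prim, sec, capacity = 5, n_second = 2)
  expect_equal(mix$smiles, c(sec$smiles, prim$smiles[3:5]))
  pure <- build_mixed_dataset(prim, sec, capacity = 5, n_second = 0)
  expect_equal(pure$smiles, prim$smiles)
  expect_error(build_mixed_dataset(prim, sec, capacity = 6, n_second = 2))
  expect_error(build_mixed_dataset(prim, sec, capacity = 5, n_second = 3))
})

test_that("fixture generation is seeded, valid, deduplicated and bounded", {
  a <- generate_fixture_molecules(100, max_atoms = 9, seed = 5)
  b <- generate_fixture_molecules(100, max_atoms = 9, seed = 5)
  expect_identical(a$smiles, b$smiles)
  expect_equal(anyDuplicated(a$smiles), 0L)
  expect_length(a$smiles, 100L)
  for (g in a$graphs[1:20]) {
    chem <- molevolve:::mol_chem(g)
    expect_true(chem$ok)
    expect_lte(length(chem$els), 9L)
  }
  # canonical smiles are the decode of their graphs (same sanitization gate)
  expect_identical(vapply(a$graphs[1:10], decode_graph, character(1)),
                   a$smiles[1:10])
})

test_that("fixture generation honours the element set and exhausts finitely", {
  cn <- generate_fixture_molecules(30, max_atoms = 7,
                                   elements = c("C", "N"), seed = 6)
  expect_false(any(grepl("[OF]", cn$smiles)))
  one <- generate_fixture_molecules(1, max_atoms = 1, elements = "C",
                                    seed = 1)
  expect_equal(one$smiles, "C")
  expect_error(
    generate_fixture_molecules(2, max_atoms = 1, elements = "C", seed = 1),
    class = "molevolve_fixture_exhausted_error")
})
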