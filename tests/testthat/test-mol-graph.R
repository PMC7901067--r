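# Adjacency-matrix molecular representation: encode/decode round trips,
# one-hot layout and discretization.

test_that("single heavy atom encodes to a bare diagonal", {
  g <- encode_molecule("C", max_atoms = 3)
  expect_equal(diag(g), c(1L, 0L, 0L))
  expect_true(all(g[row(g) != col(g)] == 0L))
  expect_identical(decode_graph(g), "C")
})

test_that("carbon dioxide round-trips through encode and decode", {
  g <- encode_molecule("O=C=O", max_atoms = 4)
  expect_equal(sort(diag(g)[diag(g) != 0L]), c(1L, 3L, 3L))
  expect_equal(sum(g[upper.tri(g)] == 2L), 2L)  # two double bonds
  expect_identical(decode_graph(g), canonical_smiles("O=C=O"))
})

test_that("encode rejects bad input with an encoding error", {
  expect_error(encode_molecule("CCS", 9), class = "molevolve_encoding_error")
  expect_error(encode_molecule("not-a-smiles", 9),
               class = "molevolve_encoding_error")
  expect_error(encode_molecule("CCCCCC", 4),   # too many atoms
               class = "molevolve_encoding_error")
  expect_error(encode_molecule("C(C)(C)(C)(C)C", 9),  # 5-valent carbon
               class = "molevolve_encoding_error")
})

test_that("round trip preserves molecular identity on varied molecules", {
  smiles <- c("CCO", "c1ccccc1", "c1cc[nH]c1", "CC(=O)NC", "N#CCO",
              "C1CC1C(=O)O", "FC(F)F", "OCC1CCCCC1O", "C1=CC2CC1C2")
  for (s in smiles) {
    g <- encode_molecule(s, max_atoms = 12)
    expect_identical(decode_graph(g), canonical_smiles(s), label = s)
  }
})

test_that("decode flags empty, valence-violating and disconnected graphs", {
  expect_true(is.na(decode_graph(mol_graph(diag(0L, 3)))))  # no atoms
  # O#F exceeds fluorine valence
  bad <- make_graph(c("O", "F"), cbind(1, 2, 3))
  expect_true(is.na(decode_graph(bad)))
  # two fragments
  frag <- make_graph(c("C", "C", "O"), cbind(1, 2, 1))
  expect_true(is.na(decode_graph(frag)))
  # bonds hanging off padding slots are ignored, not lethal
  m <- diag(0L, 3); m[1, 1] <- 1L; m[2, 3] <- m[3, 2] <- 1L
  expect_identical(decode_graph(mol_graph(m)), "C")
})

test_that("one-hot layout length counts atom and bond channels", {
  expect_equal(layout_length(9), 9 * 5 + 36 * 4)   # 189
  expect_equal(layout_length(2), 2 * 5 + 1 * 4)    # 14
  expect_equal(layout_length(1), 5)
})

test_that("one-hot encoding is exactly invertible and one-hot per cell", {
  set.seed(11)
  for (rep in 1:20) {
    g <- random_any_graph(sample(2:7, 1))
    v <- to_one_hot(g)
    expect_true(all(v %in% c(0, 1)))
    L <- nrow(g)
    expect_equal(sum(v), L + L * (L - 1) / 2)  # one active channel per cell
    expect_identical(discretize(v, L), g)
  }
})

test_that("discretize takes the per-cell argmax and breaks ties low", {
  # all-zero raw vector: every block ties, lowest channel (NONE/NOBOND) wins
  g <- discretize(numeric(layout_length(3)), 3)
  expect_true(all(unclass(g) == 0L))
  # a deliberate tie between channels 2 and 3 of the first atom block
  v <- numeric(layout_length(2))
  v[2] <- v[3] <- 5
  expect_equal(diag(discretize(v, 2))[1], 1L)  # channel 2 => code 1 (C)
  expect_error(discretize(numeric(10), 3))
  expect_error(discretize(c(NA, numeric(layout_length(2) - 1)), 2))
})

test_that("discretize always yields well-formed symmetric graphs", {
  set.seed(99)
  raw <- matrix(rnorm(1000 * layout_length(5)), 1000)
  gs <- discretize(raw, 5)
  for (g in gs) {
    expect_true(identical(unclass(g), t(unclass(g))))
    expect_true(all(diag(g) %in% 0:4))
    expect_true(all(g[row(g) != col(g)] %in% 0:3))
  }
})

test_that("mol_graph validates its input", {
  expect_error(mol_graph(matrix(0L, 2, 3)), "square")
  m <- diag(0L, 2); m[1, 2] <- 1L
  expect_error(mol_graph(m), "symmetric")
  expect_error(mol_graph(diag(7L, 2)), "atom codes")
})
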