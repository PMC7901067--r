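# Shared helpers: graph constructors and independent brute-force oracles.

# build a mol_graph from atom symbols and a bond list (i, j, order)
make_graph <- function(atoms, bonds = NULL, max_atoms = length(atoms)) {
  m <- matrix(0L, max_atoms, max_atoms)
  codes <- c(NONE = 0L, C = 1L, N = 2L, O = 3L, F = 4L)
  diag(m)[seq_along(atoms)] <- codes[atoms]
  if (!is.null(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      m[bonds[b, 1L], bonds[b, 2L]] <- as.integer(bonds[b, 3L])
      m[bonds[b, 2L], bonds[b, 1L]] <- as.integer(bonds[b, 3L])
    }
  }
  mol_graph(m)
}

# arbitrary random mol_graph (not necessarily chemically valid)
random_any_graph <- function(L = 5L) {
  m <- matrix(0L, L, L)
  diag(m) <- sample(0:4, L, replace = TRUE)
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    o <- sample(0:3, 1L, prob = c(0.7, 0.15, 0.1, 0.05))
    m[i, j] <- m[j, i] <- o
  }
  mol_graph(m)
}

# element-wise brute-force slice crossover oracle
oracle_crossover <- function(parent, generated, k) {
  L <- nrow(parent)
  out <- matrix(0L, L, L)
  for (i in seq_len(L)) for (j in seq_len(L))
    out[i, j] <- if (i <= k || j <= k) generated[i, j] else parent[i, j]
  out
}

# brute-force guided-replacement oracle: returns the multiset of metric
# scores after pairing sorted candidates against sorted incumbents
oracle_guided_scores <- function(pop_scores, cand_scores) {
  ps <- sort(pop_scores)
  cs <- sort(cand_scores, decreasing = TRUE)
  k <- 0L
  while (k < min(length(cs), length(ps)) && cs[k + 1L] > ps[k + 1L])
    k <- k + 1L
  if (k > 0L) ps[seq_len(k)] <- cs[seq_len(k)]
  sort(ps)
}

# shared small scorer: calibrated once per test run on a fixed fixture corpus
test_scorer <- local({
  cached <- NULL
  function() {
    if (is.null(cached))
      cached <<- make_scorer(
        generate_fixture_molecules(150, max_atoms = 9, seed = 2468)$graphs)
    cached
  }
})

# a small scored candidate set built from SMILES, with fabricated scores
# optionally overriding the computed ones (for replacement logic tests)
make_candidates <- function(smiles, max_atoms = 9L, qed = NULL) {
  enc <- lapply(smiles, encode_molecule, max_atoms = max_atoms)
  led <- novelty_ledger()
  set <- filter_valid_novel(enc, led, test_scorer())
  if (!is.null(qed)) {
    stopifnot(length(qed) == length(set$smiles))
    set$scores$qed <- qed
  }
  set
}

make_population <- function(smiles, max_atoms = 9L, qed = NULL) {
  enc <- lapply(smiles, encode_molecule, max_atoms = max_atoms)
  ms <- molevolve:::molecule_set(canonical_smiles(smiles), enc,
                                 max_atoms = max_atoms)
  pop <- training_population(ms, scorer = test_scorer())
  if (!is.null(qed)) pop$scores$qed <- qed
  pop
}
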