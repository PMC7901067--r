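# Structural-alert panel for the drug-likeness score. The reference alert
# collection is a set of ~100 SMARTS patterns for reactive or undesirable
# substructures; restricted to neutral C/N/O/F chemistry most of them can
# never match, so the panel below keeps the twenty patterns that account for
# essentially all firings in this chemical space, hand-compiled as direct
# graph predicates (each counts at most once, like a substructure search).

count_alerts <- function(ctx) {
  n <- length(ctx$els)
  bonds <- ctx$bonds
  sym <- ctx$sym
  order_of <- matrix(0L, n, n)
  ring_of <- matrix(FALSE, n, n)
  if (nrow(bonds) > 0L) {
    order_of[bonds[, 1:2, drop = FALSE]] <- bonds[, 3L]
    order_of[bonds[, c(2L, 1L), drop = FALSE]] <- bonds[, 3L]
    ring_of[bonds[, 1:2, drop = FALSE]] <- ctx$ring_bond
    ring_of[bonds[, c(2L, 1L), drop = FALSE]] <- ctx$ring_bond
  }
  nbrs <- function(a) which(order_of[a, ] > 0L)
  sp3_carbon <- function(a) sym[a] == "C" && !ctx$has_double[a] &&
    !ctx$has_triple[a]
  hetero <- sym %in% c("N", "O")

  hits <- logical(20)
  db <- which(bonds[, 3L] == 2L)
  sb <- which(bonds[, 3L] == 1L)
  tb <- which(bonds[, 3L] == 3L)

  # 1: isolated alkene -- C=C whose remaining substituents are all sp3 C
  for (b in db) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    if (sym[i] != "C" || sym[j] != "C") next
    others <- c(setdiff(nbrs(i), j), setdiff(nbrs(j), i))
    if (all(vapply(others, sp3_carbon, logical(1))) &&
        all(order_of[cbind(c(rep(i, ctx$deg[i] - 1L),
                             rep(j, ctx$deg[j] - 1L)),
                           others)] == 1L)) {
      hits[1] <- TRUE; break
    }
  }
  # 2: acyclic heteroatom-heteroatom single bond (N/O - N/O)
  for (b in sb) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    if (hetero[i] && hetero[j] && !ctx$in_ring[i] && !ctx$in_ring[j]) {
      hits[2] <- TRUE; break
    }
  }
  # 3: two acyclic N/O substituents on one sp3 carbon (acetal / aminal)
  for (a in seq_len(n)) {
    if (!sp3_carbon(a)) next
    het_nb <- Filter(function(x) hetero[x] && !ctx$in_ring[x] &&
                       order_of[a, x] == 1L &&
                       (sym[x] == "O" || ctx$deg[x] + ctx$nH[x] >= 3L),
                     nbrs(a))
    if (length(het_nb) >= 2L) { hits[3] <- TRUE; break }
  }
  # 4: acyclic imine C=N
  for (b in db) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    if (setequal(sym[c(i, j)], c("C", "N")) &&
        !ctx$in_ring[i] && !ctx$in_ring[j]) { hits[4] <- TRUE; break }
  }
  # 5: three-membered heterocycle
  for (r in ctx$rings)
    if (length(r) == 3L && any(hetero[r])) { hits[5] <- TRUE; break }
  # 6: enol ether / enol -- C=C with acyclic sp2 carbon bearing single-bond O
  for (b in db) {
    for (pick in list(bonds[b, 1:2], bonds[b, 2:1])) {
      i <- pick[1L]; j <- pick[2L]
      if (sym[i] != "C" || sym[j] != "C" || ctx$in_ring[j]) next
      onb <- Filter(function(x) sym[x] == "O" && order_of[j, x] == 1L, nbrs(j))
      if (length(onb) > 0L) { hits[6] <- TRUE; break }
    }
    if (hits[6]) break
  }
  # 7: alkyne C#C
  for (b in tb)
    if (all(sym[bonds[b, 1:2]] == "C")) { hits[7] <- TRUE; break }
  # 8: peroxide O-O (any bond)
  for (b in seq_len(nrow(bonds)))
    if (all(sym[bonds[b, 1:2]] == "O")) { hits[8] <- TRUE; break }
  # 9: allene C=C=C
  for (a in seq_len(n)) {
    if (sym[a] != "C") next
    dnb <- Filter(function(x) order_of[a, x] == 2L && sym[x] == "C", nbrs(a))
    if (length(dnb) >= 2L) { hits[9] <- TRUE; break }
  }
  # 10: aldehyde CH=O
  for (b in db) {
    for (pick in list(bonds[b, 1:2], bonds[b, 2:1])) {
      if (sym[pick[1L]] == "C" && sym[pick[2L]] == "O" &&
          ctx$nH[pick[1L]] == 1L) { hits[10] <- TRUE; break }
    }
    if (hits[10]) break
  }
  # 11: four consecutive acyclic two-connected atoms (floppy chain)
  d2 <- which(ctx$deg == 2L & !ctx$in_ring)
  if (length(d2) >= 4L) {
    for (b in sb) {
      i <- bonds[b, 1L]; j <- bonds[b, 2L]
      if (!(i %in% d2) || !(j %in% d2)) next
      ii <- Filter(function(x) x %in% d2 && x != j && order_of[i, x] == 1L,
                   nbrs(i))
      jj <- Filter(function(x) x %in% d2 && x != i && order_of[j, x] == 1L,
                   nbrs(j))
      if (length(ii) > 0L && length(jj) > 0L &&
          any(outer(ii, jj, `!=`))) { hits[11] <- TRUE; break }
    }
  }
  # 12: hydrazine N-NH2
  for (b in sb) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    if (sym[i] == "N" && sym[j] == "N" &&
        (ctx$nH[i] == 2L || ctx$nH[j] == 2L)) { hits[12] <- TRUE; break }
  }
  # 13: acyclic conjugated diene C=C-C=C
  for (b in sb) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    if (sym[i] != "C" || sym[j] != "C") next
    if (ctx$in_ring[i] || ctx$in_ring[j]) next
    di <- Filter(function(x) order_of[i, x] == 2L && sym[x] == "C" &&
                   !ctx$in_ring[x] && x != j, nbrs(i))
    dj <- Filter(function(x) order_of[j, x] == 2L && sym[x] == "C" &&
                   !ctx$in_ring[x] && x != i, nbrs(j))
    if (length(di) > 0L && length(dj) > 0L) { hits[13] <- TRUE; break }
  }
  # 14: amidine-type N=C-[N,O] with acyclic central carbon
  for (b in db) {
    for (pick in list(bonds[b, 1:2], bonds[b, 2:1])) {
      i <- pick[1L]; j <- pick[2L]  # i = N, j = C
      if (sym[i] != "N" || sym[j] != "C" || ctx$in_ring[j]) next
      het_nb <- Filter(function(x) hetero[x] && order_of[j, x] == 1L, nbrs(j))
      if (length(het_nb) > 0L) { hits[14] <- TRUE; break }
    }
    if (hits[14]) break
  }
  # 15: nitroso N=O
  for (b in db) {
    for (pick in list(bonds[b, 1:2], bonds[b, 2:1])) {
      if (sym[pick[1L]] == "N" && sym[pick[2L]] == "O" &&
          ctx$deg[pick[1L]] <= 2L && ctx$nH[pick[1L]] == 0L) {
        hits[15] <- TRUE; break
      }
    }
    if (hits[15]) break
  }
  # 16: N-F bond
  for (b in seq_len(nrow(bonds)))
    if (setequal(sym[bonds[b, 1:2]], c("N", "F"))) { hits[16] <- TRUE; break }
  # 17: ketene C=C=O
  for (a in seq_len(n)) {
    if (sym[a] != "C") next
    dnb <- nbrs(a)[order_of[a, nbrs(a)] == 2L]
    if (length(dnb) >= 2L && any(sym[dnb] == "C") && any(sym[dnb] == "O")) {
      hits[17] <- TRUE; break
    }
  }
  # 18: acyclic azo N=N
  for (b in db) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    if (sym[i] == "N" && sym[j] == "N" &&
        !ctx$in_ring[i] && !ctx$in_ring[j]) { hits[18] <- TRUE; break }
  }
  # 19: acyclic vinyl carbonyl C=C-C=O
  for (b in db) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    if (sym[i] != "C" || sym[j] != "C" || ctx$ring_bond[b]) next
    for (a in c(i, j)) {
      cnb <- Filter(function(x) sym[x] == "C" && order_of[a, x] == 1L &&
                      any(order_of[x, ] == 2L &
                            sym == "O"), nbrs(a))
      if (length(cnb) > 0L) { hits[19] <- TRUE; break }
    }
    if (hits[19]) break
  }
  # 20: N-C-F (alpha-fluoro amine motif)
  for (a in seq_len(n)) {
    if (sym[a] != "C") next
    nb <- nbrs(a)
    if (any(sym[nb] == "N" & order_of[a, nb] == 1L) &&
        any(sym[nb] == "F")) { hits[20] <- TRUE; break }
  }
  sum(hits)
}
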