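# Native molecular descriptors computed on the kekulized adjacency-matrix
# graph. Everything here is a deterministic function of the heavy-atom graph
# (hydrogens implicit); logP and TPSA are the only descriptors delegated to
# OpenBabel (see decode_graphs).

# Ring/valence context shared by descriptors, alerts and the SA score.
# Extends a mol_chem() result with per-atom and per-bond ring information.
mol_context <- function(chem) {
  n <- length(chem$els)
  bonds <- chem$bonds
  ring_bond <- ring_bond_flags(n, bonds)
  rings <- sssr_rings(n, bonds)
  in_ring <- logical(n)
  for (r in rings) in_ring[r] <- TRUE
  has_double <- logical(n); has_triple <- logical(n)
  if (nrow(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      if (bonds[b, 3L] == 2L) has_double[bonds[b, 1:2]] <- TRUE
      if (bonds[b, 3L] == 3L) has_triple[bonds[b, 1:2]] <- TRUE
    }
  }
  c(chem, list(ring_bond = ring_bond, rings = rings, in_ring = in_ring,
               has_double = has_double, has_triple = has_triple,
               sym = ATOM_SYMBOLS[chem$els + 1L]))
}

# Simplified Hueckel aromaticity over the smallest set of smallest rings:
# a ring is aromatic when every member is sp2-capable and the pi-electron
# count is 4n + 2. Per ring atom: an endocyclic double bond contributes one
# electron, a lone pair of an N/O without any double bond two, an exocyclic
# double bond towards another ring atom one, towards a chain atom zero
# (carbonyl-type carbon); an sp3 carbon disqualifies the ring.
aromatic_rings <- function(ctx) {
  if (length(ctx$rings) == 0L) return(list(flags = logical(0),
                                           atoms = logical(length(ctx$els))))
  bonds <- ctx$bonds
  order_of <- matrix(0L, length(ctx$els), length(ctx$els))
  if (nrow(bonds) > 0L) {
    order_of[bonds[, 1:2, drop = FALSE]] <- bonds[, 3L]
    order_of[bonds[, c(2L, 1L), drop = FALSE]] <- bonds[, 3L]
  }
  flags <- vapply(ctx$rings, function(r) {
    k <- length(r)
    pi_e <- 0
    for (t in seq_len(k)) {
      a <- r[t]
      nb <- which(order_of[a, ] > 0L)
      dbl <- nb[order_of[a, nb] == 2L]
      if (length(dbl) > 0L && any(dbl %in% r)) {
        pi_e <- pi_e + 1
      } else if (length(dbl) > 0L) {
        # exocyclic double bond; sp2 but contributes only if the partner is
        # itself a ring atom (fused aromatic systems)
        if (any(ctx$in_ring[dbl])) pi_e <- pi_e + 1
      } else if (ctx$sym[a] %in% c("N", "O")) {
        pi_e <- pi_e + 2
      } else if (ctx$has_triple[a]) {
        return(FALSE)
      } else {
        return(FALSE)  # sp3 carbon
      }
    }
    pi_e >= 6 && (pi_e - 2) %% 4 == 0
  }, logical(1))
  atoms <- logical(length(ctx$els))
  for (i in which(flags)) atoms[ctx$rings[[i]]] <- TRUE
  list(flags = flags, atoms = atoms)
}

# Molecular weight with implicit hydrogens, standard atomic weights.
descriptor_mw <- function(ctx) {
  sum(ATOM_MASS[ctx$sym]) + H_MASS * sum(ctx$nH)
}

# Hydrogen-bond donors: N/O atoms carrying at least one hydrogen.
descriptor_hbd <- function(ctx) {
  sum(ctx$sym %in% c("N", "O") & ctx$nH > 0L)
}

# Hydrogen-bond acceptors: every O, plus N except amide-type N (single bond
# to a carbonyl carbon), N with a non-aromatic double bond (imine, nitroso)
# and pyrrole-type aromatic N-H.
descriptor_hba <- function(ctx, arom_atoms) {
  nacc <- sum(ctx$sym == "O")
  bonds <- ctx$bonds
  carbonyl_c <- logical(length(ctx$els))
  if (nrow(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      if (bonds[b, 3L] == 2L) {
        i <- bonds[b, 1L]; j <- bonds[b, 2L]
        if (ctx$sym[i] == "C" && ctx$sym[j] == "O") carbonyl_c[i] <- TRUE
        if (ctx$sym[j] == "C" && ctx$sym[i] == "O") carbonyl_c[j] <- TRUE
      }
    }
  }
  for (a in which(ctx$sym == "N")) {
    amide <- FALSE
    if (nrow(bonds) > 0L) {
      for (b in seq_len(nrow(bonds))) {
        if (bonds[b, 3L] != 1L) next
        other <- if (bonds[b, 1L] == a) bonds[b, 2L]
                 else if (bonds[b, 2L] == a) bonds[b, 1L] else next
        if (carbonyl_c[other]) { amide <- TRUE; break }
      }
    }
    if (amide) next
    if (ctx$has_double[a] && !arom_atoms[a]) next
    if (arom_atoms[a] && ctx$nH[a] > 0L) next
    nacc <- nacc + 1L
  }
  nacc
}

# Rotatable bonds (strict definition): acyclic single bonds between two
# non-terminal heavy atoms, neither of which sits in a triple bond.
descriptor_rotb <- function(ctx) {
  bonds <- ctx$bonds
  if (nrow(bonds) == 0L) return(0L)
  cnt <- 0L
  for (b in seq_len(nrow(bonds))) {
    if (bonds[b, 3L] != 1L || ctx$ring_bond[b]) next
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    if (ctx$deg[i] < 2L || ctx$deg[j] < 2L) next
    if (ctx$has_triple[i] || ctx$has_triple[j]) next
    cnt <- cnt + 1L
  }
  cnt
}

# Full descriptor set for one sanitized molecule. logp/tpsa come from the
# decode step (OpenBabel) and are passed through.
descriptor_panel <- function(chem, logp = NA_real_, tpsa = NA_real_) {
  ctx <- mol_context(chem)
  arom <- aromatic_rings(ctx)
  fracs <- table(factor(ctx$sym, levels = c("C", "N", "O", "F")))
  fracs <- fracs / length(ctx$sym)
  list(
    mw = descriptor_mw(ctx),
    logp = logp,
    tpsa = tpsa,
    hba = descriptor_hba(ctx, arom$atoms),
    hbd = descriptor_hbd(ctx),
    n_rotatable = descriptor_rotb(ctx),
    n_aromatic_rings = sum(arom$flags),
    n_alerts = count_alerts(ctx),
    n_atoms = length(ctx$els),
    n_rings = length(ctx$rings),
    ring_sizes = sort(lengths(ctx$rings)),
    atom_fractions = as.numeric(fracs) |> stats::setNames(names(fracs)),
    ctx = ctx
  )
}
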