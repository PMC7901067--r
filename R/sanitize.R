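# Native sanitization of molecular graphs.
#
# A graph decodes to a valid molecule iff it has at least one atom, every
# atom's bond-order sum fits the neutral default valence (C 4, N 3, O 2, F 1;
# implicit hydrogens fill the remainder), and the heavy-atom graph is a single
# connected component. Bonds incident to padding slots (diagonal code 0) are
# ignored. For the neutral kekulized C/N/O/F chemical space handled here this
# coincides with toolkit sanitization; every accepted molecule additionally
# round-trips through OpenBabel when its canonical SMILES is produced.

# Extract the chemistry of a graph: atom element codes, bond table and
# implicit hydrogen counts, or a failure reason. Returns a list:
#   ok (logical), reason, els (codes 1..4 of the n active atoms),
#   bonds (m x 3 matrix: i, j, order; 1-based over active atoms), nH, deg.
mol_chem <- function(g) {
  d <- diag(g)
  active <- which(d != 0L)
  n <- length(active)
  if (n == 0L) return(list(ok = FALSE, reason = "empty"))
  els <- d[active]
  sub <- unclass(g)[active, active, drop = FALSE]
  diag(sub) <- 0L
  idx <- which(upper.tri(sub) & sub != 0L, arr.ind = TRUE)
  bonds <- cbind(i = idx[, 1L], j = idx[, 2L],
                 order = sub[idx])
  if (nrow(bonds) == 0L)
    bonds <- matrix(integer(0), 0L, 3L,
                    dimnames = list(NULL, c("i", "j", "order")))
  vsum <- integer(n)
  deg <- integer(n)
  if (nrow(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      vsum[bonds[b, 1L]] <- vsum[bonds[b, 1L]] + bonds[b, 3L]
      vsum[bonds[b, 2L]] <- vsum[bonds[b, 2L]] + bonds[b, 3L]
      deg[bonds[b, 1L]] <- deg[bonds[b, 1L]] + 1L
      deg[bonds[b, 2L]] <- deg[bonds[b, 2L]] + 1L
    }
  }
  maxval <- ATOM_VALENCE[ATOM_SYMBOLS[els + 1L]]
  if (any(vsum > maxval)) return(list(ok = FALSE, reason = "valence"))
  if (n > 1L) {
    comp <- graph_components(n, bonds)
    if (max(comp) > 1L) return(list(ok = FALSE, reason = "disconnected"))
  }
  list(ok = TRUE, reason = "", els = els, bonds = bonds,
       nH = as.integer(maxval - vsum), deg = deg)
}

# Connected components by BFS; returns component id per atom.
graph_components <- function(n, bonds) {
  adj <- bond_adjacency(n, bonds)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}

bond_adjacency <- function(n, bonds) {
  adj <- rep(list(integer(0)), n)
  if (nrow(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1L]; j <- bonds[b, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# Which bonds lie on a ring? A bond is a ring bond iff it is not a bridge,
# i.e. removing it leaves its endpoints connected. Graphs here are tiny, so
# the direct check is fine.
ring_bond_flags <- function(n, bonds) {
  m <- nrow(bonds)
  if (m == 0L) return(logical(0))
  flags <- logical(m)
  for (b in seq_len(m)) {
    rest <- bonds[-b, , drop = FALSE]
    adj <- bond_adjacency(n, rest)
    # BFS from endpoint i looking for endpoint j
    src <- bonds[b, 1L]; dst <- bonds[b, 2L]
    seen <- logical(n); seen[src] <- TRUE
    queue <- src
    while (length(queue) > 0L && !seen[dst]) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    flags[b] <- seen[dst]
  }
  flags
}

# Smallest set of smallest rings via Horton's algorithm: candidate cycles are
# shortest cycles through each (vertex, edge) pair; a minimum cycle basis is
# picked greedily by GF(2) independence over edge incidence vectors. Returns a
# list of integer vectors (atom indices per ring).
sssr_rings <- function(n, bonds) {
  m <- nrow(bonds)
  if (m == 0L) return(list())
  n_rings <- m - n + max(graph_components(n, bonds))
  if (n_rings <= 0L) return(list())
  adj <- bond_adjacency(n, bonds)
  edge_id <- matrix(0L, n, n)
  for (b in seq_len(m)) {
    edge_id[bonds[b, 1L], bonds[b, 2L]] <- b
    edge_id[bonds[b, 2L], bonds[b, 1L]] <- b
  }
  candidates <- list()
  for (v in seq_len(n)) {
    # BFS tree from v with parents
    dist <- rep(NA_integer_, n); parent <- integer(n)
    dist[v] <- 0L
    queue <- v
    while (length(queue) > 0L) {
      x <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[x]]) if (is.na(dist[w])) {
        dist[w] <- dist[x] + 1L; parent[w] <- x; queue <- c(queue, w)
      }
    }
    path_to <- function(x) {
      p <- x
      while (x != v) { x <- parent[x]; p <- c(p, x) }
      p
    }
    for (b in seq_len(m)) {
      x <- bonds[b, 1L]; y <- bonds[b, 2L]
      if (is.na(dist[x]) || is.na(dist[y])) next
      px <- path_to(x); py <- path_to(y)
      # paths must share only v, else the walk is not a simple cycle
      if (length(intersect(px[-length(px)], py[-length(py)])) > 0L) next
      cyc <- c(px, rev(py[-length(py)]))
      if (anyDuplicated(cyc)) next
      if (length(cyc) < 3L) next
      candidates[[length(candidates) + 1L]] <- cyc
    }
  }
  if (length(candidates) == 0L) return(list())
  # unique cycles as edge sets
  edge_vec <- function(cyc) {
    k <- length(cyc)
    ev <- logical(m)
    for (t in seq_len(k)) {
      a <- cyc[t]; b2 <- cyc[if (t == k) 1L else t + 1L]
      id <- edge_id[a, b2]
      if (id == 0L) return(NULL)
      ev[id] <- TRUE
    }
    ev
  }
  evs <- lapply(candidates, edge_vec)
  keep <- !vapply(evs, is.null, logical(1))
  candidates <- candidates[keep]; evs <- evs[keep]
  key <- vapply(evs, function(e) paste(which(e), collapse = ","), character(1))
  dup <- duplicated(key)
  candidates <- candidates[!dup]; evs <- evs[!dup]
  ord <- order(lengths(candidates))
  candidates <- candidates[ord]; evs <- evs[ord]
  # greedy GF(2) independence (Gaussian elimination)
  basis <- list(); rings <- list()
  pivots <- integer(0)
  for (k in seq_along(candidates)) {
    v2 <- evs[[k]]
    for (t in seq_along(basis)) {
      if (v2[pivots[t]]) v2 <- xor(v2, basis[[t]])
    }
    if (any(v2)) {
      basis[[length(basis) + 1L]] <- v2
      pivots <- c(pivots, which(v2)[1L])
      rings[[length(rings) + 1L]] <- candidates[[k]]
      if (length(rings) == n_rings) break
    }
  }
  rings
}

# Serialize chem structures to a V2000 MOL block (coordinates zero; implicit
# hydrogens are left to the reader's default valence model).
mol_block <- function(chem, title = "") {
  n <- length(chem$els)
  m <- nrow(chem$bonds)
  lines <- c(
    title, "", " molevolve",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, ATOM_SYMBOLS[chem$els + 1L])
  )
  if (m > 0L)
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              chem$bonds[, 1L], chem$bonds[, 2L],
                              chem$bonds[, 3L]))
  c(lines, "M  END", "$$$$")
}
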