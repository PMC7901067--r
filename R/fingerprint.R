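# Morgan-style (ECFP-like) circular fingerprints computed directly on the
# adjacency-matrix graph. Atom environments of radius 0..r are identified by
# iterative neighbourhood hashing with a deterministic integer hash (exact
# double arithmetic below 2^53, so bit patterns are platform-independent),
# then folded into a fixed-length bit vector.

FP_MOD <- 2147483647  # 2^31 - 1

hash_combine <- function(ints) {
  h <- 1000003
  for (x in ints) h <- (h * 69069 + x + 1) %% FP_MOD
  h
}

# Unfolded environment identifiers with counts; used by both the folded
# fingerprint and the synthetic-accessibility fragment score.
morgan_environments <- function(chem, radius = 2L) {
  n <- length(chem$els)
  bonds <- chem$bonds
  order_of <- matrix(0L, n, n)
  if (nrow(bonds) > 0L) {
    order_of[bonds[, 1:2, drop = FALSE]] <- bonds[, 3L]
    order_of[bonds[, c(2L, 1L), drop = FALSE]] <- bonds[, 3L]
  }
  adj <- lapply(seq_len(n), function(a) which(order_of[a, ] > 0L))
  # radius-0 invariant: element, heavy degree, implicit H, total bond order
  ids <- vapply(seq_len(n), function(a)
    hash_combine(c(chem$els[a], chem$deg[a], chem$nH[a],
                   sum(order_of[a, ]))), numeric(1))
  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- numeric(n)
    for (a in seq_len(n)) {
      nb <- adj[[a]]
      if (length(nb) == 0L) { new_ids[a] <- hash_combine(c(r, ids[a])); next }
      pairs <- cbind(order_of[a, nb], ids[nb])
      pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
      new_ids[a] <- hash_combine(c(r, ids[a], t(pairs)))
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  all_ids
}

#' Morgan-style circular fingerprint
#'
#' Computes an ECFP-like bit-vector fingerprint of a molecular graph by
#' iterative neighbourhood hashing. Stored sparsely as the sorted indices of
#' set bits.
#'
#' @param g a \code{\link{mol_graph}}, or a SMILES string (encoded first).
#' @param radius neighbourhood radius (default 2, the ECFP4 convention).
#' @param nbits folded fingerprint length (default 2048).
#' @return Object of class \code{morgan_fp}: integer vector of set bit
#'   positions (1-based) with attributes \code{nbits} and \code{radius}.
#' @export
morgan_fingerprint <- function(g, radius = 2L, nbits = 2048L) {
  if (is.character(g)) g <- encode_molecule(g, max_atoms = 64L)
  chem <- mol_chem(g)
  if (!chem$ok)
    condition_stop("molevolve_metric_error", "invalid molecule")
  ids <- morgan_environments(chem, radius)
  bits <- sort(unique(as.integer(ids %% nbits) + 1L))
  structure(bits, nbits = as.integer(nbits), radius = as.integer(radius),
            class = "morgan_fp")
}

#' Tanimoto distance between fingerprints
#'
#' \code{1 - |a & b| / |a | b|}; two all-zero fingerprints have distance 0.
#'
#' @param a,b \code{morgan_fp} objects of equal length.
#' @return Distance in \eqn{[0, 1]}.
#' @export
tanimoto_distance <- function(a, b) {
  if (!identical(attr(a, "nbits"), attr(b, "nbits")))
    condition_stop("molevolve_metric_error", "fingerprint length mismatch")
  u <- length(union(a, b))
  if (u == 0L) return(0)
  1 - length(intersect(a, b)) / u
}

#' Nearest reference molecule by Tanimoto distance
#'
#' Scans a reference set for the molecule closest to \code{m} in fingerprint
#' space; ties are broken by first occurrence.
#'
#' @param m a \code{morgan_fp}, \code{mol_graph} or SMILES string.
#' @param reference a list of the same kinds of objects (non-empty).
#' @param radius,nbits fingerprint parameters used where inputs still need
#'   fingerprinting.
#' @return List with \code{index}, \code{distance} and the matching
#'   \code{reference} element.
#' @export
nearest_neighbor <- function(m, reference, radius = 2L, nbits = 2048L) {
  if (length(reference) == 0L)
    condition_stop("molevolve_metric_error", "empty reference set")
  as_fp <- function(x)
    if (inherits(x, "morgan_fp")) x else morgan_fingerprint(x, radius, nbits)
  fm <- as_fp(m)
  d <- vapply(reference, function(r) tanimoto_distance(fm, as_fp(r)),
              numeric(1))
  i <- which.min(d)
  list(index = i, distance = d[i], reference = reference[[i]])
}
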