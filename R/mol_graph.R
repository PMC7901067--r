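# Atom and bond vocabularies. Codes are fixed package-wide: the diagonal of a
# molecular graph holds atom-type codes, the off-diagonal bond-order codes.
ATOM_CODES <- c(NONE = 0L, C = 1L, N = 2L, O = 3L, F = 4L)
BOND_CODES <- c(NOBOND = 0L, SINGLE = 1L, DOUBLE = 2L, TRIPLE = 3L)
ATOM_SYMBOLS <- c("NONE", "C", "N", "O", "F")
# neutral default valences; implicit hydrogens fill the remainder
ATOM_VALENCE <- c(C = 4L, N = 3L, O = 2L, F = 1L)
ATOM_MASS <- c(C = 12.011, N = 14.007, O = 15.999, F = 18.998)
H_MASS <- 1.008
N_ATOM_TYPES <- 5L
N_BOND_TYPES <- 4L

#' Molecular graph as a categorical adjacency matrix
#'
#' A molecule is stored as a square integer matrix of edge length
#' \code{max_atoms}: diagonal entries are atom-type codes (0 = empty slot,
#' 1 = C, 2 = N, 3 = O, 4 = F), off-diagonal entries are bond-order codes
#' (0 = no bond, 1..3 = single/double/triple). The matrix is symmetric;
#' hydrogens are implicit. Slots whose diagonal code is 0 are padding and
#' carry no chemical meaning.
#'
#' @param mat square integer matrix with valid atom codes on the diagonal
#'   and valid bond codes off-diagonal.
#' @return An object of class \code{mol_graph}.
#' @examples
#' m <- diag(0L, 3)
#' m[1, 1] <- 1L  # a single carbon: methane
#' g <- mol_graph(m)
#' decode_graph(g)
#' @export
mol_graph <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("mol_graph: 'mat' must be a square matrix", call. = FALSE)
  storage.mode(mat) <- "integer"
  d <- diag(mat)
  off <- mat[row(mat) != col(mat)]
  if (anyNA(mat))
    stop("mol_graph: NA entries", call. = FALSE)
  if (any(d < 0L | d >= N_ATOM_TYPES))
    stop("mol_graph: diagonal atom codes must be in 0..4", call. = FALSE)
  if (any(off < 0L | off >= N_BOND_TYPES))
    stop("mol_graph: off-diagonal bond codes must be in 0..3", call. = FALSE)
  if (!identical(mat, t(mat)))
    stop("mol_graph: matrix must be symmetric", call. = FALSE)
  structure(mat, class = "mol_graph")
}

is_mol_graph <- function(x) inherits(x, "mol_graph")

#' @export
print.mol_graph <- function(x, ...) {
  L <- nrow(x)
  active <- which(diag(x) != 0L)
  cat(sprintf("<mol_graph> %d slots, %d atoms (%s)\n", L, length(active),
              paste(ATOM_SYMBOLS[diag(x)[active] + 1L], collapse = "")))
  print(unclass(x))
  invisible(x)
}

# ---- one-hot layout ---------------------------------------------------------
# The discriminator input / generator output is a flat numeric vector:
# max_atoms blocks of 5 atom-type channels (one per diagonal cell), followed
# by one 4-channel bond block per unordered atom pair (i < j), pairs ordered
# (1,2),(1,3),...,(1,L),(2,3),... Each unordered pair owns a single block, so
# a discretized matrix is symmetric by construction.

layout_pairs <- local({
  cache <- new.env(parent = emptyenv())
  function(L) {
    key <- as.character(L)
    if (!is.null(cache[[key]])) return(cache[[key]])
    idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    cache[[key]] <- idx
    idx
  }
})

#' Length of the flattened one-hot encoding
#'
#' @param max_atoms matrix edge length.
#' @return Integer: \code{5 * max_atoms + 4 * choose(max_atoms, 2)}.
#' @examples
#' layout_length(9)  # 189
#' @export
layout_length <- function(max_atoms) {
  max_atoms <- as.integer(max_atoms)
  if (max_atoms < 1L) stop("max_atoms must be >= 1", call. = FALSE)
  N_ATOM_TYPES * max_atoms +
    N_BOND_TYPES * ((max_atoms * (max_atoms - 1L)) %/% 2L)
}

#' One-hot encoding of a molecular graph
#'
#' Expands each diagonal cell into 5 atom-type channels and each unordered
#' off-diagonal pair into 4 bond-order channels, flattened into one numeric
#' vector (the discriminator's input layout). Exactly one channel per cell is
#' active; the per-cell argmax recovers the graph exactly.
#'
#' @param g a \code{\link{mol_graph}}.
#' @return Numeric 0/1 vector of length \code{layout_length(nrow(g))}.
#' @export
to_one_hot <- function(g) {
  if (!is_mol_graph(g)) stop("to_one_hot: not a mol_graph", call. = FALSE)
  L <- nrow(g)
  pairs <- layout_pairs(L)
  out <- numeric(layout_length(L))
  out[(seq_len(L) - 1L) * N_ATOM_TYPES + diag(g) + 1L] <- 1
  bond <- g[pairs]
  out[N_ATOM_TYPES * L + (seq_len(nrow(pairs)) - 1L) * N_BOND_TYPES +
        bond + 1L] <- 1
  out
}

# One-hot encode a list of graphs into an n x layout matrix (training cache).
one_hot_matrix <- function(graphs, max_atoms) {
  if (length(graphs) == 0L)
    return(matrix(0, 0L, if (max_atoms >= 1L) layout_length(max_atoms)
                  else 0L))
  out <- matrix(0, nrow = length(graphs), ncol = layout_length(max_atoms))
  for (i in seq_along(graphs)) out[i, ] <- to_one_hot(graphs[[i]])
  out
}

#' Discretize raw generator output into molecular graphs
#'
#' Applies a per-cell argmax over each cell's channel block of the one-hot
#' layout. Ties are broken toward the lowest channel index, so the result is
#' deterministic; symmetry holds by construction because each unordered atom
#' pair owns a single channel block.
#'
#' @param raw numeric vector of length \code{layout_length(max_atoms)}, or a
#'   matrix with one such row per sample.
#' @param max_atoms matrix edge length of the target graphs.
#' @return A \code{\link{mol_graph}} (vector input) or a list of them
#'   (matrix input).
#' @export
discretize <- function(raw, max_atoms) {
  single <- !is.matrix(raw)
  if (single) raw <- matrix(raw, nrow = 1L)
  if (!all(is.finite(raw)))
    stop("discretize: raw output must be finite", call. = FALSE)
  L <- as.integer(max_atoms)
  if (ncol(raw) != layout_length(L))
    stop(sprintf("discretize: expected length %d, got %d",
                 layout_length(L), ncol(raw)), call. = FALSE)
  n <- nrow(raw)
  pairs <- layout_pairs(L)
  npair <- nrow(pairs)
  ch <- to_chunks(raw, L)
  atom <- matrix(max.col(ch$atoms, ties.method = "first") - 1L, n, L)
  bond <- if (npair > 0L)
    matrix(max.col(ch$bonds, ties.method = "first") - 1L, n, npair)
  else matrix(0L, n, 0L)
  res <- vector("list", n)
  for (s in seq_len(n)) {
    m <- matrix(0L, L, L)
    diag(m) <- atom[s, ]
    m[pairs] <- bond[s, ]
    m[pairs[, c(2L, 1L), drop = FALSE]] <- bond[s, ]
    res[[s]] <- structure(m, class = "mol_graph")
  }
  if (single) res[[1L]] else res
}
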