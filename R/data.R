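# Training-set construction: SMILES file loaders with the element /
# atom-count filters used for QM9- and ZINC-style data, prefix splicing of
# two sources into one population, and a download-free fixture generator
# that rejection-samples random valid molecular graphs.

#' Load and filter a SMILES file
#'
#' Reads one SMILES per line, or a delimited file with a header containing a
#' \code{smiles} column (auto-detected; comma, semicolon or tab). Each
#' molecule is parsed and sanitized; failures are dropped silently, then the
#' element and heavy-atom-count filters are applied in file order and the
#' result truncated to \code{take_first}.
#'
#' @param path file path.
#' @param max_atoms matrix edge length for the encoded graphs (also the
#'   upper atom-count filter unless \code{max_filter_atoms} is smaller).
#' @param elements allowed heavy-atom elements, a subset of C, N, O, F.
#' @param min_atoms,max_filter_atoms heavy-atom count range to keep
#'   (defaults: 1 and \code{max_atoms}); the 10-20 atom ZINC-style filter is
#'   \code{min_atoms = 10, max_filter_atoms = 20}.
#' @param take_first keep at most this many molecules after filtering.
#' @return A \code{molecule_set} of canonical SMILES and graphs, in file
#'   order.
#' @export
load_smiles_file <- function(path, max_atoms, elements = c("C", "N", "O", "F"),
                             min_atoms = 1L, max_filter_atoms = max_atoms,
                             take_first = Inf) {
  if (!file.exists(path))
    condition_stop("molevolve_io_error", sprintf("cannot read '%s'", path))
  stopifnot(all(elements %in% c("C", "N", "O", "F")), take_first >= 1)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  smiles <- smiles_column(lines)
  enc <- encode_molecules(smiles, max_atoms)
  keep <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    g <- enc$graphs[[i]]
    if (is.null(g)) {
      # molecules that are fine chemically but exceed max_atoms may still
      # fail only the matrix size; they are dropped either way
      next
    }
    chem <- mol_chem(g)
    syms <- ATOM_SYMBOLS[chem$els + 1L]
    n <- length(syms)
    keep[i] <- all(syms %in% elements) &&
      n >= min_atoms && n <= min(max_filter_atoms, max_atoms)
  }
  idx <- which(keep)
  if (is.finite(take_first)) idx <- utils::head(idx, take_first)
  if (length(idx) == 0L)
    condition_stop("molevolve_empty_dataset_error",
                   sprintf("no molecules in '%s' pass the filters", path))
  molecule_set(enc$smiles[idx], enc$graphs[idx], max_atoms = max_atoms)
}

# Pull the SMILES column out of raw lines: delimited-with-header files are
# detected by a 'smiles' field in the first line.
smiles_column <- function(lines) {
  first <- lines[1L]
  for (sep in c(",", ";", "\t")) {
    header <- tolower(trimws(strsplit(first, sep, fixed = TRUE)[[1L]]))
    col <- match("smiles", header)
    if (!is.na(col) && length(header) >= 1L) {
      rows <- strsplit(lines[-1L], sep, fixed = TRUE)
      return(vapply(rows, function(r)
        if (length(r) >= col) trimws(r[[col]]) else NA_character_,
        character(1)))
    }
  }
  # plain SMILES lines (optionally with a trailing title)
  vapply(strsplit(trimws(lines), "[[:space:]]+"), `[[`, character(1), 1L)
}

#' Splice two molecule sources into one training set
#'
#' Takes the first \code{capacity} records of the primary source and
#' overwrites its first \code{n_second} entries with the first
#' \code{n_second} records of the secondary source (the QM9 + ZINC mixing
#' scheme), preserving order.
#'
#' @param primary,secondary \code{molecule_set} objects with equal
#'   \code{max_atoms}.
#' @param capacity total population size.
#' @param n_second number of leading entries taken from \code{secondary}.
#' @return A \code{molecule_set} of length \code{capacity}.
#' @export
build_mixed_dataset <- function(primary, secondary, capacity,
                                n_second = length(secondary)) {
  capacity <- as.integer(capacity); n_second <- as.integer(n_second)
  if (length(primary) < capacity)
    stop("build_mixed_dataset: primary source too small", call. = FALSE)
  if (length(secondary) < n_second)
    stop("build_mixed_dataset: secondary source too small", call. = FALSE)
  if (n_second > capacity)
    stop("build_mixed_dataset: n_second exceeds capacity", call. = FALSE)
  if (n_second > 0L && primary$max_atoms != secondary$max_atoms)
    stop("build_mixed_dataset: max_atoms mismatch", call. = FALSE)
  out <- subset_molecule_set(primary, seq_len(capacity))
  if (n_second > 0L) {
    idx <- seq_len(n_second)
    out$smiles[idx] <- secondary$smiles[idx]
    out$graphs[idx] <- secondary$graphs[idx]
    out$onehot[idx, ] <- secondary$onehot[idx, , drop = FALSE]
  }
  out
}

#' Generate fixture molecules
#'
#' Download-free stand-in for a QM9-like training set: random molecular
#' graphs (QM9-like element frequencies, random spanning tree plus
#' occasional ring-closing edges, mostly single bonds) are rejection-sampled
#' through the package's sanitization gate, canonicalized and deduplicated
#' until \code{n} distinct valid molecules are collected. Deterministic
#' given \code{seed}.
#'
#' @param n number of distinct molecules.
#' @param max_atoms heavy-atom budget per molecule (matrix edge length).
#' @param elements allowed elements (subset of C, N, O, F).
#' @param seed integer seed.
#' @return A \code{molecule_set} of length \code{n}.
#' @export
generate_fixture_molecules <- function(n, max_atoms = 9L,
                                       elements = c("C", "N", "O", "F"),
                                       seed = 1L) {
  stopifnot(n >= 1L, max_atoms >= 1L, all(elements %in% c("C", "N", "O", "F")))
  max_atoms <- as.integer(max_atoms)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  wts <- c(C = 0.70, N = 0.12, O = 0.16, F = 0.02)[elements]
  wts <- wts / sum(wts)
  smiles <- character(0)
  graphs <- list()
  attempts <- 0L
  max_attempts <- 400L * n + 4000L
  batch <- max(256L, min(4L * n, 5000L))
  while (length(smiles) < n && attempts < max_attempts) {
    cand <- vector("list", batch)
    for (b in seq_len(batch)) cand[[b]] <- random_graph(max_atoms, elements, wts)
    attempts <- attempts + batch
    decoded <- decode_graphs(cand)
    ok <- which(decoded$valid & !is.na(decoded$smiles))
    ok <- ok[!duplicated(decoded$smiles[ok])]
    new <- ok[!decoded$smiles[ok] %in% smiles]
    smiles <- c(smiles, decoded$smiles[new])
    graphs <- c(graphs, cand[new])
  }
  if (length(smiles) < n)
    condition_stop("molevolve_fixture_exhausted_error",
                   sprintf(paste0("only %d distinct valid molecules found ",
                                  "in %d attempts; relax max_atoms/elements"),
                           length(smiles), attempts))
  molecule_set(smiles[seq_len(n)], graphs[seq_len(n)], max_atoms = max_atoms)
}

# One random candidate graph: random size (skewed towards the atom budget),
# elements by QM9-like frequency, a random spanning tree for connectivity
# and a few extra ring-closing edges; bond orders mostly single.
random_graph <- function(max_atoms, elements, wts) {
  lo <- min(4L, max_atoms)
  sizes <- seq.int(lo, max_atoms)
  nh <- if (length(sizes) == 1L) sizes else
    sample(sizes, 1L, prob = sizes^1.5)
  els <- sample(elements, nh, replace = TRUE, prob = wts)
  m <- matrix(0L, max_atoms, max_atoms)
  diag(m)[seq_len(nh)] <- ATOM_CODES[els]
  if (nh > 1L) {
    ord <- sample.int(nh)
    for (t in 2L:nh) {
      a <- ord[t]; b <- ord[sample.int(t - 1L, 1L)]
      o <- sample(1:3, 1L, prob = c(0.75, 0.2, 0.05))
      m[a, b] <- m[b, a] <- o
    }
    extra <- stats::rbinom(1L, 2L, 0.35)
    for (e in seq_len(extra)) {
      ab <- sample.int(nh, 2L)
      if (m[ab[1L], ab[2L]] == 0L) {
        o <- sample(1:2, 1L, prob = c(0.8, 0.2))
        m[ab[1L], ab[2L]] <- m[ab[2L], ab[1L]] <- o
      }
    }
  }
  structure(m, class = "mol_graph")
}
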