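# Molecular scoring panel: drug-likeness (QED), synthesizability (Ertl-style
# SA, normalized), solubility (clipped Crippen logP) and the descriptor set
# used in downstream analyses. A `mol_scorer` bundles the score configuration
# (fingerprint parameters and the SA fragment calibration) so every score in
# a run is computed under one fixed convention.

#' Create a molecular scorer
#'
#' Bundles the scoring configuration: the synthetic-accessibility fragment
#' calibration (see \code{\link{sa_calibrate}}) and fingerprint parameters.
#' Scores produced by one scorer are directly comparable; the calibration
#' reference is typically the initial training population of a run.
#'
#' @param reference list of \code{\link{mol_graph}} objects used to calibrate
#'   the SA fragment table; \code{NULL} uses a built-in fixture corpus of 300
#'   small C/N/O/F molecules.
#' @param radius,nbits Morgan fingerprint parameters (defaults 2 and 2048).
#' @return An object of class \code{mol_scorer}.
#' @export
make_scorer <- function(reference = NULL, radius = 2L, nbits = 2048L) {
  if (is.null(reference)) {
    fx <- generate_fixture_molecules(300L, max_atoms = 9L, seed = 104729L)
    reference <- fx$graphs
  }
  structure(list(sa_table = sa_calibrate(reference, radius = radius),
                 radius = as.integer(radius), nbits = as.integer(nbits)),
            class = "mol_scorer")
}

#' @export
print.mol_scorer <- function(x, ...) {
  cat(sprintf("<mol_scorer> radius %d, %d bits; ", x$radius, x$nbits))
  print(x$sa_table)
  invisible(x)
}

default_scorer <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- make_scorer()
    cached
  }
})

# Batch scoring core. `graphs` is a list of mol_graphs; `decoded` an optional
# precomputed decode_graphs() result aligned with it. Returns a data.frame
# with one row per graph (NA rows for invalid molecules).
score_graphs <- function(graphs, scorer = NULL, decoded = NULL) {
  if (length(graphs) > 0L && is.null(scorer)) scorer <- default_scorer()
  if (is.null(decoded)) decoded <- decode_graphs(graphs)
  n <- length(graphs)
  if (n == 0L)
    return(data.frame(smiles = character(0), qed = numeric(0),
                      sa = numeric(0), solubility = numeric(0),
                      logp = numeric(0), tpsa = numeric(0),
                      mw = numeric(0), hba = integer(0), hbd = integer(0),
                      n_rotatable = integer(0),
                      n_aromatic_rings = integer(0), n_alerts = integer(0),
                      n_atoms = integer(0), n_rings = integer(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(smiles = decoded$smiles,
                    qed = NA_real_, sa = NA_real_, solubility = NA_real_,
                    logp = decoded$logp, tpsa = decoded$tpsa,
                    mw = NA_real_, hba = NA_integer_, hbd = NA_integer_,
                    n_rotatable = NA_integer_, n_aromatic_rings = NA_integer_,
                    n_alerts = NA_integer_, n_atoms = NA_integer_,
                    n_rings = NA_integer_, stringsAsFactors = FALSE)
  for (i in which(decoded$valid)) {
    chem <- mol_chem(graphs[[i]])
    panel <- descriptor_panel(chem, logp = decoded$logp[i],
                              tpsa = decoded$tpsa[i])
    out$qed[i] <- qed_from_panel(panel)
    out$sa[i] <- sa_normalized(chem, panel$ctx, scorer$sa_table)
    out$solubility[i] <- solubility_score(decoded$logp[i])
    out$mw[i] <- panel$mw
    out$hba[i] <- panel$hba
    out$hbd[i] <- panel$hbd
    out$n_rotatable[i] <- panel$n_rotatable
    out$n_aromatic_rings[i] <- panel$n_aromatic_rings
    out$n_alerts[i] <- panel$n_alerts
    out$n_atoms[i] <- panel$n_atoms
    out$n_rings[i] <- panel$n_rings
  }
  out
}

#' Score panel for one molecule
#'
#' Computes drug-likeness (QED, in \eqn{[0,1]}), normalized synthesizability
#' (higher = easier), solubility (rescaled Crippen logP), and the descriptor
#' panel (raw logP, TPSA, rotatable bonds, ring statistics, atom fractions).
#'
#' @param smiles a valid SMILES string (or a \code{\link{mol_graph}}).
#' @param scorer optional \code{\link{make_scorer}} object.
#' @param max_atoms matrix size used when encoding a SMILES input.
#' @return A list with components \code{qed}, \code{sa}, \code{solubility},
#'   \code{raw_logp}, \code{tpsa}, \code{n_rotatable}, \code{n_atoms},
#'   \code{n_rings}, \code{ring_sizes}, \code{atom_fractions} and the
#'   remaining descriptors.
#' @examples
#' \dontrun{score_panel("CCO")$qed}
#' @export
score_panel <- function(smiles, scorer = NULL, max_atoms = 64L) {
  g <- if (is_mol_graph(smiles)) smiles else
    tryCatch(encode_molecule(smiles, max_atoms),
             molevolve_encoding_error = function(e)
               condition_stop("molevolve_metric_error", conditionMessage(e)))
  chem <- mol_chem(g)
  if (!chem$ok)
    condition_stop("molevolve_metric_error", "invalid molecule")
  row <- score_graphs(list(g), scorer)
  if (!is.finite(row$qed[1L]))
    condition_stop("molevolve_metric_error", "scoring failed")
  panel <- descriptor_panel(chem, logp = row$logp[1L], tpsa = row$tpsa[1L])
  list(qed = row$qed[1L], sa = row$sa[1L], solubility = row$solubility[1L],
       raw_logp = row$logp[1L], tpsa = row$tpsa[1L],
       n_rotatable = panel$n_rotatable, n_atoms = panel$n_atoms,
       n_rings = panel$n_rings, ring_sizes = panel$ring_sizes,
       atom_fractions = panel$atom_fractions,
       mw = panel$mw, hba = panel$hba, hbd = panel$hbd,
       n_aromatic_rings = panel$n_aromatic_rings,
       n_alerts = panel$n_alerts, smiles = row$smiles[1L])
}

metric_column <- function(metric) {
  metric <- match.arg(metric, c("qed", "drug", "sa", "solubility"))
  if (metric == "drug") "qed" else metric
}

#' Count molecules above a score threshold
#'
#' A molecule is a top performer when its score is strictly above the
#' threshold (default 0.6 for drug-likeness).
#'
#' @param records a data.frame of scored molecules (e.g. the \code{produced}
#'   table of a fit) or a numeric vector of scores.
#' @param metric metric column: \code{"qed"} (alias \code{"drug"}),
#'   \code{"sa"} or \code{"solubility"}.
#' @param threshold strict lower bound (default 0.6).
#' @return Integer count.
#' @export
count_top_performers <- function(records, metric = "qed", threshold = 0.6) {
  x <- if (is.numeric(records)) records else records[[metric_column(metric)]]
  sum(x > threshold, na.rm = TRUE)
}

#' Histogram counts of a molecular score
#'
#' Bins are left-closed, right-open; the final bin is closed on both sides.
#' Values outside the bin range are dropped.
#'
#' @param records scored data.frame or numeric vector.
#' @param metric metric column (ignored for numeric input).
#' @param breaks strictly increasing bin edges.
#' @return Named integer vector of per-bin counts.
#' @export
score_histogram <- function(records, metric = "qed", breaks) {
  if (any(diff(breaks) <= 0))
    stop("score_histogram: bin edges must be strictly increasing",
         call. = FALSE)
  x <- if (is.numeric(records)) records else records[[metric_column(metric)]]
  x <- x[!is.na(x)]
  bin <- findInterval(x, breaks, rightmost.closed = TRUE)
  bin[x < breaks[1L] | x > breaks[length(breaks)]] <- 0L
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  names(counts) <- paste0("[", utils::head(breaks, -1L), ",",
                          utils::tail(breaks, -1L),
                          c(rep(")", length(breaks) - 2L), "]"))
  counts
}
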