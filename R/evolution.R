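# The evolutionary layer: the GAN's training data is treated as the
# population of a genetic algorithm. Valid, never-seen-before generated
# molecules become candidates; between training intervals they replace
# population entries either at random or only when they beat the weakest
# incumbents on a metric; optionally candidates are first recombined with
# population members by adjacency-matrix slice crossover.

# ---- molecule sets ----------------------------------------------------------

# A molecule_set holds parallel columns: canonical SMILES, graphs, cached
# one-hot encodings (rows) and a score table. It is the common currency of
# the loaders, the filter and the population.
molecule_set <- function(smiles, graphs, onehot = NULL, scores = NULL,
                         max_atoms = NULL) {
  if (is.null(max_atoms))
    max_atoms <- if (length(graphs) > 0L) nrow(graphs[[1L]]) else 0L
  if (is.null(onehot)) onehot <- one_hot_matrix(graphs, max_atoms)
  structure(list(smiles = as.character(smiles), graphs = graphs,
                 onehot = onehot, scores = scores,
                 max_atoms = as.integer(max_atoms)),
            class = "molecule_set")
}

#' @export
length.molecule_set <- function(x) length(x$smiles)

#' @export
print.molecule_set <- function(x, ...) {
  cat(sprintf("<molecule_set> %d molecules (max_atoms %d)\n",
              length(x), x$max_atoms))
  if (length(x) > 0L)
    cat(" ", paste(utils::head(x$smiles, 5L), collapse = " "),
        if (length(x) > 5L) "..." else "", "\n")
  invisible(x)
}

subset_molecule_set <- function(x, idx) {
  molecule_set(x$smiles[idx], x$graphs[idx],
               x$onehot[idx, , drop = FALSE],
               if (!is.null(x$scores)) x$scores[idx, , drop = FALSE],
               x$max_atoms)
}

concat_molecule_sets <- function(sets) {
  sets <- Filter(function(s) length(s) > 0L, sets)
  if (length(sets) == 0L) return(NULL)
  molecule_set(unlist(lapply(sets, `[[`, "smiles")),
               do.call(c, lapply(sets, `[[`, "graphs")),
               do.call(rbind, lapply(sets, `[[`, "onehot")),
               do.call(rbind, lapply(sets, `[[`, "scores")),
               sets[[1L]]$max_atoms)
}

#' Training population
#'
#' A fixed-capacity ordered molecule collection: replacement operators
#' overwrite entries one-for-one, so the size never changes after
#' construction. Scores are intrinsic to each molecule and computed once at
#' insertion.
#'
#' @param records a \code{molecule_set} (e.g. from
#'   \code{\link{generate_fixture_molecules}} or
#'   \code{\link{load_smiles_file}}).
#' @param capacity population size; the first \code{capacity} records are
#'   used (default: all records).
#' @param scorer a \code{\link{make_scorer}} object used to score members;
#'   \code{NULL} calibrates a scorer on the records themselves.
#' @return An object of class \code{training_population} (also a
#'   \code{molecule_set}).
#' @export
training_population <- function(records, capacity = length(records),
                                scorer = NULL) {
  capacity <- as.integer(capacity)
  if (length(records) < capacity)
    stop(sprintf("training_population: need >= %d records, have %d",
                 capacity, length(records)), call. = FALSE)
  pop <- subset_molecule_set(records, seq_len(capacity))
  if (is.null(scorer)) scorer <- make_scorer(pop$graphs)
  if (is.null(pop$scores))
    pop$scores <- score_graphs(pop$graphs, scorer)
  pop$capacity <- capacity
  class(pop) <- c("training_population", "molecule_set")
  attr(pop, "scorer") <- scorer
  pop
}

#' @export
print.training_population <- function(x, ...) {
  cat(sprintf("<training_population> capacity %d (max_atoms %d)\n",
              x$capacity, x$max_atoms))
  if (!is.null(x$scores))
    cat(sprintf("  mean qed %.3f  sa %.3f  solubility %.3f\n",
                mean(x$scores$qed, na.rm = TRUE),
                mean(x$scores$sa, na.rm = TRUE),
                mean(x$scores$solubility, na.rm = TRUE)))
  invisible(x)
}

# ---- novelty ledger ---------------------------------------------------------

#' Novelty ledger
#'
#' Tracks every canonical SMILES seen so far: the original training set plus
#' everything the generator has produced. A generated molecule is novel only
#' if its canonical SMILES has never appeared in either. The ledger has
#' reference semantics (an environment), so filtering updates it in place.
#'
#' @param initial character vector of canonical SMILES forming the reference
#'   set (typically the original training data).
#' @return An object of class \code{novelty_ledger}.
#' @export
novelty_ledger <- function(initial = character(0)) {
  seen <- new.env(parent = emptyenv(), hash = TRUE,
                  size = max(1024L, 2L * length(initial)))
  for (s in unique(initial)) assign(s, TRUE, envir = seen)
  led <- new.env(parent = emptyenv())
  led$seen <- seen
  led$n_initial <- length(unique(initial))
  led$cumulative_new <- 0L
  led$per_interval_new <- integer(0)
  led$open_count <- 0L
  class(led) <- "novelty_ledger"
  led
}

ledger_contains <- function(ledger, smiles) {
  vapply(smiles, function(s) !is.null(get0(s, envir = ledger$seen,
                                           inherits = FALSE)), logical(1),
         USE.NAMES = FALSE)
}

ledger_insert <- function(ledger, smiles) {
  for (s in smiles) assign(s, TRUE, envir = ledger$seen)
  ledger$cumulative_new <- ledger$cumulative_new + length(smiles)
  ledger$open_count <- ledger$open_count + length(smiles)
  invisible(ledger)
}

# close the running interval: push the count of novel molecules seen since
# the last close onto per_interval_new
ledger_mark_interval <- function(ledger) {
  ledger$per_interval_new <- c(ledger$per_interval_new, ledger$open_count)
  ledger$open_count <- 0L
  invisible(ledger)
}

#' @export
print.novelty_ledger <- function(x, ...) {
  cat(sprintf(
    "<novelty_ledger> %d reference + %d produced molecules (%d intervals)\n",
    x$n_initial, x$cumulative_new, length(x$per_interval_new)))
  invisible(x)
}

# ---- filtering --------------------------------------------------------------

#' Keep valid, novel generated molecules
#'
#' Decodes each generated graph, drops invalid ones, canonicalizes, drops
#' molecules whose canonical SMILES is already in the ledger, deduplicates
#' within the batch, registers the survivors in the ledger and returns them
#' scored.
#'
#' @param graphs list of \code{\link{mol_graph}} objects (generator output).
#' @param ledger a \code{\link{novelty_ledger}}; updated in place.
#' @param scorer optional \code{\link{make_scorer}} object.
#' @return A \code{molecule_set} of the scored survivors (possibly empty).
#' @export
filter_valid_novel <- function(graphs, ledger, scorer = NULL) {
  empty_set <- function(L) {
    out <- molecule_set(character(0), list(), max_atoms = L)
    out$scores <- score_graphs(list(), scorer)
    out
  }
  if (length(graphs) == 0L) return(empty_set(0L))
  decoded <- decode_graphs(graphs)
  n_valid <- sum(decoded$valid)
  keep <- which(decoded$valid & !is.na(decoded$smiles))
  if (length(keep) > 0L) {
    smi <- decoded$smiles[keep]
    keep <- keep[!duplicated(smi)]
    keep <- keep[!ledger_contains(ledger, decoded$smiles[keep])]
  }
  if (length(keep) == 0L) {
    out <- empty_set(nrow(graphs[[1L]]))
    attr(out, "n_valid") <- n_valid
    return(out)
  }
  ledger_insert(ledger, decoded$smiles[keep])
  scores <- score_graphs(graphs[keep], scorer,
                         decoded = decoded[keep, , drop = FALSE])
  out <- molecule_set(decoded$smiles[keep], graphs[keep],
                      max_atoms = nrow(graphs[[1L]]))
  out$scores <- scores
  attr(out, "n_valid") <- n_valid
  out
}

# ---- replacement ------------------------------------------------------------

#' Random replacement of training data
#'
#' Each candidate overwrites a uniformly chosen population slot; when two
#' candidates hit the same slot the later write wins, so the number of new
#' entries can be smaller than the number of candidates. Capacity never
#' changes.
#'
#' @param pop a \code{\link{training_population}}.
#' @param candidates a \code{molecule_set} of scored candidates.
#' @return The updated population, with attribute \code{n_replaced} (number
#'   of slots that received a candidate).
#' @export
replace_random <- function(pop, candidates) {
  n <- length(candidates)
  if (n == 0L) {
    attr(pop, "n_replaced") <- 0L
    return(pop)
  }
  idx <- sample.int(pop$capacity, n, replace = TRUE)
  pop$smiles[idx] <- candidates$smiles
  pop$graphs[idx] <- candidates$graphs
  pop$onehot[idx, ] <- candidates$onehot
  pop$scores[idx, ] <- candidates$scores
  attr(pop, "n_replaced") <- length(unique(idx))
  pop
}

#' Metric-guided replacement of training data
#'
#' Population entries are sorted ascending by the metric, candidates
#' descending; the best candidate is paired with the weakest incumbent and a
#' replacement happens only when the candidate's score is strictly greater.
#' Pairing stops at the first failed comparison, so after the call the
#' population's sorted score vector is pointwise no worse than before.
#'
#' @param pop a \code{\link{training_population}} with scored members.
#' @param candidates a \code{molecule_set} of scored candidates.
#' @param metric \code{"qed"} (alias \code{"drug"}), \code{"sa"} or
#'   \code{"solubility"}.
#' @return The updated population with attribute \code{n_replaced}.
#' @export
replace_guided <- function(pop, candidates, metric = "qed") {
  col <- metric_column(metric)
  if (is.null(pop$scores[[col]]) ||
      (length(candidates) > 0L && is.null(candidates$scores[[col]])))
    condition_stop("molevolve_metric_error",
                   sprintf("missing metric scores '%s'", col))
  n <- length(candidates)
  if (n == 0L) {
    attr(pop, "n_replaced") <- 0L
    return(pop)
  }
  if (anyNA(candidates$scores[[col]]))
    condition_stop("molevolve_metric_error",
                   sprintf("missing metric scores '%s'", col))
  pop_ord <- order(pop$scores[[col]])            # weakest first
  cand_ord <- order(candidates$scores[[col]], decreasing = TRUE)
  k <- 0L
  limit <- min(n, pop$capacity)
  while (k < limit) {
    cand <- cand_ord[k + 1L]
    slot <- pop_ord[k + 1L]
    if (candidates$scores[[col]][cand] > pop$scores[[col]][slot]) k <- k + 1L
    else break
  }
  if (k > 0L) {
    slots <- pop_ord[seq_len(k)]
    cands <- cand_ord[seq_len(k)]
    pop$smiles[slots] <- candidates$smiles[cands]
    pop$graphs[slots] <- candidates$graphs[cands]
    pop$onehot[slots, ] <- candidates$onehot[cands, , drop = FALSE]
    pop$scores[slots, ] <- candidates$scores[cands, , drop = FALSE]
  }
  attr(pop, "n_replaced") <- k
  pop
}

# ---- crossover --------------------------------------------------------------

#' Adjacency-matrix slice crossover
#'
#' Copies the parent matrix and overwrites its first \code{k} rows and
#' columns with those of the generated matrix: the first \code{k} diagonal
#' (atom) entries and every bond with at least one endpoint among the first
#' \code{k} slots come from the generated molecule. Symmetry is preserved.
#'
#' @param parent,generated \code{\link{mol_graph}} objects of equal size.
#' @param k slice width, an integer in \code{1..nrow(parent)}.
#' @return A \code{\link{mol_graph}}.
#' @export
crossover <- function(parent, generated, k) {
  L <- nrow(parent)
  if (nrow(generated) != L)
    condition_stop("molevolve_size_error", "parent/generated size mismatch")
  k <- as.integer(k)
  if (k < 1L || k > L)
    condition_stop("molevolve_range_error",
                   sprintf("k must be in 1..%d", L))
  child <- unclass(parent)
  gen <- unclass(generated)
  child[seq_len(k), ] <- gen[seq_len(k), ]
  child[, seq_len(k)] <- gen[, seq_len(k)]
  structure(child, class = "mol_graph")
}

#' Draw a parent from the population
#'
#' Uniform draw, or softmax-weighted by a metric: the probability of record
#' \eqn{i} is \eqn{\exp(s_i) / \sum_j \exp(s_j)} over the raw metric scores
#' (no temperature).
#'
#' @param pop a \code{\link{training_population}}.
#' @param metric \code{NULL} for uniform, else \code{"qed"}/\code{"drug"},
#'   \code{"sa"} or \code{"solubility"}.
#' @return List with \code{index}, \code{smiles} and \code{graph} of the
#'   drawn parent.
#' @export
sample_parent <- function(pop, metric = NULL) {
  i <- sample_parent_idx(pop, metric, 1L)
  list(index = i, smiles = pop$smiles[i], graph = pop$graphs[[i]])
}

sample_parent_idx <- function(pop, metric = NULL, n = 1L) {
  if (pop$capacity == 0L)
    stop("sample_parent: empty population", call. = FALSE)
  if (is.null(metric))
    return(sample.int(pop$capacity, n, replace = TRUE))
  s <- pop$scores[[metric_column(metric)]]
  if (is.null(s) || anyNA(s))
    condition_stop("molevolve_metric_error", "missing metric scores")
  w <- exp(s - max(s))
  sample.int(pop$capacity, n, replace = TRUE, prob = w / sum(w))
}

#' Recombine a generated batch with the population
#'
#' A uniformly chosen fraction of the generated graphs is crossed with
#' freshly drawn parents (see \code{\link{sample_parent}}) at an
#' independently drawn slice width \code{k ~ Uniform(1..L)} per pair; the
#' remaining graphs pass through untouched. Output order matches input.
#'
#' @param generated list of \code{\link{mol_graph}} objects.
#' @param pop a \code{\link{training_population}}.
#' @param fraction fraction of graphs to recombine, in \eqn{[0, 1]}
#'   (default 0.5).
#' @param metric \code{NULL} for uniform parent draws, else softmax
#'   weighting by this metric.
#' @return List of \code{\link{mol_graph}} objects, same length as the
#'   input.
#' @export
recombine_batch <- function(generated, pop, fraction = 0.5, metric = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- length(generated)
  m <- as.integer(floor(fraction * n))
  if (m == 0L) return(generated)
  pick <- sample.int(n, m)
  L <- pop$max_atoms
  parents <- sample_parent_idx(pop, metric, m)
  ks <- sample.int(L, m, replace = TRUE)
  for (t in seq_len(m)) {
    generated[[pick[t]]] <- crossover(pop$graphs[[parents[t]]],
                                      generated[[pick[t]]], ks[t])
  }
  generated
}
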