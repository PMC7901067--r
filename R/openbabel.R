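# OpenBabel backend. All SMILES canonicalization and the two descriptor
# lookups that are not computed natively (Wildman-Crippen logP, Ertl TPSA) go
# through the `obabel` command-line tool, batched: one process call handles an
# arbitrary number of molecules, so per-molecule overhead is microseconds.

condition_stop <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

ob_available <- local({
  ok <- NULL
  function() {
    if (is.null(ok)) ok <<- nzchar(Sys.which("obabel"))
    ok
  }
})

# Run obabel on `input_lines`, return output lines.
ob_run <- function(input_lines, in_fmt, out_fmt, extra = character(0)) {
  if (!ob_available())
    stop("obabel executable not found on PATH", call. = FALSE)
  fin <- tempfile(fileext = paste0(".", in_fmt))
  fout <- tempfile(fileext = paste0(".", out_fmt))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(input_lines, fin)
  suppressWarnings(system2("obabel",
                           c(paste0("-i", in_fmt), shQuote(fin),
                             paste0("-o", out_fmt), "-O", shQuote(fout),
                             "-e", extra),
                           stdout = FALSE, stderr = FALSE))
  if (!file.exists(fout)) return(character(0))
  readLines(fout, warn = FALSE)
}

# Parse "SMILES<TAB>title [desc...]" output lines into a data.frame keyed by
# integer title. Molecules obabel failed on are simply absent.
ob_parse_smiles <- function(lines, n_desc = 0L) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(id = integer(0), smiles = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[[`, character(1), 1L)
  rest <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "",
                 character(1))
  fields <- strsplit(trimws(rest), "[[:space:]]+")
  id <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 1L)))
  out <- data.frame(id = id, smiles = smiles, stringsAsFactors = FALSE)
  if (n_desc > 0L) {
    for (k in seq_len(n_desc)) {
      out[[paste0("d", k)]] <- suppressWarnings(as.numeric(
        vapply(fields, function(f) if (length(f) >= k + 1L) f[[k + 1L]]
               else NA_character_, character(1))))
    }
  }
  out[!is.na(out$id), , drop = FALSE]
}

#' Canonical SMILES
#'
#' Canonicalizes SMILES strings through OpenBabel. Stereochemistry and isotope
#' labels are stripped, so two SMILES describe the same molecule here exactly
#' when their canonical forms are equal (the package-wide identity used for
#' novelty counting). Unparseable strings yield \code{NA}.
#'
#' @param smiles character vector of SMILES strings.
#' @return Character vector of canonical SMILES, \code{NA} where parsing
#'   failed.
#' @examples
#' \dontrun{canonical_smiles(c("OCC", "CCO"))  # both "CCO"}
#' @export
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  bad <- is.na(smiles) | !nzchar(trimws(smiles)) | grepl("[\t ]", smiles)
  out <- rep(NA_character_, n)
  idx <- which(!bad)
  if (length(idx) > 0L) {
    lines <- paste(smiles[idx], idx)
    # -xi strips isotope and stereo markings; identity is the constitution
    res <- ob_parse_smiles(ob_run(lines, "smi", "can", "-xi"))
    if (nrow(res) > 0L) out[res$id] <- res$smiles
  }
  out
}

# Decode a list of graphs in one pass: native sanitization, then one obabel
# call for canonical SMILES + logP + TPSA of the valid ones. Returns a
# data.frame aligned with `graphs`: valid, smiles, logp, tpsa.
decode_graphs <- function(graphs) {
  n <- length(graphs)
  if (n == 0L)
    return(data.frame(valid = logical(0), smiles = character(0),
                      logp = numeric(0), tpsa = numeric(0),
                      stringsAsFactors = FALSE))
  chems <- lapply(graphs, mol_chem)
  valid <- vapply(chems, `[[`, logical(1), "ok")
  out <- data.frame(valid = valid, smiles = NA_character_,
                    logp = NA_real_, tpsa = NA_real_,
                    stringsAsFactors = FALSE)
  idx <- which(valid)
  if (length(idx) > 0L) {
    blocks <- unlist(lapply(idx, function(i) mol_block(chems[[i]], title = i)))
    res <- ob_parse_smiles(
      ob_run(blocks, "sdf", "can", c("-xi", "--append", "logP TPSA")),
      n_desc = 2L)
    if (nrow(res) > 0L) {
      out$smiles[res$id] <- res$smiles
      out$logp[res$id] <- res$d1
      out$tpsa[res$id] <- res$d2
    }
    # a graph OpenBabel cannot serialize is not a valid molecule
    out$valid[is.na(out$smiles)] <- FALSE
  }
  out
}

#' Decode a molecular graph to canonical SMILES
#'
#' Builds a molecule from the non-empty diagonal entries and the bonds among
#' them (bonds incident to padding slots are ignored), applies the
#' sanitization rules (neutral valences, connectivity, at least one atom) and
#' returns the canonical SMILES. Graphs with no atoms, valence violations or
#' disconnected fragments are invalid; no largest-fragment rescue is applied.
#'
#' @param g a \code{\link{mol_graph}}.
#' @return Canonical SMILES string, or \code{NA_character_} for an invalid
#'   graph.
#' @export
decode_graph <- function(g) {
  if (!is_mol_graph(g)) g <- mol_graph(g)
  res <- decode_graphs(list(g))
  if (!res$valid[1L]) NA_character_ else res$smiles[1L]
}

# Parse SMILES into element codes / bond tables via OpenBabel's V2000 SDF
# output. Returns list of chem-like lists (els, bonds, charged) or NULL per
# entry, indexed by the record title.
parse_smiles_batch <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  ok <- !is.na(smiles) & nzchar(smiles)
  idx <- which(ok)
  if (length(idx) == 0L) return(out)
  lines <- paste(smiles[idx], idx)
  sdf_lines <- ob_run(lines, "smi", "sdf", character(0))
  if (length(sdf_lines) == 0L) return(out)
  ends <- which(sdf_lines == "$$$$")
  start <- 1L
  for (e in ends) {
    rec <- sdf_lines[start:(e - 1L)]
    start <- e + 1L
    p <- parse_molblock(rec)
    if (!is.null(p) && !is.na(p$id) && p$id >= 1L && p$id <= n)
      out[[p$id]] <- p
  }
  out
}

# Minimal V2000 molfile reader (fixed-width fields per the CTAB spec);
# handles the zero-bond records some general-purpose readers reject.
parse_molblock <- function(rec) {
  if (length(rec) < 4L) return(NULL)
  id <- suppressWarnings(as.integer(trimws(rec[1L])))
  na <- suppressWarnings(as.integer(substr(rec[4L], 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(rec[4L], 4L, 6L)))
  if (is.na(na) || is.na(nb) || length(rec) < 4L + na + nb) return(NULL)
  atom_lines <- rec[4L + seq_len(na)]
  els <- trimws(substr(atom_lines, 32L, 34L))
  old_chg <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  bonds <- matrix(integer(0), 0L, 3L,
                  dimnames = list(NULL, c("i", "j", "order")))
  if (nb > 0L) {
    bond_lines <- rec[4L + na + seq_len(nb)]
    bonds <- cbind(
      i = as.integer(substr(bond_lines, 1L, 3L)),
      j = as.integer(substr(bond_lines, 4L, 6L)),
      order = as.integer(substr(bond_lines, 7L, 9L)))
  }
  charged <- any(grepl("^M  CHG", rec)) ||
    any(!is.na(old_chg) & old_chg != 0L)
  list(id = id, els = els, bonds = bonds, charged = charged)
}

#' Encode a SMILES string as a molecular graph
#'
#' Parses and canonicalizes the molecule, kekulizes aromatic systems, and
#' writes atom types and bond orders into a square adjacency matrix of edge
#' length \code{max_atoms}. Atom order follows OpenBabel's canonical atom
#' ranking, so encoding is deterministic. The molecule must be neutral, fit
#' in \code{max_atoms} heavy atoms and use only C, N, O and F.
#'
#' @param smiles a SMILES string.
#' @param max_atoms matrix edge length (maximum heavy-atom count).
#' @return A \code{\link{mol_graph}}.
#' @examples
#' \dontrun{decode_graph(encode_molecule("O=C=O", 4))  # "O=C=O"}
#' @export
encode_molecule <- function(smiles, max_atoms) {
  res <- encode_molecules(smiles, max_atoms)
  if (is.null(res$graphs[[1L]]))
    condition_stop("molevolve_encoding_error",
                   sprintf("cannot encode '%s': %s", smiles, res$reason[1L]))
  res$graphs[[1L]]
}

# Vectorized encoder used by the data loaders. Returns list(graphs, smiles
# (canonical), reason). Entries that cannot be encoded have NULL graphs and a
# reason string.
encode_molecules <- function(smiles, max_atoms) {
  max_atoms <- as.integer(max_atoms)
  n <- length(smiles)
  graphs <- vector("list", n)
  reason <- rep(NA_character_, n)
  can <- canonical_smiles(smiles)
  reason[is.na(can)] <- "parse failure"
  parsed <- parse_smiles_batch(can)
  for (i in seq_len(n)) {
    if (is.na(can[i])) next
    p <- parsed[[i]]
    if (is.null(p)) { reason[i] <- "parse failure"; next }
    if (isTRUE(p$charged)) { reason[i] <- "charged species"; next }
    els <- p$els
    if (any(!els %in% c("C", "N", "O", "F"))) {
      reason[i] <- paste0("atom outside vocabulary: ",
                          paste(setdiff(unique(els), c("C", "N", "O", "F")),
                                collapse = ","))
      next
    }
    if (length(els) > max_atoms) { reason[i] <- "too many atoms"; next }
    if (nrow(p$bonds) > 0L && any(!p$bonds[, 3L] %in% 1:3)) {
      reason[i] <- "unsupported bond order"; next
    }
    m <- matrix(0L, max_atoms, max_atoms)
    diag(m)[seq_along(els)] <- ATOM_CODES[els]
    if (nrow(p$bonds) > 0L) {
      m[p$bonds[, 1:2, drop = FALSE]] <- p$bonds[, 3L]
      m[p$bonds[, c(2L, 1L), drop = FALSE]] <- p$bonds[, 3L]
    }
    g <- structure(m, class = "mol_graph")
    if (!mol_chem(g)$ok) { reason[i] <- "sanitization failure"; next }
    graphs[[i]] <- g
  }
  list(graphs = graphs, smiles = can, reason = reason)
}
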