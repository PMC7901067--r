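# S3 methods for fitted gan_evolve objects.

#' @export
print.gan_evolve <- function(x, ...) {
  cfg <- x$config
  cat("Adaptive-training-data GAN run\n")
  cat(sprintf("  strategy: %s%s%s\n", cfg$strategy,
              if (cfg$strategy == "guided")
                paste0(" (", cfg$guide_metric, ")") else "",
              if (cfg$recombine)
                sprintf(" + recombination (fraction %.2f)",
                        cfg$recombine_fraction) else ""))
  cat(sprintf(
    "  population %d x max_atoms %d | %d intervals x %d epochs | %d/epoch\n",
    cfg$capacity, cfg$max_atoms, cfg$n_intervals, cfg$interval_epochs,
    cfg$samples_per_epoch))
  cat(sprintf("  replicates: %d (seed %d)\n", cfg$n_replicates, cfg$seed))
  if (nrow(x$intervals) > 0L) {
    per_rep <- vapply(split(x$intervals, x$intervals$replicate),
                      function(d) utils::tail(d$cumulative_novel, 1L),
                      numeric(1))
    cat(sprintf("  novel molecules: %s (mean %.1f)\n",
                paste(per_rep, collapse = "/"), mean(per_rep)))
  }
  invisible(x)
}

#' Summarize an adaptive GAN run
#'
#' @param object a \code{gan_evolve} fit.
#' @param threshold top-performer cutoff on drug-likeness (default 0.6).
#' @param ... unused.
#' @return A list of class \code{summary.gan_evolve} with per-interval
#'   means across replicates, totals and top-performer counts.
#' @export
summary.gan_evolve <- function(object, threshold = 0.6, ...) {
  iv <- object$intervals
  by_iv <- if (nrow(iv) > 0L)
    do.call(rbind, lapply(split(iv, iv$interval), function(d)
      data.frame(interval = d$interval[1L],
                 new_mean = mean(d$n_novel),
                 new_sd = stats::sd(d$n_novel),
                 cumulative_mean = mean(d$cumulative_novel),
                 replaced_mean = mean(d$n_replaced),
                 pop_mean_qed = mean(d$pop_mean_qed))))
  else NULL
  tops <- if (nrow(object$produced) > 0L)
    vapply(split(object$produced, object$produced$replicate),
           function(d) count_top_performers(d, "qed", threshold), numeric(1))
  else numeric(0)
  structure(list(config = object$config, by_interval = by_iv,
                 top_performers = tops, threshold = threshold,
                 n_produced = nrow(object$produced),
                 produced_qed_mean = if (nrow(object$produced) > 0L)
                   mean(object$produced$qed, na.rm = TRUE) else NA_real_),
            class = "summary.gan_evolve")
}

#' @export
print.summary.gan_evolve <- function(x, ...) {
  cat(sprintf("Run: %s%s | %d replicate(s)\n", x$config$strategy,
              if (x$config$recombine) "+recombination" else "",
              x$config$n_replicates))
  if (!is.null(x$by_interval)) {
    cat("Per-interval novel molecules (mean across replicates):\n")
    print(format(x$by_interval, digits = 3), row.names = FALSE)
  }
  cat(sprintf("Produced %d molecules | mean drug-likeness %.3f\n",
              x$n_produced, x$produced_qed_mean))
  if (length(x$top_performers) > 0L)
    cat(sprintf("Top performers (qed > %.2f) per replicate: %s\n",
                x$threshold, paste(x$top_performers, collapse = "/")))
  invisible(x)
}

#' Plot an adaptive GAN run
#'
#' Two base-graphics panels: new novel molecules per interval (one line per
#' replicate) and the drug-likeness histogram of all produced molecules.
#'
#' @param x a \code{gan_evolve} fit.
#' @param which subset of panels (1 = novelty curve, 2 = score histogram).
#' @param ... passed to the underlying plot calls.
#' @method plot gan_evolve
#' @export
plot.gan_evolve <- function(x, which = c(1L, 2L), ...) {
  iv <- x$intervals
  panels <- intersect(which, c(1L, 2L))
  if (length(panels) > 1L) {
    old <- graphics::par(mfrow = c(1, length(panels)))
    on.exit(graphics::par(old))
  }
  if (1L %in% panels && nrow(iv) > 0L) {
    reps <- split(iv, iv$replicate)
    graphics::plot(NA, xlim = range(iv$interval),
                   ylim = c(0, max(iv$n_novel, 1)),
                   xlab = "training interval", ylab = "new molecules",
                   main = sprintf("%s%s", x$config$strategy,
                                  if (x$config$recombine) "+re" else ""),
                   ...)
    for (r in seq_along(reps))
      graphics::lines(reps[[r]]$interval, reps[[r]]$n_novel, col = r)
  }
  if (2L %in% panels && nrow(x$produced) > 0L) {
    graphics::hist(x$produced$qed, breaks = seq(0, 1, by = 0.05),
                   xlab = "drug-likeness (QED)", main = "produced molecules",
                   col = "grey80", ...)
    graphics::abline(v = 0.6, lty = 2)
  }
  invisible(x)
}

#' Sample molecules from a fitted generator
#'
#' Draws \code{nsim} molecules from the trained generator of one replicate
#' and scores the valid ones.
#'
#' @param object a \code{gan_evolve} fit.
#' @param nsim number of samples (default 100).
#' @param seed optional seed for the latent draws.
#' @param replicate which replicate's generator to use (default 1).
#' @param ... unused.
#' @return A data.frame with columns \code{smiles} (NA for invalid
#'   samples), \code{valid}, \code{qed}, \code{sa}, \code{solubility}.
#' @export
simulate.gan_evolve <- function(object, nsim = 100L, seed = NULL,
                                replicate = 1L, ...) {
  if (!is.null(seed)) set.seed(seed)
  state <- object$replicates[[replicate]]$gan_state
  graphs <- gan_sample(state, nsim)
  scorer <- attr(object$initial_population, "scorer")
  sc <- score_graphs(graphs, scorer)
  data.frame(smiles = sc$smiles, valid = !is.na(sc$smiles),
             qed = sc$qed, sa = sc$sa, solubility = sc$solubility,
             stringsAsFactors = FALSE)
}

#' Discriminator realness scores for new molecules
#'
#' Runs molecules through a fitted discriminator. Higher scores mean the
#' discriminator finds the molecule more similar to its current training
#' data; \code{type = "probability"} applies the logistic link.
#'
#' @param object a \code{gan_evolve} fit.
#' @param newdata SMILES character vector, \code{molecule_set} or list of
#'   \code{\link{mol_graph}} objects (default: the initial population).
#' @param type \code{"score"} (raw) or \code{"probability"}.
#' @param replicate which replicate's discriminator to use.
#' @param ... unused.
#' @return Numeric vector (NA for molecules that cannot be encoded).
#' @export
predict.gan_evolve <- function(object, newdata = NULL,
                               type = c("score", "probability"),
                               replicate = 1L, ...) {
  type <- match.arg(type)
  state <- object$replicates[[replicate]]$gan_state
  if (is.null(newdata)) newdata <- object$initial_population
  if (is.character(newdata)) {
    enc <- encode_molecules(newdata, object$config$max_atoms)
    ok <- !vapply(enc$graphs, is.null, logical(1))
    out <- rep(NA_real_, length(newdata))
    if (any(ok))
      out[ok] <- gan_discriminate(state, enc$graphs[ok])
  } else {
    out <- gan_discriminate(state, newdata)
  }
  if (type == "probability") out <- 1 / (1 + exp(-out))
  out
}
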