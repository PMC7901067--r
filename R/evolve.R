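# The experiment driver. gan_evolve() is the package's fitting function: it
# trains the GAN in intervals, collects valid novel molecules per epoch,
# applies the configured replacement strategy between intervals and returns
# a classed result with per-interval and per-molecule tables.

#' Evolve a GAN's training data while it trains
#'
#' Runs the adaptive-training-data experiment: a small GAN is trained on a
#' molecular population in intervals of \code{interval_epochs} epochs; after
#' every training epoch \code{samples_per_epoch} molecules are sampled from
#' the generator (optionally recombined with population members by slice
#' crossover), and those that are chemically valid and never seen before are
#' pooled over the interval. At the end of each interval the pool replaces
#' population entries according to \code{strategy}: \code{"control"} leaves
#' the population untouched (the traditional GAN baseline), \code{"random"}
#' overwrites uniformly chosen entries, \code{"guided"} replaces the weakest
#' incumbents only with strictly better candidates under
#' \code{guide_metric}. Replicates differ only in their seed offset.
#'
#' @param x training data: a \code{molecule_set} (see
#'   \code{\link{generate_fixture_molecules}},
#'   \code{\link{load_smiles_file}}), a \code{training_population}, or a
#'   character vector of SMILES.
#' @param strategy \code{"control"}, \code{"random"} or \code{"guided"}.
#' @param guide_metric metric for guided replacement and softmax parent
#'   weighting: \code{"qed"} (alias \code{"drug"}), \code{"sa"} or
#'   \code{"solubility"}.
#' @param recombine logical; cross a fraction of each epoch's samples with
#'   population parents before filtering.
#' @param recombine_fraction fraction of samples recombined (default 0.5).
#' @param burnin_epochs plain training epochs run before the first interval,
#'   without sampling or novelty accounting (default 0). At reduced scale a
#'   burn-in lets the generator reach its productive regime (where a
#'   non-negligible fraction of samples is chemically valid) before the
#'   experiment's bookkeeping starts, mirroring the early training phase
#'   that a full-scale run passes through within its first interval.
#' @param n_intervals number of training intervals.
#' @param interval_epochs epochs per interval (default 5).
#' @param samples_per_epoch generator samples collected per epoch
#'   (default 10000).
#' @param capacity population size (default: all records in \code{x}).
#' @param max_atoms matrix edge length (default: taken from \code{x}).
#' @param gan a \code{\link{gan_config}}; its seed field is overridden by
#'   \code{seed}.
#' @param init_state optional pretrained \code{\link{gan_state}} (or a list
#'   with one per replicate, e.g. from \code{\link{gan_pretrain}} at seeds
#'   \code{seed}, \code{seed + 1}, ...). When given, GAN initialization and
#'   \code{burnin_epochs} are skipped and training resumes from this
#'   checkpoint.
#' @param n_replicates independent replicate runs (seed offsets 0, 1, ...).
#' @param seed master seed.
#' @param out_dir optional directory; per-interval and produced-molecule
#'   tables are (re)written there after every interval so a crashed run
#'   remains inspectable.
#' @param verbose print per-interval progress lines.
#' @return An object of class \code{gan_evolve} with components
#'   \code{intervals} (per replicate x interval statistics),
#'   \code{produced} (one row per novel molecule with its scores),
#'   \code{replicates} (final population, GAN state and novelty ledger per
#'   replicate) and \code{config}.
#' @seealso \code{\link{summary.gan_evolve}}, \code{\link{compare_runs}},
#'   \code{\link{simulate.gan_evolve}}
#' @export
gan_evolve <- function(x,
                       strategy = c("control", "random", "guided"),
                       guide_metric = "qed",
                       recombine = FALSE, recombine_fraction = 0.5,
                       burnin_epochs = 0L,
                       n_intervals = 10L, interval_epochs = 5L,
                       samples_per_epoch = 10000L,
                       capacity = NULL, max_atoms = NULL,
                       gan = gan_config(), init_state = NULL,
                       n_replicates = 1L,
                       seed = 1L, out_dir = NULL, verbose = FALSE) {
  strategy <- match.arg(strategy)
  guide_col <- metric_column(guide_metric)
  stopifnot(recombine_fraction >= 0, recombine_fraction <= 1,
            n_intervals >= 0L, interval_epochs >= 1L,
            samples_per_epoch >= 1L, n_replicates >= 1L)
  if (is.character(x)) {
    if (is.null(max_atoms)) stop("max_atoms is required for SMILES input",
                                 call. = FALSE)
    enc <- encode_molecules(x, max_atoms)
    keep <- !vapply(enc$graphs, is.null, logical(1))
    x <- molecule_set(enc$smiles[keep], enc$graphs[keep],
                      max_atoms = max_atoms)
  }
  if (is.null(max_atoms)) max_atoms <- x$max_atoms
  if (is.null(capacity)) capacity <- length(x)
  base_pop <- if (inherits(x, "training_population") &&
                  x$capacity == capacity) x
  else training_population(x, capacity)
  scorer <- attr(base_pop, "scorer")

  cfg <- list(strategy = strategy, guide_metric = guide_col,
              recombine = recombine,
              recombine_fraction = recombine_fraction,
              burnin_epochs = as.integer(burnin_epochs),
              n_intervals = as.integer(n_intervals),
              interval_epochs = as.integer(interval_epochs),
              samples_per_epoch = as.integer(samples_per_epoch),
              capacity = as.integer(capacity),
              max_atoms = as.integer(max_atoms),
              gan = gan, n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  if (inherits(init_state, "gan_state"))
    init_state <- rep(list(init_state), n_replicates)
  replicates <- vector("list", n_replicates)
  interval_tabs <- list(); produced_tabs <- list()
  for (rep_i in seq_len(n_replicates)) {
    res <- run_one_replicate(base_pop, scorer, cfg, rep_i, out_dir, verbose,
                             init_state[[rep_i]])
    replicates[[rep_i]] <- res[c("population", "gan_state", "ledger",
                                 "losses")]
    interval_tabs[[rep_i]] <- res$intervals
    produced_tabs[[rep_i]] <- res$produced
  }
  out <- structure(list(call = match.call(),
                        config = cfg,
                        intervals = do.call(rbind, interval_tabs),
                        produced = do.call(rbind, produced_tabs),
                        replicates = replicates,
                        initial_population = base_pop),
                   class = "gan_evolve")
  if (!is.null(out_dir)) write_run_tables(out, out_dir)
  out
}

# one replicate: fresh copies of population and GAN, seed offset by index
run_one_replicate <- function(base_pop, scorer, cfg, rep_i, out_dir,
                              verbose, init_state = NULL) {
  rep_seed <- cfg$seed + rep_i - 1L
  gan_cfg <- cfg$gan
  gan_cfg$seed <- rep_seed
  pop <- base_pop
  if (is.null(init_state)) {
    state <- gan_init(gan_cfg, layout_length(cfg$max_atoms), cfg$max_atoms)
    set.seed(rep_seed)  # gan_init seeds too; reseed for the run stream
    for (ep in seq_len(cfg$burnin_epochs))
      state <- gan_train_epoch(state, pop, gan_cfg)
  } else {
    state <- init_state
    if (state$max_atoms != cfg$max_atoms)
      condition_stop("molevolve_config_error",
                     "init_state max_atoms does not match the run")
    set.seed(rep_seed)
  }
  ledger <- novelty_ledger(pop$smiles)
  parent_metric <- if (cfg$strategy == "guided") cfg$guide_metric else NULL

  iv_rows <- list(); prod_rows <- list(); losses <- list()
  metric_cols <- c("qed", "sa", "solubility")
  for (iv in seq_len(cfg$n_intervals)) {
    interval_sets <- list()
    n_sampled <- 0L; n_valid <- 0L
    g_loss <- numeric(0); d_loss <- numeric(0)
    for (ep in seq_len(cfg$interval_epochs)) {
      state <- gan_train_epoch(state, pop, gan_cfg)
      ls <- attr(state, "losses")
      g_loss <- c(g_loss, ls[["g"]]); d_loss <- c(d_loss, ls[["d"]])
      graphs <- gan_sample(state, cfg$samples_per_epoch)
      if (cfg$recombine)
        graphs <- recombine_batch(graphs, pop, cfg$recombine_fraction,
                                  parent_metric)
      n_sampled <- n_sampled + length(graphs)
      survivors <- filter_valid_novel(graphs, ledger, scorer)
      n_valid <- n_valid + (attr(survivors, "n_valid", exact = TRUE) %||% 0L)
      interval_sets[[ep]] <- survivors
    }
    cands <- concat_molecule_sets(interval_sets)
    n_novel <- if (is.null(cands)) 0L else length(cands)
    pop <- switch(cfg$strategy,
                  control = { attr(pop, "n_replaced") <- 0L; pop },
                  random = if (is.null(cands)) {
                    attr(pop, "n_replaced") <- 0L; pop
                  } else replace_random(pop, cands),
                  guided = if (is.null(cands)) {
                    attr(pop, "n_replaced") <- 0L; pop
                  } else replace_guided(pop, cands, cfg$guide_metric))
    ledger_mark_interval(ledger)
    stats_row <- data.frame(replicate = rep_i, interval = iv,
                            n_sampled = n_sampled, n_valid = n_valid,
                            n_novel = n_novel,
                            cumulative_novel = ledger$cumulative_new,
                            n_replaced = attr(pop, "n_replaced"),
                            g_loss = mean(g_loss), d_loss = mean(d_loss))
    for (mc in metric_cols) {
      stats_row[[paste0("pop_mean_", mc)]] <- mean(pop$scores[[mc]])
      stats_row[[paste0("pop_min_", mc)]] <- min(pop$scores[[mc]])
      stats_row[[paste0("pop_max_", mc)]] <- max(pop$scores[[mc]])
    }
    iv_rows[[iv]] <- stats_row
    if (n_novel > 0L)
      prod_rows[[iv]] <- data.frame(replicate = rep_i, interval = iv,
                                    smiles = cands$smiles,
                                    qed = cands$scores$qed,
                                    sa = cands$scores$sa,
                                    solubility = cands$scores$solubility,
                                    stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf(
        "  rep %d interval %2d: sampled %5d valid %5d novel %5d replaced %5d",
        rep_i, iv, n_sampled, n_valid, n_novel, attr(pop, "n_replaced")))
    if (!is.null(out_dir)) {
      utils::write.csv(do.call(rbind, iv_rows),
                       file.path(out_dir,
                                 sprintf("intervals_rep%d.csv", rep_i)),
                       row.names = FALSE)
      if (length(prod_rows) > 0L)
        utils::write.csv(do.call(rbind, prod_rows),
                         file.path(out_dir,
                                   sprintf("produced_rep%d.csv", rep_i)),
                         row.names = FALSE)
    }
  }
  empty_iv <- data.frame(replicate = integer(0), interval = integer(0),
                         n_sampled = integer(0), n_valid = integer(0),
                         n_novel = integer(0), cumulative_novel = integer(0),
                         n_replaced = integer(0), g_loss = numeric(0),
                         d_loss = numeric(0))
  list(population = pop, gan_state = state, ledger = ledger,
       losses = do.call(rbind, losses),
       intervals = if (length(iv_rows) > 0L) do.call(rbind, iv_rows)
       else empty_iv,
       produced = if (length(prod_rows) > 0L) do.call(rbind, prod_rows)
       else data.frame(replicate = integer(0), interval = integer(0),
                       smiles = character(0), qed = numeric(0),
                       sa = numeric(0), solubility = numeric(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_run_tables <- function(fit, out_dir) {
  utils::write.csv(fit$intervals, file.path(out_dir, "intervals.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$produced, file.path(out_dir, "produced.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Compare runs across conditions
#'
#' Summarizes one or more fits per condition: mean and standard deviation
#' across replicates of the cumulative novel-molecule count and of the
#' top-performer count (score strictly above \code{threshold}).
#'
#' @param ... named \code{gan_evolve} objects (the names label conditions),
#'   or a single named list of them.
#' @param metric score used for top-performer counting.
#' @param threshold top-performer cutoff (default 0.6).
#' @return A data.frame with one row per condition, ordered by mean
#'   cumulative novel count (descending).
#' @export
compare_runs <- function(..., metric = "qed", threshold = 0.6) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "gan_evolve"))
    fits <- fits[[1L]]
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("condition", seq_along(fits))
  ma <- unique(vapply(fits, function(f) f$config$max_atoms, integer(1)))
  if (length(ma) > 1L)
    condition_stop("molevolve_comparison_error",
                   "runs use different max_atoms and are not comparable")
  col <- metric_column(metric)
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    per_rep <- lapply(split(f$intervals, f$intervals$replicate),
                      function(d) utils::tail(d$cumulative_novel, 1L))
    cum <- as.numeric(unlist(per_rep))
    if (length(cum) == 0L) cum <- 0
    tops <- vapply(split(f$produced, factor(f$produced$replicate,
                                            levels = unique(f$intervals$replicate))),
                   function(d) count_top_performers(d, col, threshold),
                   numeric(1))
    if (length(tops) == 0L) tops <- 0
    data.frame(condition = nm,
               n_replicates = f$config$n_replicates,
               novel_mean = mean(cum), novel_sd = stats::sd(cum),
               top_mean = mean(tops), top_sd = stats::sd(tops),
               produced_mean_score = mean(f$produced[[col]], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$novel_mean), , drop = FALSE]
}
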