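# The reduced-scale comparative study used by the acceptance tests:
# 2000-molecule fixture population (max_atoms 9), shared 60-epoch pretrained
# generators, then 10 intervals x 5 epochs x 500 samples per condition,
# 3 replicates (seeds 1, 2, 3). Computed once and memoized; several test
# blocks read different aspects of the same runs.

acceptance_study <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    seed <- 1L
    fixture <- generate_fixture_molecules(2000L, max_atoms = 9L, seed = 7L)
    pop <- training_population(fixture)
    states <- lapply(0:2, function(off)
      gan_pretrain(pop, gan_config(batch_size = 32L, seed = seed + off),
                   60L))
    gcfg <- gan_config(batch_size = 32L)
    run <- function(strategy, recombine)
      gan_evolve(pop, strategy = strategy, guide_metric = "qed",
                 recombine = recombine, n_intervals = 10L,
                 interval_epochs = 5L, samples_per_epoch = 500L,
                 gan = gcfg, init_state = states, n_replicates = 3L,
                 seed = seed)
    cached <<- list(pop = pop,
                    control = run("control", FALSE),
                    random = run("random", FALSE),
                    guided = run("guided", FALSE),
                    guided_recomb = run("guided", TRUE))
    cached
  }
})

study_per_rep <- function(fit, f) {
  vapply(split(fit$intervals, fit$intervals$replicate), f, numeric(1))
}
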