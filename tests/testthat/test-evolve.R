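# Experiment driver: reproducibility, control freezing, bookkeeping.

small_fit <- function(strategy = "control", seed = 21L, ...) {
  fx <- generate_fixture_molecules(120, max_atoms = 6, seed = 55)
  pop <- training_population(fx, scorer = test_scorer())
  gan_evolve(pop, strategy = strategy, n_intervals = 2L,
             interval_epochs = 2L, samples_per_epoch = 60L,
             gan = gan_config(batch_size = 16L), seed = seed, ...)
}

test_that("zero intervals produce empty tables and no molecules", {
  fx <- generate_fixture_molecules(50, max_atoms = 6, seed = 55)
  pop <- training_population(fx, scorer = test_scorer())
  fit <- gan_evolve(pop, strategy = "random", n_intervals = 0L,
                    samples_per_epoch = 10L, seed = 1)
  expect_equal(nrow(fit$intervals), 0L)
  expect_equal(nrow(fit$produced), 0L)
})

test_that("control runs freeze the population exactly", {
  fit <- small_fit("control")
  pop0 <- fit$initial_population
  pop1 <- fit$replicates[[1]]$population
  expect_identical(pop0$smiles, pop1$smiles)
  expect_identical(pop0$onehot, pop1$onehot)
  expect_identical(pop0$scores, pop1$scores)
  expect_true(all(fit$intervals$n_replaced == 0L))
})

test_that("the same seed reproduces all tables bitwise", {
  a <- small_fit("random", seed = 77L)
  b <- small_fit("random", seed = 77L)
  expect_identical(a$intervals, b$intervals)
  expect_identical(a$produced, b$produced)
  c2 <- small_fit("random", seed = 78L)
  expect_false(identical(a$intervals, c2$intervals))
})

test_that("interval bookkeeping is internally consistent", {
  fit <- small_fit("random", n_replicates = 2L)
  iv <- fit$intervals
  expect_equal(nrow(iv), 4L)
  for (r in 1:2) {
    d <- iv[iv$replicate == r, ]
    expect_equal(d$cumulative_novel, cumsum(d$n_novel))
    led <- fit$replicates[[r]]$ledger
    expect_equal(led$per_interval_new, d$n_novel)
    expect_equal(led$cumulative_new, sum(d$n_novel))
    prod_r <- fit$produced[fit$produced$replicate == r, ]
    expect_equal(nrow(prod_r), sum(d$n_novel))
    expect_equal(anyDuplicated(prod_r$smiles), 0L)
    # novel molecules are novel: none is in the initial population
    expect_false(any(prod_r$smiles %in% fit$initial_population$smiles))
  }
  expect_true(all(iv$n_valid <= iv$n_sampled))
  expect_true(all(iv$n_novel <= iv$n_valid))
  expect_true(all(iv$n_replaced <= iv$n_novel))
})

test_that("run tables are written and rewritten incrementally", {
  dir <- tempfile("run")
  fit <- small_fit("random", out_dir = dir)
  expect_true(file.exists(file.path(dir, "intervals.csv")))
  expect_true(file.exists(file.path(dir, "intervals_rep1.csv")))
  got <- utils::read.csv(file.path(dir, "intervals.csv"))
  expect_equal(nrow(got), nrow(fit$intervals))
  unlink(dir, recursive = TRUE)
})

test_that("fit methods run and report coherently", {
  fit <- small_fit("random")
  expect_output(print(fit), "random")
  s <- summary(fit)
  expect_s3_class(s, "summary.gan_evolve")
  expect_output(print(s), "Produced")
  sims <- simulate(fit, nsim = 20L, seed = 3L)
  expect_equal(nrow(sims), 20L)
  expect_type(sims$valid, "logical")
  scores <- predict(fit, c("CCO", "CCCC"))
  expect_length(scores, 2L)
  probs <- predict(fit, c("CCO", "CCCC"), type = "probability")
  expect_true(all(probs >= 0 & probs <= 1, na.rm = TRUE))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("compare_runs aggregates replicates with closed-form statistics", {
  a <- small_fit("control", n_replicates = 1L)
  # single replicate: standard deviation is NA-free zero-length, mean exact
  cmp1 <- compare_runs(ctrl = a)
  expect_equal(cmp1$novel_mean,
               tail(a$intervals$cumulative_novel, 1))
  b <- small_fit("random", n_replicates = 3L)
  per_rep <- vapply(split(b$intervals, b$intervals$replicate),
                    function(d) tail(d$cumulative_novel, 1), numeric(1))
  cmp <- compare_runs(ctrl = a, rnd = b)
  expect_equal(cmp$novel_mean[cmp$condition == "rnd"], mean(per_rep))
  expect_equal(cmp$novel_sd[cmp$condition == "rnd"], sd(per_rep))
  expect_equal(cmp$novel_mean, sort(cmp$novel_mean, decreasing = TRUE))
})

test_that("runs with different matrix sizes cannot be compared", {
  a <- small_fit("control")
  fx <- generate_fixture_molecules(40, max_atoms = 5, seed = 3)
  b <- gan_evolve(training_population(fx, scorer = test_scorer()),
                  strategy = "control", n_intervals = 1L,
                  interval_epochs = 1L, samples_per_epoch = 10L, seed = 1)
  expect_error(compare_runs(a = a, b = b),
               class = "molevolve_comparison_error")
})

test_that("mean and sd across replicate counts follow the closed form", {
  # three replicates with cumulative counts 10, 20, 30 give mean 20, sd 10
  fit <- small_fit("control")
  fake <- fit
  fake$config$n_replicates <- 3L
  fake$intervals <- data.frame(replicate = c(1, 1, 2, 2, 3, 3),
                               interval = rep(1:2, 3),
                               cumulative_novel = c(5, 10, 15, 20, 25, 30))
  fake$produced <- fit$produced[0, ]
  cmp <- compare_runs(x = fake)
  expect_equal(cmp$novel_mean, 20)
  expect_equal(cmp$novel_sd, 10)
})
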