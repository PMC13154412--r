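test_that("objective is the diagonal-down-weighted squared discrepancy", {
  X <- diag(3)
  expect_equal(mcsa_objective(X, X), 0)
  Y <- X; Y[2, 2] <- Y[2, 2] + 1
  expect_equal(mcsa_objective(Y, X, diag_weight = 0.1), 0.1)
  set.seed(1)
  D <- crossprod(matrix(rnorm(16), 4))
  N <- crossprod(matrix(rnorm(16), 4))
  expect_equal(mcsa_objective(D, N, 0.1), oracle_objective(D, N, 0.1),
               tolerance = 1e-12)
  expect_equal(mcsa_objective(D, N, 0.1, sqrt_scale = TRUE),
               sqrt(oracle_objective(D, N, 0.1)))
  expect_error(mcsa_objective(D, N[1:3, 1:3]), "dimensions")
})

test_that("Metropolis criterion accepts per exp(-dE/T)", {
  expect_true(metropolis_accept(-1, 5))
  expect_true(metropolis_accept(0, 1e-9))   # exp(0) = 1
  expect_error(metropolis_accept(1, 0), "positive")
  # empirical acceptance at dE = T ln 2 is 0.5 within 3 binomial sigma
  set.seed(42)
  T <- 2
  hits <- sum(vapply(1:10000, function(i)
    metropolis_accept(T * log(2), T), logical(1)))
  expect_lt(abs(hits / 10000 - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("binned acceptance rates follow the Boltzmann factor", {
  set.seed(7)
  T <- 1.5
  dEs <- c(0.2, 0.7, 1.5, 3)
  for (dE in dEs) {
    n <- 4000
    rate <- mean(vapply(seq_len(n), function(i)
      metropolis_accept(dE, T), logical(1)))
    p <- exp(-dE / T)
    expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("proposal sweeps mutate cells at the stated rate", {
  set.seed(8)
  enc <- matrix(sample(0:19, 100 * 9, TRUE), 100, 9)
  same <- propose(enc, mutation_prob = 1e-12)
  expect_identical(same$design, enc)
  expect_equal(nrow(same$changes), 0L)

  all_changed <- propose(enc, mutation_prob = 1)
  expect_true(all(all_changed$design != enc))

  # mutation count over repeated sweeps is binomial with p = 0.08
  set.seed(9)
  nmut <- sum(vapply(1:100, function(i)
    nrow(propose(enc, 0.08)$changes), 0L))
  n_cells <- 100 * 9 * 100
  expect_lt(abs(nmut - 0.08 * n_cells), 3 * sqrt(n_cells * 0.08 * 0.92))

  fp <- fx_bench_stats()[[1]]$frequencies
  expect_error(propose(enc, 0.08, "frequency_guided"), "profile")
  g <- propose(enc, 1, "frequency_guided", fp)
  expect_true(nrow(g$changes) > 0)
})

test_that("temperature schedule is geometric from T0 = 15", {
  cfg <- anneal_config()
  expect_equal(cfg$T0, 15)
  expect_equal(cfg$decay, 0.99)
  expect_equal(cfg$n_outer, 2000L)
  expect_equal(cfg$n_inner, 2000L)
  expect_equal(cfg$mutation_prob, 0.08)
  expect_equal(cfg$diag_weight, 0.1)
  expect_equal(temperature_schedule(cfg, 0:3), 15 * 0.99^(0:3))
  expect_equal(temperature_schedule(cfg, 2000), 15 * 0.99^2000)
  expect_equal(temperature_schedule(cfg, 2000), 2.79e-8,
               tolerance = 2e-3)
  expect_error(anneal_config(decay = 1), "decay")
  expect_error(anneal_config(T0 = -1), "T0")
})

test_that("anneal returns a consistent, reproducible trajectory", {
  aln <- rand_alignment(40, 4, 6, 77)
  st <- evo_statistics(aln)
  cfg <- anneal_config(n_outer = 25, n_inner = 20, M = 40, seed = 3,
                       debug_check_every = 97)
  res <- anneal(st, cfg)
  tr <- res$trajectory
  expect_true(all(diff(tr$best_E) <= 0))
  expect_equal(res$final_E, min(tr$best_E))
  # temperature series: constant within an outer cycle, geometric across
  expect_true(all(tapply(tr$temperature, tr$outer, function(x)
    length(unique(x))) == 1L))
  expect_equal(tr$temperature[!duplicated(tr$outer)], 15 * 0.99^(0:24))
  # identical seed -> bit-identical trajectory; design decodes validly
  res2 <- anneal(st, cfg)
  expect_identical(res$trajectory, res2$trajectory)
  expect_identical(res$design$sequences, res2$design$sequences)
  expect_equal(res$design$M, 40L)
  validate_alignment(res$design)
})

test_that("zero-temperature annealing is greedy (E never rises)", {
  aln <- rand_alignment(30, 3, 5, 5)
  st <- evo_statistics(aln)
  cfg <- anneal_config(n_outer = 5, n_inner = 40, M = 30, seed = 4,
                       T0 = 1e-9)
  res <- anneal(st, cfg)
  expect_true(all(diff(res$trajectory$E) <= 1e-12))
})

test_that("sweep-level acceptance is available and monotone in best E", {
  aln <- rand_alignment(30, 3, 5, 6)
  st <- evo_statistics(aln)
  cfg <- anneal_config(n_outer = 10, n_inner = 30, M = 30, seed = 5,
                       acceptance = "sweep", debug_check_every = 53)
  res <- anneal(st, cfg)
  expect_true(all(diff(res$trajectory$best_E) <= 0))
  expect_true(all(res$trajectory$accepted %in% c(0, 1)))
})

test_that("early stopping halts after a rejection streak", {
  aln <- rand_alignment(25, 3, 5, 9)
  st <- evo_statistics(aln)
  cfg <- anneal_config(n_outer = 50, n_inner = 50, M = 25, seed = 6,
                       T0 = 1e-9, early_stop_rejections = 5,
                       acceptance = "sweep")
  res <- anneal(st, cfg)
  expect_lt(nrow(res$trajectory), 50 * 50)
})

test_that("MC2 preserves first-order structure better than MC1", {
  st <- fx_strong()$stats
  f_native <- as.vector(st$frequencies$f)
  pcc1 <- cor(as.vector(fx_mc("MC1")$stats$frequencies$f), f_native)
  pcc2 <- cor(as.vector(fx_mc("MC2")$stats$frequencies$f), f_native)
  expect_gte(pcc2, pcc1)
})
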