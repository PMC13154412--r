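test_that("featurize flattens row-major and inverts", {
  st9 <- fx_bench_stats()[[1]]
  ft <- featurize(st9$frequencies, st9$joint)
  expect_length(ft$F, 180L)
  expect_equal(dim(ft$T), c(180L, 180L))
  # token t = (i-1)*A + a
  expect_equal(ft$F[(3 - 1) * 20 + 5], st9$frequencies$f[[3, 5]])
  expect_equal(ft$T[(2 - 1) * 20 + 1, (4 - 1) * 20 + 7],
               st9$joint$fj[2, 1, 4, 7])
  back <- unfeaturize(ft, L = 9)
  expect_equal(back$frequencies$f, st9$frequencies$f)
  expect_equal(back$joint$fj, st9$joint$fj)

  st3 <- fx_tiny_stats()[[1]]
  expect_length(featurize(st3$frequencies, st3$joint)$F, 12L)
})

test_that("predicted statistics form the product-with-delta surrogate", {
  L <- 3; A <- 4
  P <- matrix(1 / A, L, A)
  ps <- predicted_statistics(P)
  for (i in 1:L) for (j in 1:L) if (i != j)
    expect_true(all(ps$joint[i, , j, ] == 1 / (A * A)))
  onehot <- diag(A)[1:L, ]
  po <- predicted_statistics(onehot)
  expect_equal(po$joint[1, 1, 2, 2], 1)
  expect_equal(sum(po$joint[1, , 2, ] != 0), 1L)
  # marginalization holds exactly
  set.seed(1)
  Pr <- matrix(rexp(L * A), L); Pr <- Pr / rowSums(Pr)
  pr <- predicted_statistics(Pr)
  for (i in 1:L) for (j in 1:L)
    expect_equal(rowSums(pr$joint[i, , j, ]), Pr[i, ], tolerance = 1e-14)
})

test_that("loss identities and decomposition hold", {
  st <- fx_tiny_stats()[[1]]
  ft <- featurize(st$frequencies, st$joint)
  expect_equal(loss1(ft$T, ft$T), 0)
  eps <- 0.01
  expect_equal(loss1(ft$T + eps, ft$T), eps^2, tolerance = 1e-12)

  set.seed(2)
  predF <- st$frequencies$f + matrix(rnorm(12, 0, 0.05), 3)
  predJ <- ft$T + matrix(rnorm(144, 0, 0.05), 12)
  l2 <- loss2(predF, st$frequencies$f, predJ, ft$T, lambda = 65)
  expect_equal(l2$total, l2$freq_term + 65 * l2$joint_term, tolerance = 1e-12)
  # independent recomputation of both components
  expect_equal(l2$freq_term, sum((predF - st$frequencies$f)^2),
               tolerance = 1e-10)
  expect_equal(l2$joint_term, sum((predJ - ft$T)^2) / 144, tolerance = 1e-10)
  # lambda = 0 reduces to the frequency term
  expect_equal(loss2(predF, st$frequencies$f, predJ, ft$T, lambda = 0)$total,
               l2$freq_term)
  # batched version averages over allotypes
  l2b <- loss2(list(predF, st$frequencies$f), list(st$frequencies$f, st$frequencies$f),
               list(predJ, ft$T), list(ft$T, ft$T), lambda = 65)
  expect_equal(l2b$total, l2$total / 2, tolerance = 1e-12)
})

test_that("forward pass yields normalized, deterministic distributions", {
  st <- fx_tiny_stats()[[1]]
  set.seed(10)
  model <- build_design_model(tiny_model_config())
  P1 <- model_probabilities(model, st)
  P2 <- model_probabilities(model, st)
  expect_identical(P1, P2)
  expect_equal(dim(P1), c(3L, 4L))
  expect_equal(rowSums(P1), rep(1, 3), tolerance = 1e-6)
  expect_true(all(P1 >= 0))
})

test_that("autograd gradients agree with finite differences", {
  st <- fx_tiny_stats()[[1]]
  set.seed(11)
  model <- build_design_model(tiny_model_config())
  inp <- pepcoev:::prepare_inputs(model, st$frequencies, st$joint)
  eval_loss <- function(params) {
    model$params <- params
    tape <- pepcoev:::ag_tape()
    pn <- lapply(model$params, function(x) pepcoev:::ag_param(tape, x))
    P <- pepcoev:::forward_graph(model, tape, pn, inp)
    ls <- pepcoev:::loss_graph(model, tape, P, inp, "loss2", 65)
    list(val = ls$total$value[1], tape = tape, pn = pn, node = ls$total)
  }
  r <- eval_loss(model$params)
  pepcoev:::ag_backward(r$tape, r$node)
  set.seed(12)
  for (nm in sample(names(model$params), 8)) {
    g <- r$pn[[nm]]$grad
    expect_false(is.null(g), info = nm)
    idx <- sample(length(model$params[[nm]]), 1)
    eps <- 1e-5
    up <- model$params; up[[nm]][idx] <- up[[nm]][idx] + eps
    dn <- model$params; dn[[nm]][idx] <- dn[[nm]][idx] - eps
    num <- (eval_loss(up)$val - eval_loss(dn)$val) / (2 * eps)
    expect_equal(g[idx], num, tolerance = 1e-5,
                 info = sprintf("parameter %s", nm))
  }
})

test_that("training reduces the loss deterministically on a tiny world", {
  stats <- fx_tiny_stats()
  tcfg <- training_config(epochs = 60, seed = 3, learning_rate = 1e-3)
  tm <- train_design_model(stats, tiny_model_config(), tcfg)
  h <- tm$history
  expect_equal(nrow(h), 60L)
  expect_true(all(h$freq_term >= 0) && all(h$joint_term >= 0))
  expect_lt(tail(h$total, 1), h$total[1])
  tm2 <- train_design_model(stats, tiny_model_config(), tcfg)
  expect_identical(h$total, tm2$history$total)
})

test_that("repeat trainings give consistent output distributions", {
  # converged Loss2 plateau heights vary several-fold with the seed, so
  # run-to-run robustness is asserted on the designed output statistics
  # (what the repeated-training claim is about), not on raw loss values
  stats <- fx_tiny_stats()
  tm <- train_design_model(stats, tiny_model_config(),
                           training_config(epochs = 120, seed = 4,
                                           learning_rate = 1e-3,
                                           n_repeats = 3))
  expect_length(tm$repeats, 3L)
  pccs <- vapply(tm$repeats, function(r) {
    P <- model_probabilities(r, stats[[1]])
    cor(as.vector(P), as.vector(stats[[1]]$frequencies$f))
  }, 0)
  expect_true(all(pccs >= 0.95))
  expect_lt(max(pccs) - min(pccs), 0.02)
})

test_that("plateau early stop can terminate training", {
  stats <- fx_tiny_stats()
  tm <- train_design_model(stats, tiny_model_config(),
                           training_config(epochs = 500, seed = 5,
                                           learning_rate = 1e-3,
                                           plateau_tol = 0.5,
                                           plateau_window = 10L))
  expect_lt(nrow(tm$history), 500L)
})

test_that("design_from_model samples reproducibly from P", {
  stats <- fx_tiny_stats()
  tm <- train_design_model(stats, tiny_model_config(),
                           training_config(epochs = 30, seed = 6,
                                           learning_rate = 1e-3))
  d1 <- design_from_model(tm, stats[[1]], n = 40, seed = 8, allotype = "T1")
  d2 <- design_from_model(tm, stats[[1]], n = 40, seed = 8)
  expect_identical(d1$sequences, d2$sequences)
  expect_equal(d1$M, 40L)
  expect_equal(d1$L, 3L)
  validate_alignment(d1)
  # sampled frequencies track P at moderate n
  P <- model_probabilities(tm, stats[[1]])
  big <- design_from_model(tm, stats[[1]], n = 4000, seed = 9)
  emp <- site_frequencies(big, 0)
  expect_lt(max(abs(emp$f - P)), 0.04)
})
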