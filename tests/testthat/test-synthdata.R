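test_that("exact mixture statistics match full enumeration", {
  # K = 1: joints factorize exactly
  A <- 4; L <- 3
  set.seed(1)
  p <- matrix(rexp(L * A), L); p <- p / rowSums(p)
  s1 <- synthetic_spec(L, aa_alphabet(A), weights = 1, profiles = list(p))
  ex1 <- exact_statistics(s1)
  for (i in 1:L) for (j in 1:L) if (i != j)
    expect_equal(ex1$joint$fj[i, , j, ], tcrossprod(p[i, ], p[j, ]),
                 tolerance = 1e-14)

  # two-point mixture arithmetic
  pa <- matrix(1 / A, 2, A); pa[1, ] <- c(1, 0, 0, 0); pa[2, ] <- c(0, 1, 0, 0)
  pb <- matrix(1 / A, 2, A); pb[1, ] <- c(0, 0, 1, 0); pb[2, ] <- c(0, 0, 0, 1)
  s2 <- synthetic_spec(2, aa_alphabet(A), weights = c(0.5, 0.5),
                       profiles = list(pa, pb))
  ex2 <- exact_statistics(s2)
  expect_equal(ex2$joint$fj[1, 1, 2, 2], 0.5)      # f_12^{A,B}
  expect_equal(ex2$frequencies$f[[1, 1]] * ex2$frequencies$f[[2, 2]], 0.25)

  # random spec vs exhaustive enumeration over all A^L sequences
  set.seed(2)
  profs <- replicate(3, {
    m <- matrix(rexp(L * A), L); m / rowSums(m)
  }, simplify = FALSE)
  w <- rexp(3); w <- w / sum(w)
  sp <- synthetic_spec(L, aa_alphabet(A), weights = w, profiles = profs)
  ex <- exact_statistics(sp)
  grid <- as.matrix(expand.grid(rep(list(seq_len(A)), L)))
  prob <- vapply(seq_len(nrow(grid)), function(r) {
    sum(vapply(1:3, function(k)
      w[k] * prod(profs[[k]][cbind(1:L, grid[r, ])]), 0))
  }, 0)
  expect_equal(sum(prob), 1, tolerance = 1e-12)
  f_enum <- matrix(0, L, A)
  fj_enum <- array(0, dim = c(L, A, L, A))
  for (r in seq_len(nrow(grid))) {
    ix <- grid[r, ]
    for (i in 1:L) {
      f_enum[i, ix[i]] <- f_enum[i, ix[i]] + prob[r]
      for (j in 1:L) if (i != j)
        fj_enum[i, ix[i], j, ix[j]] <- fj_enum[i, ix[i], j, ix[j]] + prob[r]
    }
  }
  expect_equal(unname(ex$frequencies$f), f_enum, tolerance = 1e-12)
  for (i in 1:L) for (j in 1:L) if (i != j)
    expect_equal(ex$joint$fj[i, , j, ], fj_enum[i, , j, ], tolerance = 1e-12)
})

test_that("sample_msa reproduces the spec distribution", {
  A <- 6; L <- 4
  onehot <- matrix(0, L, A); onehot[, 2] <- 1
  s <- synthetic_spec(L, aa_alphabet(A), weights = 1, profiles = list(onehot))
  aln <- sample_msa(s, 20, seed = 1)
  expect_true(all(aln$sequences == strrep("C", L)))

  expect_identical(sample_msa(fx_strong()$spec, 50, seed = 3)$sequences,
                   sample_msa(fx_strong()$spec, 50, seed = 3)$sequences)

  big <- sample_msa(fx_strong()$spec, 5000, seed = 4)
  ex <- exact_statistics(fx_strong()$spec)
  emp <- site_frequencies(big, 0)
  expect_lt(max(abs(emp$f - ex$frequencies$f)), 0.025)

  # empirical coupling matches coupling from exact statistics
  reg <- regularize_statistics(ex, 1e-3)
  st <- evo_statistics(big, bg = "pooled", pseudocount = 1e-3)
  expect_gte(coupling_pcc(st$coupling, reg$coupling), 0.95)
})

test_that("estimator errors shrink with sample size", {
  ex <- exact_statistics(fx_strong()$spec)
  err <- vapply(c(500, 5000), function(M) {
    emp <- site_frequencies(sample_msa(fx_strong()$spec, M, seed = M), 0)
    max(abs(emp$f - ex$frequencies$f))
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("benchmark suite is reproducible and filter-compatible", {
  suite <- make_benchmark_suite(11)
  expect_length(suite$dataset, 3L)
  expect_true(all(vapply(suite$dataset, function(a) a$M, integer(1)) == 500L))
  expect_true(all(vapply(suite$dataset, function(a) a$L, integer(1)) == 9L))
  expect_length(filter_allotypes(suite$dataset, 200), 3L)
  # registry reproduces the alignments bit-identically
  for (nm in names(suite$registry)) {
    sp <- suite$registry[[nm]]
    expect_identical(sample_msa(sp, 500, seed = sp$sample_seed)$sequences,
                     suite$dataset[[nm]]$sequences)
  }
  # distinct allotypes
  expect_gt(length(unique(lapply(suite$dataset, `[[`, "sequences"))), 1L)
})

test_that("spec validation rejects broken simplexes", {
  p <- matrix(1 / 4, 2, 4)
  expect_error(synthetic_spec(2, aa_alphabet(4), weights = c(0.6, 0.6),
                              profiles = list(p, p)), "simplex")
  bad <- p; bad[1, ] <- bad[1, ] * 2
  expect_error(synthetic_spec(2, aa_alphabet(4), weights = 1,
                              profiles = list(bad)), "sum to 1")
})
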