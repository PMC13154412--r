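test_that("site frequencies match exhaustive counting", {
  # fixed small example: position-1 column (A, A, C)
  aln <- peptide_alignment(c("AA", "AC", "CA"), alphabet = aa_alphabet(4))
  fp <- site_frequencies(aln, pseudocount = 0)
  expect_equal(unname(fp$f[1, ]), c(2 / 3, 1 / 3, 0, 0))
  # degenerate column
  expect_equal(unname(site_frequencies(
    peptide_alignment(c("A", "A", "A"), alphabet = aa_alphabet(2)), 0)$f[1, ]),
    c(1, 0))
  # random alignments vs oracle, with and without pseudocount
  for (seed in 1:6) {
    a <- rand_alignment(12, 4, 5, seed)
    expect_equal(unname(site_frequencies(a, 0)$f),
                 oracle_site_freq(a$sequences, a$alphabet, 0),
                 tolerance = 1e-15)
    expect_equal(unname(site_frequencies(a, 1e-3)$f),
                 oracle_site_freq(a$sequences, a$alphabet, 1e-3),
                 tolerance = 1e-15)
  }
})

test_that("background frequencies cover all three modes", {
  aln <- rand_alignment(10, 4, 6, 1)
  expect_equal(unname(background_frequencies(aln, "uniform",
                                             alphabet = aln$alphabet)$q),
               rep(1 / 6, 6))
  expect_equal(unname(background_frequencies(aln, "pooled", 1e-3)$q),
               oracle_background(aln$sequences, aln$alphabet, 1e-3),
               tolerance = 1e-15)
  # 100% alanine closed form
  ala <- peptide_alignment(c("AAA", "AAA"))
  qa <- background_frequencies(ala, "pooled", 1e-3)$q[["A"]]
  expect_equal(qa, (1 - 1e-3) + 1e-3 / 20)
  expect_error(background_frequencies(aln, "user", q = rep(1, 6)),
               "sum to 1")
  expect_equal(sum(background_frequencies(aln, "pooled")$q), 1,
               tolerance = 1e-12)
})

test_that("conservation is the positional KL divergence in nats", {
  A <- 20
  q <- background_frequencies(mode = "uniform", alphabet = AA_ALPHABET)
  # f = q -> 0 ; single-residue column -> ln 20
  fp_flat <- frequency_profile(matrix(1 / A, 1, A))
  expect_equal(unname(conservation(fp_flat, q)), 0)
  onehot <- matrix(0, 1, A); onehot[1, 3] <- 1
  expect_equal(unname(conservation(frequency_profile(onehot), q)), log(20))
  # random case vs independent summation
  set.seed(2)
  f <- matrix(rexp(5 * 20), 5); f <- f / rowSums(f)
  qv <- rexp(20); qv <- qv / sum(qv)
  bg <- background_frequencies(mode = "user", q = qv, alphabet = AA_ALPHABET)
  expect_equal(unname(conservation(frequency_profile(f), bg)),
               oracle_conservation(f, qv), tolerance = 1e-12)
  expect_true(all(conservation(frequency_profile(f), bg) >= 0))
})

test_that("positional weights follow the log-odds formula", {
  q <- background_frequencies(mode = "uniform", alphabet = AA_ALPHABET)
  f <- matrix(1 / 20, 2, 20)
  expect_equal(unname(positional_weights(frequency_profile(f), q)),
               matrix(0, 2, 20))
  f2 <- matrix(1 / 20, 1, 20); f2[1, 1] <- 0.5
  f2 <- f2 / sum(f2)  # keep simplex but perturbs other entries
  # direct closed form at f = 0.5, q = 0.05
  kv <- log((0.5 * (1 - 0.05)) / (0.05 * (1 - 0.5)))
  expect_equal(kv, log(19))
  set.seed(3)
  f3 <- matrix(rexp(4 * 20), 4); f3 <- f3 / rowSums(f3)
  expect_equal(unname(positional_weights(frequency_profile(f3), q)),
               oracle_weights(f3, rep(0.05, 20)), tolerance = 1e-12)
  # degenerate frequency names the offending cell
  bad <- matrix(0, 1, 20); bad[1, 5] <- 1
  expect_error(positional_weights(frequency_profile(bad), q),
               "position 1, residue")
})

test_that("joint frequencies satisfy their structural invariants", {
  # single sequence example
  aln1 <- peptide_alignment("AC", alphabet = aa_alphabet(3))
  jf1 <- joint_frequencies(aln1, 0)
  expect_equal(jf1$fj[1, 1, 2, 2], 1)
  expect_equal(sum(jf1$fj[1, , 2, ]), 1)
  expect_equal(sum(jf1$fj[1, , 2, ] != 0), 1L)

  for (seed in 1:5) {
    a <- rand_alignment(15, 4, 5, seed)
    for (pc in c(0, 1e-3)) {
      jf <- joint_frequencies(a, pc)$fj
      f <- site_frequencies(a, pc)$f
      expect_equal(jf, oracle_joint(a$sequences, a$alphabet, pc),
                   tolerance = 1e-15)
      for (i in 1:4) for (j in 1:4) {
        expect_equal(sum(jf[i, , j, ]), 1, tolerance = 1e-12)
        # marginal consistency and symmetry
        expect_equal(rowSums(jf[i, , j, ]), unname(f[i, ]), tolerance = 1e-12)
        expect_equal(jf[i, , j, ], t(jf[j, , i, ]), tolerance = 1e-15)
      }
      # diagonal blocks carry the delta convention
      offdiag <- jf[1, , 1, ]; diag(offdiag) <- 0
      expect_true(all(offdiag == 0))
    }
  }
})

test_that("coupling matrix matches the weighted double sum", {
  # exact product joint -> zero off-diagonal coupling
  set.seed(4)
  f <- matrix(rexp(3 * 20), 3); f <- f / rowSums(f)
  f <- 0.9 * f + 0.1 / 20  # keep strictly inside (0,1)
  fj <- array(0, dim = c(3, 20, 3, 20))
  for (i in 1:3) for (j in 1:3) {
    fj[i, , j, ] <- tcrossprod(f[i, ], f[j, ])
    if (i == j) {
      blk <- matrix(0, 20, 20); diag(blk) <- f[i, ]
      fj[i, , i, ] <- blk
    }
  }
  fp <- frequency_profile(f)
  bg <- background_frequencies(mode = "uniform", alphabet = AA_ALPHABET)
  kw <- positional_weights(fp, bg)
  C <- coupling_matrix(joint_frequencies_from_array(fj), fp, kw)
  expect_equal(C[upper.tri(C)], rep(0, 3), tolerance = 1e-14)

  # two-column alignment {AB, CD} x 5 against the 400-term brute force
  a <- peptide_alignment(rep(c("AC", "DE"), 5))
  st <- evo_statistics(a, bg = "pooled", pseudocount = 1e-3)
  expect_equal(st$coupling,
               oracle_coupling(st$joint$fj, st$frequencies$f, st$weights),
               tolerance = 1e-12)
  expect_true(isSymmetric(st$coupling))
  expect_true(all(st$coupling >= 0))

  # permuting sequence order leaves coupling unchanged
  set.seed(5)
  b <- rand_alignment(20, 4, 6, 6)
  bp <- peptide_alignment(sample(b$sequences), alphabet = b$alphabet)
  expect_equal(evo_statistics(b)$coupling, evo_statistics(bp)$coupling)
})

test_that("coupling_pcc follows the textbook correlation", {
  set.seed(7)
  X <- crossprod(matrix(rnorm(9), 3))
  Y <- crossprod(matrix(rnorm(9), 3))
  expect_equal(coupling_pcc(X, X), 1)
  expect_equal(coupling_pcc(X, 2 * X + 3), 1)
  sel <- upper.tri(X, diag = TRUE)
  expect_equal(coupling_pcc(X, Y), oracle_pcc(X[sel], Y[sel]),
               tolerance = 1e-12)
  expect_error(coupling_pcc(X[1:2, 1:2], Y[1:2, 1:2],
                            include_diagonal = FALSE), "at least 3")
  Z <- matrix(1, 3, 3)
  expect_error(coupling_pcc(Z, Y), "zero variance")
})

test_that("independent columns lose coupling relative to a coupled mixture", {
  strong <- fx_strong()$spec
  coupled <- sample_msa(strong, 5000, seed = 21)
  # column-independent sampling from the same marginals
  ex <- exact_statistics(strong)
  indep <- sample_fs(frequency_profile(ex$frequencies$f,
                                       alphabet = strong$alphabet),
                     n = 5000, seed = 22)
  offmean <- function(aln) {
    C <- evo_statistics(aln)$coupling
    mean(C[row(C) != col(C)])
  }
  expect_lt(offmean(indep), 0.01 * offmean(coupled))
})

test_that("anchor positions carry the top conservation values", {
  suite <- fx_bench()
  for (nm in names(suite$registry)) {
    st <- evo_statistics(suite$dataset[[nm]])
    anchors <- suite$registry[[nm]]$anchor_positions
    top <- order(st$conservation, decreasing = TRUE)[seq_along(anchors)]
    expect_setequal(top, anchors)
  }
})

test_that("long-format joint export matches the tensor", {
  a <- rand_alignment(8, 3, 4, 9)
  jf <- joint_frequencies(a, 1e-3)
  tab <- joint_table(jf)
  expect_equal(nrow(tab), 3^2 * 4^2)
  r <- tab[tab$i == 1 & tab$j == 3 & tab$a == "C" & tab$b == "D", ]
  expect_equal(r$frequency, jf$fj[1, 2, 3, 3])
  # every (i, j) block sums to 1
  expect_equal(as.vector(tapply(tab$frequency,
                                interaction(tab$i, tab$j), sum)),
               rep(1, 9), tolerance = 1e-12)
})

test_that("logo export is normalized per position", {
  a <- rand_alignment(10, 3, 20, 8)
  tab <- logo_table(site_frequencies(a))
  expect_equal(as.vector(tapply(tab$frequency, tab$position, sum)),
               rep(1, 3), tolerance = 1e-12)
})
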