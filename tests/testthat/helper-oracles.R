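# Independent brute-force oracles: naive loops over sequences and residue
# pairs, written without reference to the package internals.  All expected
# values in the oracle-equivalence tests are computed by these.

oracle_site_freq <- function(seqs, alphabet, pc = 0) {
  M <- length(seqs)
  L <- nchar(seqs[1])
  A <- length(alphabet)
  f <- matrix(0, L, A)
  for (s in seqs) for (i in seq_len(L)) {
    a <- match(substr(s, i, i), alphabet)
    f[i, a] <- f[i, a] + 1
  }
  (1 - pc) * f / M + pc / A
}

oracle_background <- function(seqs, alphabet, pc = 0) {
  A <- length(alphabet)
  cnt <- numeric(A)
  for (s in seqs) for (ch in strsplit(s, "")[[1]])
    cnt[match(ch, alphabet)] <- cnt[match(ch, alphabet)] + 1
  (1 - pc) * cnt / sum(cnt) + pc / A
}

oracle_joint <- function(seqs, alphabet, pc = 0) {
  M <- length(seqs)
  L <- nchar(seqs[1])
  A <- length(alphabet)
  fj <- array(0, dim = c(L, A, L, A))
  for (s in seqs) {
    ix <- match(strsplit(s, "")[[1]], alphabet)
    for (i in seq_len(L)) for (j in seq_len(L)) if (i != j)
      fj[i, ix[i], j, ix[j]] <- fj[i, ix[i], j, ix[j]] + 1
  }
  fj <- (1 - pc) * fj / M + pc / (A * A)
  f1 <- oracle_site_freq(seqs, alphabet, pc)
  for (i in seq_len(L)) {
    blk <- matrix(0, A, A)
    diag(blk) <- f1[i, ]
    fj[i, , i, ] <- blk
  }
  fj
}

oracle_conservation <- function(f, q) {
  out <- numeric(nrow(f))
  for (i in seq_len(nrow(f))) {
    s <- 0
    for (a in seq_len(ncol(f)))
      if (f[i, a] > 0) s <- s + f[i, a] * log(f[i, a] / q[a])
    out[i] <- s
  }
  out
}

oracle_weights <- function(f, q) {
  k <- matrix(0, nrow(f), ncol(f))
  for (i in seq_len(nrow(f))) for (a in seq_len(ncol(f)))
    k[i, a] <- log((f[i, a] * (1 - q[a])) / (q[a] * (1 - f[i, a])))
  k
}

oracle_coupling <- function(fj, f, k) {
  L <- nrow(f)
  A <- ncol(f)
  C <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    s <- 0
    for (a in seq_len(A)) for (b in seq_len(A))
      s <- s + (k[i, a] * k[j, b])^2 * (fj[i, a, j, b] - f[i, a] * f[j, b])^2
    C[i, j] <- s
  }
  C
}

oracle_pcc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_objective <- function(dC, nC, dw) {
  E <- 0
  for (i in seq_len(nrow(dC))) for (j in seq_len(ncol(dC))) {
    d <- dC[i, j] - nC[i, j]
    E <- E + if (i == j) dw * d * d else d * d
  }
  E
}

# random gap-free alignment over the first A letters
rand_alignment <- function(M, L, A, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alpha <- aa_alphabet(A)
  seqs <- vapply(seq_len(M), function(i)
    paste(sample(alpha, L, replace = TRUE), collapse = ""), "")
  peptide_alignment(seqs, alphabet = alpha)
}
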