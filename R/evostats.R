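#' Per-position residue frequencies
#'
#' Estimates the site frequency matrix `f_ia` (positions in rows, residues in
#' columns, alphabetical residue order).  A uniform-mixture pseudocount
#' regularizes the estimate,
#' `f_ia = (1 - pc) * count_ia / M + pc / A`,
#' so that downstream logarithms (conservation, positional weights) stay
#' finite; `pc = 0` recovers the raw maximum-likelihood frequencies.
#'
#' @param aln a [peptide_alignment].
#' @param pseudocount uniform mixing weight in `[0, 1)` (default `1e-3`).
#' @return Object of class `frequency_profile`: list with `f` (L x A matrix,
#'   rows summing to 1), `pseudocount`, `M_source`, `alphabet`.
#' @export
site_frequencies <- function(aln, pseudocount = 1e-3) {
  validate_alignment(aln)
  stopifnot(pseudocount >= 0, pseudocount < 1)
  enc <- encode_alignment(aln)
  A <- length(aln$alphabet)
  counts <- vapply(seq_len(aln$L),
                   function(i) tabulate(enc[, i] + 1L, nbins = A),
                   numeric(A))
  f <- (1 - pseudocount) * t(counts) / aln$M + pseudocount / A
  dimnames(f) <- list(position = seq_len(aln$L), residue = aln$alphabet)
  structure(list(f = f, pseudocount = pseudocount, M_source = aln$M,
                 alphabet = aln$alphabet),
            class = "frequency_profile")
}

#' Build a frequency profile from an explicit matrix
#'
#' Used by the synthetic-data module (closed-form mixture frequencies) and by
#' tests.  Rows must sum to 1.
#'
#' @param f L x A matrix of frequencies, rows on the simplex.
#' @param pseudocount pseudocount recorded as provenance (already applied).
#' @param M_source sequence count the matrix was estimated from (NA if exact).
#' @param alphabet residue alphabet matching `ncol(f)`.
#' @return A `frequency_profile`.
#' @export
frequency_profile <- function(f, pseudocount = 0, M_source = NA_integer_,
                              alphabet = aa_alphabet(ncol(f))) {
  stopifnot(is.matrix(f), ncol(f) == length(alphabet))
  if (max(abs(rowSums(f) - 1)) > 1e-9) stop("profile rows must sum to 1")
  dimnames(f) <- list(position = seq_len(nrow(f)), residue = alphabet)
  structure(list(f = f, pseudocount = pseudocount, M_source = M_source,
                 alphabet = alphabet),
            class = "frequency_profile")
}

#' Background residue frequencies
#'
#' The background `q_a` entering conservation and positional weights.  Modes:
#' `"pooled"` (default) pools residue counts over all sequences and positions
#' of the input — conservation then measures deviation from the family's own
#' composition; `"uniform"` uses `1/A`; `"user"` takes a supplied vector.
#' The pooled mode applies the same uniform-mixture pseudocount as
#' [site_frequencies()] so all entries are strictly inside (0, 1).
#'
#' @param x a [peptide_alignment] or [allotype_dataset] (ignored for
#'   `mode = "uniform"` with explicit `alphabet`).
#' @param mode one of `"pooled"`, `"uniform"`, `"user"`.
#' @param pseudocount uniform mixing weight for the pooled estimate.
#' @param q user-supplied probability vector (mode `"user"`).
#' @param alphabet residue alphabet.
#' @return Object of class `background_frequencies`: list with `q` (named,
#'   sums to 1), `source`.
#' @export
background_frequencies <- function(x = NULL, mode = c("pooled", "uniform", "user"),
                                   pseudocount = 1e-3, q = NULL,
                                   alphabet = NULL) {
  mode <- match.arg(mode)
  if (is.null(alphabet)) {
    alphabet <- if (inherits(x, "peptide_alignment")) x$alphabet
      else if (inherits(x, "allotype_dataset")) x[[1L]]$alphabet
      else AA_ALPHABET
  }
  A <- length(alphabet)
  qv <- switch(mode,
    uniform = rep(1 / A, A),
    user = {
      if (is.null(q) || length(q) != A) stop("mode 'user' requires q of length A")
      if (abs(sum(q) - 1) > 1e-9) stop("user background must sum to 1")
      q
    },
    pooled = {
      alns <- if (inherits(x, "allotype_dataset")) unclass(x)
        else if (inherits(x, "peptide_alignment")) list(x)
        else stop("pooled mode requires an alignment or dataset")
      counts <- numeric(A)
      for (a in alns) counts <- counts + tabulate(encode_alignment(a) + 1L, nbins = A)
      if (sum(counts) == 0) stop("empty dataset in pooled mode")
      (1 - pseudocount) * counts / sum(counts) + pseudocount / A
    })
  names(qv) <- alphabet
  structure(list(q = qv, source = mode), class = "background_frequencies")
}

#' First-order positional conservation (KL divergence)
#'
#' `C_i = sum_a f_ia * ln(f_ia / q_a)`, the Kullback-Leibler divergence of the
#' observed position-i residue distribution from the background, in nats.
#' The convention `0 * ln(0/q) = 0` applies when `pseudocount = 0` leaves
#' exact zeros in the profile.  `C_i >= 0`, with equality iff `f_i = q`.
#'
#' @param fp a `frequency_profile`.
#' @param bg a `background_frequencies`.
#' @return Numeric vector of length L (named by position).
#' @export
conservation <- function(fp, bg) {
  stopifnot(inherits(fp, "frequency_profile"), inherits(bg, "background_frequencies"))
  f <- fp$f
  q <- bg$q
  if (ncol(f) != length(q)) stop("profile and background alphabet sizes differ")
  term <- f * log(sweep(f, 2L, q, "/"))
  term[f == 0] <- 0
  C <- rowSums(term)
  names(C) <- rownames(f)
  C
}

#' Positional log-odds weights
#'
#' `k_ia = ln[ f_ia (1 - q_a) / ( q_a (1 - f_ia) ) ]`, the coefficient
#' weighting how surprising residue a's frequency at position i is relative
#' to background; it vanishes exactly when `f_ia = q_a`.  Requires all
#' frequencies strictly inside (0, 1), which the pseudocount guarantees.
#'
#' @param fp a `frequency_profile`.
#' @param bg a `background_frequencies`.
#' @return L x A matrix of weights.
#' @export
positional_weights <- function(fp, bg) {
  stopifnot(inherits(fp, "frequency_profile"), inherits(bg, "background_frequencies"))
  f <- fp$f
  q <- bg$q
  if (ncol(f) != length(q)) stop("profile and background alphabet sizes differ")
  degenerate <- f <= 0 | f >= 1
  if (any(degenerate)) {
    idx <- which(degenerate, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "positional_weights undefined at f in {0,1}: position %s, residue %s; use a pseudocount",
      rownames(f)[idx[1L]], colnames(f)[idx[2L]]))
  }
  if (any(q <= 0 | q >= 1)) stop("background entries must be strictly in (0,1)")
  k <- log(sweep(f, 2L, 1 - q, "*")) - log(sweep(1 - f, 2L, q, "*"))
  dimnames(k) <- dimnames(f)
  k
}

#' Pairwise joint residue frequencies
#'
#' Estimates the rank-4 tensor `f_ij^ab` (dimension L x A x L x A): the
#' fraction of sequences carrying residue a at position i and residue b at
#' position j simultaneously.  Off-diagonal blocks are regularized as
#' `(1 - pc) * count / M + pc / A^2`; diagonal blocks (i = j) follow the
#' delta convention — zero off the 20-entry diagonal, and
#' `(1 - pc) * count_ia / M + pc / A` on it — so every (i, j) block still
#' sums to 1 and marginalizing over b recovers the regularized `f_ia`
#' exactly (off-diagonal blocks) or up to the shared pseudocount scheme.
#'
#' @param aln a [peptide_alignment].
#' @param pseudocount uniform mixing weight (default `1e-3`).
#' @return Object of class `joint_frequencies`: list with `fj` (array
#'   `c(L, A, L, A)`), `pseudocount`, `M_source`, `alphabet`.
#' @export
joint_frequencies <- function(aln, pseudocount = 1e-3) {
  validate_alignment(aln)
  stopifnot(pseudocount >= 0, pseudocount < 1)
  enc <- encode_alignment(aln)
  L <- aln$L
  A <- length(aln$alphabet)
  fj <- array(0, dim = c(L, A, L, A))
  f1 <- vapply(seq_len(L), function(i) tabulate(enc[, i] + 1L, nbins = A) / aln$M,
               numeric(A))  # A x L raw marginals
  for (i in seq_len(L)) {
    fj[i, , i, ][cbind(seq_len(A), seq_len(A))] <-
      (1 - pseudocount) * f1[, i] + pseudocount / A
    if (i < L) for (j in seq((i + 1L), L)) {
      cnt <- tabulate(enc[, i] * A + enc[, j] + 1L, nbins = A * A)
      block <- (1 - pseudocount) * matrix(cnt, nrow = A, byrow = TRUE) / aln$M +
        pseudocount / (A * A)
      fj[i, , j, ] <- block
      fj[j, , i, ] <- t(block)
    }
  }
  joint_frequencies_from_array(fj, pseudocount = pseudocount,
                               M_source = aln$M, alphabet = aln$alphabet)
}

#' Wrap a joint-frequency array
#'
#' @param fj array `c(L, A, L, A)`; every (i, j) block must sum to 1.
#' @param pseudocount provenance record.
#' @param M_source provenance record.
#' @param alphabet residue alphabet.
#' @return A `joint_frequencies` object.
#' @export
joint_frequencies_from_array <- function(fj, pseudocount = 0,
                                         M_source = NA_integer_,
                                         alphabet = aa_alphabet(dim(fj)[2L])) {
  stopifnot(length(dim(fj)) == 4L, dim(fj)[1L] == dim(fj)[3L],
            dim(fj)[2L] == dim(fj)[4L])
  structure(list(fj = fj, pseudocount = pseudocount, M_source = M_source,
                 alphabet = alphabet),
            class = "joint_frequencies")
}

#' Coupling-conservation matrix
#'
#' `C_ij = sum_{a,b} (k_ia k_jb)^2 (f_ij^ab - f_ia f_jb)^2`: the squared
#' deviation of joint frequencies from the product of marginals, weighted by
#' squared positional log-odds.  Symmetric and non-negative; off-diagonal
#' entries vanish for statistically independent columns (in the large-M
#' limit), while diagonal entries are dominated by first-order conservation.
#'
#' @param jf a `joint_frequencies` object.
#' @param fp the matching `frequency_profile` (same pseudocount provenance).
#' @param kw L x A matrix of positional weights from [positional_weights()].
#' @return L x L symmetric matrix.
#' @export
coupling_matrix <- function(jf, fp, kw) {
  stopifnot(inherits(jf, "joint_frequencies"), inherits(fp, "frequency_profile"))
  f <- fp$f
  L <- nrow(f)
  A <- ncol(f)
  if (!all(dim(jf$fj) == c(L, A, L, A)) || !all(dim(kw) == c(L, A)))
    stop("shape mismatch between joint frequencies, profile, and weights")
  k2 <- kw^2
  C2 <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(i)) {
    D <- jf$fj[i, , j, ] - tcrossprod(f[i, ], f[j, ])
    C2[i, j] <- C2[j, i] <- sum(tcrossprod(k2[i, ], k2[j, ]) * D * D)
  }
  C2
}

#' Pearson correlation of two coupling matrices
#'
#' Correlates the flattened upper triangles of two L x L coupling matrices —
#' the agreement metric used to compare designed and native sets.  The
#' diagonal is included by default (it carries the strong first-order
#' signal); set `include_diagonal = FALSE` to restrict to genuine
#' off-diagonal coupling.
#'
#' @param A,B symmetric L x L matrices of equal dimension.
#' @param include_diagonal include the diagonal in the correlated elements.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
coupling_pcc <- function(A, B, include_diagonal = TRUE) {
  if (!all(dim(A) == dim(B))) stop("coupling matrices must share dimensions")
  sel <- upper.tri(A, diag = include_diagonal)
  x <- A[sel]
  y <- B[sel]
  if (length(x) < 3L) stop("need at least 3 included elements")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in included elements")
  stats::cor(x, y)
}

#' Full evolutionary-statistics stack for one alignment
#'
#' Convenience wrapper computing, with one shared pseudocount and background,
#' everything the design routes consume: site frequencies, background,
#' conservation, positional weights, joint frequencies, and the coupling
#' matrix.
#'
#' @param aln a [peptide_alignment].
#' @param bg background mode (`"pooled"`, `"uniform"`) or a ready
#'   `background_frequencies` object.
#' @param pseudocount shared uniform-mixture weight (default `1e-3`).
#' @return Object of class `evo_statistics`: list with `frequencies` (profile),
#'   `background`, `conservation`, `weights`, `joint` and `coupling`, plus
#'   `pseudocount` and `allotype`.
#' @export
evo_statistics <- function(aln, bg = "pooled", pseudocount = 1e-3) {
  fp <- site_frequencies(aln, pseudocount)
  if (!inherits(bg, "background_frequencies"))
    bg <- background_frequencies(aln, mode = bg, pseudocount = pseudocount)
  kw <- positional_weights(fp, bg)
  jf <- joint_frequencies(aln, pseudocount)
  structure(list(frequencies = fp, background = bg,
                 conservation = conservation(fp, bg), weights = kw,
                 joint = jf, coupling = coupling_matrix(jf, fp, kw),
                 pseudocount = pseudocount, allotype = aln$allotype),
            class = "evo_statistics")
}

#' @export
print.evo_statistics <- function(x, ...) {
  L <- nrow(x$frequencies$f)
  cat(sprintf("evo_statistics: L=%d, alphabet=%d, pseudocount=%g, background=%s\n",
              L, length(x$background$q), x$pseudocount, x$background$source))
  cat("conservation C_i (nats): ",
      paste(sprintf("%.3f", x$conservation), collapse = " "), "\n")
  invisible(x)
}

#' Export joint frequencies in long tabular format
#'
#' One row per (i, j, a, b) with the joint frequency `f_ij^ab`; the
#' documented text serialization of the rank-4 tensor (32,400 rows at
#' L = 9, A = 20).
#'
#' @param jf a `joint_frequencies` object.
#' @param path optional CSV path.
#' @return data.frame with columns `i`, `j`, `a`, `b`, `frequency`.
#' @export
joint_table <- function(jf, path = NULL) {
  stopifnot(inherits(jf, "joint_frequencies"))
  d <- dim(jf$fj)
  L <- d[1L]
  A <- d[2L]
  grid <- expand.grid(a = seq_len(A), i = seq_len(L),
                      b = seq_len(A), j = seq_len(L))
  out <- data.frame(i = grid$i, j = grid$j,
                    a = jf$alphabet[grid$a], b = jf$alphabet[grid$b],
                    frequency = as.vector(jf$fj[cbind(grid$i, grid$a,
                                                      grid$j, grid$b)]))
  if (!is.null(path))
    utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  out
}

#' Export per-position frequencies in logo-ready long format
#'
#' @param fp a `frequency_profile`.
#' @param path optional CSV path; when given the table is written there.
#' @return data.frame with columns `position`, `residue`, `frequency`.
#' @export
logo_table <- function(fp, path = NULL) {
  stopifnot(inherits(fp, "frequency_profile"))
  L <- nrow(fp$f)
  A <- ncol(fp$f)
  out <- data.frame(position = rep(seq_len(L), each = A),
                    residue = rep(fp$alphabet, times = L),
                    frequency = as.vector(t(fp$f)))
  if (!is.null(path))
    utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  out
}
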