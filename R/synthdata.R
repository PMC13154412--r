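#' Mixture-of-profiles specification for synthetic alignments
#'
#' The generator draws each sequence by first picking a mixture component
#' `k ~ w` and then sampling every position independently from that
#' component's profile `p_k`.  Mixing K > 1 contrasting product
#' distributions induces pairwise covariation between positions while
#' keeping both the site frequencies and the joint frequencies available in
#' closed form (see [exact_statistics()]), so every downstream estimator and
#' design route can be checked against an exact oracle.  Designated anchor
#' positions receive low-entropy (highly conserved) profiles, mimicking the
#' P1/P4/P6/P9 pocket anchors of MHCII binding cores.
#'
#' @param L alignment length (default 9).
#' @param alphabet residue alphabet (smaller alphabets allowed for
#'   enumeration oracles).
#' @param weights mixture weights, summing to 1.
#' @param profiles list of K matrices, each L x A with rows on the simplex.
#' @param anchor_positions integer positions documented as anchors.
#' @param name label used when the spec stands in for an allotype.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(L, alphabet = AA_ALPHABET, weights, profiles,
                           anchor_positions = integer(0), name = "synthetic") {
  A <- length(alphabet)
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
    stop("mixture weights must be a point on the simplex")
  if (length(profiles) != length(weights)) stop("one profile per weight required")
  for (p in profiles) {
    stopifnot(is.matrix(p), nrow(p) == L, ncol(p) == A)
    if (max(abs(rowSums(p) - 1)) > 1e-9) stop("profile rows must sum to 1")
  }
  structure(list(L = L, alphabet = alphabet, K = length(weights),
                 weights = weights, profiles = profiles,
                 anchor_positions = as.integer(anchor_positions), name = name),
            class = "synthetic_spec")
}

#' Closed-form statistics of a mixture spec
#'
#' `f_ia = sum_k w_k p_k[i,a]` and, for i != j,
#' `f_ij^ab = sum_k w_k p_k[i,a] p_k[j,b]`; diagonal blocks follow the
#' delta convention.  With K = 1 the joints factorize exactly (no coupling);
#' with K > 1 the mixture induces `f_ij^ab - f_ia f_jb != 0`.
#'
#' @param spec a [synthetic_spec].
#' @return List with `frequencies` (a `frequency_profile`, pseudocount 0) and
#'   `joint` (a `joint_frequencies`, pseudocount 0).
#' @export
exact_statistics <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$L
  A <- length(spec$alphabet)
  f <- Reduce(`+`, Map(function(w, p) w * p, spec$weights, spec$profiles))
  fj <- array(0, dim = c(L, A, L, A))
  for (i in seq_len(L)) {
    fj[i, , i, ][cbind(seq_len(A), seq_len(A))] <- f[i, ]
    if (i < L) for (j in seq((i + 1L), L)) {
      block <- Reduce(`+`, Map(function(w, p) w * tcrossprod(p[i, ], p[j, ]),
                               spec$weights, spec$profiles))
      fj[i, , j, ] <- block
      fj[j, , i, ] <- t(block)
    }
  }
  list(frequencies = frequency_profile(f, pseudocount = 0, alphabet = spec$alphabet),
       joint = joint_frequencies_from_array(fj, pseudocount = 0,
                                            alphabet = spec$alphabet))
}

#' Apply the package pseudocount scheme to exact statistics
#'
#' Transforms closed-form (pseudocount 0) statistics onto the same
#' regularized scale the estimators produce, so exact-oracle coupling
#' matrices are comparable with estimated ones.
#'
#' @param stats list as returned by [exact_statistics()].
#' @param pseudocount uniform mixing weight.
#' @return List with regularized `frequencies`, `joint`, plus `weights` and
#'   `coupling` computed against the pooled background of the exact profile.
#' @export
regularize_statistics <- function(stats, pseudocount = 1e-3) {
  f0 <- stats$frequencies$f
  A <- ncol(f0)
  L <- nrow(f0)
  f <- (1 - pseudocount) * f0 + pseudocount / A
  fj0 <- stats$joint$fj
  fj <- (1 - pseudocount) * fj0 + pseudocount / (A * A)
  for (i in seq_len(L)) {
    blk <- matrix(0, A, A)
    blk[cbind(seq_len(A), seq_len(A))] <- (1 - pseudocount) * f0[i, ] + pseudocount / A
    fj[i, , i, ] <- blk
  }
  fp <- frequency_profile(f, pseudocount = pseudocount,
                          alphabet = stats$frequencies$alphabet)
  jf <- joint_frequencies_from_array(fj, pseudocount = pseudocount,
                                     alphabet = stats$frequencies$alphabet)
  # pooled background of the exact model: average of f over positions
  q <- (1 - pseudocount) * colMeans(f0) + pseudocount / A
  bg <- structure(list(q = q / sum(q), source = "pooled"),
                  class = "background_frequencies")
  kw <- positional_weights(fp, bg)
  list(frequencies = fp, joint = jf, background = bg, weights = kw,
       coupling = coupling_matrix(jf, fp, kw))
}

#' Sample a synthetic alignment from a mixture spec
#'
#' @param spec a [synthetic_spec].
#' @param M number of sequences.
#' @param seed RNG seed (required for reproducibility).
#' @return A [peptide_alignment] labelled with the spec name.
#' @export
sample_msa <- function(spec, M, seed) {
  stopifnot(inherits(spec, "synthetic_spec"), M >= 1)
  set.seed(seed)
  A <- length(spec$alphabet)
  comp <- sample.int(spec$K, M, replace = TRUE, prob = spec$weights)
  enc <- matrix(0L, nrow = M, ncol = spec$L)
  for (k in seq_len(spec$K)) {
    rows <- which(comp == k)
    if (!length(rows)) next
    p <- spec$profiles[[k]]
    for (i in seq_len(spec$L))
      enc[rows, i] <- sample.int(A, length(rows), replace = TRUE, prob = p[i, ]) - 1L
  }
  decode_alignment(enc, allotype = spec$name, alphabet = spec$alphabet)
}

# Low-entropy anchor row: mass `peak` on one residue, remainder spread
anchor_row <- function(A, idx, peak = 0.9) {
  p <- rep((1 - peak) / (A - 1), A)
  p[idx] <- peak
  p
}

# Component-specific variable row: moderate preference for one residue
variable_row <- function(A, idx, peak = 0.7) {
  p <- rep((1 - peak) / (A - 1), A)
  p[idx] <- peak
  p
}

#' Strongly coupled two-component mixture spec
#'
#' The canonical maximal-coupling mixture: two equally weighted components
#' sharing low-entropy anchor profiles but preferring disjoint residues
#' (mass `peak`) at every non-anchor position.  Pairwise deviations
#' `f_ij^ab - f_ia f_jb` then reach the order of `peak^2 / 4` at all
#' non-anchor pairs, giving native coupling values of order 1-10 — the
#' regime the annealing schedule is designed for.  Used by the
#' coupling-recovery tests and as the "strongly coupled" contrast in the
#' independence-limit property.
#'
#' @param L alignment length.
#' @param alphabet residue alphabet.
#' @param seed seed for choosing anchor/preferred residues.
#' @param anchor_positions anchored (conserved) positions.
#' @param peak profile mass on the preferred residue.
#' @return A [synthetic_spec] with `K = 2`.
#' @export
strongly_coupled_spec <- function(L = 9L, alphabet = AA_ALPHABET, seed = 99L,
                                  anchor_positions = c(1L, 4L, 6L, 9L),
                                  peak = 0.9) {
  set.seed(seed)
  A <- length(alphabet)
  anchor_positions <- anchor_positions[anchor_positions <= L]
  anchor_res <- sample.int(A, length(anchor_positions), replace = TRUE)
  # preferred residues distinct across positions and components wherever the
  # alphabet allows: repeated preferences would concentrate the pooled
  # background on a few residues, shrink the k weights, and with them the
  # whole coupling scale
  if (A >= 2L * L) {
    perm <- sample.int(A, 2L * L)
    pref1 <- perm[seq_len(L)]
    pref2 <- perm[L + seq_len(L)]
  } else {
    pref1 <- sample.int(A, L, replace = A < L)
    pref2 <- ((pref1 + A %/% 2 - 1L) %% A) + 1L
  }
  mk <- function(prefs) {
    p <- matrix(1 / A, L, A)
    for (ai in seq_along(anchor_positions))
      p[anchor_positions[ai], ] <- anchor_row(A, anchor_res[ai], peak)
    for (i in setdiff(seq_len(L), anchor_positions))
      p[i, ] <- anchor_row(A, prefs[i], peak)
    p
  }
  synthetic_spec(L, alphabet, weights = c(0.5, 0.5),
                 profiles = list(mk(pref1), mk(pref2)),
                 anchor_positions = anchor_positions,
                 name = "strongly-coupled")
}

#' Benchmark suite of synthetic allotypes
#'
#' Builds a reproducible multi-allotype dataset of >= 3 synthetic
#' "allotypes" with distinct anchors and coupling strengths, each with at
#' least 200 sequences (so all pass the default [filter_allotypes()]
#' threshold), plus the spec registry giving oracle access to the exact
#' generating statistics.  Anchor positions default to the binding-core
#' pockets P1, P4, P6, P9; coupling is induced at the non-anchor positions
#' by giving each mixture component its own residue preferences there, with
#' per-allotype contrast controlling coupling strength.
#'
#' @param seed base RNG seed; per-allotype sampling seeds derive from it.
#' @param n_allotypes number of synthetic allotypes (default 3).
#' @param M sequences per allotype (default 500).
#' @param L alignment length (default 9).
#' @param alphabet residue alphabet.
#' @return List with `dataset` (an [allotype_dataset]) and `registry`
#'   (named list of [synthetic_spec]).
#' @export
make_benchmark_suite <- function(seed, n_allotypes = 3L, M = 500L, L = 9L,
                                 alphabet = AA_ALPHABET) {
  A <- length(alphabet)
  set.seed(seed)
  anchor_sets <- list(c(1L, 4L, 6L, 9L), c(1L, 4L, 6L, 9L), c(1L, 3L, 6L, 9L))
  peaks <- c(0.90, 0.85, 0.80)        # anchor conservation strength
  contrasts <- c(0.75, 0.65, 0.55)    # component contrast -> coupling strength
  Ks <- c(3L, 3L, 4L)
  registry <- list()
  alns <- list()
  for (s in seq_len(n_allotypes)) {
    idx <- ((s - 1L) %% 3L) + 1L
    anchors <- pmin(anchor_sets[[idx]], L)
    K <- Ks[idx]
    anchor_res <- sample.int(A, length(anchors), replace = TRUE)
    profiles <- vector("list", K)
    for (k in seq_len(K)) {
      p <- matrix(1 / A, nrow = L, ncol = A)
      for (ai in seq_along(anchors))
        p[anchors[ai], ] <- anchor_row(A, anchor_res[ai], peaks[idx])
      for (i in setdiff(seq_len(L), anchors))
        p[i, ] <- variable_row(A, sample.int(A, 1L), contrasts[idx])
      profiles[[k]] <- p
    }
    name <- sprintf("SYN-%02d", s)
    spec <- synthetic_spec(L, alphabet, weights = rep(1 / K, K),
                           profiles = profiles, anchor_positions = anchors,
                           name = name)
    spec$sample_seed <- seed + 1000L * s
    registry[[name]] <- spec
    alns[[name]] <- sample_msa(spec, M, seed = spec$sample_seed)
  }
  list(dataset = allotype_dataset(alns), registry = registry)
}
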