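#' Frequency-sampling (FS) design
#'
#' Generates artificial sequences by drawing every position independently
#' from the native per-site residue frequencies.  The designed set retains
#' first-order conservation by construction but, because positions are
#' sampled independently, carries no off-diagonal coupling beyond sampling
#' noise — the statistical signature separating FS designs from
#' coupling-aware ones.
#'
#' @param fp a `frequency_profile` (typically the regularized native
#'   profile, so every residue has nonzero support).
#' @param n number of sequences to draw; defaults to the profile's source
#'   M so designed and native sets are size-matched.
#' @param seed RNG seed (explicit, for reproducibility).
#' @param allotype label for the designed alignment.
#' @return A [peptide_alignment] of `n` FS sequences.
#' @export
sample_fs <- function(fp, n = fp$M_source, seed, allotype = NA_character_) {
  stopifnot(inherits(fp, "frequency_profile"))
  if (is.na(n) || n < 1) stop("n must be a positive integer")
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  L <- nrow(fp$f)
  A <- ncol(fp$f)
  enc <- matrix(0L, nrow = n, ncol = L)
  for (i in seq_len(L))
    enc[, i] <- sample.int(A, n, replace = TRUE, prob = fp$f[i, ]) - 1L
  decode_alignment(enc, allotype = allotype, alphabet = fp$alphabet)
}
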