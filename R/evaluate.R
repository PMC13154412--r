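#' Uniform random baseline sequences
#'
#' I.i.d. sequences uniform over the alphabet — the "random peptide"
#' control against which designed sets are compared.
#'
#' @param L sequence length.
#' @param n number of sequences.
#' @param seed RNG seed.
#' @param alphabet residue alphabet.
#' @return A [peptide_alignment] labelled `"random"`.
#' @export
random_baseline <- function(L, n, seed, alphabet = AA_ALPHABET) {
  stopifnot(n >= 1)
  set.seed(seed)
  enc <- matrix(sample.int(length(alphabet), n * L, replace = TRUE) - 1L,
                nrow = n, ncol = L)
  decode_alignment(enc, allotype = "random", alphabet = alphabet)
}

#' Compare a designed set against its native set
#'
#' Computes both statistics stacks with a shared background (pooled over
#' the union of both sets in `"pooled"` mode, so the comparison is
#' invariant under swapping the two roles) and a shared pseudocount, then
#' summarizes agreement: Pearson correlation of
#' flattened site frequencies, Pearson correlation of coupling matrices
#' (upper triangle, diagonal included by default), and the per-position KL
#' divergence of designed from native frequencies.
#'
#' @param native,designed [peptide_alignment]s of the same length L.
#' @param strategy label recorded in the report (`"FS"`, `"L1"`, `"L2"`,
#'   `"MC1"`, `"MC2"`, `"random"`, `"native"`, ...).
#' @param bg_mode background mode for the native statistics stack.
#' @param pseudocount shared regularization weight.
#' @param include_diagonal convention for the coupling PCC.
#' @return Object of class `design_report`: strategy, `pcc_freq`,
#'   `pcc_coupling`, `kl_per_position`, conservation vectors and coupling
#'   matrices of both sets, and the statistics stacks themselves.
#' @export
compare_designs <- function(native, designed, strategy = "design",
                            bg_mode = "pooled", pseudocount = 1e-3,
                            include_diagonal = TRUE) {
  stopifnot(inherits(native, "peptide_alignment"),
            inherits(designed, "peptide_alignment"))
  if (native$L != designed$L) stop("native and designed lengths differ")
  bg <- if (identical(bg_mode, "pooled")) {
    both <- allotype_dataset(list(native. = native, designed. = designed))
    background_frequencies(both, mode = "pooled", pseudocount = pseudocount)
  } else {
    background_frequencies(native, mode = bg_mode, pseudocount = pseudocount)
  }
  ns <- evo_statistics(native, bg = bg, pseudocount = pseudocount)
  ds <- evo_statistics(designed, bg = bg, pseudocount = pseudocount)
  fN <- ns$frequencies$f
  fD <- ds$frequencies$f
  kl <- rowSums(fD * log(fD / fN))
  structure(list(strategy = strategy,
                 pcc_freq = stats::cor(as.vector(fN), as.vector(fD)),
                 pcc_coupling = coupling_pcc(ds$coupling, ns$coupling,
                                             include_diagonal = include_diagonal),
                 kl_per_position = kl,
                 conservation_native = ns$conservation,
                 conservation_designed = ds$conservation,
                 coupling_native = ns$coupling,
                 coupling_designed = ds$coupling,
                 native_stats = ns, designed_stats = ds,
                 include_diagonal = include_diagonal),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("design_report [%s]: first-order PCC %.4f | coupling PCC %.4f | mean KL %.4g nats\n",
              x$strategy, x$pcc_freq, x$pcc_coupling, mean(x$kl_per_position)))
  invisible(x)
}

#' Export a report bundle for downstream tools
#'
#' Writes, under `outdir`: the designed sequences as FASTA
#' (`designed.fasta`, headers carrying allotype and strategy), logo-ready
#' frequency tables for both sets (`logo_native.csv`, `logo_designed.csv`),
#' both coupling matrices as CSV (`coupling_native.csv`,
#' `coupling_designed.csv`), and a machine-readable `summary.txt`
#' (key/value lines).  Affinity and structure validation are export-only
#' concerns: the bundle feeds external predictors, no services are called.
#'
#' @param report a `design_report` from [compare_designs()].
#' @param designed the designed [peptide_alignment] that was compared.
#' @param outdir output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
export_bundle <- function(report, designed, outdir) {
  stopifnot(inherits(report, "design_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("designed.fasta", "logo_native.csv",
                               "logo_designed.csv", "coupling_native.csv",
                               "coupling_designed.csv", "summary.txt"))
  write_designed(designed, paths[1L], format = "fasta",
                 strategy = report$strategy)
  logo_table(report$native_stats$frequencies, paths[2L])
  logo_table(report$designed_stats$frequencies, paths[3L])
  utils::write.table(report$coupling_native, paths[4L], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(report$coupling_designed, paths[5L], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  kv <- c(sprintf("strategy=%s", report$strategy),
          sprintf("pcc_freq=%.10g", report$pcc_freq),
          sprintf("pcc_coupling=%.10g", report$pcc_coupling),
          sprintf("include_diagonal=%s", report$include_diagonal),
          sprintf("kl_position_%d=%.10g", seq_along(report$kl_per_position),
                  report$kl_per_position),
          sprintf("conservation_native_%d=%.10g",
                  seq_along(report$conservation_native),
                  report$conservation_native),
          sprintf("conservation_designed_%d=%.10g",
                  seq_along(report$conservation_designed),
                  report$conservation_designed))
  writeLines(kv, paths[6L])
  invisible(paths)
}
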