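#' Simulated-annealing configuration
#'
#' Defaults follow the published schedule: 2000 annealing cycles (outer
#' loop), 2000 iterations per temperature (inner loop), initial temperature
#' 15 with geometric decay `T_{k+1} = 0.99 T_k`, an 8% per-cell mutation
#' probability, and diagonal objective terms down-weighted to 0.1 because
#' the strongly conserved diagonal of the coupling matrix would otherwise
#' dominate the objective.
#'
#' `init_mode`/`proposal_mode` select the two published variants: MC1 uses
#' completely random initialization with uniform mutations; MC2 initializes
#' from FS sequences and draws mutations from the native per-site
#' frequencies (resampling may return the current residue).
#'
#' `acceptance` sets the Metropolis granularity.  The default
#' `"sequence"` retains or reverts each mutated sequence by its own
#' Metropolis decision (one inner iteration = one pass over all M
#' sequences).  `"sweep"` treats all mutations of a pass as a single
#' proposal; near an optimum a ~8%-of-all-cells joint move is almost
#' surely uphill, so sweep-level acceptance stalls well above the
#' attainable objective floor — see the methods vignette.
#'
#' @param n_outer annealing cycles (temperature updates).
#' @param n_inner Monte Carlo iterations per temperature.
#' @param T0 initial temperature.
#' @param decay geometric cooling factor in (0, 1).
#' @param mutation_prob per-(sequence, position)-cell mutation probability.
#' @param diag_weight weight on diagonal terms of the objective.
#' @param init_mode `"random"` (MC1) or `"fs"` (MC2).
#' @param proposal_mode `"uniform"` (MC1) or `"frequency_guided"` (MC2).
#' @param acceptance `"sequence"` (default) or `"sweep"` Metropolis
#'   granularity.
#' @param M design-set size; defaults to the native M at [anneal()] time.
#' @param seed RNG seed.
#' @param early_stop_rejections terminate after this many consecutive
#'   rejected sweeps (0 = disabled, the fixed printed schedule).
#' @param sqrt_objective report/optimize the square root of the summed
#'   squared coupling differences instead of the sum itself.  At fixed
#'   temperature this monotone transform only rescales uphill acceptance;
#'   the default follows the displayed sum-of-squares objective.
#' @param trace_every record every k-th inner step in the trajectory.
#' @param debug_check_every every k-th step, recount all pair statistics
#'   from scratch and assert agreement with the incrementally maintained
#'   tallies to 1e-9 (0 = disabled).
#' @return Object of class `anneal_config`.
#' @export
anneal_config <- function(n_outer = 2000L, n_inner = 2000L, T0 = 15,
                          decay = 0.99, mutation_prob = 0.08,
                          diag_weight = 0.1,
                          init_mode = c("random", "fs"),
                          proposal_mode = c("uniform", "frequency_guided"),
                          acceptance = c("sequence", "sweep"),
                          M = NA_integer_, seed = 1L,
                          early_stop_rejections = 0L,
                          sqrt_objective = FALSE,
                          trace_every = 1L, debug_check_every = 0L) {
  init_mode <- match.arg(init_mode)
  proposal_mode <- match.arg(proposal_mode)
  acceptance <- match.arg(acceptance)
  stopifnot(T0 > 0, decay > 0, decay < 1,
            mutation_prob > 0, mutation_prob <= 1, diag_weight >= 0,
            n_outer >= 1, n_inner >= 1, trace_every >= 1)
  structure(list(n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
                 T0 = T0, decay = decay, mutation_prob = mutation_prob,
                 diag_weight = diag_weight, init_mode = init_mode,
                 proposal_mode = proposal_mode, acceptance = acceptance,
                 M = as.integer(M),
                 seed = as.integer(seed),
                 early_stop_rejections = as.integer(early_stop_rejections),
                 sqrt_objective = isTRUE(sqrt_objective),
                 trace_every = as.integer(trace_every),
                 debug_check_every = as.integer(debug_check_every)),
            class = "anneal_config")
}

#' MC1/MC2 preset configurations
#'
#' @param variant `"MC1"` (coupling-only: random init, uniform mutations) or
#'   `"MC2"` (frequency + coupling: FS init, frequency-guided mutations).
#' @param ... overrides passed to [anneal_config()].
#' @return An `anneal_config`.
#' @export
mcsa_preset <- function(variant = c("MC1", "MC2"), ...) {
  variant <- match.arg(variant)
  if (variant == "MC1")
    anneal_config(init_mode = "random", proposal_mode = "uniform", ...)
  else
    anneal_config(init_mode = "fs", proposal_mode = "frequency_guided", ...)
}

#' Annealing objective: squared coupling-matrix discrepancy
#'
#' `E = sum_{i != j} (C^design_ij - C^native_ij)^2
#'     + diag_weight * sum_i (C^design_ii - C^native_ii)^2`,
#' summed over ordered pairs (each off-diagonal pair contributes twice, as
#' in the full double sum).  The diagonal is down-weighted because its
#' strongly conserved entries would otherwise dominate.
#'
#' @param design_C,native_C L x L coupling matrices.
#' @param diag_weight weight on diagonal terms (default 0.1).
#' @param sqrt_scale return `sqrt(E)` instead of `E`.
#' @return Non-negative scalar.
#' @export
mcsa_objective <- function(design_C, native_C, diag_weight = 0.1,
                           sqrt_scale = FALSE) {
  if (!all(dim(design_C) == dim(native_C)))
    stop("coupling matrices must share dimensions")
  D <- design_C - native_C
  off <- D
  diag(off) <- 0
  E <- sum(off^2) + diag_weight * sum(diag(D)^2)
  if (sqrt_scale) sqrt(E) else E
}

#' Metropolis acceptance rule
#'
#' Accepts every non-uphill move (`delta_E <= 0`); uphill moves are accepted
#' with probability `exp(-delta_E / T)`.
#'
#' @param delta_E objective change of the proposed move.
#' @param T current temperature (> 0).
#' @return Logical.
#' @export
metropolis_accept <- function(delta_E, T) {
  if (T <= 0) stop("temperature must be positive")
  if (delta_E <= 0) return(TRUE)
  stats::runif(1) < exp(-delta_E / T)
}

#' Propose a whole-set mutation sweep
#'
#' Every (sequence, position) cell of the encoded design mutates
#' independently with probability `mutation_prob`.  In `uniform` mode the
#' replacement is drawn uniformly from the other A - 1 residues; in
#' `frequency_guided` mode it is drawn from the native per-site frequencies
#' (and may equal the current residue).  This R implementation is the
#' reference for the compiled annealing loop and for tests.
#'
#' @param design integer matrix M x L with 0-based residue codes.
#' @param mutation_prob per-cell mutation probability.
#' @param proposal_mode `"uniform"` or `"frequency_guided"`.
#' @param fp `frequency_profile` (required in guided mode).
#' @return List with `design` (mutated copy) and `changes` (data.frame with
#'   columns `seq`, `pos`, `old`, `new`; cells whose guided redraw returned
#'   the same residue are not listed).
#' @export
propose <- function(design, mutation_prob,
                    proposal_mode = c("uniform", "frequency_guided"),
                    fp = NULL) {
  proposal_mode <- match.arg(proposal_mode)
  if (proposal_mode == "frequency_guided" && is.null(fp))
    stop("frequency_guided proposals require a frequency profile")
  A <- if (is.null(fp)) 20L else ncol(fp$f)
  M <- nrow(design)
  L <- ncol(design)
  hit <- matrix(stats::runif(M * L) < mutation_prob, M, L)
  out <- design
  for (i in seq_len(L)) {
    rows <- which(hit[, i])
    if (!length(rows)) next
    cur <- design[rows, i]
    new <- if (proposal_mode == "uniform") {
      r <- sample.int(A - 1L, length(rows), replace = TRUE) - 1L
      ifelse(r >= cur, r + 1L, r)
    } else {
      sample.int(A, length(rows), replace = TRUE, prob = fp$f[i, ]) - 1L
    }
    out[rows, i] <- new
  }
  ch <- which(out != design, arr.ind = TRUE)
  list(design = out,
       changes = data.frame(seq = ch[, 1L], pos = ch[, 2L],
                            old = design[ch], new = out[ch]))
}

#' Temperature schedule
#'
#' @param cfg an `anneal_config`.
#' @param k 0-based outer-cycle index (vectorized).
#' @return `T0 * decay^k`.
#' @export
temperature_schedule <- function(cfg, k) cfg$T0 * cfg$decay^k

#' Monte Carlo simulated annealing of a peptide design set
#'
#' Evolves a whole M-sequence design set so that its coupling matrix matches
#' a native target.  Outer loop: `n_outer` temperature updates under
#' geometric cooling from `T0`.  Inner loop: `n_inner` iterations at each
#' temperature; each iteration proposes a whole-set mutation sweep (8% of
#' cells by default), recomputes the design coupling matrix from
#' incrementally maintained single- and pair-count tallies under the same
#' pseudocount scheme and background as the native statistics, and accepts
#' or rejects the sweep as a unit by the Metropolis criterion.  The design
#' with the lowest objective seen anywhere is returned.
#'
#' @param native_stats an `evo_statistics` object for the native set (or a
#'   list with elements `frequencies`, `background`, `coupling`,
#'   `pseudocount`).
#' @param cfg an [anneal_config()]; `cfg$M` defaults to the native M.
#' @return Object of class `anneal_result`: `design` (a
#'   [peptide_alignment]), `trajectory` (one row per inner iteration:
#'   `outer`, `inner`, `temperature`, `E`, `best_E`, and `accepted`, the
#'   fraction of that iteration's Metropolis decisions accepted),
#'   `initial_E`, `final_E`, `accept_rate`, and the `config` used.
#' @export
anneal <- function(native_stats, cfg = anneal_config()) {
  stopifnot(inherits(cfg, "anneal_config"))
  fp <- native_stats$frequencies
  bg <- native_stats$background
  Cnat <- native_stats$coupling
  pc <- native_stats$pseudocount
  if (is.null(fp) || is.null(bg) || is.null(Cnat) || is.null(pc))
    stop("native_stats must provide frequencies, background, coupling, pseudocount")
  L <- nrow(fp$f)
  A <- ncol(fp$f)
  M <- if (is.na(cfg$M)) fp$M_source else cfg$M
  if (is.na(M) || M < 2L) stop("design-set size M must be at least 2")

  set.seed(cfg$seed)
  init <- if (cfg$init_mode == "random") {
    matrix(sample.int(A, M * L, replace = TRUE) - 1L, nrow = M, ncol = L)
  } else {
    enc <- matrix(0L, nrow = M, ncol = L)
    for (i in seq_len(L))
      enc[, i] <- sample.int(A, M, replace = TRUE, prob = fp$f[i, ]) - 1L
    enc
  }

  res <- mcsa_run(init, fp$f, bg$q, pc, Cnat,
                  cfg$T0, cfg$decay, cfg$n_outer, cfg$n_inner,
                  cfg$mutation_prob, cfg$diag_weight,
                  cfg$proposal_mode == "frequency_guided",
                  cfg$acceptance == "sequence",
                  cfg$early_stop_rejections, cfg$trace_every,
                  cfg$debug_check_every)

  rescale <- function(E) if (cfg$sqrt_objective) sqrt(E) else E
  traj <- data.frame(outer = res$outer, inner = res$inner,
                     temperature = res$temperature,
                     E = rescale(res$E), best_E = rescale(res$best_E),
                     accepted = res$accepted)
  design <- decode_alignment(res$design, alphabet = fp$alphabet)
  design$allotype <- native_stats$allotype %||% NA_character_
  structure(list(design = design, trajectory = traj,
                 initial_E = rescale(res$initial_E),
                 final_E = rescale(res$final_E),
                 accept_rate = res$accept_rate, config = cfg),
            class = "anneal_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf(
    "anneal_result: M=%d, L=%d | E: %.4g -> %.4g (%.1f%% of initial) | accept rate %.3f\n",
    x$design$M, x$design$L, x$initial_E, x$final_E,
    100 * x$final_E / x$initial_E, x$accept_rate))
  invisible(x)
}
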