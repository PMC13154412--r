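#' Attention-model architecture configuration
#'
#' The generative designer maps one allotype's evolutionary statistics — the
#' site-frequency matrix flattened to a length `L*A` vector `F` and the
#' joint-frequency tensor reshaped to an `(L*A) x (L*A)` matrix `T` — to
#' per-position output distributions `P_ia`.  `F` passes through a 1-D
#' convolution and `T` through a 2-D convolution; the per-token convolved
#' features are concatenated along the feature dimension, linearly embedded
#' (plus a learned positional embedding) and fed to a stack of pre-norm
#' Transformer blocks with multi-head scaled dot-product attention
#' (`softmax(Q K' / sqrt(d_k))`).  A 1-D convolutional head over the token
#' axis produces one logit per (position, residue) token, and a per-position
#' softmax yields `P_ia`.
#'
#' Published essentials are the defaults (12 blocks); head count, width and
#' kernel sizes are unpublished and exposed here as standard small-attention
#' defaults.
#'
#' @param L alignment length (default 9).
#' @param alphabet_size residue alphabet size (default 20).
#' @param n_blocks number of Transformer blocks (default 12).
#' @param n_heads attention heads H (default 4); `d_k = d / H`.
#' @param d model width (default 128), divisible by `n_heads`.
#' @param conv1d_channels,conv1d_kernel frequency-branch convolution.
#' @param conv2d_channels,conv2d_kernel joint-branch convolution.
#' @param head_kernel kernel of the convolutional output head (odd).
#' @param ffn_mult feed-forward width multiplier (default 4).
#' @return Object of class `design_model_config`.
#' @export
design_model_config <- function(L = 9L, alphabet_size = 20L, n_blocks = 12L,
                                n_heads = 4L, d = 128L,
                                conv1d_channels = 16L, conv1d_kernel = 3L,
                                conv2d_channels = 4L, conv2d_kernel = 3L,
                                head_kernel = 3L, ffn_mult = 4L) {
  stopifnot(n_blocks >= 1, d %% n_heads == 0,
            conv1d_kernel %% 2 == 1, conv2d_kernel %% 2 == 1,
            head_kernel %% 2 == 1)
  structure(list(L = as.integer(L), alphabet_size = as.integer(alphabet_size),
                 n_blocks = as.integer(n_blocks), n_heads = as.integer(n_heads),
                 d = as.integer(d), d_k = as.integer(d / n_heads),
                 conv1d_channels = as.integer(conv1d_channels),
                 conv1d_kernel = as.integer(conv1d_kernel),
                 conv2d_channels = as.integer(conv2d_channels),
                 conv2d_kernel = as.integer(conv2d_kernel),
                 head_kernel = as.integer(head_kernel),
                 ffn_mult = as.integer(ffn_mult)),
            class = "design_model_config")
}

#' Reduced test-profile preset
#'
#' A small configuration (2 blocks, width 64) that trains in minutes on one
#' CPU; used by the test suite and benchmark scripts.
#'
#' @param L alignment length.
#' @param alphabet_size residue alphabet size.
#' @param ... further overrides for [design_model_config()].
#' @return A `design_model_config`.
#' @export
reduced_model_config <- function(L = 9L, alphabet_size = 20L, ...) {
  design_model_config(L = L, alphabet_size = alphabet_size,
                      n_blocks = 2L, d = 64L, ...)
}

#' Training configuration
#'
#' Defaults follow the published recipe: Adam with learning rate 1e-4,
#' 2000 epochs, and the frequency/joint balance `lambda = 65` for the
#' integrated loss.  One training example is one allotype's statistics
#' pair; `batch_size = 1` performs one optimizer step per allotype per
#' epoch (the published batch composition is unstated).
#'
#' @param loss_kind `"loss2"` (frequency + joint, default) or `"loss1"`
#'   (joint only).
#' @param lambda balance coefficient of the joint term in Loss2.
#' @param learning_rate Adam step size.
#' @param epochs training epochs (one pass over all allotypes).
#' @param batch_size allotypes per optimizer step (`NA` = all).
#' @param seed RNG seed fixing initialization and batch order.
#' @param n_repeats independent training repetitions (seeds derived).
#' @param plateau_tol optional early stop: relative loss change below this
#'   over `plateau_window` epochs terminates training (0 = disabled).
#' @param plateau_window epochs over which the plateau is measured.
#' @return Object of class `training_config`.
#' @export
training_config <- function(loss_kind = c("loss2", "loss1"), lambda = 65,
                            learning_rate = 1e-4, epochs = 2000L,
                            batch_size = 1L, seed = 1L, n_repeats = 1L,
                            plateau_tol = 0, plateau_window = 100L) {
  loss_kind <- match.arg(loss_kind)
  stopifnot(lambda >= 0, epochs >= 1, learning_rate > 0, n_repeats >= 1)
  structure(list(loss_kind = loss_kind, lambda = lambda,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = batch_size, seed = as.integer(seed),
                 n_repeats = as.integer(n_repeats),
                 plateau_tol = plateau_tol,
                 plateau_window = as.integer(plateau_window)),
            class = "training_config")
}

#' Flatten statistics into model inputs
#'
#' Row-major flattening consistent with the fixed alphabet ordering: token
#' `t = (i - 1) * A + a` indexes (position i, residue a).  `F` has `L*A`
#' entries and `T` is `(L*A) x (L*A)`; for L = 9, A = 20 these are the
#' 180-vector and 180 x 180 matrix the network consumes.  Invertible via
#' [unfeaturize()].
#'
#' @param fp a `frequency_profile`.
#' @param jf a `joint_frequencies` object with matching L and alphabet.
#' @return List with `F` (numeric vector) and `T` (matrix).
#' @export
featurize <- function(fp, jf) {
  f <- fp$f
  fj <- jf$fj
  L <- nrow(f)
  A <- ncol(f)
  if (!all(dim(fj) == c(L, A, L, A))) stop("profile/joint shape mismatch")
  Tm <- matrix(aperm(fj, c(2L, 1L, 4L, 3L)), L * A, L * A)
  list(F = as.vector(t(f)), T = Tm)
}

#' Invert [featurize()]
#'
#' @param x list with `F` and `T` as produced by [featurize()].
#' @param L alignment length.
#' @param alphabet residue alphabet.
#' @return List with `frequencies` and `joint`.
#' @export
unfeaturize <- function(x, L, alphabet = AA_ALPHABET) {
  A <- length(alphabet)
  f <- matrix(x$F, nrow = L, ncol = A, byrow = TRUE)
  fj <- aperm(array(x$T, dim = c(A, L, A, L)), c(2L, 1L, 4L, 3L))
  list(frequencies = frequency_profile(f, alphabet = alphabet),
       joint = joint_frequencies_from_array(fj, alphabet = alphabet))
}

#' Differentiable statistics implied by output distributions
#'
#' Because designed sequences are sampled independently per position, the
#' statistics implied by `P` are `fhat_ia = P_ia` and, for i != j,
#' `fhat_ij^ab = P_ia * P_jb`, with delta diagonal blocks — the unique
#' joint-frequency surrogate consistent with independent per-position
#' sampling, and differentiable in `P`.
#'
#' @param P L x A matrix of per-position probabilities (rows sum to 1).
#' @return List with `frequencies` (L x A) and `joint` (array L,A,L,A).
#' @export
predicted_statistics <- function(P) {
  L <- nrow(P)
  A <- ncol(P)
  fj <- array(0, dim = c(L, A, L, A))
  for (i in seq_len(L)) {
    fj[i, , i, ][cbind(seq_len(A), seq_len(A))] <- P[i, ]
    if (i < L) for (j in seq((i + 1L), L)) {
      blk <- tcrossprod(P[i, ], P[j, ])
      fj[i, , j, ] <- blk
      fj[j, , i, ] <- t(blk)
    }
  }
  list(frequencies = P, joint = fj)
}

#' Joint-frequency matching loss (Loss1)
#'
#' Mean over a batch of allotypes of the `(L*A)^-2`-normalized sum of
#' squared joint-frequency errors.
#'
#' @param pred_joint,native_joint single arrays/matrices or lists of them
#'   (one per allotype); any shape, compared elementwise after flattening.
#' @return Non-negative scalar.
#' @export
loss1 <- function(pred_joint, native_joint) {
  if (!is.list(pred_joint)) pred_joint <- list(pred_joint)
  if (!is.list(native_joint)) native_joint <- list(native_joint)
  stopifnot(length(pred_joint) == length(native_joint))
  terms <- mapply(function(p, n) {
    if (length(p) != length(n)) stop("joint-frequency shape mismatch")
    # (L*A)^2 normalizer == element count of the (L*A) x (L*A) layout
    sum((as.numeric(p) - as.numeric(n))^2) / length(p)
  }, pred_joint, native_joint)
  mean(terms)
}

#' Integrated frequency + joint-frequency loss (Loss2)
#'
#' `Loss2 = MSE(f, fhat) + lambda * Loss1`: the frequency term is the batch
#' mean of the un-normalized sum of squared per-position frequency errors;
#' the joint term is [loss1()] scaled by `lambda` (default 65).
#'
#' @param pred_freq,native_freq L x A matrices or lists of them.
#' @param pred_joint,native_joint as in [loss1()].
#' @param lambda balance coefficient.
#' @return List with `total`, `freq_term`, `joint_term`.
#' @export
loss2 <- function(pred_freq, native_freq, pred_joint, native_joint,
                  lambda = 65) {
  if (!is.list(pred_freq)) pred_freq <- list(pred_freq)
  if (!is.list(native_freq)) native_freq <- list(native_freq)
  stopifnot(length(pred_freq) == length(native_freq))
  ft <- mean(mapply(function(p, n) {
    if (length(p) != length(n)) stop("frequency shape mismatch")
    sum((as.numeric(p) - as.numeric(n))^2)
  }, pred_freq, native_freq))
  jt <- loss1(pred_joint, native_joint)
  list(total = ft + lambda * jt, freq_term = ft, joint_term = jt)
}

# ---- model internals ---------------------------------------------------

xavier <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)

# im2col for a 1-D signal with zero padding (same output length)
im2col_1d <- function(x, kernel) {
  n <- length(x)
  half <- (kernel - 1L) %/% 2L
  out <- matrix(0, n, kernel)
  for (r in seq_len(kernel)) {
    off <- r - 1L - half
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, r] <- x[src[ok]]
  }
  out
}

# im2col for a 2-D image (n x n), rows ordered row-major by (t, j)
im2col_2d <- function(img, kernel) {
  n <- nrow(img)
  half <- (kernel - 1L) %/% 2L
  out <- matrix(0, n * n, kernel * kernel)
  col <- 0L
  for (dr in -half:half) for (dc in -half:half) {
    col <- col + 1L
    tt <- rep(seq_len(n), each = n) + dr
    jj <- rep(seq_len(n), times = n) + dc
    ok <- tt >= 1L & tt <= n & jj >= 1L & jj <= n
    vals <- numeric(n * n)
    vals[ok] <- img[cbind(tt[ok], jj[ok])]
    out[, col] <- vals
  }
  out
}

# linear index map: conv2d output ((N^2) x c2, image rows row-major (t, j))
# -> token features (N x (N * c2)) with columns grouped (j, channel)
reshape_idx_conv2 <- function(N, c2) {
  o <- seq_len(N * N * c2)
  t <- ((o - 1L) %% N) + 1L
  col <- ((o - 1L) %/% N) + 1L
  j <- ((col - 1L) %/% c2) + 1L
  ch <- ((col - 1L) %% c2) + 1L
  ((t - 1L) * N + j) + (ch - 1L) * N * N
}

# linear index map: logits (N x 1, token-major) -> L x A matrix
reshape_idx_logits <- function(L, A) {
  o <- seq_len(L * A)
  i <- ((o - 1L) %% L) + 1L
  a <- ((o - 1L) %/% L) + 1L
  (i - 1L) * A + a
}

# linear index map: P (L x A) -> token column vector (N x 1)
reshape_idx_tokens <- function(L, A) {
  tk <- seq_len(L * A)
  i <- ((tk - 1L) %/% A) + 1L
  a <- ((tk - 1L) %% A) + 1L
  i + (a - 1L) * L
}

shift_matrix <- function(n, off) {
  S <- matrix(0, n, n)
  src <- seq_len(n) + off
  ok <- src >= 1L & src <= n
  S[cbind(which(ok), src[ok])] <- 1
  S
}

#' Build an untrained design model
#'
#' Initializes all parameters (Xavier for weight matrices, zeros for biases,
#' unit/zero layer-norm affines, small random positional embeddings) from
#' the current RNG state.
#'
#' @param mcfg a [design_model_config()].
#' @return Object of class `design_model` (parameters, config, constant
#'   structure matrices).
#' @export
build_design_model <- function(mcfg) {
  L <- mcfg$L; A <- mcfg$alphabet_size; N <- L * A
  d <- mcfg$d; H <- mcfg$n_heads; dk <- mcfg$d_k
  c1 <- mcfg$conv1d_channels; c2 <- mcfg$conv2d_channels
  p <- list()
  p$W_c1 <- xavier(mcfg$conv1d_kernel, c1)
  p$b_c1 <- matrix(0, 1L, c1)
  p$W_c2 <- xavier(mcfg$conv2d_kernel^2, c2)
  p$b_c2 <- matrix(0, 1L, c2)
  p$W_emb <- xavier(c1 + N * c2, d)
  p$b_emb <- matrix(0, 1L, d)
  p$pos <- matrix(stats::rnorm(N * d, 0, 0.02), N, d)
  for (b in seq_len(mcfg$n_blocks)) {
    pre <- sprintf("blk%d_", b)
    p[[paste0(pre, "ln1_g")]] <- matrix(1, 1L, d)
    p[[paste0(pre, "ln1_b")]] <- matrix(0, 1L, d)
    for (h in seq_len(H)) {
      p[[sprintf("%sWq%d", pre, h)]] <- xavier(d, dk)
      p[[sprintf("%sWk%d", pre, h)]] <- xavier(d, dk)
      p[[sprintf("%sWv%d", pre, h)]] <- xavier(d, dk)
    }
    p[[paste0(pre, "Wo")]] <- xavier(d, d)
    p[[paste0(pre, "ln2_g")]] <- matrix(1, 1L, d)
    p[[paste0(pre, "ln2_b")]] <- matrix(0, 1L, d)
    p[[paste0(pre, "Wf1")]] <- xavier(d, d * mcfg$ffn_mult)
    p[[paste0(pre, "bf1")]] <- matrix(0, 1L, d * mcfg$ffn_mult)
    p[[paste0(pre, "Wf2")]] <- xavier(d * mcfg$ffn_mult, d)
    p[[paste0(pre, "bf2")]] <- matrix(0, 1L, d)
  }
  p$lnf_g <- matrix(1, 1L, d)
  p$lnf_b <- matrix(0, 1L, d)
  hk <- mcfg$head_kernel
  for (o in seq_len(hk)) p[[sprintf("Wh%d", o)]] <- xavier(d, d)
  p$bh <- matrix(0, 1L, d)
  p$W_out <- xavier(d, 1L)
  p$b_out <- matrix(0, 1L, 1L)

  half <- (hk - 1L) %/% 2L
  shifts <- lapply(-half:half, function(off) shift_matrix(N, off))
  structure(list(params = p, config = mcfg,
                 shifts = shifts,
                 idx_conv2 = reshape_idx_conv2(N, c2),
                 idx_logits = reshape_idx_logits(L, A),
                 idx_tokens = reshape_idx_tokens(L, A)),
            class = "design_model")
}

#' @export
print.design_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("design_model: L=%d, A=%d, %d block(s), %d head(s), d=%d, %d parameters\n",
              x$config$L, x$config$alphabet_size, x$config$n_blocks,
              x$config$n_heads, x$config$d, np))
  invisible(x)
}

# Precompute the constant input structures for one allotype
prepare_inputs <- function(model, fp, jf) {
  ft <- featurize(fp, jf)
  list(P1 = im2col_1d(ft$F, model$config$conv1d_kernel),
       P2 = im2col_2d(ft$T, model$config$conv2d_kernel),
       Tnat = ft$T, Fnat = fp$f)
}

# Forward pass on a tape; pn = named list of parameter nodes
forward_graph <- function(model, tape, pn, inp) {
  cfg <- model$config
  L <- cfg$L; A <- cfg$alphabet_size; N <- L * A
  Fp <- ag_relu(tape, ag_add_rowvec(
    tape, ag_matmul(tape, ag_const(tape, inp$P1), pn$W_c1), pn$b_c1))
  Tc <- ag_relu(tape, ag_add_rowvec(
    tape, ag_matmul(tape, ag_const(tape, inp$P2), pn$W_c2), pn$b_c2))
  Tf <- ag_index_reshape(tape, Tc, model$idx_conv2,
                         c(N, N * cfg$conv2d_channels))
  Z <- ag_concat_cols(tape, list(Fp, Tf))
  X <- ag_add(tape,
              ag_add_rowvec(tape, ag_matmul(tape, Z, pn$W_emb), pn$b_emb),
              pn$pos)
  sc <- 1 / sqrt(cfg$d_k)
  for (b in seq_len(cfg$n_blocks)) {
    pre <- sprintf("blk%d_", b)
    h <- ag_layernorm_rows(tape, X, pn[[paste0(pre, "ln1_g")]],
                           pn[[paste0(pre, "ln1_b")]])
    heads <- vector("list", cfg$n_heads)
    for (hh in seq_len(cfg$n_heads)) {
      Q <- ag_matmul(tape, h, pn[[sprintf("%sWq%d", pre, hh)]])
      K <- ag_matmul(tape, h, pn[[sprintf("%sWk%d", pre, hh)]])
      V <- ag_matmul(tape, h, pn[[sprintf("%sWv%d", pre, hh)]])
      Aw <- ag_softmax_rows(tape, ag_scale(tape, ag_matmul(tape, Q, ag_transpose(tape, K)), sc))
      heads[[hh]] <- ag_matmul(tape, Aw, V)
    }
    att <- ag_matmul(tape, ag_concat_cols(tape, heads), pn[[paste0(pre, "Wo")]])
    X <- ag_add(tape, X, att)
    h2 <- ag_layernorm_rows(tape, X, pn[[paste0(pre, "ln2_g")]],
                            pn[[paste0(pre, "ln2_b")]])
    ff <- ag_matmul(tape, ag_relu(tape, ag_add_rowvec(
      tape, ag_matmul(tape, h2, pn[[paste0(pre, "Wf1")]]), pn[[paste0(pre, "bf1")]])),
      pn[[paste0(pre, "Wf2")]])
    X <- ag_add(tape, X, ag_add_rowvec(tape, ff, pn[[paste0(pre, "bf2")]]))
  }
  Xf <- ag_layernorm_rows(tape, X, pn$lnf_g, pn$lnf_b)
  hk <- cfg$head_kernel
  conv <- NULL
  for (o in seq_len(hk)) {
    term <- ag_matmul(tape, ag_matmul(tape, ag_const(tape, model$shifts[[o]]), Xf),
                      pn[[sprintf("Wh%d", o)]])
    conv <- if (is.null(conv)) term else ag_add(tape, conv, term)
  }
  Hn <- ag_relu(tape, ag_add_rowvec(tape, conv, pn$bh))
  logits <- ag_add_rowvec(tape, ag_matmul(tape, Hn, pn$W_out), pn$b_out)
  Pm <- ag_index_reshape(tape, logits, model$idx_logits, c(L, A))
  ag_softmax_rows(tape, Pm)
}

# loss graph for one allotype; returns list of scalar nodes
loss_graph <- function(model, tape, Pnode, inp, loss_kind, lambda) {
  cfg <- model$config
  L <- cfg$L; A <- cfg$alphabet_size; N <- L * A
  v <- ag_index_reshape(tape, Pnode, model$idx_tokens, c(N, 1L))
  J <- ag_matmul(tape, v, ag_transpose(tape, v))
  Moff <- 1 - (kronecker(diag(L), matrix(1, A, A)))
  Jhat <- ag_add(tape, ag_mul_const(tape, J, Moff), ag_diag_embed(tape, v))
  jt <- ag_sum_sq_diff(tape, Jhat, inp$Tnat, scale = 1 / (N * N))
  ft <- ag_sum_sq_diff(tape, Pnode, inp$Fnat, scale = 1)
  total <- if (loss_kind == "loss1") jt else ag_add(tape, ft, ag_scale(tape, jt, lambda))
  list(total = total, freq = ft, joint = jt)
}

adam_init <- function(params) list(m = lapply(params, function(x) x * 0),
                                   v = lapply(params, function(x) x * 0), t = 0L)

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

#' Train the generative design model
#'
#' Gradient training of the attention model against Loss1 (joint-frequency
#' matching) or Loss2 (frequency + joint-frequency matching).  One training
#' example is one allotype's `(frequencies, joint)` statistics pair; each
#' epoch visits all allotypes in seeded-shuffled batches.  The seed fixes
#' initialization and batch order, making reruns bit-identical.  A
#' non-finite loss aborts with a diagnostic.
#'
#' @param stats_by_allotype named list; each element an `evo_statistics`
#'   object or a list with `frequencies` (`frequency_profile`) and `joint`
#'   (`joint_frequencies`).
#' @param mcfg a [design_model_config()].
#' @param tcfg a [training_config()].
#' @return Object of class `trained_design_model`: the trained `model`, a
#'   `history` data.frame (`epoch`, `total`, `freq_term`, `joint_term`),
#'   and, when `n_repeats > 1`, `repeats` — one full trained model (with
#'   its history) per repetition; the top-level model/history are the
#'   first repetition's.
#' @export
train_design_model <- function(stats_by_allotype, mcfg = design_model_config(),
                               tcfg = training_config()) {
  stopifnot(length(stats_by_allotype) >= 1)
  run_one <- function(seed) {
    set.seed(seed)
    model <- build_design_model(mcfg)
    inputs <- lapply(stats_by_allotype, function(s)
      prepare_inputs(model, s$frequencies, s$joint))
    n_allo <- length(inputs)
    bs <- if (is.na(tcfg$batch_size)) n_allo else min(tcfg$batch_size, n_allo)
    state <- adam_init(model$params)
    hist <- matrix(NA_real_, nrow = tcfg$epochs, ncol = 3L)
    for (epoch in seq_len(tcfg$epochs)) {
      ord <- sample.int(n_allo)
      ep <- c(0, 0, 0)
      for (start in seq(1L, n_allo, by = bs)) {
        batch <- ord[start:min(start + bs - 1L, n_allo)]
        tape <- ag_tape()
        pn <- lapply(model$params, function(x) ag_param(tape, x))
        tot <- NULL; ftv <- 0; jtv <- 0
        for (ai in batch) {
          Pn <- forward_graph(model, tape, pn, inputs[[ai]])
          ls <- loss_graph(model, tape, Pn, inputs[[ai]], tcfg$loss_kind, tcfg$lambda)
          tot <- if (is.null(tot)) ls$total else ag_add(tape, tot, ls$total)
          ftv <- ftv + ls$freq$value[1L]
          jtv <- jtv + ls$joint$value[1L]
        }
        tot <- ag_scale(tape, tot, 1 / length(batch))
        if (!is.finite(tot$value[1L]))
          stop(sprintf("divergent loss at epoch %d: %g", epoch, tot$value[1L]))
        ag_backward(tape, tot)
        grads <- lapply(pn, function(nd) nd$grad)
        upd <- adam_step(model$params, grads, state, tcfg$learning_rate)
        model$params <- upd$params
        state <- upd$state
        ep <- ep + c(tot$value[1L] * length(batch), ftv, jtv)
      }
      hist[epoch, ] <- ep / n_allo
      if (tcfg$plateau_tol > 0 && epoch > tcfg$plateau_window) {
        prev <- hist[epoch - tcfg$plateau_window, 1L]
        if (abs(prev - hist[epoch, 1L]) < tcfg$plateau_tol * max(prev, .Machine$double.eps)) {
          hist <- hist[seq_len(epoch), , drop = FALSE]
          break
        }
      }
    }
    history <- data.frame(epoch = seq_len(nrow(hist)), total = hist[, 1L],
                          freq_term = hist[, 2L], joint_term = hist[, 3L])
    list(model = model, history = history, inputs = inputs)
  }

  seeds <- tcfg$seed + 101L * (seq_len(tcfg$n_repeats) - 1L)
  runs <- lapply(seeds, run_one)
  structure(list(model = runs[[1L]]$model, history = runs[[1L]]$history,
                 inputs = runs[[1L]]$inputs,
                 repeats = if (tcfg$n_repeats > 1L)
                   lapply(runs, function(r)
                     structure(list(model = r$model, history = r$history,
                                    training = tcfg),
                               class = "trained_design_model"))
                 else NULL,
                 training = tcfg),
            class = "trained_design_model")
}

#' Per-position output distribution of a (trained) model
#'
#' Deterministic inference: two identical calls give identical output; rows
#' sum to 1 by the softmax construction.
#'
#' @param tm a `trained_design_model` (or bare `design_model`).
#' @param stats an `evo_statistics` object or `(frequencies, joint)` list
#'   for the allotype to design for.
#' @return L x A matrix `P_ia`.
#' @export
model_probabilities <- function(tm, stats) {
  model <- if (inherits(tm, "trained_design_model")) tm$model else tm
  inp <- prepare_inputs(model, stats$frequencies, stats$joint)
  tape <- ag_tape()
  pn <- lapply(model$params, function(x) ag_param(tape, x))
  forward_graph(model, tape, pn, inp)$value
}

#' Sample designed sequences from a trained model
#'
#' Draws `n` sequences, each position independently from the model's output
#' distribution `P_i.` for the given allotype.
#'
#' @param tm a `trained_design_model`.
#' @param stats statistics of the target allotype (as in
#'   [model_probabilities()]).
#' @param n number of sequences.
#' @param seed RNG seed.
#' @param allotype label for the designed alignment.
#' @param alphabet residue alphabet.
#' @return A [peptide_alignment].
#' @export
design_from_model <- function(tm, stats, n, seed, allotype = NA_character_,
                              alphabet = NULL) {
  P <- model_probabilities(tm, stats)
  if (is.null(alphabet)) alphabet <- stats$frequencies$alphabet
  set.seed(seed)
  L <- nrow(P)
  A <- ncol(P)
  enc <- matrix(0L, nrow = n, ncol = L)
  for (i in seq_len(L))
    enc[, i] <- sample.int(A, n, replace = TRUE, prob = P[i, ]) - 1L
  decode_alignment(enc, allotype = allotype, alphabet = alphabet)
}
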