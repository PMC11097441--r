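# Semi-supervised double-attention denoiser.
#
# Layer 1: two parallel recurrent attention blocks over the embedded
# diagnosis sequence -- a bidirectional "full sequence" block capturing
# overall context, and a reverse-direction "noise reduction" block tuned to
# the noise disease set. Their states are mixed as v_t = alpha*h_t +
# beta*hhat_t. Layer 2: scaled dot-product attention over the mixed states;
# the per-position attention mass a_i feeds a dense sigmoid head f_s whose
# score decides, against a threshold theta, whether position i survives into
# the denoised sequence.
#
# No autodiff is available, so gradients are derived and implemented by hand,
# batched across sequences; test-suite finite-difference checks guard every
# path.

.slice <- function(A, t) matrix(A[, t, ], nrow = dim(A)[1L])

#' Initialize denoiser parameters
#'
#' @param p input (embedding) dimension.
#' @param q hidden dimension.
#' @param seed integer seed for reproducible initialization.
#' @return object of class \code{denoiser_params}: recurrent weights of the
#'   full block (\code{W_t}, \code{W_x}, \code{b}, output projection
#'   \code{W_y} from the concatenated bidirectional state, \code{b_y}), the
#'   hatted reverse-block analogues, the second-layer query/key/value
#'   projections, and the scalar scoring affine (\code{w_s}, \code{b_s}).
#' @export
denoiser_params <- function(p, q, seed = 1L) {
  with_seed_(seed, {
    g <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc)
    structure(list(
      W_t = g(q, q), W_x = g(q, p), b = numeric(q),
      W_y = g(q, 2L * q), b_y = numeric(q),
      What_t = g(q, q), What_x = g(q, p), bhat = numeric(q),
      What_y = g(q, q), bhat_y = numeric(q),
      Wq = g(q, q), Wk = g(q, q), Wv = g(q, q),
      w_s = 1, b_s = 0,
      p = p, q = q, seed = seed), class = "denoiser_params")
  })
}

.check_X <- function(X, params) {
  stopifnot(is.matrix(X), nrow(X) == params$p, ncol(X) >= 1L)
}

# Batched forward of the shared-weight forward recurrence (pads ignored:
# gradient from pad positions is zero, see .denoiser_backward).
.rnn_fwd <- function(X, W_t, W_x, b) {
  q <- nrow(W_t); L <- dim(X)[2L]; B <- dim(X)[3L]
  S <- array(0, c(q, L, B))
  prev <- matrix(0, q, B)
  for (t in seq_len(L)) {
    prev <- .sigmoid(W_t %*% prev + W_x %*% .slice(X, t) + rep(b, B))
    S[, t, ] <- prev
  }
  S
}

# Batched reverse recurrence honouring per-sequence lengths: the state enters
# each sequence's last valid position as the initial zero vector, i.e. the
# recurrence only starts once the (end-padded) pad region has been passed.
# Returns state array [q, L+1, B]; state[, t, ] is the value at position t
# (zero at pads), state[, t+1, ] the input consumed by step t.
.rnn_bwd <- function(X, W_t, W_x, b, lengths) {
  q <- nrow(W_t); L <- dim(X)[2L]; B <- dim(X)[3L]
  S <- array(0, c(q, L + 1L, B))
  state <- matrix(0, q, B)
  for (t in L:1) {
    active <- lengths >= t
    if (any(active)) {
      new <- .sigmoid(W_t %*% state + W_x %*% .slice(X, t) + rep(b, B))
      state[, active] <- new[, active]
    }
    S[, t, ] <- state
  }
  S
}

#' Full-sequence attention block
#'
#' Bidirectional recurrence with shared weights: forward and backward sigmoid
#' recurrences over the embedded sequence are concatenated and projected back
#' to the hidden size through a tanh output layer.
#'
#' @param X p x n matrix, one column per sequence position.
#' @param params a [denoiser_params()].
#' @return q x n matrix of hidden states h_t.
#' @export
attn_full_block <- function(X, params) {
  .check_X(X, params)
  n <- ncol(X)
  Xa <- array(X, c(nrow(X), n, 1L))
  Ffwd <- .rnn_fwd(Xa, params$W_t, params$W_x, params$b)
  Rbwd <- .rnn_bwd(Xa, params$W_t, params$W_x, params$b, n)
  FR <- rbind(matrix(Ffwd[, , 1L], nrow = params$q),
              matrix(Rbwd[, seq_len(n), 1L], nrow = params$q))
  tanh(params$W_y %*% FR + params$b_y)
}

#' Noise-reduction attention block
#'
#' Single reverse-direction sigmoid recurrence (reading the sequence
#' backwards) followed by a tanh output projection; outputs are aligned to
#' forward positions.
#'
#' @inheritParams attn_full_block
#' @return q x n matrix of hidden states hhat_t.
#' @export
attn_noise_block <- function(X, params) {
  .check_X(X, params)
  n <- ncol(X)
  Xa <- array(X, c(nrow(X), n, 1L))
  G <- .rnn_bwd(Xa, params$What_t, params$What_x, params$bhat, n)
  tanh(params$What_y %*% matrix(G[, seq_len(n), 1L], nrow = params$q) +
         params$bhat_y)
}

#' Mix the two first-layer blocks
#'
#' Elementwise \eqn{v_t = \alpha h_t + \beta \hat h_t}. The defaults follow
#' the corpus conditional probabilities returned by [estimate_mix_weights()].
#'
#' @param h,hhat equal-shaped hidden-state matrices.
#' @param alpha,beta mixing weights.
#' @return matrix of mixed states.
#' @export
mix_states <- function(h, hhat, alpha, beta) {
  stopifnot(identical(dim(h), dim(hhat)))
  alpha * h + beta * hhat
}

#' Estimate the mixing weights from a corpus
#'
#' With A = "patient has any noise-set diagnosis" and B = "patient has the
#' trigger diagnosis": \eqn{\alpha = P(B|A)} and \eqn{\beta = P(A|B)}.
#'
#' @param records list of [patient_record()] objects.
#' @param noise_codes noise disease set.
#' @param trigger trigger disease code.
#' @return list with \code{alpha}, \code{beta} and the marginals
#'   \code{p_noise}, \code{p_trigger}.
#' @export
estimate_mix_weights <- function(records, noise_codes, trigger) {
  has <- function(r, codes) any(vapply(r$visits, function(v)
    any(v$codes %in% codes), FALSE))
  A <- vapply(records, has, FALSE, codes = noise_codes)
  B <- vapply(records, has, FALSE, codes = trigger)
  list(alpha = if (any(A)) mean(B[A]) else 0,
       beta = if (any(B)) mean(A[B]) else 0,
       p_noise = mean(A), p_trigger = mean(B))
}

#' Second attention layer (scaled dot-product)
#'
#' Learned linear projections of the mixed states give Q, K, V; the masked
#' row-softmax of \eqn{QK^\top/\sqrt{q}} yields the attention matrix, and the
#' per-position attention mass \eqn{a_i} is the column mean over valid query
#' rows (so \eqn{\sum_i a_i = 1} over non-pad positions).
#'
#' @param v q x n matrix of mixed states.
#' @param params a [denoiser_params()].
#' @param valid logical vector of non-pad positions (default: all).
#' @return list with \code{a} (attention mass per position, 0 at pads) and
#'   \code{context} (q x n attended representations).
#' @export
attn_second_layer <- function(v, params, valid = NULL) {
  stopifnot(is.matrix(v), ncol(v) >= 1L)
  n <- ncol(v)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (!any(valid)) stop("all positions are padded", call. = FALSE)
  idx <- which(valid)
  vv <- v[, idx, drop = FALSE]
  Q <- params$Wq %*% vv; K <- params$Wk %*% vv; V <- params$Wv %*% vv
  S <- crossprod(Q, K) / sqrt(params$q)
  A <- exp(S - apply(S, 1L, max))
  A <- A / rowSums(A)
  a_valid <- colMeans(A)
  a <- numeric(n); a[idx] <- a_valid
  ctx <- matrix(0, nrow(v), n)
  ctx[, idx] <- V %*% t(A)
  list(a = a, context = ctx)
}

#' Per-position scores and sequence score
#'
#' The dense score is \eqn{y_i = f_s(a_i) = \sigma(w' \, n a_i + b')} at
#' non-pad positions, and \eqn{\hat y = \sum_i y_i}. The attention mass is
#' length-normalized (\eqn{n a_i}, which equals 1 under uniform attention)
#' before the affine so that one threshold \eqn{\theta} is comparable across
#' sequences of different lengths; \eqn{\hat y} is a diagnostic proxy for
#' the expected kept-position count.
#'
#' @param a attention mass vector.
#' @param params a [denoiser_params()].
#' @param valid logical vector of non-pad positions (default: all).
#' @return list with \code{y} (scores, \code{NA} at pads) and \code{y_hat}.
#' @export
position_scores <- function(a, params, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(a))
  if (!any(valid)) stop("all positions are padded", call. = FALSE)
  n <- sum(valid)
  y <- rep(NA_real_, length(a))
  y[valid] <- .sigmoid(params$w_s * n * a[valid] + params$b_s)
  list(y = y, y_hat = sum(y[valid]))
}

#' Extract the denoised sequence
#'
#' Keeps position i iff \eqn{f_s(a_i) > \theta} (strictly), preserving the
#' original order, and zero-pads the end back to the original length. Visit
#' and time-interval entries travel with their positions.
#'
#' @param seqs an [aligned_sequences()].
#' @param scores numeric vector of dense scores \eqn{f_s(a_i)}, same length.
#' @param theta threshold in (0, 1).
#' @param pad_value pad sentinel for the code channel.
#' @return an [aligned_sequences()] of the original length.
#' @export
extract_sequence <- function(seqs, scores, theta = 0.5, pad_value = "0") {
  stopifnot(inherits(seqs, "aligned_sequences"),
            length(scores) == length(seqs$D), theta > 0, theta < 1)
  keep <- which(scores > theta)
  n <- length(seqs$D)
  k <- length(keep)
  aligned_sequences(c(seqs$D[keep], rep(pad_value, n - k)),
                    c(seqs$VS[keep], rep(0L, n - k)),
                    c(seqs$TIS[keep], rep(0L, n - k)))
}

# ---- batched forward/backward used by training ------------------------------

.denoiser_forward <- function(params, X, lengths, alpha, beta) {
  q <- params$q; L <- dim(X)[2L]; B <- dim(X)[3L]
  Ffwd <- .rnn_fwd(X, params$W_t, params$W_x, params$b)
  Rbwd <- .rnn_bwd(X, params$W_t, params$W_x, params$b, lengths)
  Ghat <- .rnn_bwd(X, params$What_t, params$What_x, params$bhat, lengths)
  H <- array(0, c(q, L, B)); Hhat <- array(0, c(q, L, B))
  for (t in seq_len(L)) {
    H[, t, ] <- tanh(params$W_y %*% rbind(.slice(Ffwd, t), .slice(Rbwd, t)) +
                       params$b_y)
    Hhat[, t, ] <- tanh(params$What_y %*% .slice(Ghat, t) + params$bhat_y)
  }
  V <- alpha * H + beta * Hhat
  attn <- vector("list", B)
  Ymat <- matrix(NA_real_, L, B)
  Amat <- matrix(0, L, B)
  for (b in seq_len(B)) {
    n <- lengths[b]
    vv <- matrix(V[, seq_len(n), b], nrow = q)
    Q <- params$Wq %*% vv; K <- params$Wk %*% vv
    S <- crossprod(Q, K) / sqrt(q)
    A <- exp(S - apply(S, 1L, max)); A <- A / rowSums(A)
    a <- colMeans(A)
    Amat[seq_len(n), b] <- a
    Ymat[seq_len(n), b] <- .sigmoid(params$w_s * n * a + params$b_s)
    attn[[b]] <- list(A = A, Q = Q, K = K, v = vv, a = a)
  }
  list(Ffwd = Ffwd, Rbwd = Rbwd, Ghat = Ghat, H = H, Hhat = Hhat, V = V,
       attn = attn, a = Amat, y = Ymat)
}

# labels: L x B matrix, 1 = noise, 0 = keep, NA = unlabeled.
# Loss: mean over labeled positions of BCE(f_s(a_i), 1 - label).
.denoiser_loss <- function(fw, labels) {
  lab <- !is.na(labels) & !is.na(fw$y)
  kappa <- 1 - labels[lab]
  yk <- pmin(pmax(fw$y[lab], 1e-12), 1 - 1e-12)
  -mean(kappa * log(yk) + (1 - kappa) * log(1 - yk))
}

.zeros_like <- function(params) {
  g <- lapply(params[1:13], function(m) if (is.matrix(m)) m * 0 else m * 0)
  g$w_s <- 0; g$b_s <- 0
  g
}

.denoiser_backward <- function(params, X, lengths, alpha, beta, fw, labels) {
  q <- params$q; L <- dim(X)[2L]; B <- dim(X)[3L]
  gr <- .zeros_like(params)
  n_lab <- sum(!is.na(labels) & !is.na(fw$y))
  if (n_lab == 0L) stop("no labeled positions", call. = FALSE)
  dV <- array(0, c(q, L, B))
  for (b in seq_len(B)) {
    n <- lengths[b]
    at <- fw$attn[[b]]
    y <- fw$y[seq_len(n), b]
    lb <- labels[seq_len(n), b]
    dz <- numeric(n)
    has <- !is.na(lb)
    if (any(has)) dz[has] <- (y[has] - (1 - lb[has])) / n_lab
    gr$w_s <- gr$w_s + sum(dz * n * at$a)
    gr$b_s <- gr$b_s + sum(dz)
    da <- params$w_s * n * dz
    # a = colMeans(A): dA[r, ] = da / n for every valid row r
    dArow <- da / n
    dots <- as.numeric(at$A %*% dArow)            # per-row sum(dA * A)
    dS <- at$A * (matrix(dArow, n, n, byrow = TRUE) - dots)
    dQ <- at$K %*% t(dS) / sqrt(q)
    dK <- at$Q %*% dS / sqrt(q)
    gr$Wq <- gr$Wq + dQ %*% t(at$v)
    gr$Wk <- gr$Wk + dK %*% t(at$v)
    dv <- crossprod(params$Wq, dQ) + crossprod(params$Wk, dK)
    dV[, seq_len(n), b] <- dv
  }
  dH <- alpha * dV; dHhat <- beta * dV

  # output projections (tanh)
  dFdir <- array(0, c(q, L, B)); dRdir <- array(0, c(q, L, B))
  dGdir <- array(0, c(q, L, B))
  for (t in seq_len(L)) {
    h <- .slice(fw$H, t); dU <- (1 - h^2) * .slice(dH, t)
    FR <- rbind(.slice(fw$Ffwd, t), .slice(fw$Rbwd, t))
    gr$W_y <- gr$W_y + dU %*% t(FR)
    gr$b_y <- gr$b_y + rowSums(dU)
    dFR <- crossprod(params$W_y, dU)
    dFdir[, t, ] <- dFR[seq_len(q), ]
    dRdir[, t, ] <- dFR[q + seq_len(q), ]
    hh <- .slice(fw$Hhat, t); dUh <- (1 - hh^2) * .slice(dHhat, t)
    gr$What_y <- gr$What_y + dUh %*% t(.slice(fw$Ghat, t))
    gr$bhat_y <- gr$bhat_y + rowSums(dUh)
    dGdir[, t, ] <- crossprod(params$What_y, dUh)
  }

  # BPTT, forward direction of the full block (shared weights)
  dAcc <- matrix(0, q, B)
  for (t in L:1) {
    Ft <- .slice(fw$Ffwd, t)
    dtot <- .slice(dFdir, t) + crossprod(params$W_t, dAcc)
    dAcc <- Ft * (1 - Ft) * dtot
    prev <- if (t > 1L) .slice(fw$Ffwd, t - 1L) else matrix(0, q, B)
    gr$W_t <- gr$W_t + dAcc %*% t(prev)
    gr$W_x <- gr$W_x + dAcc %*% t(.slice(X, t))
    gr$b <- gr$b + rowSums(dAcc)
  }
  # BPTT, backward direction of the full block (same weights, reversed chain)
  dAcc <- matrix(0, q, B)
  for (t in seq_len(L)) {
    active <- matrix(rep(lengths >= t, each = q), q, B)
    Rt <- .slice(fw$Rbwd, t)
    dtot <- .slice(dRdir, t) + crossprod(params$W_t, dAcc)
    dAcc <- active * Rt * (1 - Rt) * dtot
    nxt <- .slice(fw$Rbwd, t + 1L)
    gr$W_t <- gr$W_t + dAcc %*% t(nxt)
    gr$W_x <- gr$W_x + dAcc %*% t(.slice(X, t))
    gr$b <- gr$b + rowSums(dAcc)
  }
  # BPTT, noise block (reverse chain, hatted weights)
  dAcc <- matrix(0, q, B)
  for (t in seq_len(L)) {
    active <- matrix(rep(lengths >= t, each = q), q, B)
    Gt <- .slice(fw$Ghat, t)
    dtot <- .slice(dGdir, t) + crossprod(params$What_t, dAcc)
    dAcc <- active * Gt * (1 - Gt) * dtot
    nxt <- .slice(fw$Ghat, t + 1L)
    gr$What_t <- gr$What_t + dAcc %*% t(nxt)
    gr$What_x <- gr$What_x + dAcc %*% t(.slice(X, t))
    gr$bhat <- gr$bhat + rowSums(dAcc)
  }
  gr
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(params, keys) {
  list(m = lapply(params[keys], function(x) x * 0),
       v = lapply(params[keys], function(x) x * 0), t = 0L)
}

.adam_step <- function(params, gr, st, keys, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  for (k in keys) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * gr[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * gr[[k]]^2
    mh <- st$m[[k]] / (1 - beta1^st$t)
    vh <- st$v[[k]] / (1 - beta2^st$t)
    params[[k]] <- params[[k]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, st = st)
}

.denoiser_keys <- c("W_t", "W_x", "b", "W_y", "b_y", "What_t", "What_x",
                    "bhat", "What_y", "bhat_y", "Wq", "Wk", "w_s", "b_s")

.pack_batch <- function(X_list, p) {
  lengths <- vapply(X_list, ncol, 0L)
  L <- max(lengths); B <- length(X_list)
  X <- array(0, c(p, L, B))
  for (b in seq_len(B)) X[, seq_len(lengths[b]), b] <- X_list[[b]]
  list(X = X, lengths = lengths)
}

#' Train the denoiser (semi-supervised)
#'
#' Minimizes the binary cross-entropy of the keep score \eqn{f_s(a_i)}
#' against keep/noise labels at labeled positions only: label 1 marks a
#' position whose code is in the noise set, label 0 a trigger/target
#' position, \code{NA} an unlabeled position (which contributes no loss).
#' Optimized with Adam; deterministic under a fixed seed.
#'
#' @param X_list list of p x n embedded sequences.
#' @param labels_list list of numeric vectors (1/0/\code{NA}) parallel to
#'   \code{X_list}.
#' @param params a [denoiser_params()]; initialized from \code{seed} when
#'   \code{NULL}.
#' @param q hidden size used when initializing.
#' @param alpha,beta mixing weights (see [estimate_mix_weights()]).
#' @param epochs training epochs; 0 returns \code{params} unchanged.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed for initialization and shuffling.
#' @return list with \code{params} (fitted), \code{loss_trace} (per-epoch
#'   mean minibatch loss), \code{alpha}, \code{beta}.
#' @export
train_denoiser <- function(X_list, labels_list, params = NULL, q = 16L,
                           alpha = 1, beta = 0.2107, epochs = 10L, lr = 2e-2,
                           batch_size = 64L, seed = 1L) {
  stopifnot(length(X_list) == length(labels_list), length(X_list) > 0L)
  p <- nrow(X_list[[1L]])
  if (is.null(params)) params <- denoiser_params(p, q, seed = seed)
  if (sum(vapply(labels_list, function(l) sum(!is.na(l)), 0L)) == 0L) {
    stop("semi-supervision requires at least one labeled position", call. = FALSE)
  }
  if (epochs == 0L) {
    return(list(params = params, loss_trace = numeric(0),
                alpha = alpha, beta = beta))
  }
  N <- length(X_list)
  trace <- numeric(epochs)
  with_seed_(seed + 1L, {
    st <- .adam_init(params, .denoiser_keys)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      losses <- c()
      for (start in seq(1L, N, by = batch_size)) {
        ii <- ord[start:min(start + batch_size - 1L, N)]
        pk <- .pack_batch(X_list[ii], p)
        L <- dim(pk$X)[2L]
        lab <- matrix(NA_real_, L, length(ii))
        for (j in seq_along(ii)) {
          lab[seq_len(pk$lengths[j]), j] <- labels_list[[ii[j]]]
        }
        fw <- .denoiser_forward(params, pk$X, pk$lengths, alpha, beta)
        if (!any(!is.na(lab) & !is.na(fw$y))) next
        losses <- c(losses, .denoiser_loss(fw, lab))
        gr <- .denoiser_backward(params, pk$X, pk$lengths, alpha, beta, fw, lab)
        upd <- .adam_step(params, gr, st, .denoiser_keys, lr)
        params <- upd$params; st <- upd$st
      }
      trace[ep] <- mean(losses)
    }
  })
  list(params = params, loss_trace = trace, alpha = alpha, beta = beta)
}

#' Dense keep scores for one sequence
#'
#' Runs the full denoiser forward pass (both first-layer blocks, mixing,
#' second attention, scoring head) and returns \eqn{f_s(a_i)} per position.
#'
#' @param params a [denoiser_params()].
#' @param X p x n embedded sequence.
#' @param alpha,beta mixing weights.
#' @return numeric vector of keep scores in (0, 1).
#' @export
denoiser_scores <- function(params, X, alpha = 1, beta = 0.2107) {
  h <- attn_full_block(X, params)
  hh <- attn_noise_block(X, params)
  v <- mix_states(h, hh, alpha, beta)
  at <- attn_second_layer(v, params)
  position_scores(at$a, params)$y
}

#' Serialize / restore denoiser parameters
#'
#' Checkpoints are JSON with a shape manifest and the initialization seed,
#' so they survive as plain text.
#'
#' @param params a [denoiser_params()].
#' @param path file path.
#' @return \code{path} (write) or a \code{denoiser_params} (read).
#' @export
write_denoiser <- function(params, path) {
  obj <- lapply(unclass(params), function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x)) else x
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_denoiser
#' @export
read_denoiser <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(obj, function(x) {
    if (is.list(x) && !is.null(x$dim)) matrix(x$data, x$dim[1L], x$dim[2L])
    else if (length(x) > 1L) as.numeric(x) else x
  })
  class(out) <- "denoiser_params"
  out
}
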