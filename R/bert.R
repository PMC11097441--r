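# Compact BERT-style encoder over diagnosis sequences.
#
# Input embeddings follow the three aligned channels: token embedding of the
# (denoised) disease sequence, segment embedding of the visit index, and a
# positional embedding of the bucketized time-interval sequence. The encoder
# is a standard post-LayerNorm transformer (multi-head scaled dot-product
# attention + ReLU feed-forward, residuals) with a masked-code head and a
# binary next-sentence head on [CLS]. Forward and backward passes are
# hand-written (batched matrix ops); finite-difference tests check the
# gradients.

#' Encoder configuration
#'
#' @param n_layers,n_heads,hidden transformer depth, heads, and width
#'   (hidden must be divisible by heads). Defaults give the desk-scale
#'   2-layer, 2-head, 64-wide encoder.
#' @param d_ff feed-forward width (default \code{4 * hidden}).
#' @param L maximum sequence length (default 75; 285 is the supported long
#'   alternative).
#' @param max_visit segment-embedding cap.
#' @param n_time number of time-interval buckets.
#' @param seed initialization seed.
#' @return a list of class \code{bert_config}.
#' @export
bert_config <- function(n_layers = 2L, n_heads = 2L, hidden = 64L,
                        d_ff = NULL, L = 75L, max_visit = 50L, n_time = 6L,
                        seed = 1L) {
  if (is.null(d_ff)) d_ff <- 4L * hidden
  stopifnot(hidden %% n_heads == 0L, L >= 4L)
  structure(list(n_layers = n_layers, n_heads = n_heads, hidden = hidden,
                 d_ff = d_ff, L = L, max_visit = max_visit, n_time = n_time,
                 seed = seed),
            class = "bert_config")
}

.ln_eps <- 1e-5

#' Initialize an encoder model
#'
#' @param config a [bert_config()].
#' @param vocab a [dx_vocabulary()].
#' @param seed overrides \code{config$seed} when given.
#' @return object of class \code{bert_model} holding \code{params},
#'   \code{config} and \code{vocab}.
#' @export
bert_init <- function(config, vocab, seed = config$seed) {
  d <- config$hidden; V <- length(vocab$tokens)
  with_seed_(seed, {
    g <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
    layer <- function() list(
      Wq = g(d, d), bq = numeric(d), Wk = g(d, d), bk = numeric(d),
      Wv = g(d, d), bv = numeric(d), Wo = g(d, d), bo = numeric(d),
      g1 = rep(1, d), c1 = numeric(d),
      W1 = g(d, config$d_ff), bf1 = numeric(config$d_ff),
      W2 = g(config$d_ff, d), bf2 = numeric(d),
      g2 = rep(1, d), c2 = numeric(d))
    params <- list(
      E_tok = g(V, d), E_seg = g(config$max_visit, d),
      E_time = g(config$n_time, d), E_side = g(2L, d),
      layers = lapply(seq_len(config$n_layers), function(i) layer()),
      W_mlm = g(d, V), b_mlm = numeric(V),
      w_cls = stats::rnorm(d, sd = 0.02), b_cls = 0)
    structure(list(params = params, config = config, vocab = vocab,
                   seed = seed),
              class = "bert_model")
  })
}

#' @export
print.bert_model <- function(x, ...) {
  cat(sprintf("bert_model: %d layers, %d heads, hidden %d, L %d, vocab %d\n",
              x$config$n_layers, x$config$n_heads, x$config$hidden,
              x$config$L, length(x$vocab$tokens)))
  invisible(x)
}

# nested-list arithmetic for params/grads/Adam state
.tmap <- function(f, x) if (is.list(x)) lapply(x, .tmap, f = f) else f(x)
.tmap2 <- function(f, x, y) {
  if (is.list(x)) Map(function(a, b) .tmap2(f, a, b), x, y) else f(x, y)
}

.addb <- function(M, b) M + rep(b, each = nrow(M))

.ln_fwd <- function(X, g, c) {
  mu <- rowMeans(X); xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + .ln_eps)
  xhat <- xc * inv
  list(Y = .addb(xhat * rep(g, each = nrow(X)), c), xhat = xhat, inv = inv)
}

.ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = nrow(dY))
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), dc = colSums(dY))
}

.stack_encodings <- function(encs) {
  B <- length(encs); L <- length(encs[[1L]]$token_ids)
  tok <- matrix(0L, B, L); seg <- matrix(0L, B, L)
  tim <- matrix(0L, B, L); sid <- matrix(1L, B, L)
  msk <- matrix(FALSE, B, L)
  for (b in seq_len(B)) {
    tok[b, ] <- encs[[b]]$token_ids; seg[b, ] <- encs[[b]]$segment_ids
    tim[b, ] <- encs[[b]]$time_ids;  msk[b, ] <- encs[[b]]$pad_mask
    if (!is.null(encs[[b]]$side_ids)) sid[b, ] <- encs[[b]]$side_ids
  }
  list(tok = tok, seg = seg, tim = tim, sid = sid, mask = msk, B = B, L = L)
}

# Forward (and optional backward) pass over one stacked batch.
# mlm_targets: list(rows = global row indices, ids = original token ids).
# nsp_labels: length-B 0/1 vector (NULL disables the sentence head).
.bert_apply <- function(params, cfg, bt, mlm_targets = NULL,
                        nsp_labels = NULL, want_grad = FALSE) {
  d <- cfg$hidden; nh <- cfg$n_heads; dh <- d %/% nh
  B <- bt$B; L <- bt$L; N <- B * L
  tokv <- as.integer(t(bt$tok)); segv <- as.integer(t(bt$seg))
  timv <- as.integer(t(bt$tim)); sidv <- as.integer(t(bt$sid))
  H <- params$E_tok[tokv, , drop = FALSE] +
    params$E_seg[segv, , drop = FALSE] +
    params$E_time[timv, , drop = FALSE] +
    params$E_side[sidv, , drop = FALSE]
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    ly <- params$layers[[l]]
    X <- H
    Q <- .addb(X %*% ly$Wq, ly$bq); K <- .addb(X %*% ly$Wk, ly$bk)
    Vm <- .addb(X %*% ly$Wv, ly$bv)
    C <- matrix(0, N, d)
    Acache <- vector("list", B)
    for (b in seq_len(B)) {
      rows <- (b - 1L) * L + seq_len(L)
      keymask <- bt$mask[b, ]
      Ah <- vector("list", nh)
      for (h in seq_len(nh)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) / sqrt(dh)
        S[, !keymask] <- -Inf
        A <- exp(S - apply(S, 1L, max))
        A <- A / rowSums(A)
        C[rows, cols] <- A %*% Vm[rows, cols, drop = FALSE]
        Ah[[h]] <- A
      }
      Acache[[b]] <- Ah
    }
    O <- .addb(C %*% ly$Wo, ly$bo)
    R1 <- X + O
    ln1 <- .ln_fwd(R1, ly$g1, ly$c1)
    H1 <- ln1$Y
    Pre <- .addb(H1 %*% ly$W1, ly$bf1)
    F1 <- pmax(Pre, 0)
    R2 <- H1 + .addb(F1 %*% ly$W2, ly$bf2)
    ln2 <- .ln_fwd(R2, ly$g2, ly$c2)
    caches[[l]] <- list(X = X, Q = Q, K = K, Vm = Vm, C = C, A = Acache,
                        ln1 = ln1, H1 = H1, F1 = F1, ln2 = ln2)
    H <- ln2$Y
  }

  out <- list(H = H)
  loss <- 0
  dH <- if (want_grad) matrix(0, N, d) else NULL

  if (!is.null(mlm_targets) && length(mlm_targets$rows) > 0L) {
    M <- length(mlm_targets$rows)
    logits <- .addb(H[mlm_targets$rows, , drop = FALSE] %*% params$W_mlm,
                    params$b_mlm)
    lse <- apply(logits, 1L, function(z) { m <- max(z); m + log(sum(exp(z - m))) })
    picked <- logits[cbind(seq_len(M), mlm_targets$ids)]
    out$mlm_loss <- mean(lse - picked)
    P <- exp(logits - lse)
    out$mlm_acc <- mean(max.col(logits) == mlm_targets$ids)
    loss <- loss + out$mlm_loss
    if (want_grad) {
      dlog <- P
      dlog[cbind(seq_len(M), mlm_targets$ids)] <-
        dlog[cbind(seq_len(M), mlm_targets$ids)] - 1
      dlog <- dlog / M
      gW_mlm <- crossprod(H[mlm_targets$rows, , drop = FALSE], dlog)
      gb_mlm <- colSums(dlog)
      dH[mlm_targets$rows, ] <- dH[mlm_targets$rows, ] +
        tcrossprod(dlog, params$W_mlm)
    }
  } else { gW_mlm <- NULL }

  if (!is.null(nsp_labels)) {
    cls_rows <- (seq_len(B) - 1L) * L + 1L
    z <- as.numeric(H[cls_rows, , drop = FALSE] %*% params$w_cls) + params$b_cls
    p <- .sigmoid(z)
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    out$nsp_loss <- -mean(nsp_labels * log(pc) + (1 - nsp_labels) * log(1 - pc))
    out$probs <- p
    out$nsp_acc <- mean((p > 0.5) == (nsp_labels > 0.5))
    loss <- loss + out$nsp_loss
    if (want_grad) {
      dz <- (p - nsp_labels) / B
      gw_cls <- as.numeric(crossprod(H[cls_rows, , drop = FALSE], dz))
      gb_cls <- sum(dz)
      dH[cls_rows, ] <- dH[cls_rows, ] + outer(dz, params$w_cls)
    }
  } else {
    cls_rows <- (seq_len(B) - 1L) * L + 1L
    out$probs <- .sigmoid(as.numeric(H[cls_rows, , drop = FALSE] %*%
                                       params$w_cls) + params$b_cls)
    gw_cls <- NULL
  }
  out$loss <- loss
  if (!want_grad) return(out)

  gr <- .tmap(function(x) x * 0, params)
  if (!is.null(gW_mlm)) { gr$W_mlm <- gW_mlm; gr$b_mlm <- gb_mlm }
  if (!is.null(gw_cls)) { gr$w_cls <- gw_cls; gr$b_cls <- gb_cls }

  for (l in rev(seq_len(cfg$n_layers))) {
    ly <- params$layers[[l]]; ca <- caches[[l]]
    bw2 <- .ln_bwd(dH, ca$ln2, ly$g2)
    gr$layers[[l]]$g2 <- bw2$dg; gr$layers[[l]]$c2 <- bw2$dc
    dR2 <- bw2$dX
    dF2 <- dR2
    gr$layers[[l]]$W2 <- crossprod(ca$F1, dF2)
    gr$layers[[l]]$bf2 <- colSums(dF2)
    dF1 <- tcrossprod(dF2, ly$W2)
    dPre <- dF1 * (ca$F1 > 0)
    gr$layers[[l]]$W1 <- crossprod(ca$H1, dPre)
    gr$layers[[l]]$bf1 <- colSums(dPre)
    dH1 <- dR2 + tcrossprod(dPre, ly$W1)
    bw1 <- .ln_bwd(dH1, ca$ln1, ly$g1)
    gr$layers[[l]]$g1 <- bw1$dg; gr$layers[[l]]$c1 <- bw1$dc
    dR1 <- bw1$dX
    dO <- dR1
    gr$layers[[l]]$Wo <- crossprod(ca$C, dO)
    gr$layers[[l]]$bo <- colSums(dO)
    dC <- tcrossprod(dO, ly$Wo)
    dQ <- matrix(0, N, d); dK <- matrix(0, N, d); dV <- matrix(0, N, d)
    for (b in seq_len(B)) {
      rows <- (b - 1L) * L + seq_len(L)
      for (h in seq_len(nh)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        A <- ca$A[[b]][[h]]
        dctx <- dC[rows, cols, drop = FALSE]
        dA <- tcrossprod(dctx, ca$Vm[rows, cols, drop = FALSE])
        dV[rows, cols] <- dV[rows, cols] + crossprod(A, dctx)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- dQ[rows, cols] +
          dS %*% ca$K[rows, cols, drop = FALSE] / sqrt(dh)
        dK[rows, cols] <- dK[rows, cols] +
          crossprod(dS, ca$Q[rows, cols, drop = FALSE]) / sqrt(dh)
      }
    }
    gr$layers[[l]]$Wq <- crossprod(ca$X, dQ); gr$layers[[l]]$bq <- colSums(dQ)
    gr$layers[[l]]$Wk <- crossprod(ca$X, dK); gr$layers[[l]]$bk <- colSums(dK)
    gr$layers[[l]]$Wv <- crossprod(ca$X, dV); gr$layers[[l]]$bv <- colSums(dV)
    dH <- dR1 + tcrossprod(dQ, ly$Wq) + tcrossprod(dK, ly$Wk) +
      tcrossprod(dV, ly$Wv)
  }
  agg <- rowsum(dH, tokv)
  gr$E_tok[as.integer(rownames(agg)), ] <- agg
  agg <- rowsum(dH, segv)
  gr$E_seg[as.integer(rownames(agg)), ] <- agg
  agg <- rowsum(dH, timv)
  gr$E_time[as.integer(rownames(agg)), ] <- agg
  agg <- rowsum(dH, sidv)
  gr$E_side[as.integer(rownames(agg)), ] <- agg
  out$grads <- gr
  out
}

.tadam_init <- function(params) {
  list(m = .tmap(function(x) x * 0, params),
       v = .tmap(function(x) x * 0, params), t = 0L)
}

.tadam_step <- function(params, gr, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, frozen = character(0)) {
  st$t <- st$t + 1L
  st$m <- .tmap2(function(m, g) beta1 * m + (1 - beta1) * g, st$m, gr)
  st$v <- .tmap2(function(v, g) beta2 * v + (1 - beta2) * g^2, st$v, gr)
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  upd <- .tmap2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps), st$m, st$v)
  for (nm in frozen) upd[[nm]] <- .tmap(function(x) x * 0, upd[[nm]])
  params <- .tmap2(`-`, params, upd)
  list(params = params, st = st)
}

# Draw MLM corruption for a batch and return stacked inputs + target map.
.mask_batch <- function(encs, vocab, policy) {
  rows <- integer(0); ids <- integer(0)
  L <- length(encs[[1L]]$token_ids)
  for (b in seq_along(encs)) {
    mk <- apply_mlm_mask(encs[[b]], vocab, policy)
    encs[[b]] <- mk$encoding
    if (length(mk$targets) > 0L) {
      rows <- c(rows, (b - 1L) * L + as.integer(names(mk$targets)))
      ids <- c(ids, unname(mk$targets))
    }
  }
  list(bt = .stack_encodings(encs), targets = list(rows = rows, ids = ids))
}

#' Pretrain the encoder (masked-code + next-sentence)
#'
#' Joint training: cross-entropy at corrupted positions plus binary
#' cross-entropy of the sentence head on \code{[CLS]}. Deterministic under a
#' fixed seed in a single-threaded run.
#'
#' @param model a [bert_init()] model.
#' @param examples list of [make_nsp_example()] results (already balanced if
#'   desired, see [balance_pretraining()]).
#' @param policy a [masking_policy()].
#' @param epochs,batch_size,lr training schedule (0 epochs returns the model
#'   unchanged, with an empty loss trace).
#' @param seed integer seed for masking and shuffling.
#' @return the model with fitted params and a \code{loss_trace} data.frame
#'   (epoch, loss, mlm_loss, nsp_loss).
#' @export
pretrain_bert <- function(model, examples, policy = masking_policy(),
                          epochs = 3L, batch_size = 32L, lr = 1e-3,
                          seed = 1L) {
  stopifnot(inherits(model, "bert_model"), length(examples) > 0L)
  if (epochs == 0L) { model$loss_trace <- data.frame(); return(model) }
  params <- model$params; cfg <- model$config; vocab <- model$vocab
  N <- length(examples)
  trace <- NULL
  with_seed_(seed, {
    st <- .tadam_init(params)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ls <- ml <- ns <- c()
      for (start in seq(1L, N, by = batch_size)) {
        ii <- ord[start:min(start + batch_size - 1L, N)]
        encs <- lapply(examples[ii], `[[`, "encoding")
        labs <- vapply(examples[ii], `[[`, 0L, "label")
        mb <- .mask_batch(encs, vocab, policy)
        res <- .bert_apply(params, cfg, mb$bt, mlm_targets = mb$targets,
                           nsp_labels = labs, want_grad = TRUE)
        upd <- .tadam_step(params, res$grads, st, lr)
        params <- upd$params; st <- upd$st
        ls <- c(ls, res$loss)
        ml <- c(ml, if (is.null(res$mlm_loss)) NA_real_ else res$mlm_loss)
        ns <- c(ns, res$nsp_loss)
      }
      trace <- rbind(trace, data.frame(epoch = ep, loss = mean(ls),
                                       mlm_loss = mean(ml, na.rm = TRUE),
                                       nsp_loss = mean(ns)))
    }
  })
  model$params <- params
  model$loss_trace <- trace
  model
}

#' Fine-tune the encoder for target-disease prediction
#'
#' Attaches a freshly initialized prediction head on \code{[CLS]} and updates
#' it (and, unless \code{freeze_body}, the encoder body) by gradient descent
#' on the binary next-sentence objective.
#'
#' @param model a pretrained [bert_init()] model.
#' @param examples labeled [make_nsp_example()] list.
#' @param epochs,batch_size,lr schedule; 0 epochs returns the model with the
#'   new head but an unchanged body.
#' @param freeze_body update only the head when \code{TRUE}.
#' @param seed integer seed (head init + shuffling).
#' @return the fine-tuned model with a \code{finetune_trace}.
#' @export
finetune_bert <- function(model, examples, epochs = 5L, batch_size = 32L,
                          lr = 1e-3, freeze_body = FALSE, seed = 1L) {
  stopifnot(inherits(model, "bert_model"), length(examples) > 0L)
  params <- model$params; cfg <- model$config
  with_seed_(seed, {
    params$w_cls <- stats::rnorm(cfg$hidden, sd = 0.02)
    params$b_cls <- 0
  })
  if (epochs == 0L) { model$params <- params; model$finetune_trace <- data.frame(); return(model) }
  frozen <- if (freeze_body)
    setdiff(names(params), c("w_cls", "b_cls")) else character(0)
  N <- length(examples)
  trace <- NULL
  with_seed_(seed + 1L, {
    st <- .tadam_init(params)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ls <- ac <- c()
      for (start in seq(1L, N, by = batch_size)) {
        ii <- ord[start:min(start + batch_size - 1L, N)]
        bt <- .stack_encodings(lapply(examples[ii], `[[`, "encoding"))
        labs <- vapply(examples[ii], `[[`, 0L, "label")
        res <- .bert_apply(params, cfg, bt, nsp_labels = labs,
                           want_grad = TRUE)
        upd <- .tadam_step(params, res$grads, st, lr, frozen = frozen)
        params <- upd$params; st <- upd$st
        ls <- c(ls, res$loss); ac <- c(ac, res$nsp_acc)
      }
      trace <- rbind(trace, data.frame(epoch = ep, loss = mean(ls),
                                       accuracy = mean(ac)))
    }
  })
  model$params <- params
  model$finetune_trace <- trace
  model
}

#' Predict the target-onset probability for encoded examples
#'
#' @param model a fine-tuned [bert_init()] model.
#' @param examples list of [make_nsp_example()] results (entries may be
#'   \code{NULL} for excluded patients; their probability is \code{NA},
#'   the explicit "not scoreable" result).
#' @return numeric vector of probabilities in [0, 1] (or \code{NA}).
#' @export
predict_bert <- function(model, examples) {
  ok <- !vapply(examples, is.null, FALSE)
  out <- rep(NA_real_, length(examples))
  if (!any(ok)) return(out)
  bt <- .stack_encodings(lapply(examples[ok], `[[`, "encoding"))
  res <- .bert_apply(model$params, model$config, bt)
  out[ok] <- res$probs
  out
}

# recursive (de)serialization of the nested parameter tree
.ser_tree <- function(x) {
  if (is.list(x)) lapply(x, .ser_tree)
  else if (is.matrix(x)) list(.dim = dim(x), .data = as.numeric(x))
  else x
}

.deser_tree <- function(x) {
  if (is.list(x) && !is.null(x$.dim)) matrix(x$.data, x$.dim[1L], x$.dim[2L])
  else if (is.list(x)) lapply(x, .deser_tree)
  else if (length(x) > 1L) as.numeric(x) else x
}

#' Serialize / restore an encoder checkpoint
#'
#' Plain-text JSON checkpoint carrying the weights, the configuration, the
#' vocabulary and the initialization seed.
#'
#' @param model a [bert_init()] model.
#' @param path file path.
#' @return \code{path} (write) or a \code{bert_model} (read).
#' @export
write_bert <- function(model, path) {
  stopifnot(inherits(model, "bert_model"))
  obj <- list(params = .ser_tree(model$params),
              config = unclass(model$config),
              vocab = unclass(model$vocab), seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bert
#' @export
read_bert <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  cfg <- obj$config; class(cfg) <- "bert_config"
  vocab <- obj$vocab
  vocab$tokens <- as.character(vocab$tokens)
  class(vocab) <- "dx_vocab"
  structure(list(params = .deser_tree(obj$params), config = cfg,
                 vocab = vocab, seed = obj$seed),
            class = "bert_model")
}
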