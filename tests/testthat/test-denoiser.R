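# The denoiser is hand-differentiated; the finite-difference check below is
# the authoritative guard on every parameter group.

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  p <- 3L; q <- 4L
  params <- denoiser_params(p, q, seed = 7L)
  X_list <- list(matrix(rnorm(p * 5), p, 5), matrix(rnorm(p * 3), p, 3))
  lab <- list(c(1, NA, 0, 1, NA), c(0, 1, NA))
  alpha <- 0.8; beta <- 0.4
  pk <- dxbert:::.pack_batch(X_list, p)
  L <- dim(pk$X)[2L]
  labm <- matrix(NA_real_, L, 2L)
  for (j in 1:2) labm[seq_len(pk$lengths[j]), j] <- lab[[j]]
  fw <- dxbert:::.denoiser_forward(params, pk$X, pk$lengths, alpha, beta)
  gr <- dxbert:::.denoiser_backward(params, pk$X, pk$lengths, alpha, beta,
                                    fw, labm)
  lossfun <- function(pp) {
    dxbert:::.denoiser_loss(
      dxbert:::.denoiser_forward(pp, pk$X, pk$lengths, alpha, beta), labm)
  }
  eps <- 1e-6
  for (k in dxbert:::.denoiser_keys) {
    for (i in sample(length(params[[k]]), min(4L, length(params[[k]])))) {
      pp <- params; pp[[k]][i] <- pp[[k]][i] + eps; up <- lossfun(pp)
      pp[[k]][i] <- pp[[k]][i] - 2 * eps; dn <- lossfun(pp)
      expect_equal(gr[[k]][i], (up - dn) / (2 * eps), tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", k, i))
    }
  }
})

test_that("full block handles degenerate inputs analytically", {
  p <- 2L; q <- 3L
  params <- denoiser_params(p, q, seed = 1L)
  # n = 1: one column out, finite
  h1 <- attn_full_block(matrix(0.3, p, 1L), params)
  expect_identical(dim(h1), c(q, 1L))
  # zero input, zero recurrent weights and biases: every pre-activation is 0,
  # the recurrence sits at sigmoid(0) = 0.5 and the output at tanh(W_y 0.5+0)
  pz <- params
  pz$W_t[] <- 0; pz$b[] <- 0; pz$W_x[] <- 0
  X0 <- matrix(0, p, 4L)
  h <- attn_full_block(X0, pz)
  want <- tanh(pz$W_y %*% matrix(0.5, 2L * q, 1L) + pz$b_y)
  for (t in 1:4) expect_equal(h[, t], as.numeric(want))
})

test_that("a 1-dimensional full block matches a hand-unrolled recurrence", {
  params <- denoiser_params(1L, 1L, seed = 2L)
  params$W_t[] <- 0.5; params$W_x[] <- 1; params$b[] <- 0.1
  params$W_y <- matrix(c(0.7, -0.3), 1L, 2L); params$b_y[] <- 0.2
  x <- c(0.4, -0.2, 0.9)
  sg <- function(z) 1 / (1 + exp(-z))
  f1 <- sg(0.5 * 0 + x[1] + 0.1); f2 <- sg(0.5 * f1 + x[2] + 0.1)
  f3 <- sg(0.5 * f2 + x[3] + 0.1)
  r3 <- sg(0.5 * 0 + x[3] + 0.1); r2 <- sg(0.5 * r3 + x[2] + 0.1)
  r1 <- sg(0.5 * r2 + x[1] + 0.1)
  want <- tanh(0.7 * c(f1, f2, f3) - 0.3 * c(r1, r2, r3) + 0.2)
  got <- attn_full_block(matrix(x, 1L), params)
  expect_equal(as.numeric(got), want)
})

test_that("the noise block is the reversal of a forward pass", {
  p <- 3L; q <- 4L
  params <- denoiser_params(p, q, seed = 5L)
  X <- matrix(rnorm(p * 6), p, 6)
  got <- attn_noise_block(X, params)
  # oracle: run the same weights forward over the reversed input
  fwd_params <- params
  fwd_params$W_t <- params$What_t; fwd_params$W_x <- params$What_x
  fwd_params$b <- params$bhat
  Xr <- X[, 6:1, drop = FALSE]
  S <- dxbert:::.rnn_fwd(array(Xr, c(p, 6L, 1L)), fwd_params$W_t,
                         fwd_params$W_x, fwd_params$b)
  want <- tanh(params$What_y %*% matrix(S[, 6:1, 1L], q) + params$bhat_y)
  expect_equal(got, want)
  # n = 1 equals a single forward step
  x1 <- X[, 1L, drop = FALSE]
  one <- tanh(params$What_y %*%
                dxbert:::.sigmoid(params$What_x %*% x1 + params$bhat) +
                params$bhat_y)
  expect_equal(attn_noise_block(x1, params), one)
})

test_that("mixing is the stated linear combination and additive in weights", {
  h <- matrix(rnorm(12), 3L); hh <- matrix(rnorm(12), 3L)
  expect_identical(mix_states(h, hh, 1, 0), h)
  expect_identical(mix_states(h, hh, 0, 1), hh)
  expect_equal(mix_states(h, hh, 1, 0.2107), 1 * h + 0.2107 * hh)
  expect_equal(mix_states(h, hh, 0.3, 0.6) + mix_states(h, hh, 0.5, 0.1),
               mix_states(h, hh, 0.8, 0.7))
})

test_that("second attention layer normalizes mass and honours masks", {
  q <- 4L
  params <- denoiser_params(2L, q, seed = 3L)
  # identical states at every position -> uniform mass 1/n
  v <- matrix(rep(rnorm(q), 5L), q, 5L)
  at <- attn_second_layer(v, params)
  expect_equal(at$a, rep(1 / 5, 5L), tolerance = 1e-12)
  # random inputs: the mass is a distribution over non-pad positions
  for (i in 1:5) {
    vr <- matrix(rnorm(q * 7), q, 7L)
    valid <- c(rep(TRUE, 5L), FALSE, FALSE)
    ar <- attn_second_layer(vr, params, valid = valid)
    expect_equal(sum(ar$a), 1, tolerance = 1e-6)
    expect_true(all(ar$a[!valid] == 0))
    expect_true(all(ar$a >= 0))
  }
  expect_error(attn_second_layer(v, params, valid = rep(FALSE, 5L)), "padded")
})

test_that("a 1-dim two-position attention matches the closed-form softmax", {
  params <- denoiser_params(1L, 1L, seed = 4L)
  params$Wq[] <- 2; params$Wk[] <- 1; params$Wv[] <- 1
  v <- matrix(c(0.5, -0.25), 1L, 2L)
  S <- outer(2 * as.numeric(v), as.numeric(v))  # q_i * k_j / sqrt(1)
  A <- exp(S) / rowSums(exp(S))
  want <- colMeans(A)
  at <- attn_second_layer(v, params)
  expect_equal(at$a, want, tolerance = 1e-12)
})

test_that("position scores follow the affine-sigmoid head", {
  params <- denoiser_params(1L, 1L, seed = 1L)
  params$w_s <- 0; params$b_s <- 0
  a <- rep(1 / 6, 6L)
  ps <- position_scores(a, params)
  expect_equal(ps$y, rep(0.5, 6L))
  expect_equal(ps$y_hat, 3)
  params$w_s <- 2; params$b_s <- -0.5
  a2 <- c(0.5, 0.3, 0.2)
  ps2 <- position_scores(a2, params)
  expect_equal(ps2$y, 1 / (1 + exp(-(2 * 3 * a2 - 0.5))))
  expect_error(position_scores(a2, params, valid = rep(FALSE, 3L)), "padded")
})

test_that("extraction keeps above-threshold positions in order and re-pads", {
  s <- derive_sequences(worked_example())
  all_kept <- extract_sequence(s, rep(1, 8L) - 1e-9, theta = 0.5)
  expect_identical(all_kept, s)
  none <- extract_sequence(s, rep(0, 8L) + 1e-9, theta = 0.5)
  expect_identical(none$D, rep("0", 8L))
  s3 <- aligned_sequences(c("A", "B", "C"), 1:3, c(0L, 5L, 2L))
  got <- extract_sequence(s3, c(0.9, 0.2, 0.7), theta = 0.5)
  expect_identical(got$D, c("A", "C", "0"))
  expect_identical(got$VS, c(1L, 3L, 0L))
  expect_identical(got$TIS, c(0L, 2L, 0L))
  # threshold is strict: a score equal to theta is dropped
  eq <- extract_sequence(s3, c(0.5, 0.6, 0.5), theta = 0.5)
  expect_identical(eq$D, c("B", "0", "0"))
})

test_that("extraction preserves subsequence order on random inputs", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:12, 1L)
    s <- aligned_sequences(sample(LETTERS, n, TRUE), seq_len(n),
                           sample(0:20, n, TRUE))
    sc <- runif(n)
    out <- extract_sequence(s, sc, theta = 0.5)
    expect_length(out$D, n)
    kept <- out$D[out$D != "0"]
    expect_identical(kept, s$D[sc > 0.5][seq_along(kept)])
  }
})

test_that("mixing weights are estimated as corpus conditional probabilities", {
  recs <- list(rec("a", "2020-01-01 N", "2020-02-01 T"),   # noise + trigger
               rec("b", "2020-01-01 N"),                   # noise only
               rec("c", "2020-01-01 T"),                   # trigger only
               rec("d", "2020-01-01 X"))                   # neither
  mw <- estimate_mix_weights(recs, noise_codes = "N", trigger = "T")
  expect_equal(mw$alpha, 0.5)   # P(trigger | noise history)
  expect_equal(mw$beta, 0.5)    # P(noise history | trigger)
  expect_equal(mw$p_noise, 0.5)
})

test_that("training requires labels, honours zero epochs, and descends", {
  set.seed(6)
  p <- 4L
  X_list <- lapply(1:30, function(i) matrix(rnorm(p * 8), p, 8L))
  labs <- lapply(1:30, function(i) sample(c(1, 0, NA), 8L, replace = TRUE))
  none <- lapply(1:30, function(i) rep(NA_real_, 8L))
  expect_error(train_denoiser(X_list, none, q = 4L, epochs = 1L),
               "labeled position")
  p0 <- denoiser_params(p, 4L, seed = 9L)
  out0 <- train_denoiser(X_list, labs, params = p0, epochs = 0L)
  expect_identical(out0$params, p0)
  out <- train_denoiser(X_list, labs, q = 4L, epochs = 6L, seed = 9L)
  expect_lte(tail(out$loss_trace, 1L), out$loss_trace[1L])
  # determinism
  out2 <- train_denoiser(X_list, labs, q = 4L, epochs = 6L, seed = 9L)
  expect_identical(out$params, out2$params)
})

test_that("separable embeddings are separated by the trained scores", {
  # noise codes occupy one half-space of the embedding, chronic the other
  set.seed(10)
  p <- 6L
  emb_noise <- function() rnorm(p, mean = c(2, rep(0, p - 1)), sd = 0.3)
  emb_keep <- function() rnorm(p, mean = c(-2, rep(0, p - 1)), sd = 0.3)
  mk <- function() {
    n <- sample(6:12, 1L)
    noise <- runif(n) < 0.3
    X <- vapply(noise, function(z) if (z) emb_noise() else emb_keep(),
                numeric(p))
    list(X = X, lab = as.numeric(noise))
  }
  data <- lapply(1:60, function(i) mk())
  fit <- train_denoiser(lapply(data, `[[`, "X"), lapply(data, `[[`, "lab"),
                        q = 6L, epochs = 12L, seed = 2L)
  sc <- unlist(lapply(data, function(d)
    denoiser_scores(fit$params, d$X, 1, 0.2107)))
  fl <- unlist(lapply(data, `[[`, "lab")) == 1
  expect_lt(mean(sc[fl]), mean(sc[!fl]))
})

test_that("denoiser checkpoints round-trip through JSON", {
  params <- denoiser_params(3L, 4L, seed = 11L)
  path <- withr::local_tempfile(fileext = ".json")
  write_denoiser(params, path)
  back <- read_denoiser(path)
  for (k in dxbert:::.denoiser_keys) expect_equal(back[[k]], params[[k]])
})
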