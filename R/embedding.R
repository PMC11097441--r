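# Seed hygiene: run code under a fixed seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Embed diseases via random walks and skip-gram
#'
#' Runs weighted random walks over the comorbidity graph (transition
#' probability proportional to \code{1/(1+weight)}: the rank-difference weight
#' is a distance, so closely ranked comorbid pairs are walked more often) and
#' fits skip-gram vectors with negative sampling on the walk corpus.
#' Vocabulary codes absent from the graph receive seeded random rows, so the
#' embedding covers the full code vocabulary deterministically.
#'
#' @param g a [comorbidity_graph()].
#' @param d_emb embedding dimension (default 64).
#' @param vocab optional character vector of codes the embedding must cover;
#'   defaults to the graph's vertex set.
#' @param n_walks walks started per vertex (default 10).
#' @param walk_len walk length (default 20).
#' @param window skip-gram context window (default 5).
#' @param epochs,lr,n_neg skip-gram training epochs, learning rate, and
#'   negative samples per pair.
#' @param seed integer seed; the result is bitwise reproducible for a fixed
#'   seed.
#' @return object of class \code{disease_embedding}: \code{vocab} (ordered
#'   codes) and \code{vectors} (one row per code, \code{d_emb} columns).
#' @export
embed_graph <- function(g, d_emb = 64L, vocab = NULL, n_walks = 10L,
                        walk_len = 20L, window = 5L, epochs = 5L,
                        lr = 0.025, n_neg = 5L, seed = 1L) {
  stopifnot(inherits(g, "comorbidity_graph"), length(g$vertices) >= 1L)
  verts <- g$vertices
  if (is.null(vocab)) vocab <- verts
  vocab <- unique(c(vocab, verts))

  with_seed_(seed, {
    nv <- length(verts)
    vidx <- stats::setNames(seq_len(nv), verts)
    # adjacency with affinity = 1/(1+distance)
    adj <- vector("list", nv)
    if (nrow(g$edges) > 0L) {
      for (i in seq_len(nrow(g$edges))) {
        u <- vidx[[g$edges$u[i]]]; v <- vidx[[g$edges$v[i]]]
        aff <- 1 / (1 + g$edges$weight[i])
        adj[[u]] <- rbind(adj[[u]], c(v, aff))
        adj[[v]] <- rbind(adj[[v]], c(u, aff))
      }
    }
    walks <- list()
    for (s in seq_len(nv)) {
      for (w in seq_len(n_walks)) {
        cur <- s; path <- integer(walk_len); path[1L] <- cur
        len <- 1L
        while (len < walk_len) {
          nb <- adj[[cur]]
          if (is.null(nb)) break
          cur <- nb[sample.int(nrow(nb), 1L, prob = nb[, 2L]), 1L]
          len <- len + 1L; path[len] <- cur
        }
        walks[[length(walks) + 1L]] <- path[seq_len(len)]
      }
    }
    # skip-gram pairs
    centers <- integer(0); contexts <- integer(0)
    for (p in walks) {
      n <- length(p)
      if (n < 2L) next
      for (i in seq_len(n)) {
        lo <- max(1L, i - window); hi <- min(n, i + window)
        ctx <- p[setdiff(lo:hi, i)]
        centers <- c(centers, rep.int(p[i], length(ctx)))
        contexts <- c(contexts, ctx)
      }
    }
    W <- matrix(stats::rnorm(nv * d_emb, sd = 0.5 / sqrt(d_emb)), nrow = nv)
    C <- matrix(0, nrow = nv, ncol = d_emb)
    np <- length(centers)
    if (np > 0L) {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(np)
        for (j in ord) {
          ci <- centers[j]; oi <- contexts[j]
          negs <- sample.int(nv, n_neg, replace = TRUE)
          targets <- c(oi, negs); labels <- c(1, rep(0, n_neg))
          h <- W[ci, ]
          scores <- .sigmoid(C[targets, , drop = FALSE] %*% h)
          err <- as.numeric(scores) - labels            # d/dscore of logistic loss
          gh <- crossprod(C[targets, , drop = FALSE], err)
          C[targets, ] <- C[targets, ] - lr * tcrossprod(err, h)
          W[ci, ] <- h - lr * as.numeric(gh)
        }
      }
    }
    extra <- setdiff(vocab, verts)
    vecs <- matrix(0, nrow = length(vocab), ncol = d_emb,
                   dimnames = list(vocab, NULL))
    vecs[verts, ] <- W
    if (length(extra) > 0L) {
      vecs[extra, ] <- matrix(stats::rnorm(length(extra) * d_emb,
                                           sd = 0.5 / sqrt(d_emb)),
                              nrow = length(extra))
    }
    structure(list(vocab = vocab, vectors = vecs, d_emb = d_emb, seed = seed),
              class = "disease_embedding")
  })
}

#' @export
print.disease_embedding <- function(x, ...) {
  cat(sprintf("disease_embedding: %d codes x %d dims (seed %d)\n",
              length(x$vocab), x$d_emb, x$seed))
  invisible(x)
}

#' Export an embedding in word2vec text format
#'
#' Writes a headerless numeric matrix plus a sidecar vocabulary file
#' (one code per line, same row order).
#'
#' @param emb a \code{disease_embedding}.
#' @param stem output path stem; writes \code{<stem>_vectors.txt} and
#'   \code{<stem>_vocab.txt}.
#' @return the two paths, invisibly.
#' @export
write_embedding <- function(emb, stem) {
  vp <- paste0(stem, "_vectors.txt"); cp <- paste0(stem, "_vocab.txt")
  utils::write.table(emb$vectors, vp, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  writeLines(emb$vocab, cp)
  invisible(c(vp, cp))
}
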