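# Internal differentiable layers for the fusion network. Each *_fwd returns
# the output plus the cache its *_bwd needs; backward functions return the
# input gradient and parameter gradients. Node batches stack S samples of an
# n-node graph as N = S * n rows (node-major within sample), which makes the
# per-sample attention a block-diagonal masked softmax over one shared edge
# structure.

# ---- multi-head GAT layer ------------------------------------------------

# H: N x d_in node features; heads: list of list(W, a_src, a_dst);
# recv/send: 1-based directed edge endpoints (self-loops included).
gat_layer_fwd <- function(H, heads, recv, send, slope) {
  K <- length(heads)
  out <- NULL
  caches <- vector("list", K)
  for (k in seq_len(K)) {
    p <- heads[[k]]
    Z <- H %*% p$W
    s <- drop(Z %*% p$a_src)
    t <- drop(Z %*% p$a_dst)
    f <- gat_edge_forward(Z, s, t, recv, send, slope)
    out <- if (is.null(out)) f$out else out + f$out
    caches[[k]] <- list(Z = Z, alpha = f$alpha, pre = f$pre)
  }
  list(out = out / K, cache = list(H = H, caches = caches))
}

gat_layer_bwd <- function(dout, heads, cache, recv, send, slope) {
  K <- length(heads)
  dH <- NULL
  dheads <- vector("list", K)
  dk <- dout / K
  for (k in seq_len(K)) {
    p <- heads[[k]]
    ck <- cache$caches[[k]]
    b <- gat_edge_backward(ck$Z, ck$alpha, ck$pre, recv, send, slope, dk)
    dZ <- b$dZ + outer(b$ds, drop(p$a_src)) + outer(b$dt, drop(p$a_dst))
    dheads[[k]] <- list(W = crossprod(cache$H, dZ),
                        a_src = drop(crossprod(ck$Z, b$ds)),
                        a_dst = drop(crossprod(ck$Z, b$dt)))
    g <- dZ %*% t(p$W)
    dH <- if (is.null(dH)) g else dH + g
  }
  list(dH = dH, dheads = dheads)
}

# ---- batch normalization (over rows, per feature column) -----------------

bn_fwd <- function(X, gamma, beta, running, training, momentum = 0.1,
                   eps = 1e-5) {
  N <- nrow(X)
  if (training && N > 1) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    v <- pmax(v, 0)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
    const_stats <- FALSE
  } else {
    # eval mode, or a 1-row training batch where batch statistics degenerate
    mu <- running$mean
    v <- running$var
    const_stats <- TRUE
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (X - matrix(mu, N, length(mu), byrow = TRUE)) *
    matrix(invstd, N, length(mu), byrow = TRUE)
  out <- xhat * matrix(gamma, N, length(gamma), byrow = TRUE) +
    matrix(beta, N, length(beta), byrow = TRUE)
  list(out = out, running = running,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    const_stats = const_stats))
}

bn_bwd <- function(dout, cache) {
  N <- nrow(dout); d <- ncol(dout)
  g <- matrix(cache$gamma, N, d, byrow = TRUE)
  is_ <- matrix(cache$invstd, N, d, byrow = TRUE)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  if (cache$const_stats) {
    dX <- dout * g * is_
  } else {
    dX <- (g * is_ / N) *
      (N * dout -
         matrix(dbeta, N, d, byrow = TRUE) -
         cache$xhat * matrix(dgamma, N, d, byrow = TRUE))
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- dropout -------------------------------------------------------------

dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, mask = NULL))
  mask <- matrix((runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(out = X * mask, mask = mask)
}

dropout_bwd <- function(dout, mask) if (is.null(mask)) dout else dout * mask

# ---- max-pool graph readout ----------------------------------------------

# H: (S*n) x d node embeddings, node-major within sample; returns S x d
# pooled embeddings plus the argmax row indices for backprop.
maxpool_fwd <- function(H, n, S) {
  d <- ncol(H)
  P <- matrix(0, S, d)
  idx <- matrix(0L, S, d)
  for (c in seq_len(d)) {
    M <- matrix(H[, c], nrow = n)
    am <- max.col(t(M), ties.method = "first")
    P[, c] <- M[cbind(am, seq_len(S))]
    idx[, c] <- (seq_len(S) - 1L) * n + am
  }
  list(out = P, idx = idx)
}

maxpool_bwd <- function(dP, idx, N) {
  d <- ncol(dP)
  dH <- matrix(0, N, d)
  for (c in seq_len(d)) dH[idx[, c], c] <- dP[, c]
  dH
}

# ---- dense / softmax -----------------------------------------------------

dense_fwd <- function(X, W, b) {
  X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE)
}

softmax_rows <- function(L) {
  e <- exp(L - apply(L, 1L, max))
  e / rowSums(e)
}
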