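#' Configuration of the graph-attention fusion classifier
#'
#' The architecture: for every PPI graph, `n_blocks` GNN blocks (a
#' multi-head graph-attention layer whose heads are combined by averaging,
#' ReLU, batch normalization over the node batch, dropout), then a max-pool
#' readout to one graph-wise embedding per sample; image features pass
#' through a fully connected layer, ReLU and batch normalization; the
#' concatenated graph embeddings and transformed image features feed a
#' two-layer fully connected classifier with a softmax over the two
#' classes. Either branch may be absent (genes-only or images-only models).
#'
#' @param n_blocks GNN blocks per graph (default 3).
#' @param gat_hidden embedding dimension per attention head (default 8).
#' @param heads attention heads per GAT layer (default 3).
#' @param leaky_slope negative slope of the LeakyReLU in the attention
#'   logits (default 0.2).
#' @param dropout dropout rate inside GNN blocks, training only
#'   (default 0.3).
#' @param image_fc_dim output dimension of the image branch (default 32).
#' @param classifier_hidden hidden width of the classifier (default 64).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(n_blocks = 3, gat_hidden = 8, heads = 3,
                          leaky_slope = 0.2, dropout = 0.3,
                          image_fc_dim = 32, classifier_hidden = 64) {
  stopifnot(n_blocks >= 1, gat_hidden >= 1, heads >= 1,
            dropout >= 0, dropout < 1, image_fc_dim >= 1,
            classifier_hidden >= 1)
  structure(list(n_blocks = n_blocks, gat_hidden = gat_hidden,
                 heads = heads, leaky_slope = leaky_slope,
                 dropout = dropout, image_fc_dim = image_fc_dim,
                 classifier_hidden = classifier_hidden, n_classes = 2L),
            class = "fusion_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

# Directed edge lists (receiver, sender) of one graph, self-loops included.
graph_edge_index <- function(adj) {
  diag(adj) <- 1
  idx <- which(adj > 0, arr.ind = TRUE)
  list(recv = as.integer(idx[, 1]), send = as.integer(idx[, 2]))
}

#' Build an untrained fusion model over a fixed set of PPI graphs
#'
#' Graphs are ordered by sorted name at build time so the concatenation
#' order of graph embeddings is reproducible. Weights use Glorot-uniform
#' initialization.
#'
#' @param graphs named list of [induce_subgraph()] objects (features not
#'   required at build time). May be empty for an images-only model.
#' @param n_image_features number of image features, or 0 for a genes-only
#'   model.
#' @param config a [fusion_config()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `fusion_model`.
#' @export
build_fusion_model <- function(graphs, n_image_features = 0,
                               config = fusion_config(), seed = 1L) {
  if (!length(graphs) && n_image_features == 0)
    stopf("model needs at least one PPI graph or image features")
  if (length(graphs)) {
    nm <- names(graphs)
    if (is.null(nm) || any(!nzchar(nm)))
      nm <- vapply(seq_along(graphs), function(i)
        if (!is.null(graphs[[i]]$name)) graphs[[i]]$name
        else sprintf("graph%02d", i), "")
    names(graphs) <- nm
    graphs <- graphs[order(nm)]
  }
  with_seed(seed, {
    d <- config$gat_hidden
    gat <- lapply(graphs, function(g) {
      lapply(seq_len(config$n_blocks), function(b) {
        d_in <- if (b == 1) 1L else d
        list(heads = lapply(seq_len(config$heads), function(h)
               list(W = glorot(d_in, d),
                    a_src = runif(d, -sqrt(3 / d), sqrt(3 / d)),
                    a_dst = runif(d, -sqrt(3 / d), sqrt(3 / d)))),
             bn = list(gamma = rep(1, d), beta = rep(0, d)))
      })
    })
    image <- NULL
    if (n_image_features > 0)
      image <- list(W = glorot(n_image_features, config$image_fc_dim),
                    b = rep(0, config$image_fc_dim),
                    bn = list(gamma = rep(1, config$image_fc_dim),
                              beta = rep(0, config$image_fc_dim)))
    concat_dim <- length(graphs) * d +
      if (n_image_features > 0) config$image_fc_dim else 0L
    clf <- list(W1 = glorot(concat_dim, config$classifier_hidden),
                b1 = rep(0, config$classifier_hidden),
                W2 = glorot(config$classifier_hidden, config$n_classes),
                b2 = rep(0, config$n_classes))
    structure(list(
      config = config,
      graph_order = names(graphs),
      graph_struct = lapply(graphs, function(g)
        c(graph_edge_index(g$adjacency), list(n = length(g$nodes),
                                              nodes = g$nodes))),
      params = list(gat = gat, image = image, clf = clf),
      bn_state = list(
        gat = lapply(graphs, function(g)
          lapply(seq_len(config$n_blocks), function(b)
            list(mean = rep(0, d), var = rep(1, d)))),
        image = if (n_image_features > 0)
          list(mean = rep(0, config$image_fc_dim),
               var = rep(1, config$image_fc_dim))),
      n_image_features = n_image_features),
      class = "fusion_model")
  })
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf(paste0("Fusion model: %d PPI graph(s) [%s], %d image",
                     " feature(s), %d blocks x %d heads, hidden %d\n"),
              length(x$graph_order),
              paste(x$graph_order, collapse = ", "),
              x$n_image_features, x$config$n_blocks, x$config$heads,
              x$config$gat_hidden))
  invisible(x)
}

# Expand a graph's edge lists to a batch of S stacked copies.
batch_edges <- function(struct, S) {
  off <- rep((seq_len(S) - 1L) * struct$n, each = length(struct$recv))
  list(recv = rep(struct$recv, S) + off,
       send = rep(struct$send, S) + off)
}

# Validate and order per-graph feature matrices (S x n each).
check_inputs <- function(model, graph_features, image) {
  if (length(model$graph_order)) {
    if (is.null(graph_features) ||
        !all(model$graph_order %in% names(graph_features)))
      stopf("graph_features must contain a matrix for every model graph: %s",
            paste(model$graph_order, collapse = ", "))
    graph_features <- graph_features[model$graph_order]
    S <- nrow(graph_features[[1]])
    for (g in model$graph_order)
      if (ncol(graph_features[[g]]) != model$graph_struct[[g]]$n ||
          nrow(graph_features[[g]]) != S)
        stopf("feature matrix for graph '%s' has wrong shape", g)
  } else S <- nrow(image)
  if (model$n_image_features > 0) {
    if (is.null(image) || ncol(image) != model$n_image_features ||
        nrow(image) != S)
      stopf("image feature matrix must be %d x %d", S,
            model$n_image_features)
  } else image <- NULL
  list(graph_features = graph_features, image = image, S = S)
}

# Full forward pass. Returns class probabilities, the cache needed by the
# backward pass (training only) and updated batch-norm running statistics.
fusion_forward_full <- function(model, graph_features, image,
                                training = FALSE) {
  cfg <- model$config
  inp <- check_inputs(model, graph_features, image)
  S <- inp$S
  embeds <- list()
  gcaches <- list()
  bn_state <- model$bn_state
  for (g in model$graph_order) {
    st <- model$graph_struct[[g]]
    eb <- batch_edges(st, S)
    H <- matrix(as.vector(t(inp$graph_features[[g]])), ncol = 1)
    bcaches <- vector("list", cfg$n_blocks)
    for (b in seq_len(cfg$n_blocks)) {
      blk <- model$params$gat[[g]][[b]]
      gat <- gat_layer_fwd(H, blk$heads, eb$recv, eb$send, cfg$leaky_slope)
      A <- pmax(gat$out, 0)
      bn <- bn_fwd(A, blk$bn$gamma, blk$bn$beta, bn_state$gat[[g]][[b]],
                   training)
      bn_state$gat[[g]][[b]] <- bn$running
      dp <- dropout_fwd(bn$out, cfg$dropout, training)
      bcaches[[b]] <- list(gat = gat$cache, relu_in = gat$out,
                           bn = bn$cache, mask = dp$mask)
      H <- dp$out
    }
    pool <- maxpool_fwd(H, st$n, S)
    embeds[[g]] <- pool$out
    gcaches[[g]] <- list(blocks = bcaches, pool_idx = pool$idx,
                         edges = eb, N = st$n * S)
  }
  icache <- NULL
  if (!is.null(inp$image)) {
    ip <- model$params$image
    Z <- dense_fwd(inp$image, ip$W, ip$b)
    A <- pmax(Z, 0)
    bn <- bn_fwd(A, ip$bn$gamma, ip$bn$beta, bn_state$image, training)
    bn_state$image <- bn$running
    embeds[["..image"]] <- bn$out
    icache <- list(X = inp$image, relu_in = Z, bn = bn$cache)
  }
  C <- do.call(cbind, unname(embeds))
  cp <- model$params$clf
  Z1 <- dense_fwd(C, cp$W1, cp$b1)
  A1 <- pmax(Z1, 0)
  logits <- dense_fwd(A1, cp$W2, cp$b2)
  probs <- softmax_rows(logits)
  list(probs = probs,
       cache = list(C = C, Z1 = Z1, A1 = A1, gcaches = gcaches,
                    icache = icache, S = S),
       bn_state = bn_state)
}

# Backward pass from softmax cross-entropy; returns gradients shaped like
# model$params. `labels` are 0/1.
fusion_backward <- function(model, fwd, labels) {
  cfg <- model$config
  cp <- model$params$clf
  S <- fwd$cache$S
  Y <- matrix(0, S, 2)
  Y[cbind(seq_len(S), as.integer(labels) + 1L)] <- 1
  dlogits <- (fwd$probs - Y) / S
  dW2 <- crossprod(fwd$cache$A1, dlogits)
  db2 <- colSums(dlogits)
  dA1 <- dlogits %*% t(cp$W2)
  dZ1 <- dA1 * (fwd$cache$Z1 > 0)
  dW1 <- crossprod(fwd$cache$C, dZ1)
  db1 <- colSums(dZ1)
  dC <- dZ1 %*% t(cp$W1)

  d <- cfg$gat_hidden
  col0 <- 0L
  dgat <- list()
  for (g in model$graph_order) {
    gc <- fwd$cache$gcaches[[g]]
    dP <- dC[, (col0 + 1):(col0 + d), drop = FALSE]
    col0 <- col0 + d
    dH <- maxpool_bwd(dP, gc$pool_idx, gc$N)
    dblocks <- vector("list", cfg$n_blocks)
    for (b in rev(seq_len(cfg$n_blocks))) {
      bc <- gc$blocks[[b]]
      dH <- dropout_bwd(dH, bc$mask)
      bn <- bn_bwd(dH, bc$bn)
      dA <- bn$dX * (bc$relu_in > 0)
      gl <- gat_layer_bwd(dA, model$params$gat[[g]][[b]]$heads, bc$gat,
                          gc$edges$recv, gc$edges$send, cfg$leaky_slope)
      dblocks[[b]] <- list(heads = gl$dheads,
                           bn = list(gamma = bn$dgamma, beta = bn$dbeta))
      dH <- gl$dH
    }
    dgat[[g]] <- dblocks
  }
  dimage <- NULL
  if (!is.null(fwd$cache$icache)) {
    ic <- fwd$cache$icache
    m <- model$config$image_fc_dim
    dI <- dC[, (col0 + 1):(col0 + m), drop = FALSE]
    bn <- bn_bwd(dI, ic$bn)
    dZ <- bn$dX * (ic$relu_in > 0)
    dimage <- list(W = crossprod(ic$X, dZ), b = colSums(dZ),
                   bn = list(gamma = bn$dgamma, beta = bn$dbeta))
  }
  list(gat = dgat, image = dimage,
       clf = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Forward pass of the fusion model
#'
#' Computes per-sample class probabilities. In evaluation mode (the
#' default) batch normalization uses running statistics and dropout is
#' disabled, so the output is deterministic for fixed parameters.
#'
#' @param model a [build_fusion_model()] (usually after [train_model()]).
#' @param graph_features named list of samples x nodes matrices, one per
#'   model graph (e.g. the `features` slot of [attach_features()]).
#' @param image samples x features image matrix, or NULL for a genes-only
#'   model.
#' @param training use batch statistics and dropout (internal; default
#'   FALSE).
#' @return samples x 2 matrix of class probabilities (columns: class 0,
#'   class 1); rows sum to 1.
#' @export
fusion_forward <- function(model, graph_features = NULL, image = NULL,
                           training = FALSE) {
  fusion_forward_full(model, graph_features, image, training)$probs
}

#' Predicted class-1 probability
#'
#' @inheritParams fusion_forward
#' @return Numeric vector of metastasis (class 1) probabilities.
#' @export
predict_fusion <- function(model, graph_features = NULL, image = NULL) {
  fusion_forward(model, graph_features, image)[, 2]
}
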