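gat_fwd <- radiogat:::gat_layer_fwd

test_that("GAT layer equals the dense masked-softmax oracle", {
  set.seed(51)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    d_in <- sample(1:3, 1); d_out <- sample(2:5, 1)
    adj <- random_adj(n)
    ei <- radiogat:::graph_edge_index(adj)
    H <- matrix(rnorm(n * d_in), n, d_in)
    heads <- lapply(1:3, function(h)
      list(W = matrix(rnorm(d_in * d_out), d_in, d_out),
           a_src = rnorm(d_out), a_dst = rnorm(d_out)))
    got <- gat_fwd(H, heads, ei$recv, ei$send, 0.2)$out
    want <- Reduce(`+`, lapply(heads, function(p)
      dense_gat_oracle(H, p$W, p$a_src, p$a_dst, adj, 0.2))) / 3
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("attention weights are a proper softmax over neighborhoods", {
  set.seed(52)
  adj <- random_adj(6)
  ei <- radiogat:::graph_edge_index(adj)
  H <- matrix(rnorm(12), 6, 2)
  p <- list(W = matrix(rnorm(8), 2, 4), a_src = rnorm(4), a_dst = rnorm(4))
  f <- radiogat:::gat_edge_forward(H %*% p$W,
                                   drop(H %*% p$W %*% p$a_src),
                                   drop(H %*% p$W %*% p$a_dst),
                                   ei$recv, ei$send, 0.2)
  sums <- tapply(f$alpha, ei$recv, sum)
  expect_equal(as.numeric(sums), rep(1, 6), tolerance = 1e-12)
  # a single node with only a self-loop averages W h over heads
  H1 <- matrix(c(1.5, -2), 1, 2)
  heads <- lapply(1:2, function(h)
    list(W = matrix(rnorm(6), 2, 3), a_src = rnorm(3), a_dst = rnorm(3)))
  out1 <- gat_fwd(H1, heads, 1L, 1L, 0.2)$out
  expect_equal(out1, (H1 %*% heads[[1]]$W + H1 %*% heads[[2]]$W) / 2,
               tolerance = 1e-12)
})

test_that("GAT gradients match numerical differentiation", {
  set.seed(53)
  n <- 5; d_in <- 2; d_out <- 3
  adj <- random_adj(n)
  ei <- radiogat:::graph_edge_index(adj)
  H <- matrix(rnorm(n * d_in), n, d_in)
  heads <- list(list(W = matrix(rnorm(d_in * d_out), d_in, d_out),
                     a_src = rnorm(d_out), a_dst = rnorm(d_out)))
  loss <- function(heads, H) sum(sin(gat_fwd(H, heads, ei$recv, ei$send,
                                             0.2)$out))
  f <- gat_fwd(H, heads, ei$recv, ei$send, 0.2)
  bwd <- radiogat:::gat_layer_bwd(cos(f$out), heads, f$cache,
                                  ei$recv, ei$send, 0.2)
  eps <- 1e-6
  # weight matrix gradient
  for (idx in seq_len(d_in * d_out)) {
    hp <- heads; hp[[1]]$W[idx] <- hp[[1]]$W[idx] + eps
    hm <- heads; hm[[1]]$W[idx] <- hm[[1]]$W[idx] - eps
    expect_equal(bwd$dheads[[1]]$W[idx],
                 (loss(hp, H) - loss(hm, H)) / (2 * eps), tolerance = 1e-4)
  }
  # attention vector and input gradients (spot checks)
  hp <- heads; hp[[1]]$a_src[2] <- hp[[1]]$a_src[2] + eps
  hm <- heads; hm[[1]]$a_src[2] <- hm[[1]]$a_src[2] - eps
  expect_equal(bwd$dheads[[1]]$a_src[2],
               (loss(hp, H) - loss(hm, H)) / (2 * eps), tolerance = 1e-4)
  Hp <- H; Hp[3, 1] <- Hp[3, 1] + eps
  Hm <- H; Hm[3, 1] <- Hm[3, 1] - eps
  expect_equal(bwd$dH[3, 1], (loss(heads, Hp) - loss(heads, Hm)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("max-pool readout is exact and node-permutation invariant", {
  H <- rbind(c(1, 5, -1), c(2, 4, 0), c(0, 6, -3))
  p <- radiogat:::maxpool_fwd(H, n = 3, S = 1)
  expect_equal(drop(p$out), c(2, 6, 0))
  set.seed(54)
  H2 <- matrix(rnorm(8 * 4), 8, 4)
  perm <- sample(8)
  expect_equal(radiogat:::maxpool_fwd(H2, 8, 1)$out,
               radiogat:::maxpool_fwd(H2[perm, ], 8, 1)$out)
  # single node: identity
  expect_equal(drop(radiogat:::maxpool_fwd(H[1, , drop = FALSE], 1, 1)$out),
               H[1, ])
})

test_that("image branch computes FC + ReLU + batch-norm as written", {
  m <- build_fusion_model(list(), n_image_features = 3,
                          config = fusion_config(image_fc_dim = 2,
                                                 classifier_hidden = 4),
                          seed = 55)
  W <- matrix(c(1, 0, -1, 2, 1, 0), 3, 2); b <- c(0.5, -0.5)
  m$params$image$W <- W; m$params$image$b <- b
  X <- matrix(c(1, 2, 0, 1, 3, -1), 2, 3, byrow = TRUE)
  # eval mode uses running stats (mean 0, var 1)
  hand <- pmax(X %*% W + matrix(b, 2, 2, byrow = TRUE), 0) / sqrt(1 + 1e-5)
  hand_logits <- pmax(hand %*% m$params$clf$W1 +
                        matrix(m$params$clf$b1, 2, 4, byrow = TRUE), 0) %*%
    m$params$clf$W2 + matrix(m$params$clf$b2, 2, 2, byrow = TRUE)
  hand_probs <- exp(hand_logits) / rowSums(exp(hand_logits))
  got <- fusion_forward(m, image = X)
  expect_equal(got, hand_probs, tolerance = 1e-10)
  # zero weights collapse the image embedding to zero
  m$params$image$W[] <- 0; m$params$image$b[] <- 0
  m$params$clf$W1[] <- 0; m$params$clf$b1[] <- 0
  m$params$clf$W2[] <- 0; m$params$clf$b2 <- c(0.3, -0.3)
  p0 <- fusion_forward(m, image = X)
  expect_equal(p0[1, ], exp(c(0.3, -0.3)) / sum(exp(c(0.3, -0.3))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fusion forward yields proper probabilities deterministically", {
  co <- tiny_cohort()
  graphs <- truth_graphs(co)
  img <- co$radiomic_pet
  m <- build_fusion_model(graphs, ncol(img), fusion_config(), seed = 56)
  gf <- lapply(graphs, `[[`, "features")
  p1 <- fusion_forward(m, gf, img)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_equal(unname(rowSums(p1)), rep(1, nrow(img)), tolerance = 1e-12)
  expect_identical(p1, fusion_forward(m, gf, img))  # eval determinism
  # genes-only and images-only modes run with matching dimensions
  mg <- build_fusion_model(graphs, 0, fusion_config(), seed = 56)
  expect_equal(dim(fusion_forward(mg, gf)), c(nrow(img), 2))
  expect_equal(nrow(mg$params$clf$W1), 2 * 8)
  mi <- build_fusion_model(list(), ncol(img), fusion_config(), seed = 56)
  expect_equal(nrow(mi$params$clf$W1), 32)
  expect_error(build_fusion_model(list(), 0), "at least one")
})

test_that("permuting graph order with permuted classifier weights is a
           no-op", {
  co <- tiny_cohort()
  graphs <- truth_graphs(co)
  gf <- lapply(graphs, `[[`, "features")
  m <- build_fusion_model(graphs, 0, fusion_config(), seed = 57)
  d <- m$config$gat_hidden
  p_ref <- fusion_forward(m, gf)
  # swap the two graphs everywhere, including the W1 row blocks they feed
  m2 <- m
  ord <- c(2L, 1L)
  m2$graph_order <- m$graph_order[ord]
  m2$graph_struct <- m$graph_struct[ord]
  m2$params$gat <- m$params$gat[ord]
  m2$bn_state$gat <- m$bn_state$gat[ord]
  rows <- c((d + 1):(2 * d), 1:d)
  m2$params$clf$W1 <- m$params$clf$W1[rows, ]
  expect_equal(fusion_forward(m2, gf), p_ref, tolerance = 1e-12)
})

test_that("GNN blocks are reproducible in eval mode and noisy in training", {
  co <- tiny_cohort()
  graphs <- truth_graphs(co)
  gf <- lapply(graphs, `[[`, "features")
  m <- build_fusion_model(graphs, 0, fusion_config(dropout = 0.5), seed = 58)
  e1 <- fusion_forward(m, gf)
  e2 <- fusion_forward(m, gf)
  expect_identical(e1, e2)
  set.seed(1); t1 <- fusion_forward(m, gf, training = TRUE)
  set.seed(2); t2 <- fusion_forward(m, gf, training = TRUE)
  expect_false(identical(t1, t2))  # dropout active only in training
})
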