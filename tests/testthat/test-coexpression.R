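make_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", 1:n_genes),
                         sprintf("s%03d", 1:n_samples)))
}

test_that("MAD filter keeps the expected quantile and drops constants", {
  e <- make_expr(100, 20)
  expect_identical(filter_genes(e, coexpr_config()), e)  # quantile 0
  f <- filter_genes(e, coexpr_config(variance_filter_quantile = 0.25))
  expect_equal(nrow(f), 75)
  expect_identical(rownames(f), intersect(rownames(e), rownames(f)))
  e2 <- rbind(e, constant = rep(1, 20))
  f2 <- filter_genes(e2, coexpr_config(variance_filter_quantile = 0.1))
  expect_false("constant" %in% rownames(f2))
})

test_that("sample outlier removal flags only genuinely distant samples", {
  e <- make_expr(50, 20)
  cfg <- coexpr_config(sample_outlier_z = 3)
  # identical samples: zero spread, nothing removed
  same <- matrix(rep(rnorm(50), 10), 50, 10)
  expect_equal(ncol(remove_outlier_samples(same, cfg)), 10)
  # one sample shifted far away is removed
  e_out <- e
  e_out[, 7] <- e_out[, 7] + 50
  r <- remove_outlier_samples(e_out, cfg)
  expect_equal(ncol(r), 19)
  expect_false("s007" %in% colnames(r))
  # z = NULL is the identity
  expect_identical(remove_outlier_samples(e, coexpr_config()), e)
})

test_that("TOM dissimilarity matches direct formula evaluation", {
  # independent oracle: evaluate adjacency/TOM with explicit loops
  tom_oracle <- function(expr, beta) {
    a <- abs(cor(t(expr)))^beta
    diag(a) <- 0
    n <- nrow(a)
    d <- matrix(0, n, n)
    k <- rowSums(a)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
      d[i, j] <- 1 - (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    d
  }
  e <- make_expr(8, 30, seed = 2)
  d <- adjacency_tom(e, coexpr_config(soft_power = 5))
  expect_equal(unname(d), tom_oracle(e, 5), tolerance = 1e-12)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1 + 1e-12))

  # two genes with |cor| = 0.5 at beta = 1: k = a = 0.5, so
  # TOM = (0 + 0.5) / (0.5 + 1 - 0.5) = 0.5 and dissimilarity 0.5
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 8)
  e2 <- rbind(g1 = x, g2 = y)
  r <- abs(cor(x, y))  # whatever it is, dissimilarity must be 1 - |cor|^beta
  d2 <- adjacency_tom(e2, coexpr_config(soft_power = 1))
  expect_equal(d2[1, 2], 1 - r, tolerance = 1e-12)
})

test_that("extreme correlation structures give extreme dissimilarities", {
  base <- rnorm(40)
  perf <- rbind(a = base, b = 2 * base + 1, c = -base)
  d <- adjacency_tom(perf + 1e-9 * matrix(rnorm(120), 3), coexpr_config())
  expect_lt(max(d[upper.tri(d)]), 0.01)
  indep <- make_expr(10, 2000, seed = 3)
  d2 <- adjacency_tom(indep, coexpr_config())
  expect_gt(mean(d2[upper.tri(d2)]), 0.9)
  expect_error(adjacency_tom(rbind(a = rep(1, 10), b = rnorm(10))),
               "zero-variance")
})

test_that("module detection recovers planted blocks and is order-invariant", {
  cfg <- synthetic_config(n_major = 50, n_minor = 43, n_genes = 45,
                          module_sizes = c(15, 15, 15),
                          within_module_cor = 0.8, signal_genes = 0, seed = 21)
  e <- generate_expression(cfg)
  ccfg <- coexpr_config(min_module_size = 10)
  modules <- detect_modules(adjacency_tom(e$expression, ccfg), ccfg)
  ari <- mclust::adjustedRandIndex(modules, e$truth$modules)
  expect_gte(ari, 0.8)

  perm <- sample(nrow(e$expression))
  mod_p <- detect_modules(adjacency_tom(e$expression[perm, ], ccfg), ccfg)
  expect_equal(mclust::adjustedRandIndex(mod_p, modules[names(mod_p)]), 1)
})

test_that("degenerate cuts behave as documented", {
  e <- make_expr(40, 30, seed = 4)
  d <- adjacency_tom(e, coexpr_config())
  # cut height 1.0: everything in one module
  all_one <- detect_modules(d, coexpr_config(tree_cut_height = 1,
                                             min_module_size = 2))
  expect_equal(unique(unname(all_one)), 1L)
  # independent genes at the default cut: no cluster reaches min size
  indep <- make_expr(60, 300, seed = 5)
  none <- detect_modules(adjacency_tom(indep, coexpr_config()),
                         coexpr_config())
  expect_true(all(none == 0L))
})

test_that("eigengene is the module's first PC, sign-oriented and unit norm", {
  cfg <- synthetic_config(n_major = 50, n_minor = 43, n_genes = 50,
                          module_sizes = c(50), within_module_cor = 0.8,
                          signal_genes = 0, seed = 22)
  ex <- generate_expression(cfg)
  me <- module_eigengene(ex$expression, ex$truth$modules)
  expect_equal(sqrt(sum(me[, 1]^2)), 1, tolerance = 1e-10)
  # tracks the planted latent factor closely
  expect_gte(abs(cor(me[, 1], ex$truth$factors[1, ])), 0.9)
  # positively oriented to mean module expression
  zc <- scale(t(ex$expression))
  expect_gt(cor(me[, 1], rowMeans(zc)), 0)
  # PCA optimality: eigengene explains at least as much module variance
  # as the best single standardized gene
  var_expl <- function(v) sum(cor(zc, v)^2)
  best_gene <- max(sapply(seq_len(ncol(zc)), function(j) var_expl(zc[, j])))
  expect_gte(var_expl(me[, 1]) + 1e-8, best_gene)
  # module of near-identical genes: eigengene is that profile
  g <- rnorm(30)
  same <- rbind(a = g, b = g + 1e-8 * rnorm(30))
  me2 <- module_eigengene(same, c(a = 1L, b = 1L))
  expect_gte(abs(cor(me2[, 1], g)), 0.999)
})

test_that("module-trait statistics are exact for perfect association and
           calibrated under the null", {
  y <- c(rep(0, 40), rep(1, 20))
  e_trait <- matrix(scale(y), ncol = 1,
                    dimnames = list(NULL, "ME1"))
  st <- module_trait_stats(e_trait, y)
  expect_equal(st$cor, 1, tolerance = 1e-12)
  expect_lt(st$p, 1e-30)
  expect_error(module_trait_stats(e_trait, rep(1, 60)), "constant")

  # null calibration: eigengene independent of trait
  set.seed(31)
  pvals <- replicate(400, {
    me <- matrix(rnorm(93), ncol = 1, dimnames = list(NULL, "ME1"))
    module_trait_stats(me, c(rep(0, 73), rep(1, 20)))$p
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.01); expect_lt(rate, 0.1)
})

test_that("gene significance ranks planted signal genes highly", {
  cfg <- synthetic_config(seed = 23)  # 4 signal genes, d = 1.5, 73/20
  ex <- generate_expression(cfg)
  gs <- gene_significance(ex$expression, ex$labels)
  expect_true(all(gs >= 0 & gs <= 1))
  top_decile <- names(sort(gs, decreasing = TRUE))[1:30]
  expect_true(all(ex$truth$signal_genes %in% top_decile))
})
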