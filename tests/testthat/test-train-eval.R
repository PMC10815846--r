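test_that("SMOTE balances 73/20 to 146 and interpolates between parents", {
  set.seed(61)
  x <- matrix(rnorm(93 * 6), 93, 6)
  y <- c(rep(0, 73), rep(1, 20))
  sm <- smote(x, y, seed = 62)
  expect_equal(nrow(sm$x), 146)
  expect_equal(sum(sm$labels == 1), sum(sm$labels == 0))
  expect_equal(sum(sm$synthetic), 53)
  # parents are minority samples and every synthetic point is collinear
  # with its two parents
  expect_true(all(sm$parents %in% which(y == 1)))
  for (i in seq_len(nrow(sm$parents))) {
    xs <- sm$x[93 + i, ]
    p1 <- x[sm$parents[i, 1], ]; p2 <- x[sm$parents[i, 2], ]
    seg <- xs - p1; dir <- p2 - p1
    lam <- sum(seg * dir) / sum(dir * dir)
    expect_lt(max(abs(seg - lam * dir)), 1e-10)
    expect_gte(lam, 0); expect_lte(lam, 1)
  }
  # balanced input is untouched
  xb <- x[1:40, ]; yb <- rep(0:1, each = 20)
  smb <- smote(xb, yb)
  expect_identical(smb$x, xb)
  # k larger than the minority triggers the reduction warning
  expect_warning(smote(x[1:76, ], c(rep(0, 73), rep(1, 3)), seed = 63),
                 "k_neighbors")
  expect_error(smote(x[1:74, ], c(rep(0, 73), 1)), "too small")
})

test_that("stratified k-fold partitions are balanced and deterministic", {
  y <- c(rep(0, 73), rep(1, 20))
  f <- kfold_split(y, 5, seed = 64)
  expect_setequal(unique(f), 1:5)
  expect_true(all(table(f[y == 1]) == 4))
  expect_true(all(abs(table(f[y == 0]) - 73 / 5) <= 1))
  expect_identical(f, kfold_split(y, 5, seed = 64))
  f10 <- kfold_split(rep(0:1, 5), 5, seed = 65)
  expect_true(all(table(f10) == 2))
  expect_error(kfold_split(c(rep(0, 10), 1, 1), 5), "smaller k")
})

test_that("evaluation metrics reproduce confusion-matrix arithmetic", {
  perfect <- evaluate_predictions(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  f1 = 1, auc = 1))
  # TP = 3, FP = 1, FN = 1, TN = 5
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  p <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.2, 0.3, 0.1, 0.2)
  m <- evaluate_predictions(p, y)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  # constant scores: AUC 0.5 by the tie rule
  expect_equal(evaluate_predictions(rep(0.4, 10), y)$auc, 0.5)
  # single-class fold: AUC reported missing
  expect_message(m1 <- evaluate_predictions(c(0.2, 0.8), c(0, 0)),
                 "single-class")
  expect_true(is.na(m1$auc))
})

test_that("confidence interval aggregation follows the normal formula", {
  same <- aggregate_ci(rep(0.7, 6))
  expect_equal(same$lower, same$upper)
  ci <- aggregate_ci(c(0.8, 0.9))
  expect_equal(ci$mean, 0.85)
  expect_equal(ci$upper - ci$mean, 1.96 * sd(c(0.8, 0.9)) / sqrt(2),
               tolerance = 1e-12)
  expect_true(ci$lower <= ci$mean && ci$mean <= ci$upper)
  expect_true(is.na(aggregate_ci(0.5)$lower))
  expect_equal(aggregate_ci(c(0.4, NA, 0.6))$n, 2)
})

fake_report <- function(acc, seed = 1) {
  structure(list(folds = data.frame(repeat_ = 1, fold = seq_along(acc),
                                    accuracy = acc),
                 seed = seed), class = "eval_report")
}

test_that("configuration comparison is exact, symmetric and calibrated", {
  a <- fake_report(rep(0.8, 10))
  expect_equal(compare_configs(a, a)$p, 1)
  set.seed(66)
  noise <- rnorm(10, sd = 1e-3)
  b <- fake_report(rep(0.8, 10) + 0.1 + noise)
  cmp <- compare_configs(b, a)
  expect_lt(cmp$p, 0.01)
  expect_equal(cmp$method, "exact sign-flip permutation")
  # symmetry
  expect_equal(compare_configs(a, b)$p, cmp$p)
  expect_equal(compare_configs(a, b)$mean_diff, -cmp$mean_diff)
  # mismatched folds refuse to compare
  c_bad <- fake_report(rep(0.8, 8))
  expect_error(compare_configs(a, c_bad), "mismatched")
  # >20 pairs falls back to the paired t-test
  big_a <- fake_report(rep(0.8, 25))
  big_b <- fake_report(rep(0.8, 25) + rnorm(25, 0.05, 0.01))
  expect_equal(compare_configs(big_a, big_b)$method, "paired t-test")
  expect_lt(compare_configs(big_a, big_b)$p, 0.001)
})

test_that("zero-epoch training returns the initial parameters", {
  co <- tiny_cohort()
  graphs <- truth_graphs(co)
  gf <- lapply(graphs, `[[`, "features")
  m <- build_fusion_model(graphs, 0, fusion_config(), seed = 67)
  m0 <- train_model(m, gf, NULL, co$labels,
                    train_config(epochs = 0), seed = 68)
  expect_identical(m0$params, m$params)
})

test_that("training fits a separable cohort and stays deterministic", {
  co <- tiny_cohort()
  graphs <- truth_graphs(co)
  gf <- lapply(graphs, `[[`, "features")
  img <- co$radiomic_pet
  m <- build_fusion_model(graphs, ncol(img), fusion_config(), seed = 69)
  hy <- train_config(lr = 5e-3, epochs = 40, val_frac = 0)
  fit1 <- train_model(m, gf, img, co$labels, hy, seed = 70)
  fit2 <- train_model(m, gf, img, co$labels, hy, seed = 70)
  expect_identical(fit1$params, fit2$params)
  acc <- mean((predict_fusion(fit1, gf, img) > 0.5) == (co$labels == 1))
  expect_gt(acc, 0.9)  # training-set fit on a strong-signal cohort
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
})

test_that("cross-validation wiring keeps folds honest", {
  co <- tiny_cohort()
  graphs <- truth_graphs(co)
  rep1 <- cross_validate(graphs, co$radiomic_pet, co$labels,
                         fusion_config(gat_hidden = 4, image_fc_dim = 8,
                                       classifier_hidden = 16),
                         k = 3, repeats = 1, seed = 71,
                         hyper = train_config(lr = 5e-3, epochs = 10),
                         label = "tiny")
  expect_s3_class(rep1, "eval_report")
  expect_equal(nrow(rep1$folds), 3)
  for (mm in c("accuracy", "precision", "recall", "f1", "auc")) {
    v <- rep1$folds[[mm]]
    expect_true(all(is.na(v) | (v >= 0 & v <= 1)))
  }
  # per-fold F1 consistency with precision/recall
  ok <- !is.na(rep1$folds$f1)
  expect_equal(rep1$folds$f1[ok],
               2 * rep1$folds$precision[ok] * rep1$folds$recall[ok] /
                 (rep1$folds$precision[ok] + rep1$folds$recall[ok]),
               tolerance = 1e-12)
})
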