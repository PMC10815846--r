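#' SMOTE configuration
#'
#' @param k_neighbors nearest minority neighbors considered per synthetic
#'   point (default 5).
#' @param leakage_mode `"fold_train_only"` (default) applies SMOTE inside
#'   each training fold only; `"pre_split"` balances the whole cohort before
#'   cross-validation splitting. The latter mirrors balancing an imbalanced
#'   cohort up-front (73/20 -> 146) but lets synthetic points share parents
#'   with test folds, so reports label it explicitly.
#' @return An object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5,
                         leakage_mode = c("fold_train_only", "pre_split")) {
  if (!is_count(k_neighbors) || k_neighbors < 1)
    stopf("`k_neighbors` must be >= 1")
  structure(list(k_neighbors = k_neighbors,
                 leakage_mode = match.arg(leakage_mode)),
            class = "smote_config")
}

#' Synthetic minority over-sampling (SMOTE)
#'
#' Equalizes the two classes by interpolating minority samples: each
#' synthetic point is `x_i + lambda * (x_nn - x_i)` for a random minority
#' sample `x_i`, one of its `k_neighbors` nearest minority neighbors
#' `x_nn` (Euclidean), and `lambda ~ U(0, 1)`. A 73/20 cohort becomes 146
#' samples. Already-balanced data are returned unchanged.
#'
#' @param x samples x features numeric matrix.
#' @param labels 0/1 vector aligned with rows.
#' @param cfg a [smote_config()].
#' @param seed RNG seed.
#' @return A list: `x` (augmented matrix), `labels`, `synthetic` (logical
#'   per row), `parents` (n_synthetic x 2 matrix of parent row indices in
#'   the input).
#' @export
smote <- function(x, labels, cfg = smote_config(), seed = NULL) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  tab <- table(factor(labels, levels = c(0, 1)))
  n_need <- abs(tab[["1"]] - tab[["0"]])
  if (n_need == 0)
    return(list(x = x, labels = labels,
                synthetic = rep(FALSE, nrow(x)),
                parents = matrix(integer(), 0, 2)))
  minority <- if (tab[["1"]] < tab[["0"]]) 1L else 0L
  min_idx <- which(labels == minority)
  n_min <- length(min_idx)
  if (n_min < 2) stopf("minority class too small for SMOTE (need >= 2)")
  k <- cfg$k_neighbors
  if (k > n_min - 1) {
    warnf("k_neighbors = %d exceeds minority size - 1; using k = %d",
          k, n_min - 1)
    k <- n_min - 1L
  }
  with_seed(seed, {
    d <- as.matrix(dist(x[min_idx, , drop = FALSE]))
    diag(d) <- Inf
    knn <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
    pick <- sample.int(n_min, n_need, replace = TRUE)
    nn <- knn[cbind(pick, sample.int(k, n_need, replace = TRUE))]
    lam <- runif(n_need)
    xi <- x[min_idx[pick], , drop = FALSE]
    xs <- xi + lam * (x[min_idx[nn], , drop = FALSE] - xi)
    rownames(xs) <- sprintf("synthetic%03d", seq_len(n_need))
    list(x = rbind(x, xs),
         labels = c(labels, rep(minority, n_need)),
         synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_need)),
         parents = cbind(min_idx[pick], min_idx[nn]))
  })
}

#' Stratified k-fold assignment
#'
#' @param labels 0/1 vector.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @param stratified keep class proportions within +/- 1 sample per fold
#'   (default TRUE).
#' @return Integer fold id (1..k) per sample; each sample tests exactly
#'   once.
#' @export
kfold_split <- function(labels, k = 5, seed = NULL, stratified = TRUE) {
  if (!is_count(k) || k < 2) stopf("`k` must be >= 2")
  labels <- as.integer(labels)
  n <- length(labels)
  with_seed(seed, {
    folds <- integer(n)
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < k)
          stopf("class %d has %d < k = %d members; use a smaller k",
                cl, length(idx), k)
        folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      if (n < k) stopf("fewer samples than folds")
      folds[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    folds
  })
}

#' Training hyperparameters
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs full-batch epochs (default 200); 0 returns the initial
#'   parameters untouched.
#' @param val_frac fraction of training samples held out (stratified) for
#'   best-validation-loss checkpointing; 0 disables checkpointing.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, epochs = 200, val_frac = 0.1,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(lr > 0, epochs >= 0, val_frac >= 0, val_frac < 0.5)
  structure(list(lr = lr, epochs = epochs, val_frac = val_frac,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
            class = "train_config")
}

# Recursive Adam update over the nested parameter list.
adam_step <- function(params, grads, state, hyper, t) {
  walk <- function(p, g, m, v) {
    if (is.null(p) || is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(p)) {
      if (is.null(m)) m <- vector("list", length(p))
      if (is.null(v)) v <- vector("list", length(p))
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        # single-bracket assignment keeps NULL leaves (absent branches)
        # from being deleted, which would shift later indices
        p[i] <- list(r$p); m[i] <- list(r$m); v[i] <- list(r$v)
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(m)) { m <- p * 0; v <- p * 0 }
    m <- hyper$beta1 * m + (1 - hyper$beta1) * g
    v <- hyper$beta2 * v + (1 - hyper$beta2) * g * g
    mh <- m / (1 - hyper$beta1^t)
    vh <- v / (1 - hyper$beta2^t)
    list(p = p - hyper$lr * mh / (sqrt(vh) + hyper$adam_eps), m = m, v = v)
  }
  # gradients index params by graph name/position in the same order
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v))
}

cross_entropy <- function(probs, labels) {
  -mean(log(pmax(probs[cbind(seq_along(labels), as.integer(labels) + 1L)],
                 1e-12)))
}

subset_inputs <- function(graph_features, image, idx) {
  list(graph_features = if (!is.null(graph_features))
         lapply(graph_features, function(m) m[idx, , drop = FALSE]),
       image = if (!is.null(image)) image[idx, , drop = FALSE])
}

#' Train the fusion model
#'
#' Full-batch training with Adam on the softmax cross-entropy. When
#' `val_frac > 0` a stratified validation split is held out and the
#' parameters with the best validation loss are returned; otherwise the
#' final-epoch parameters are returned. Deterministic for a fixed seed.
#'
#' @param model a [build_fusion_model()].
#' @param graph_features named list of samples x nodes feature matrices.
#' @param image samples x features matrix or NULL.
#' @param labels 0/1 vector.
#' @param hyper a [train_config()].
#' @param seed RNG seed (validation split, dropout).
#' @param val optional explicit validation set, a list with
#'   `graph_features`, `image`, `labels`; when given, `val_frac` is ignored
#'   and checkpointing uses this set. [cross_validate()] passes real
#'   (pre-SMOTE) samples here so validation loss is not flattered by
#'   synthetic points interpolated from the training minority.
#' @param verbose print the loss every 25 epochs.
#' @return The fitted model, with `history` (per-epoch train/validation
#'   loss) attached.
#' @export
train_model <- function(model, graph_features = NULL, image = NULL, labels,
                        hyper = train_config(), seed = 1L, val = NULL,
                        verbose = FALSE) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stopf("training data needs both classes")
  with_seed(seed, {
    n <- length(labels)
    if (!is.null(val)) {
      tr <- list(graph_features = graph_features, image = image)
      va <- list(graph_features = val$graph_features, image = val$image)
      y_tr <- labels; y_va <- as.integer(val$labels)
    } else {
      val_idx <- integer(0)
      if (hyper$val_frac > 0) {
        for (cl in unique(labels)) {
          idx <- which(labels == cl)
          n_val <- floor(hyper$val_frac * length(idx))
          if (n_val >= 1) val_idx <- c(val_idx, sample(idx, n_val))
        }
      }
      tr_idx <- setdiff(seq_len(n), val_idx)
      tr <- subset_inputs(graph_features, image, tr_idx)
      va <- subset_inputs(graph_features, image, val_idx)
      y_tr <- labels[tr_idx]; y_va <- labels[val_idx]
    }
    use_val <- length(y_va) >= 2 && length(unique(y_va)) == 2
    opt <- list(m = NULL, v = NULL)
    best <- list(loss = Inf, params = model$params,
                 bn_state = model$bn_state)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    if (hyper$epochs > 0) for (ep in seq_len(hyper$epochs)) {
      fwd <- fusion_forward_full(model, tr$graph_features, tr$image,
                                 training = TRUE)
      model$bn_state <- fwd$bn_state
      loss <- cross_entropy(fwd$probs, y_tr)
      if (!is.finite(loss))
        stopf("training diverged at epoch %d (loss = %g)", ep, loss)
      grads <- fusion_backward(model, fwd, y_tr)
      upd <- adam_step(model$params, grads, opt, hyper, ep)
      model$params <- upd$params
      opt <- upd$state
      vloss <- NA_real_
      if (use_val) {
        vp <- fusion_forward_full(model, va$graph_features, va$image,
                                  training = FALSE)$probs
        vloss <- cross_entropy(vp, y_va)
        if (vloss < best$loss)
          best <- list(loss = vloss, params = model$params,
                       bn_state = model$bn_state)
      }
      history <- rbind(history, data.frame(epoch = ep, train_loss = loss,
                                           val_loss = vloss))
      if (verbose && ep %% 25 == 0)
        message(sprintf("epoch %3d  train %.4f  val %s", ep, loss,
                        ifelse(is.na(vloss), "-", sprintf("%.4f", vloss))))
    }
    if (use_val && is.finite(best$loss)) {
      model$params <- best$params
      model$bn_state <- best$bn_state
    }
    model$history <- history
    model
  })
}

#' Classification metrics for one evaluation fold
#'
#' Hard labels are the argmax of the class probabilities (class 1 when its
#' probability exceeds 0.5); AUC uses the class-1 probabilities via the
#' Mann-Whitney estimator. With a single-class fold the AUC is undefined
#' and reported as NA. Precision/F1 are NA when no positive predictions
#' exist.
#'
#' @param prob1 class-1 probability per sample.
#' @param labels 0/1 vector.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, `auc`.
#' @export
evaluate_predictions <- function(prob1, labels) {
  labels <- as.integer(labels)
  stopifnot(length(prob1) == length(labels))
  hard <- as.integer(prob1 > 0.5)
  tp <- sum(hard == 1 & labels == 1); fp <- sum(hard == 1 & labels == 0)
  fn <- sum(hard == 0 & labels == 1); tn <- sum(hard == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  auc <- if (length(unique(labels)) == 2)
    auc_mw(prob1[labels == 1], prob1[labels == 0])
  else {
    message("single-class fold: AUC undefined, reported as NA")
    NA_real_
  }
  list(accuracy = (tp + tn) / length(labels), precision = precision,
       recall = recall, f1 = f1, auc = auc)
}

#' Mean and normal-approximation 95% confidence interval
#'
#' @param values per-fold (x repeat) metric values; NAs are dropped.
#' @return List with `mean`, `lower`, `upper`, `n`; the CI is
#'   `mean +/- 1.96 * sd / sqrt(n)` and is NA with fewer than 2 values.
#' @export
aggregate_ci <- function(values) {
  values <- values[!is.na(values)]
  m <- length(values)
  if (m == 0) return(list(mean = NA_real_, lower = NA_real_,
                          upper = NA_real_, n = 0L))
  mu <- mean(values)
  if (m < 2) return(list(mean = mu, lower = NA_real_, upper = NA_real_,
                         n = 1L))
  half <- 1.96 * sd(values) / sqrt(m)
  list(mean = mu, lower = mu - half, upper = mu + half, n = m)
}

#' Cross-validated evaluation of a model configuration
#'
#' Repeated stratified k-fold cross-validation of the fusion model on a
#' fixed set of attributed PPI graphs and (optionally) image features.
#' SMOTE balancing is applied according to its `leakage_mode`: inside each
#' training fold (default, no leakage) or once before splitting
#' (`pre_split`). Reports the Table-style metric battery per fold and
#' aggregated with 95% confidence intervals.
#'
#' @param graphs named list of `ppi_graph` objects with features attached.
#'   May be empty/NULL for an images-only model.
#' @param image samples x features matrix or NULL for a genes-only model.
#' @param labels 0/1 vector.
#' @param config a [fusion_config()].
#' @param k folds (default 5).
#' @param repeats independent repetitions with distinct split seeds.
#' @param seed global seed; all internal seeds derive from it.
#' @param smote_cfg a [smote_config()]; NULL disables balancing.
#' @param hyper a [train_config()].
#' @param label configuration label recorded in the report.
#' @return An object of class `eval_report`: `folds` (per-fold metrics),
#'   `aggregate` (mean + CI per metric), `label`, `config` details.
#' @export
cross_validate <- function(graphs = NULL, image = NULL, labels,
                           config = fusion_config(), k = 5, repeats = 1,
                           seed = 1L, smote_cfg = smote_config(),
                           hyper = train_config(), label = "model") {
  labels <- as.integer(labels)
  graphs <- if (length(graphs)) graphs[order(names(graphs))]
  gf <- if (length(graphs)) lapply(graphs, function(g) {
    if (is.null(g$features)) stopf("graph '%s' has no features", g$name)
    g$features
  })
  n_img <- if (is.null(image)) 0L else ncol(image)
  # column layout of the SMOTE feature space: graph blocks then image
  widths <- c(if (length(gf)) vapply(gf, ncol, 0L), image = n_img)
  X_full <- do.call(cbind, c(unname(gf), if (n_img) list(as.matrix(image))))
  split_cols <- function(X) {
    out <- list(); at <- 0L
    if (length(gf)) for (g in names(gf)) {
      out$graph_features[[g]] <- X[, (at + 1):(at + ncol(gf[[g]])),
                                   drop = FALSE]
      at <- at + ncol(gf[[g]])
    }
    out$image <- if (n_img) X[, (at + 1):(at + n_img), drop = FALSE]
    out
  }
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    X <- X_full; y <- labels
    pre_parents <- NULL
    if (!is.null(smote_cfg) && smote_cfg$leakage_mode == "pre_split") {
      sm <- smote(X, y, smote_cfg,
                  seed = child_seed(seed, paste0("smote-pre", rep_i)))
      X <- sm$x; y <- sm$labels
    }
    folds <- kfold_split(y, k, seed = child_seed(seed, paste0("split", rep_i)))
    for (f in seq_len(k)) {
      tr <- which(folds != f); te <- which(folds == f)
      # hold out real samples for checkpoint validation before balancing,
      # so synthetic points never inflate the validation loss
      val_in <- NULL
      if (hyper$val_frac > 0) {
        val_idx <- with_seed(child_seed(seed, sprintf("val%d-%d", rep_i, f)), {
          vi <- integer(0)
          for (cl in unique(y[tr])) {
            idx <- tr[y[tr] == cl]
            n_val <- floor(hyper$val_frac * length(idx))
            if (n_val >= 1) vi <- c(vi, sample(idx, n_val))
          }
          vi
        })
        if (length(val_idx) >= 2 && length(unique(y[val_idx])) == 2) {
          val_in <- split_cols(X[val_idx, , drop = FALSE])
          val_in$labels <- y[val_idx]
          tr <- setdiff(tr, val_idx)
        }
      }
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      if (!is.null(smote_cfg) && smote_cfg$leakage_mode == "fold_train_only") {
        sm <- smote(Xtr, ytr, smote_cfg,
                    seed = child_seed(seed, sprintf("smote%d-%d", rep_i, f)))
        Xtr <- sm$x; ytr <- sm$labels
      }
      model <- build_fusion_model(graphs, n_img, config,
                                  seed = child_seed(seed,
                                                    sprintf("init%d-%d", rep_i, f)))
      tr_in <- split_cols(Xtr)
      model <- train_model(model, tr_in$graph_features, tr_in$image, ytr,
                           hyper = hyper, val = val_in,
                           seed = child_seed(seed,
                                             sprintf("train%d-%d", rep_i, f)))
      te_in <- split_cols(X[te, , drop = FALSE])
      p1 <- predict_fusion(model, te_in$graph_features, te_in$image)
      met <- evaluate_predictions(p1, y[te])
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_ = rep_i, fold = f, accuracy = met$accuracy,
                   precision = met$precision, recall = met$recall,
                   f1 = met$f1, auc = met$auc)
    }
  }
  folds_df <- do.call(rbind, rows)
  agg <- lapply(c(accuracy = "accuracy", precision = "precision",
                  recall = "recall", f1 = "f1", auc = "auc"),
                function(mm) aggregate_ci(folds_df[[mm]]))
  structure(list(folds = folds_df, aggregate = agg, label = label,
                 k = k, repeats = repeats, seed = seed,
                 leakage_mode = if (!is.null(smote_cfg))
                   smote_cfg$leakage_mode else "none"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report '%s' (%d-fold x %d repeats, SMOTE: %s)\n",
              x$label, x$k, x$repeats, x$leakage_mode))
  for (mm in names(x$aggregate)) {
    a <- x$aggregate[[mm]]
    cat(sprintf("  %-9s %.4f", mm, a$mean))
    if (!is.na(a$lower))
      cat(sprintf("  (95%% CI = %.4f-%.4f)", a$lower, a$upper))
    cat("\n")
  }
  invisible(x)
}

#' Compare two cross-validation reports
#'
#' Paired two-sided test on per-fold metric differences between two
#' configurations evaluated on the same splits (same k, repeats and seed).
#' With at most 20 pairs an exact sign-flip permutation test on the sum of
#' differences is used; otherwise a paired t-test.
#'
#' @param report_a,report_b `eval_report` objects with matched folds.
#' @param metric which per-fold metric to compare (default accuracy).
#' @return List with `p`, `mean_diff` (a minus b), `method`.
#' @export
compare_configs <- function(report_a, report_b, metric = "accuracy") {
  fa <- report_a$folds; fb <- report_b$folds
  if (nrow(fa) != nrow(fb) ||
      !identical(fa[c("repeat_", "fold")], fb[c("repeat_", "fold")]) ||
      report_a$seed != report_b$seed)
    stopf("reports have mismatched fold structure; rerun with shared splits")
  d <- fa[[metric]] - fb[[metric]]
  d <- d[!is.na(d)]
  m <- length(d)
  if (m < 2) stopf("need at least 2 paired folds")
  if (all(d == 0))
    return(list(p = 1, mean_diff = 0, method = "degenerate (identical)"))
  if (m <= 20) {
    sums <- 0
    for (di in d) sums <- c(sums + di, sums - di)
    p <- mean(abs(sums) >= abs(sum(d)) - 1e-12)
    list(p = p, mean_diff = mean(d), method = "exact sign-flip permutation")
  } else if (sd(d) == 0) {
    # constant nonzero difference: the t statistic degenerates to infinity
    list(p = 0, mean_diff = mean(d), method = "degenerate (constant difference)")
  } else {
    tt <- t.test(d)
    list(p = tt$p.value, mean_diff = mean(d), method = "paired t-test")
  }
}
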