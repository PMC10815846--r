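#' Configuration for weighted co-expression network analysis
#'
#' @param soft_power soft-threshold power `beta` applied to absolute Pearson
#'   correlations when building the adjacency (default 5).
#' @param min_module_size smallest cluster kept as a module; smaller clusters
#'   are relabeled 0 ("grey"/unassigned). Default 30.
#' @param variance_filter_quantile fraction in `[0, 1)`: genes whose median
#'   absolute deviation falls below this quantile of all gene MADs are
#'   removed before network construction.
#' @param sample_outlier_z remove samples whose mean inter-sample distance
#'   exceeds `mean + z * sd`; `NULL` disables outlier removal.
#' @param tree_cut_height flat cut height in `(0, 1]` on the average-linkage
#'   dendrogram of the topological-overlap dissimilarity.
#' @param signed use the signed variant `((1 + cor) / 2)^beta` instead of the
#'   unsigned `|cor|^beta` (default unsigned).
#' @return An object of class `coexpr_config`.
#' @export
coexpr_config <- function(soft_power = 5, min_module_size = 30,
                          variance_filter_quantile = 0,
                          sample_outlier_z = NULL,
                          tree_cut_height = 0.99,
                          signed = FALSE) {
  if (!is_count(soft_power) || soft_power < 1)
    stopf("`soft_power` must be a positive integer")
  if (!is_count(min_module_size) || min_module_size < 2)
    stopf("`min_module_size` must be >= 2")
  if (variance_filter_quantile < 0 || variance_filter_quantile >= 1)
    stopf("`variance_filter_quantile` must lie in [0, 1)")
  if (!is.null(sample_outlier_z) && sample_outlier_z <= 0)
    stopf("`sample_outlier_z` must be positive or NULL")
  if (tree_cut_height <= 0 || tree_cut_height > 1)
    stopf("`tree_cut_height` must lie in (0, 1]")
  structure(list(soft_power = soft_power,
                 min_module_size = min_module_size,
                 variance_filter_quantile = variance_filter_quantile,
                 sample_outlier_z = sample_outlier_z,
                 tree_cut_height = tree_cut_height,
                 signed = isTRUE(signed)),
            class = "coexpr_config")
}

#' Remove low-variability genes
#'
#' Drops genes whose median absolute deviation (MAD) across samples lies
#' strictly below the `variance_filter_quantile` quantile of all gene MADs.
#' Gene order is preserved; a quantile of 0 keeps everything, and constant
#' genes (MAD 0) are removed for any positive quantile.
#'
#' @param expr genes x samples matrix.
#' @param cfg a [coexpr_config()].
#' @return The filtered expression matrix.
#' @export
filter_genes <- function(expr, cfg = coexpr_config()) {
  if (!nrow(expr)) stopf("empty expression matrix")
  q <- cfg$variance_filter_quantile
  if (q == 0) return(expr)
  mads <- apply(expr, 1L, mad)
  keep <- mads >= quantile(mads, q)
  if (!any(keep)) stopf("variance filter removed every gene")
  expr[keep, , drop = FALSE]
}

#' Remove outlier samples by mean inter-sample distance
#'
#' A sample is an outlier when its mean Euclidean distance to all other
#' samples exceeds `mean + z * sd` of those per-sample means. At most 20% of
#' samples are removed (with a warning when the rule would flag more).
#'
#' @param expr genes x samples matrix with at least 3 samples.
#' @param cfg a [coexpr_config()]; `sample_outlier_z = NULL` is a no-op.
#' @return The expression matrix without outlier samples.
#' @export
remove_outlier_samples <- function(expr, cfg = coexpr_config()) {
  z <- cfg$sample_outlier_z
  if (is.null(z)) return(expr)
  n <- ncol(expr)
  if (n < 3) stopf("need at least 3 samples")
  d <- as.matrix(dist(t(expr)))
  md <- rowSums(d) / (n - 1)
  s <- sd(md)
  out <- if (s > 0) which(md > mean(md) + z * s) else integer(0)
  cap <- floor(0.2 * n)
  if (length(out) > cap) {
    warnf("outlier rule flagged %d/%d samples; capping removals at 20%%",
          length(out), n)
    out <- out[order(md[out], decreasing = TRUE)][seq_len(cap)]
  }
  if (length(out)) expr[, -out, drop = FALSE] else expr
}

#' Topological-overlap dissimilarity of a co-expression network
#'
#' Builds the soft-threshold adjacency `a_ij = |cor(x_i, x_j)|^beta`
#' (or the signed variant), computes the topological overlap matrix
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivity `k_i = sum_{u != i} a_iu`, and returns `1 - TOM`: a
#' symmetric dissimilarity with zero diagonal, values in `[0, 1]`.
#'
#' @param expr genes x samples matrix, at least 2 genes, no constant gene.
#' @param cfg a [coexpr_config()] supplying `soft_power` and `signed`.
#' @return genes x genes dissimilarity matrix.
#' @export
adjacency_tom <- function(expr, cfg = coexpr_config()) {
  if (nrow(expr) < 2) stopf("need at least 2 genes")
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0))
    stopf("zero-variance gene(s) present; run filter_genes() first")
  cc <- cor(t(expr))
  a <- if (cfg$signed) ((1 + cc) / 2)^cfg$soft_power
       else abs(cc)^cfg$soft_power
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diss <- 1 - tom
  diag(diss) <- 0
  diss <- (diss + t(diss)) / 2
  diss
}

#' Detect modules by average-linkage clustering of the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of the dissimilarity, flat cut at
#' `tree_cut_height`; clusters smaller than `min_module_size` are relabeled
#' 0 (unassigned). Surviving modules are renumbered 1, 2, ... by decreasing
#' size (ties broken by first gene position) so labels are reproducible.
#'
#' @param dissim square symmetric dissimilarity matrix with gene dimnames.
#' @param cfg a [coexpr_config()].
#' @return Named integer vector: gene -> module label (0 = unassigned).
#' @export
detect_modules <- function(dissim, cfg = coexpr_config()) {
  stopifnot(nrow(dissim) == ncol(dissim))
  hc <- hclust(as.dist(dissim), method = "average")
  raw <- cutree(hc, h = cfg$tree_cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= cfg$min_module_size])
  lab <- integer(length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[as.character(keep)],
                      vapply(keep, function(k) min(which(raw == k)), 0L))]
    for (j in seq_along(ord)) lab[raw == ord[j]] <- j
  }
  names(lab) <- rownames(dissim)
  lab
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' gene-standardized module submatrix: a unit-norm vector with one value per
#' sample, sign-oriented so it correlates positively with the module's mean
#' standardized expression. A single-gene module returns that gene's
#' standardized profile (unit norm).
#'
#' @param expr genes x samples matrix.
#' @param modules named gene -> module vector from [detect_modules()].
#' @return samples x modules matrix with columns `ME1`, `ME2`, ...
#' @export
module_eigengene <- function(expr, modules) {
  mods <- sort(unique(modules[modules > 0L]))
  if (!length(mods)) stopf("no assigned modules")
  out <- matrix(NA_real_, ncol(expr), length(mods),
                dimnames = list(colnames(expr), paste0("ME", mods)))
  for (j in seq_along(mods)) {
    genes <- names(modules)[modules == mods[j]]
    sub <- standardize_genes(expr[genes, , drop = FALSE])
    if (length(genes) == 1L) {
      v <- drop(sub)
      out[, j] <- v / sqrt(sum(v^2))
      next
    }
    sv <- svd(t(sub), nu = 1, nv = 0)
    e <- sv$u[, 1]
    if (cor(e, colMeans(sub)) < 0) e <- -e
    out[, j] <- e
  }
  out
}

#' Module-trait association statistics
#'
#' Pearson (point-biserial) correlation of each module eigengene with a
#' binary trait, with the two-sided Student-t p-value.
#'
#' @param eigengenes samples x modules matrix from [module_eigengene()].
#' @param trait 0/1 vector, both classes present.
#' @return data.frame with `module`, `cor`, `p`.
#' @export
module_trait_stats <- function(eigengenes, trait) {
  trait <- as.numeric(trait)
  if (length(unique(trait)) < 2) stopf("trait is constant")
  n <- nrow(eigengenes)
  r <- as.numeric(cor(eigengenes, trait))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  data.frame(module = colnames(eigengenes), cor = r,
             p = 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE),
             row.names = NULL)
}

#' Gene significance
#'
#' GS of a gene is the absolute Pearson correlation between its expression
#' and the binary trait.
#'
#' @param expr genes x samples matrix.
#' @param trait 0/1 vector, both classes present.
#' @return Named numeric vector of GS scores in `[0, 1]`.
#' @export
gene_significance <- function(expr, trait) {
  trait <- as.numeric(trait)
  if (length(unique(trait)) < 2) stopf("trait is constant")
  gs <- abs(as.numeric(cor(t(expr), trait)))
  names(gs) <- rownames(expr)
  gs
}

#' Run the full co-expression stage
#'
#' Convenience wrapper: gene filtering, optional sample outlier removal,
#' TOM dissimilarity, module detection, eigengenes, module-trait statistics
#' and gene significance.
#'
#' @param expr genes x samples matrix.
#' @param trait binary trait aligned with the (post-filter) samples.
#' @param cfg a [coexpr_config()].
#' @return A list of class `module_assignment`: `modules`, `eigengenes`,
#'   `trait_stats`, `gene_significance`, `expression` (the filtered matrix).
#' @export
coexpression_modules <- function(expr, trait, cfg = coexpr_config()) {
  expr <- filter_genes(expr, cfg)
  expr <- remove_outlier_samples(expr, cfg)
  trait <- trait[colnames(expr)]
  diss <- adjacency_tom(expr, cfg)
  modules <- detect_modules(diss, cfg)
  me <- if (any(modules > 0)) module_eigengene(expr, modules) else NULL
  structure(list(modules = modules,
                 eigengenes = me,
                 trait_stats = if (!is.null(me)) module_trait_stats(me, trait),
                 gene_significance = gene_significance(expr, trait),
                 expression = expr),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  k <- max(x$modules)
  cat(sprintf("Co-expression modules: %d genes, %d modules (%d unassigned)\n",
              length(x$modules), k, sum(x$modules == 0)))
  invisible(x)
}
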