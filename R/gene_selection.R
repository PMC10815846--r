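#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: set name, description, then member gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (pathway id -> gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line: %s", substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (any(!lengths(sets))) stopf("GMT contains an empty gene set")
  sets
}

selection_result <- function(stage, table, alpha) {
  structure(list(stage = stage, table = table, alpha = alpha,
                 retained = table$gene[table$retained]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selection stage '%s': %d/%d genes retained (alpha = %g)\n",
              x$stage, length(x$retained), nrow(x$table), x$alpha))
  invisible(x)
}

#' Differentially expressed genes by Welch's t-test
#'
#' Per-gene two-sample Welch t-test between the two label classes (expression
#' assumed to be on a log-like scale). Genes with raw p below `alpha` are
#' retained; Benjamini-Hochberg q-values are reported alongside but not used
#' for selection.
#'
#' @param expr genes x samples matrix.
#' @param labels 0/1 vector aligned with columns.
#' @param alpha significance level (default 0.05).
#' @return A `selection_result` whose table has `gene`, `statistic`, `p`,
#'   `q`, `retained`.
#' @export
deg_test <- function(expr, labels, alpha = 0.05) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 0); n2 <- sum(labels == 1)
  if (n1 < 2 || n2 < 2) stopf("each class needs >= 2 samples")
  x1 <- expr[, labels == 0, drop = FALSE]
  x2 <- expr[, labels == 1, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, var); v2 <- apply(x2, 1L, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  tab <- data.frame(gene = rownames(expr), statistic = tstat, p = p,
                    q = p.adjust(p, "BH"), retained = p < alpha,
                    row.names = NULL)
  selection_result("deg", tab, alpha)
}

#' Pathway over-representation by the hypergeometric test
#'
#' For each gene set, tests whether its overlap with the query is larger
#' than expected when drawing `|query|` genes from the background: the
#' upper-tail hypergeometric probability, identical to a one-sided Fisher
#' exact test on the 2x2 overlap table.
#'
#' @param query character vector of selected genes (must be a subset of
#'   `background`).
#' @param background character vector: the gene universe.
#' @param sets named list of gene sets (see [read_gmt()]).
#' @param alpha significance level (default 0.05).
#' @return data.frame with `pathway`, `overlap`, `set_size`, `p`, `q`,
#'   `retained`, and an `overlap_genes` list column.
#' @export
ora_enrichment <- function(query, background, sets, alpha = 0.05) {
  query <- unique(query); background <- unique(background)
  if (!all(query %in% background))
    stopf("query contains genes outside the background")
  N <- length(background); n <- length(query)
  res <- lapply(names(sets), function(id) {
    set <- intersect(sets[[id]], background)
    hit <- intersect(set, query)
    K <- length(set); k <- length(hit)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = id, overlap = k, set_size = K, p = p)
  })
  tab <- do.call(rbind, res)
  tab$q <- p.adjust(tab$p, "BH")
  tab$retained <- tab$p < alpha
  tab$overlap_genes <- lapply(names(sets), function(id)
    intersect(intersect(sets[[id]], background), query))
  tab
}

#' Univariate logistic screen
#'
#' Fits a per-gene univariate logistic regression of the label on
#' expression and retains genes whose Wald p-value is below `alpha`.
#' Perfectly separating genes are flagged and retained with p = 0 (the Wald
#' statistic degenerates); constant genes are excluded with a note.
#'
#' @param expr genes x samples matrix.
#' @param labels 0/1 vector aligned with columns.
#' @param genes gene ids to screen (default all rows); must be in `expr`.
#' @param alpha significance level (default 0.05).
#' @return A `selection_result` whose table has `gene`, `statistic` (Wald
#'   z), `p`, `q`, `retained`, `note`.
#' @export
univariate_screen <- function(expr, labels, genes = rownames(expr),
                              alpha = 0.05) {
  if (!all(genes %in% rownames(expr)))
    stopf("genes absent from expression matrix: %s",
          paste(setdiff(genes, rownames(expr)), collapse = ", "))
  y <- as.integer(labels)
  fit_one <- function(g) {
    x <- expr[g, ]
    if (sd(x) == 0)
      return(data.frame(gene = g, statistic = NA_real_, p = NA_real_,
                        note = "constant gene; excluded"))
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ x, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    # a residual deviance of ~0 means the gene separates the classes
    # perfectly even when IRLS reports convergence without a warning
    if (sep || !fit$converged || fit$deviance < 1e-6)
      return(data.frame(gene = g, statistic = Inf, p = 0,
                        note = "perfect separation; p = 0 by convention"))
    sm <- summary(fit)$coefficients
    data.frame(gene = g, statistic = sm["x", "z value"],
               p = sm["x", "Pr(>|z|)"], note = "")
  }
  tab <- do.call(rbind, lapply(genes, fit_one))
  tab$q <- p.adjust(tab$p, "BH")
  tab$retained <- !is.na(tab$p) & tab$p < alpha
  if (any(tab$note == "perfect separation; p = 0 by convention"))
    message("univariate_screen: perfect separation flagged for ",
            sum(tab$note != "" & tab$retained), " gene(s)")
  selection_result("univariate", tab, alpha)
}

#' Top-k genes by gene significance
#'
#' Ranks genes by descending GS score; ties are broken by lexicographic gene
#' id so the selection is reproducible.
#'
#' @param gs_scores named numeric vector of GS scores.
#' @param k number of genes to return (default 5).
#' @return Character vector of the top-k gene ids.
#' @export
gs_rank <- function(gs_scores, k = 5) {
  if (!is_count(k) || k <= 0) stopf("`k` must be a positive count")
  if (k > length(gs_scores)) stopf("`k` exceeds the number of genes")
  ord <- order(-gs_scores, names(gs_scores))
  names(gs_scores)[ord][seq_len(k)]
}
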