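#' Load a STRING-style PPI edge list
#'
#' Reads a TSV with columns `protein1`, `protein2`, `combined_score`
#' (scores on STRING's 0-1000 scale), drops edges below `score_min`,
#' removes self-edges and de-duplicates unordered pairs, keeping the
#' highest score of a duplicated pair.
#'
#' @param path TSV path.
#' @param score_min minimum combined score kept (default 400, STRING's
#'   medium-confidence floor).
#' @return data.frame with `protein1`, `protein2`, `combined_score`.
#' @export
load_string_edges <- function(path, score_min = 400) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(raw)))
    stopf("edge file must have columns %s", paste(need, collapse = ", "))
  score <- suppressWarnings(as.numeric(raw$combined_score))
  bad <- which(is.na(score) | !nzchar(raw$protein1) | !nzchar(raw$protein2))
  if (length(bad))
    stopf("malformed edge row at line %d of %s", bad[1] + 1L, path)
  raw$combined_score <- score
  clean_edges(raw[score >= score_min, , drop = FALSE])
}

# Canonicalize an edge table: drop self-edges, orient pairs, de-duplicate
# keeping the maximum score.
clean_edges <- function(edges) {
  edges <- edges[edges$protein1 != edges$protein2, , drop = FALSE]
  if (!nrow(edges))
    return(data.frame(protein1 = character(), protein2 = character(),
                      combined_score = numeric()))
  a <- pmin(edges$protein1, edges$protein2)
  b <- pmax(edges$protein1, edges$protein2)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -edges$combined_score)
  keep <- !duplicated(key[ord])
  out <- data.frame(protein1 = a[ord][keep], protein2 = b[ord][keep],
                    combined_score = edges$combined_score[ord][keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Induce an attributed PPI graph on a gene set
#'
#' Builds the induced subgraph of the edge list on `gene_set`. Isolated
#' genes are kept as singleton nodes, a self-loop is added to every node
#' (so attention neighborhoods are never empty), and graphs with zero
#' non-loop edges are flagged as "no PPI network formed".
#'
#' @param edges edge data.frame (see [load_string_edges()]).
#' @param gene_set non-empty character vector of gene ids.
#' @param name optional graph identifier.
#' @return An object of class `ppi_graph`: `nodes`, `edges` (non-loop),
#'   `adjacency` (0/1 with unit diagonal), `no_ppi` flag, `name`.
#' @export
induce_subgraph <- function(edges, gene_set, name = NULL) {
  if (!length(gene_set)) stopf("empty gene set")
  gene_set <- unique(gene_set)
  sub <- edges[edges$protein1 %in% gene_set & edges$protein2 %in% gene_set,
               , drop = FALSE]
  sub <- clean_edges(sub)
  g <- igraph::graph_from_data_frame(
    sub[, c("protein1", "protein2")], directed = FALSE,
    vertices = data.frame(name = gene_set))
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  adj[adj > 0] <- 1
  diag(adj) <- 1
  structure(list(nodes = gene_set, edges = sub, adjacency = adj,
                 no_ppi = nrow(sub) == 0L, name = name,
                 features = NULL),
            class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("PPI graph%s: %d nodes, %d edges%s%s\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
              length(x$nodes), nrow(x$edges),
              if (x$no_ppi) " [no PPI network formed]" else "",
              if (!is.null(x$features)) " [features attached]" else ""))
  invisible(x)
}

#' Attach per-sample node features to a PPI graph
#'
#' The node feature of gene g in sample s is the gene-wise z-scored
#' expression value (mean 0, sd 1 across samples), a single scalar per
#' node. Set `standardize = FALSE` to use raw expression.
#'
#' @param graph a [induce_subgraph()] result.
#' @param expr genes x samples matrix covering every graph node.
#' @param standardize z-score genes across samples (default TRUE).
#' @return The graph with a `features` matrix (samples x nodes).
#' @export
attach_features <- function(graph, expr, standardize = TRUE) {
  missing <- setdiff(graph$nodes, rownames(expr))
  if (length(missing))
    stopf("genes missing from expression matrix: %s",
          paste(missing, collapse = ", "))
  sub <- expr[graph$nodes, , drop = FALSE]
  if (standardize) sub <- standardize_genes(sub)
  graph$features <- t(sub)
  graph
}

#' Build attributed PPI graphs for a list of gene sets
#'
#' @param edges edge data.frame.
#' @param gene_sets named list of gene id vectors.
#' @param expr optional expression matrix; when given, features are attached
#'   and gene sets are first intersected with its rownames.
#' @param drop_no_ppi drop graphs flagged "no PPI network formed"
#'   (default TRUE, mirroring the usual analysis practice).
#' @return Named list of `ppi_graph` objects, ordered by sorted set name.
#' @export
build_ppi_graphs <- function(edges, gene_sets, expr = NULL,
                             drop_no_ppi = TRUE) {
  gene_sets <- gene_sets[order(names(gene_sets))]
  graphs <- lapply(names(gene_sets), function(nm) {
    gs <- gene_sets[[nm]]
    if (!is.null(expr)) gs <- intersect(gs, rownames(expr))
    if (!length(gs)) return(NULL)
    g <- induce_subgraph(edges, gs, name = nm)
    if (!is.null(expr)) g <- attach_features(g, expr)
    g
  })
  names(graphs) <- names(gene_sets)
  graphs <- graphs[!vapply(graphs, is.null, TRUE)]
  if (drop_no_ppi)
    graphs <- graphs[!vapply(graphs, function(g) g$no_ppi, TRUE)]
  graphs
}
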