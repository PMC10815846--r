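# Independent oracles used across tests. These deliberately reimplement the
# quantities under test with naive dense / brute-force algorithms.

# Dense masked-softmax GAT oracle for one attention head: builds the full
# N x N logit matrix, masks non-edges with -Inf, row-softmaxes, multiplies.
dense_gat_oracle <- function(H, W, a_src, a_dst, adj, slope) {
  Z <- H %*% W
  s <- drop(Z %*% a_src)
  t <- drop(Z %*% a_dst)
  n <- nrow(adj)
  E <- outer(s, rep(1, n)) + outer(rep(1, n), t)   # E[i, j] = s_i + t_j
  E <- ifelse(E > 0, E, slope * E)
  E[adj == 0] <- -Inf
  A <- exp(E - apply(E, 1, max))
  A <- A / rowSums(A)
  A %*% Z
}

# Brute-force Mann-Whitney AUC: mean over all (pos, neg) pairs.
brute_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Random undirected adjacency with self-loops on n nodes.
random_adj <- function(n, p = 0.5) {
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  a[up] <- as.numeric(runif(sum(up)) < p)
  a <- a + t(a)
  diag(a) <- 1
  a
}

# ppi_graph built directly from an adjacency matrix (test plumbing).
graph_from_adj <- function(adj, name = "g") {
  n <- nrow(adj)
  nodes <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(nodes, nodes)
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(protein1 = nodes[idx[, 1]], protein2 = nodes[idx[, 2]],
                      combined_score = 900)
  a <- adj
  diag(a) <- 1
  structure(list(nodes = nodes, edges = edges, adjacency = a,
                 no_ppi = nrow(edges) == 0, name = name, features = NULL),
            class = "ppi_graph")
}

# Small two-module cohort used by several model tests.
tiny_cohort <- function(seed = 101) {
  generate_cohort(synthetic_config(
    n_major = 30, n_minor = 12, n_genes = 50, module_sizes = c(15, 15),
    within_module_cor = 0.7, signal_genes = 3, effect_size_d = 1.5,
    n_features_per_modality = 8,
    feature_target_aucs = c(rep(0.85, 3), rep(0.5, 5)), seed = seed))
}

# Graphs with features for a cohort, built from the planted truth modules.
truth_graphs <- function(cohort) {
  mods <- cohort$truth$modules[cohort$truth$modules > 0]
  sets <- split(names(mods), paste0("module", mods))
  build_ppi_graphs(cohort$ppi_edges, sets, cohort$expression,
                   drop_no_ppi = FALSE)
}
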