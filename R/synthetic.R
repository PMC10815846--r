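#' Configuration for the synthetic radiogenomic cohort generator
#'
#' Describes a labeled two-class cohort whose statistical structure matches
#' what the downstream stages assume: block-correlated gene modules generated
#' from a latent factor model, a small set of label-associated signal genes,
#' a protein-protein interaction (PPI) edge list that is denser inside
#' modules than between them, and two radiomic feature tables (PET and CT)
#' whose per-feature discriminative AUC is controlled through the binormal
#' model.
#'
#' The default cohort is 73 non-metastasis vs 20 metastasis samples with 55
#' features per imaging modality, the shape the pipeline was designed around.
#'
#' @param n_major,n_minor samples in the majority (label 0) and minority
#'   (label 1) class.
#' @param n_genes total genes; genes beyond the planted modules are
#'   independent noise.
#' @param module_sizes integer vector of planted module sizes; their sum must
#'   not exceed `n_genes`.
#' @param within_module_cor target pairwise Pearson correlation `r` in
#'   `[0, 1)` between genes of the same module. Each module gene is
#'   `sqrt(r) * f_m + sqrt(1 - r) * eps` for a module-level latent factor
#'   `f_m`, so the population correlation of two module genes is exactly `r`.
#' @param signal_genes number of label-associated genes (taken from the start
#'   of the first module onwards).
#' @param effect_size_d standardized mean shift (Cohen's d) added to signal
#'   genes in the minority class.
#' @param ppi_within_density,ppi_between_density Bernoulli edge probabilities
#'   inside vs across modules.
#' @param n_features_per_modality radiomic features per modality (default 55).
#' @param feature_target_aucs target per-feature AUCs in `[0.5, 1)`, recycled
#'   or truncated to `n_features_per_modality`. The default plants five
#'   discriminative features (AUC 0.8) per modality among null features.
#' @param seed integer seed making the cohort reproducible.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_major = 73, n_minor = 20,
                             n_genes = 300,
                             module_sizes = c(50, 50, 50),
                             within_module_cor = 0.7,
                             signal_genes = 4,
                             effect_size_d = 1.5,
                             ppi_within_density = 0.3,
                             ppi_between_density = 0.02,
                             n_features_per_modality = 55,
                             feature_target_aucs = c(rep(0.8, 5), rep(0.5, 50)),
                             seed = 1L) {
  cfg <- list(n_major = n_major, n_minor = n_minor, n_genes = n_genes,
              n_modules = length(module_sizes), module_sizes = module_sizes,
              within_module_cor = within_module_cor,
              signal_genes = signal_genes, effect_size_d = effect_size_d,
              ppi_within_density = ppi_within_density,
              ppi_between_density = ppi_between_density,
              n_features_per_modality = n_features_per_modality,
              feature_target_aucs = feature_target_aucs,
              seed = seed)
  for (f in c("n_major", "n_minor", "n_genes", "signal_genes",
              "n_features_per_modality"))
    if (!is_count(cfg[[f]])) stopf("`%s` must be a non-negative count", f)
  if (cfg$n_major < 2 || cfg$n_minor < 2)
    stopf("each class needs at least 2 samples")
  if (!all(vapply(module_sizes, is_count, logical(1))) ||
      any(module_sizes < 1))
    stopf("`module_sizes` must be positive counts")
  if (sum(module_sizes) > n_genes)
    stopf("sum(module_sizes) = %d exceeds n_genes = %d",
          sum(module_sizes), n_genes)
  if (!is.numeric(within_module_cor) || within_module_cor < 0 ||
      within_module_cor >= 1)
    stopf("`within_module_cor` must lie in [0, 1)")
  assert_prob(ppi_within_density, "ppi_within_density")
  assert_prob(ppi_between_density, "ppi_between_density")
  if (any(feature_target_aucs < 0.5) || any(feature_target_aucs >= 1))
    stopf("`feature_target_aucs` must lie in [0.5, 1)")
  if (signal_genes > sum(module_sizes))
    stopf("`signal_genes` exceeds the number of module genes")
  n <- cfg$n_features_per_modality
  cfg$feature_target_aucs <- rep_len(feature_target_aucs, n)
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic cohort config: %d + %d samples, %d genes",
    " (%d modules, r = %.2f), %d signal genes (d = %.2f),",
    " %d radiomic features/modality\n"),
    x$n_major, x$n_minor, x$n_genes, x$n_modules, x$within_module_cor,
    x$signal_genes, x$effect_size_d, x$n_features_per_modality))
  invisible(x)
}

gene_ids <- function(n) sprintf("gene%04d", seq_len(n))
sample_ids <- function(n) sprintf("sample%03d", seq_len(n))

# Module membership implied by the config: label 0 = unassigned noise gene.
planted_modules <- function(cfg) {
  m <- integer(cfg$n_genes)
  idx <- 1L
  for (j in seq_along(cfg$module_sizes)) {
    m[idx:(idx + cfg$module_sizes[j] - 1L)] <- j
    idx <- idx + cfg$module_sizes[j]
  }
  names(m) <- gene_ids(cfg$n_genes)
  m
}

#' Generate a block-correlated expression matrix with planted signal genes
#'
#' Each planted module is a latent-factor block: gene g in module m is
#' `sqrt(r) * f_m + sqrt(1 - r) * eps_g` with r the within-module
#' correlation, so any
#' two genes of the same module have population correlation `r` and unit
#' marginal variance. Signal genes additionally receive a `+ d * label` mean
#' shift, interpretable as Cohen's d. Genes outside the modules are
#' independent standard normal noise.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with `expression` (genes x samples matrix), `labels`
#'   (named 0/1 vector) and `truth` (planted module membership, signal gene
#'   ids, latent factor matrix).
#' @export
generate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(child_seed(cfg$seed, "expression"), {
    n_samp <- cfg$n_major + cfg$n_minor
    labels <- c(rep(0L, cfg$n_major), rep(1L, cfg$n_minor))
    names(labels) <- sample_ids(n_samp)
    modules <- planted_modules(cfg)
    r <- cfg$within_module_cor
    factors <- matrix(rnorm(cfg$n_modules * n_samp), cfg$n_modules, n_samp)
    expr <- matrix(rnorm(cfg$n_genes * n_samp), cfg$n_genes, n_samp,
                   dimnames = list(names(modules), names(labels)))
    in_mod <- modules > 0L
    expr[in_mod, ] <- sqrt(r) * factors[modules[in_mod], , drop = FALSE] +
      sqrt(1 - r) * expr[in_mod, , drop = FALSE]
    sig <- names(modules)[seq_len(cfg$signal_genes)]
    if (cfg$signal_genes > 0)
      expr[sig, ] <- expr[sig, , drop = FALSE] +
        cfg$effect_size_d * rep(labels, each = cfg$signal_genes)
    truth <- list(modules = modules, signal_genes = sig, factors = factors,
                  feature_target_aucs = cfg$feature_target_aucs)
    list(expression = expr, labels = labels, truth = truth)
  })
}

#' Generate a STRING-style PPI edge list over the planted modules
#'
#' Unordered gene pairs receive an edge with probability
#' `ppi_within_density` when both genes share a planted module and
#' `ppi_between_density` otherwise; no self-edges, no duplicates. Each edge
#' gets an integer `combined_score` uniform on `[400, 999]`, mirroring the
#' medium-confidence floor of STRING exports.
#'
#' @param cfg a [synthetic_config()].
#' @param truth the `truth` record from [generate_expression()].
#' @return A data.frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @export
generate_ppi <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synthetic_config"), !is.null(truth$modules))
  with_seed(child_seed(cfg$seed, "ppi"), {
    modules <- truth$modules
    ids <- names(modules)
    pair_i <- rep(seq_along(ids), times = rev(seq_along(ids)) - 1L)
    pair_j <- unlist(lapply(seq_along(ids)[-length(ids)],
                            function(i) (i + 1L):length(ids)), use.names = FALSE)
    same <- modules[pair_i] == modules[pair_j] & modules[pair_i] > 0L
    p <- ifelse(same, cfg$ppi_within_density, cfg$ppi_between_density)
    keep <- runif(length(p)) < p
    data.frame(protein1 = ids[pair_i[keep]],
               protein2 = ids[pair_j[keep]],
               combined_score = sample(400:999, sum(keep), replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

# Printed feature names of the PET/CT texture battery; padded with generic
# texture-matrix names when more features are requested.
radiomic_feature_names <- function(n) {
  base <- c("TLG", "SHAPE Volume (mL)", "SHAPE Volume (# vx)",
            "SHAPE Compacity", "GLRLM GLNU", "GLZLM LZHGE",
            "NGLDM Busyness", "GLZLM GLNU", "SUVmax", "SUVmean",
            "SUVpeak", "GLCM Homogeneity", "GLCM Energy", "GLCM Contrast",
            "GLCM Correlation", "GLCM Entropy", "GLCM Dissimilarity",
            "GLRLM SRE", "GLRLM LRE", "GLRLM LGRE", "GLRLM HGRE",
            "GLRLM SRLGE", "GLRLM SRHGE", "GLRLM LRLGE", "GLRLM LRHGE",
            "GLRLM RLNU", "GLRLM RP", "NGLDM Coarseness", "NGLDM Contrast",
            "GLZLM SZE", "GLZLM LZE", "GLZLM LGZE", "GLZLM HGZE",
            "GLZLM SZLGE", "GLZLM SZHGE", "GLZLM LZLGE", "GLZLM LZHGE 2",
            "GLZLM ZLNU", "GLZLM ZP", "HISTO Skewness", "HISTO Kurtosis",
            "HISTO Entropy", "HISTO Energy", "SHAPE Sphericity",
            "SHAPE Surface (mm2)", "CONV Q1", "CONV Q2", "CONV Q3",
            "CONV Kurtosis", "CONV Skewness", "CONV Median", "CONV SD",
            "CONV Mean", "CONV Min", "CONV Max")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("TEXTURE F%02d", seq_len(n - length(base))))
}

#' Generate a radiomic feature table with controlled per-feature AUC
#'
#' Features are unit-variance normal; the minority class mean is shifted by
#' `delta = sqrt(2) * qnorm(A)` per feature so that under the equal-variance
#' binormal model the population ROC AUC equals the target `A`.
#'
#' @param cfg a [synthetic_config()].
#' @param labels named 0/1 label vector (one per sample).
#' @param modality string tag mixed into the RNG stream so PET and CT tables
#'   are independent draws.
#' @return A samples x features numeric matrix with named columns.
#' @export
generate_radiomics <- function(cfg, labels, modality = "pet") {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (any(cfg$feature_target_aucs >= 1))
    stopf("target AUCs must be < 1")
  with_seed(child_seed(cfg$seed, paste0("radiomics-", modality)), {
    n <- length(labels)
    p <- cfg$n_features_per_modality
    delta <- sqrt(2) * qnorm(cfg$feature_target_aucs)
    x <- matrix(rnorm(n * p), n, p)
    x <- x + outer(as.numeric(labels), delta)
    dimnames(x) <- list(names(labels), radiomic_feature_names(p))
    x
  })
}

#' Generate a complete synthetic radiogenomic cohort
#'
#' Bundles [generate_expression()], [generate_ppi()] and
#' [generate_radiomics()] (one PET and one CT table) into a single cohort
#' object. The same config and seed always produce a bit-identical cohort.
#'
#' @param cfg a [synthetic_config()].
#' @return An object of class `synthetic_cohort`: a list with `expression`,
#'   `labels`, `ppi_edges`, `radiomic_pet`, `radiomic_ct` and `truth`.
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  ex <- generate_expression(cfg)
  structure(list(expression = ex$expression,
                 labels = ex$labels,
                 ppi_edges = generate_ppi(cfg, ex$truth),
                 radiomic_pet = generate_radiomics(cfg, ex$labels, "pet"),
                 radiomic_ct = generate_radiomics(cfg, ex$labels, "ct"),
                 truth = ex$truth,
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d genes x %d samples (%d/%d),",
                     " %d PPI edges, %d radiomic features/modality\n"),
              nrow(x$expression), ncol(x$expression),
              sum(x$labels == 0), sum(x$labels == 1),
              nrow(x$ppi_edges), ncol(x$radiomic_pet)))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the expression matrix and labels as TSV, the PPI edge list in the
#' STRING export dialect (`protein1`, `protein2`, `combined_score`), the two
#' radiomic tables as CSV and the ground-truth record as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             ppi = file.path(dir, "ppi_edges.tsv"),
             pet = file.path(dir, "radiomic_pet.csv"),
             ct = file.path(dir, "radiomic_ct.csv"),
             truth = file.path(dir, "truth.json"))
  write.table(cohort$expression, paths["expression"], sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(data.frame(sample = names(cohort$labels),
                         label = as.integer(cohort$labels)),
              paths["labels"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$ppi_edges, paths["ppi"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(cohort$radiomic_pet, paths["pet"])
  write.csv(cohort$radiomic_ct, paths["ct"])
  truth <- cohort$truth
  truth$factors <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read an expression TSV (genes x samples) written by [write_cohort()]
#' @param path file path.
#' @return genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
}

#' Read a labels TSV (columns `sample`, `label`)
#' @param path file path.
#' @return named integer 0/1 vector.
#' @export
read_labels <- function(path) {
  d <- read.delim(path)
  setNames(as.integer(d$label), d$sample)
}
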