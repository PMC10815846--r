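#' Pipeline configuration
#'
#' A single nested configuration driving [run_pipeline()]. Every random
#' operation draws from a stage-scoped seed derived from the global seed,
#' so a rerun with the same configuration is bit-identical.
#'
#' @param out_dir run directory for artifacts and manifests.
#' @param seed global seed.
#' @param stages which stages to execute, in pipeline order. Later stages
#'   require the artifacts of earlier ones within the same call.
#' @param synthetic a [synthetic_config()]; its `seed` is overridden by the
#'   derived stage seed.
#' @param coexpr a [coexpr_config()].
#' @param gene_stage which gene set(s) define the PPI graphs:
#'   `"modules"` (trait-associated co-expression modules), `"deg"`,
#'   `"univariate"`, or `"gs"` (top-k hub genes).
#' @param gmt optional GMT file path for pathway over-representation.
#' @param alpha significance level for the gene-selection cascade.
#' @param top_k hub genes kept by GS ranking.
#' @param score_min STRING combined-score floor.
#' @param auc_threshold radiomic AUC selection threshold (default 0.68).
#' @param images image modality: `"petct"`, `"pet"`, `"ct"` or `"none"`.
#' @param feature_mode `"selected"` (AUC-screened) or `"whole"` image
#'   features.
#' @param fusion a [fusion_config()].
#' @param train a [train_config()].
#' @param k,repeats cross-validation folds and repeats.
#' @param smote a [smote_config()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("radiogat-run-"),
                            seed = 1L,
                            stages = c("simulate", "modules",
                                       "select_genes", "build_graphs",
                                       "select_features", "train",
                                       "report"),
                            synthetic = synthetic_config(),
                            coexpr = coexpr_config(),
                            gene_stage = c("modules", "deg", "univariate",
                                           "gs"),
                            gmt = NULL,
                            alpha = 0.05,
                            top_k = 5,
                            score_min = 400,
                            auc_threshold = 0.68,
                            images = c("petct", "pet", "ct", "none"),
                            feature_mode = c("selected", "whole"),
                            fusion = fusion_config(),
                            train = train_config(),
                            k = 5, repeats = 1,
                            smote = smote_config()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = match.arg(stages, several.ok = TRUE),
                 synthetic = synthetic, coexpr = coexpr,
                 gene_stage = match.arg(gene_stage), gmt = gmt,
                 alpha = alpha, top_k = top_k, score_min = score_min,
                 auc_threshold = auc_threshold,
                 images = match.arg(images),
                 feature_mode = match.arg(feature_mode),
                 fusion = fusion, train = train, k = k, repeats = repeats,
                 smote = smote),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()]; nested sections (`synthetic`, `coexpr`, `fusion`,
#' `train`, `smote`) override the corresponding config defaults
#' field-by-field.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fn, over) do.call(fn, if (is.null(over)) list() else over)
  args <- y[setdiff(names(y), c("synthetic", "coexpr", "fusion", "train",
                                "smote"))]
  args$synthetic <- build(synthetic_config, y$synthetic)
  args$coexpr <- build(coexpr_config, y$coexpr)
  args$fusion <- build(fusion_config, y$fusion)
  args$train <- build(train_config, y$train)
  args$smote <- build(smote_config, y$smote)
  do.call(pipeline_config, args)
}

write_manifest <- function(dir, stage, cfg_bits, inputs = character()) {
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion("radiogat")),
              seed = cfg_bits$seed,
              config = cfg_bits$config,
              input_md5 = as.list(setNames(unname(tools::md5sum(inputs)),
                                           basename(inputs))))
  jsonlite::write_json(man, file.path(dir, paste0("manifest-", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the radiogenomic prediction pipeline
#'
#' Executes the enabled stages in order: cohort simulation, co-expression
#' module discovery, the gene-selection cascade, PPI graph construction,
#' radiomic AUC screening, cross-validated fusion-model training, and the
#' final report. Each stage writes its artifact plus a manifest (seed,
#' configuration, input checksums) into the run directory; a stage failure
#' stops the run with a stage-labeled error, preserving earlier artifacts.
#'
#' @param config a [pipeline_config()] or path to a YAML file for
#'   [read_pipeline_config()].
#' @return Invisibly, a list with the run directory and in-memory artifacts
#'   of the executed stages.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list(out_dir = config$out_dir)
  on_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  has <- function(s) s %in% config$stages

  if (has("simulate")) on_stage("simulate", {
    scfg <- config$synthetic
    scfg$seed <- child_seed(config$seed, "simulate")
    art$cohort <- generate_cohort(scfg)
    cdir <- file.path(config$out_dir, "cohort")
    paths <- write_cohort(art$cohort, cdir)
    write_manifest(cdir, "simulate",
                   list(seed = scfg$seed, config = unclass(scfg)), paths)
  })
  if (has("modules")) on_stage("modules", {
    co <- art$cohort
    if (is.null(co)) stopf("no cohort available; enable the simulate stage")
    art$modules <- coexpression_modules(co$expression, co$labels,
                                        config$coexpr)
    mdir <- file.path(config$out_dir, "modules")
    dir.create(mdir, showWarnings = FALSE)
    write.table(data.frame(gene = names(art$modules$modules),
                           module = art$modules$modules),
                file.path(mdir, "module_assignment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(art$modules$trait_stats)) {
      st <- art$modules$trait_stats
      st$size <- as.integer(table(art$modules$modules[art$modules$modules > 0]))
      write.csv(st, file.path(mdir, "module_stats.csv"), row.names = FALSE)
    }
    write.csv(data.frame(gene = names(art$modules$gene_significance),
                         gs = art$modules$gene_significance),
              file.path(mdir, "gene_significance.csv"), row.names = FALSE)
    write_manifest(mdir, "modules",
                   list(seed = config$seed, config = unclass(config$coexpr)))
  })
  if (has("select_genes")) on_stage("select_genes", {
    co <- art$cohort; mo <- art$modules
    if (is.null(co) || is.null(mo))
      stopf("select_genes needs the simulate and modules stages")
    expr <- mo$expression
    labels <- co$labels[colnames(expr)]
    deg <- deg_test(expr, labels, config$alpha)
    cand <- deg$retained
    ora <- NULL
    if (!is.null(config$gmt)) {
      sets <- read_gmt(config$gmt)
      ora <- ora_enrichment(cand, rownames(expr), sets, config$alpha)
      enriched <- unique(unlist(ora$overlap_genes[ora$retained]))
      if (length(enriched)) cand <- intersect(cand, enriched)
    }
    uni <- if (length(cand))
      univariate_screen(expr, labels, cand, config$alpha)
    hub <- gs_rank(mo$gene_significance,
                   min(config$top_k, length(mo$gene_significance)))
    art$selection <- list(deg = deg, ora = ora, univariate = uni, hub = hub)
    sdir <- file.path(config$out_dir, "selection")
    dir.create(sdir, showWarnings = FALSE)
    write.csv(deg$table, file.path(sdir, "deg.csv"), row.names = FALSE)
    if (!is.null(ora))
      write.csv(ora[setdiff(names(ora), "overlap_genes")],
                file.path(sdir, "ora.csv"), row.names = FALSE)
    if (!is.null(uni))
      write.csv(uni$table, file.path(sdir, "univariate.csv"),
                row.names = FALSE)
    write.csv(data.frame(gene = hub), file.path(sdir, "hub_genes.csv"),
              row.names = FALSE)
    write_manifest(sdir, "select_genes",
                   list(seed = config$seed,
                        config = list(alpha = config$alpha,
                                      top_k = config$top_k)))
  })
  if (has("build_graphs")) on_stage("build_graphs", {
    co <- art$cohort; mo <- art$modules; sel <- art$selection
    if (is.null(co) || is.null(mo))
      stopf("build_graphs needs earlier stages")
    edges <- clean_edges(
      co$ppi_edges[co$ppi_edges$combined_score >= config$score_min, ])
    gene_sets <- switch(config$gene_stage,
      modules = {
        mods <- mo$modules[mo$modules > 0]
        split(names(mods), paste0("module", sprintf("%02d", mods)))
      },
      deg = list(deg = sel$deg$retained),
      univariate = list(univariate = sel$univariate$retained),
      gs = list(hub = sel$hub))
    gene_sets <- gene_sets[lengths(gene_sets) > 0]
    if (!length(gene_sets)) stopf("gene stage '%s' selected no genes",
                                  config$gene_stage)
    art$graphs <- build_ppi_graphs(edges, gene_sets, mo$expression)
    if (!length(art$graphs))
      stopf("no PPI network formed for any gene set")
    gdir <- file.path(config$out_dir, "graphs")
    dir.create(gdir, showWarnings = FALSE)
    jsonlite::write_json(
      lapply(art$graphs, function(g)
        list(name = g$name, nodes = g$nodes, edges = g$edges,
             no_ppi = g$no_ppi)),
      file.path(gdir, "graphs.json"), auto_unbox = TRUE, digits = NA)
    write_manifest(gdir, "build_graphs",
                   list(seed = config$seed,
                        config = list(gene_stage = config$gene_stage,
                                      score_min = config$score_min)))
  })
  if (has("select_features")) on_stage("select_features", {
    co <- art$cohort
    if (is.null(co)) stopf("select_features needs the simulate stage")
    scr <- rbind(select_features(co$radiomic_pet, co$labels,
                                 config$auc_threshold, modality = "pet"),
                 select_features(co$radiomic_ct, co$labels,
                                 config$auc_threshold, modality = "ct"))
    art$roc_screen <- scr
    fdir <- file.path(config$out_dir, "features")
    dir.create(fdir, showWarnings = FALSE)
    write.csv(scr, file.path(fdir, "roc_screen.csv"), row.names = FALSE)
    write_manifest(fdir, "select_features",
                   list(seed = config$seed,
                        config = list(threshold = config$auc_threshold)))
  })
  if (has("train")) on_stage("train", {
    co <- art$cohort
    if (is.null(art$graphs)) stopf("train needs the build_graphs stage")
    image <- NULL
    if (config$images != "none") {
      tabs <- list(pet = co$radiomic_pet, ct = co$radiomic_ct)
      use <- if (config$images == "petct") c("pet", "ct") else config$images
      mats <- lapply(use, function(mod) {
        m <- tabs[[mod]]
        if (config$feature_mode == "selected") {
          scr <- art$roc_screen
          if (is.null(scr)) stopf("selected feature mode needs select_features")
          keep <- scr$feature[scr$modality == mod & scr$selected]
          m <- m[, keep, drop = FALSE]
        }
        colnames(m) <- paste(mod, colnames(m)); m
      })
      image <- do.call(cbind, mats)
      if (!ncol(image)) stopf("no image features selected")
    }
    label <- sprintf("%s x %s(%s)", config$gene_stage, config$images,
                     config$feature_mode)
    art$report <- cross_validate(art$graphs, image,
                                 co$labels, config$fusion, k = config$k,
                                 repeats = config$repeats,
                                 seed = child_seed(config$seed, "train"),
                                 smote_cfg = config$smote,
                                 hyper = config$train, label = label)
    tdir <- file.path(config$out_dir, "train")
    dir.create(tdir, showWarnings = FALSE)
    write.csv(art$report$folds, file.path(tdir, "fold_metrics.csv"),
              row.names = FALSE)
    write_manifest(tdir, "train",
                   list(seed = child_seed(config$seed, "train"),
                        config = list(k = config$k,
                                      repeats = config$repeats,
                                      images = config$images,
                                      feature_mode = config$feature_mode,
                                      leakage_mode = config$smote$leakage_mode)))
  })
  if (has("report")) on_stage("report", {
    if (is.null(art$report)) stopf("report needs the train stage")
    rdir <- file.path(config$out_dir, "report")
    dir.create(rdir, showWarnings = FALSE)
    agg <- art$report$aggregate
    tab <- data.frame(configuration = art$report$label,
                      metric = names(agg),
                      mean = vapply(agg, function(a) a$mean, 0),
                      ci_lower = vapply(agg, function(a) a$lower, 0),
                      ci_upper = vapply(agg, function(a) a$upper, 0))
    write.csv(tab, file.path(rdir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(list(label = art$report$label, aggregate = agg,
                              k = art$report$k,
                              repeats = art$report$repeats,
                              seed = art$report$seed,
                              leakage_mode = art$report$leakage_mode),
                         file.path(rdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(art)
}
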