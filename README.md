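# radiogat

Radiogenomic prediction of lymph-node metastasis in non-small cell lung
cancer, for researchers combining tumor gene expression with PET/CT
radiomic features. The package implements the full analysis pipeline as
tested, reusable R functions:

1. **Co-expression modules** — weighted correlation network analysis:
   soft-threshold adjacency `a_ij = |cor(x_i, x_j)|^β` (default β = 5),
   topological overlap `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) +
   1 − a_ij)`, average-linkage clustering of `1 − TOM`, module eigengenes,
   module–trait correlation and gene significance `GS_g = |cor(x_g, y)|`.
2. **Gene selection cascade** — Welch t-test DEGs, hypergeometric pathway
   over-representation on GMT gene sets, univariate logistic screening,
   and top-k hub genes by GS.
3. **PPI graphs** — induced subgraphs of a STRING-style edge list
   (`protein1`, `protein2`, `combined_score`; default floor 400) per gene
   module or selected gene set, with per-sample z-scored expression as
   node features.
4. **Radiomic screening** — per-feature Mann–Whitney AUC with the
   Hanley–McNeil standard error (`Q1 = A/(2−A)`, `Q2 = 2A²/(1+A)`),
   z-statistic against 0.5, and inclusive selection at AUC ≥ 0.68.
5. **Graph-attention fusion classifier** — per-graph stacks of three GNN
   blocks (3-head GAT with head averaging, ReLU, batch norm, dropout),
   max-pool graph readout, an FC/ReLU/batch-norm image branch, and a
   two-layer softmax classifier over the concatenated embeddings. Forward
   and backward passes are implemented in the package (edge-attention
   kernels in C++), with SMOTE class balancing, full-batch Adam, and
   repeated stratified k-fold evaluation reporting accuracy, precision,
   recall, F1 and AUC with 95% confidence intervals.

A synthetic-cohort generator (`generate_cohort()`) reproduces the data
structure the pipeline assumes — block-correlated gene modules from a
latent factor model, label-associated signal genes, module-dense PPI
edges, and radiomic features with binormally controlled AUC — so every
stage can be exercised and validated without access to restricted
patient data.

## Worked example

```r
library(radiogat)

# simulate a cohort with the default study structure: 73 vs 20 samples,
# three 50-gene modules, 4 signal genes (d = 1.5), 5 planted radiomic
# features per modality at AUC 0.8
cohort <- generate_cohort(synthetic_config(seed = 7))
#> Synthetic cohort: 300 genes x 93 samples (73/20), 1887 PPI edges,
#> 55 radiomic features/modality

# discover co-expression modules
modules <- coexpression_modules(cohort$expression, cohort$labels)
#> Co-expression modules: 300 genes, 3 modules (147 unassigned)

# screen PET radiomic features at the inclusive AUC threshold of 0.68
screen <- select_features(cohort$radiomic_pet, cohort$labels,
                          threshold = 0.68, modality = "pet")
head(screen[order(-screen$auc), c("feature", "auc", "se", "z", "p", "selected")], 5)
#>               feature       auc         se        z            p selected
#> 4     SHAPE Compacity 0.8753425 0.05238195 7.165492 7.750743e-13     TRUE
#> 5          GLRLM GLNU 0.8404110 0.05789977 5.879314 4.119696e-09     TRUE
#> 2   SHAPE Volume (mL) 0.7815068 0.06487992 4.338890 1.432042e-05     TRUE
#> 3 SHAPE Volume (# vx) 0.7643836 0.06646885 3.977556 6.962734e-05     TRUE
#> 1                 TLG 0.7609589 0.06676564 3.908581 9.283988e-05     TRUE

# attributed PPI graphs for the detected modules
mods <- modules$modules[modules$modules > 0]
graphs <- build_ppi_graphs(cohort$ppi_edges,
                           split(names(mods), paste0("module", mods)),
                           modules$expression)
graphs[[1]]
#> PPI graph 'module1': 52 nodes, 381 edges [features attached]

# cross-validate the fused classifier (SMOTE inside training folds)
img <- cohort$radiomic_pet[, screen$feature[screen$selected], drop = FALSE]
report <- cross_validate(graphs, img, cohort$labels, k = 5, seed = 1,
                         hyper = train_config(lr = 5e-3, epochs = 50),
                         label = "modules x pet(selected)")
report
#> Evaluation report 'modules x pet(selected)' (5-fold x 1 repeats, SMOTE: fold_train_only)
#>   accuracy  0.8281  (95% CI = 0.7313-0.9249)
#>   precision 0.5946  (95% CI = 0.4286-0.7606)
#>   recall    0.9000  (95% CI = 0.7800-1.0200)
#>   f1        0.7077  (95% CI = 0.5610-0.8545)
#>   auc       0.9150  (95% CI = 0.8464-0.9836)
```

The five screened features are exactly the planted discriminative ones
(the binormal targets of 0.8 plus sampling noise at n = 93), and the fused
model separates the classes far better than chance — the planted signal
genes and image features carry the label, and the report quantifies how
much of it survives honest fold-wise evaluation. `run_pipeline()` chains
all stages (simulation through report) from a single `pipeline_config()`
or YAML file, writing per-stage artifacts and seed-stamped manifests;
`compare_configs()` tests two configurations against each other on shared
splits.

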