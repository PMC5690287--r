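#!/usr/bin/env Rscript

# Step 2 -- normalisation, detectability, stage of maximum expression,
# sample correlation structure and sample-space PCA.

source("analysis/00_setup.R")
ds <- read_dataset(data_dir)

det <- detectable_genes(ds)
cat(sprintf("%d of %d genes are detectable (>0 TPM in all replicates of at least one stage).\n",
            length(det), nrow(ds$counts)))

summ <- stage_name_summary(ds)
stagecourse:::write_tsv_file(summ,
                             file.path(results_dir, "stage_name_summary.tsv"))
peak_stage <- summ$stage[which.max(summ$named + summ$unnamed)]
cat(sprintf("Stage with most expression maxima: %s.\n", peak_stage))

cm <- sample_correlation_matrix(ds)
stagecourse:::write_matrix_tsv(round(cm, 4),
                               file.path(results_dir, "sample_correlation.tsv"),
                               id_col = "sample_id")
same <- outer(ds$samples$stage, ds$samples$stage, "==") & upper.tri(cm)
diff <- !outer(ds$samples$stage, ds$samples$stage, "==") & upper.tri(cm)
cat(sprintf("Mean Spearman rho: %.3f within stages, %.3f between stages.\n",
            mean(cm[same]), mean(cm[diff])))

pca <- pca_samples(ds, gene_set = config$pca_gene_set,
                   contribution_threshold = config$pca_contribution_threshold)
stagecourse:::write_matrix_tsv(round(pca$scores, 4),
                               file.path(results_dir, "pca_scores.tsv"),
                               id_col = "sample_id")
vf <- pca$variance_fraction
cat(sprintf("PC1 explains %.1f%% of variance; PC1-3 %.1f%%; PC1-6 %.1f%%.\n",
            100 * vf[1], 100 * sum(vf[1:3]), 100 * sum(vf[1:6])))
cat(sprintf("Genes contributing > %.2f%% to PC1: %d.\n",
            100 * config$pca_contribution_threshold,
            length(pca$top_contributors[[1]])))
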