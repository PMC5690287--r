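#!/usr/bin/env Rscript

# Step 3 -- co-expression graph and Markov clustering.
# Genes are linked when the Pearson correlation of their TPM profiles
# reaches the threshold; MCL partitions the graph and clusters smaller
# than the minimum size are set aside.

source("analysis/00_setup.R")
ds <- read_dataset(data_dir)

graph <- build_correlation_graph(ds, config$cor_threshold,
                                 gene_ids = detectable_genes(ds))
cat(sprintf("Graph at r >= %.2f: %d nodes, %d edges (%d zero-variance genes dropped).\n",
            config$cor_threshold, length(graph$nodes), nrow(graph$edges),
            graph$n_zero_variance))

clusters <- filter_clusters(
  mcl(graph, inflation = config$mcl_inflation,
      expansion = config$mcl_expansion, tol = config$mcl_tol,
      prune = config$mcl_prune, max_iter = config$mcl_max_iter),
  config$min_cluster_size)
cat(sprintf("MCL: %d clusters of >= %d genes (sizes %s); %d genes unassigned.\n",
            length(clusters$clusters), config$min_cluster_size,
            paste(lengths(clusters$clusters), collapse = ", "),
            length(clusters$unassigned)))

stagecourse:::write_tsv_file(cluster_table(clusters),
                             file.path(results_dir, "clusters.tsv"))
profiles <- vapply(clusters$clusters, cluster_profile, dataset = ds,
                   numeric(ncol(ds$tpm)))
stagecourse:::write_matrix_tsv(round(t(profiles), 4),
                               file.path(results_dir, "cluster_profiles.tsv"),
                               id_col = "cluster")
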