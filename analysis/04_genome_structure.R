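#!/usr/bin/env Rscript

# Step 4 -- chromosome over-representation within clusters,
# sliding-window co-expression domains, and promoter/peak overlap.

source("analysis/00_setup.R")
ds <- read_dataset(data_dir)
det <- detectable_genes(ds)
clusters_tab <- stagecourse:::read_tsv_file(
  file.path(results_dir, "clusters.tsv"))
clusters <- structure(
  list(clusters = split(clusters_tab$gene_id, clusters_tab$cluster),
       unassigned = character(0), provenance = list()),
  class = "cluster_set")

enr <- chromosome_enrichment(clusters, ds$genes, universe = det,
                             alpha = config$enrich_fdr,
                             min_count = config$enrich_min_count,
                             log2fe_threshold = config$enrich_log2fe)
stagecourse:::write_tsv_file(enr, file.path(results_dir,
                                            "chromosome_enrichment.tsv"))
sig <- enr[enr$significant, ]
cat(sprintf("Chromosome enrichment: %d (cluster, chromosome) pairs tested, %d reported.\n",
            nrow(enr), nrow(sig)))
if (nrow(sig) > 0) {
  cat(sprintf("  cluster %d on %s: %d genes vs %.2f expected, log2FE %.2f, adj p %.2e\n",
              sig$cluster, sig$chromosome, sig$count, sig$expected,
              sig$log2_fe, sig$adjusted_p))
}

dom <- sliding_window_domains(ds, w = config$window_size,
                              threshold = config$window_cor_threshold,
                              gene_ids = det, merge = config$domain_merge)
cat(sprintf("Co-expression domains (w = %d, mean r > %.1f): %d region(s).\n",
            config$window_size, config$window_cor_threshold, nrow(dom)))
if (nrow(dom) > 0) {
  write_bed(data.frame(chromosome = dom$chromosome, start = dom$start,
                       end = dom$end,
                       name = paste0("domain", seq_len(nrow(dom))),
                       score = round(100 * dom$peak_window_cor)),
            file.path(results_dir, "domains.bed"))
  truth_dom <- stagecourse:::read_tsv_file(
    file.path(results_dir, "truth_domains.tsv"))
  members <- unlist(attr(dom, "members"))
  cat(sprintf("  planted block recovery: %d/%d member genes found.\n",
              sum(truth_dom$gene_id %in% members), nrow(truth_dom)))
}

prom <- promoter_intervals(ds$genes, up = config$promoter_upstream,
                           down = config$promoter_downstream)
write_bed(data.frame(prom[, c("chromosome", "start", "end")],
                     name = prom$gene_id, strand = prom$strand),
          file.path(results_dir, "promoters.bed"))
stage <- stage_levels(ds)[zga_stage_index(length(stage_levels(ds)))]
cls <- expression_classes(ds, stage, config$expressed_tpm)
pk <- generate_peak_fixture(ds, stage,
                            seed = stagecourse:::derive_seed(config$seed,
                                                             "pipeline"))
ov <- peak_overlap_summary(prom, pk$peaks, cls$expressed, cls$silent)
stagecourse:::write_tsv_file(ov, file.path(results_dir, "peak_overlap.tsv"))
cat(sprintf("Promoter-mark overlap at %s: %.1f%% of %d expressed vs %.1f%% of %d silent genes.\n",
            stage, ov$percent[1], ov$total[1], ov$percent[2], ov$total[2]))
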